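# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Hamming distance between two equal-length strings (byte comparison).
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Hamming distance of one string against each row of a raw matrix
# (sequences stored as raw bytes, one row per sequence).
hamming_to_rows <- function(raw_mat, s) {
  sr <- charToRaw(s)
  rowSums(raw_mat != matrix(sr, nrow = nrow(raw_mat), ncol = length(sr),
                            byrow = TRUE))
}

seqs_to_raw_matrix <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(raw(0), nrow = 0, ncol = 0))
  L <- nchar(seqs[1])
  matrix(unlist(lapply(seqs, charToRaw), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE)
}

# Locale-independent (C byte order) sort, for deterministic tie-breaks.
sort_c <- function(x) sort(x, method = "radix")

# All k-mers of a sequence.
kmers_of <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  unique(substring(s, 1:(L - k + 1L), k:L))
}

random_dna <- function(n, length) {
  vapply(seq_len(n),
         function(i) paste(sample(DNA_BASES, length, replace = TRUE),
                           collapse = ""),
         character(1))
}

# Mean Phred quality of a Sanger (Phred+33) quality string.
mean_qv <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

phred_string <- function(qv, length) {
  strrep(intToUtf8(33L + qv, multiple = TRUE), length)
}

assert_reads <- function(reads, arg = "reads") {
  if (!is.data.frame(reads) ||
      !all(c("read_id", "sequence", "quality") %in% names(reads))) {
    abort(paste0("`", arg, "` must be a data frame with columns ",
                 "`read_id`, `sequence` and `quality`."))
  }
  invisible(reads)
}
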