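#' Preprocessing parameters
#'
#' Defaults follow the standard transposon-display workflow: mean read
#' quality at least 30, trimming to a fixed 50 bp, and collapsing any
#' sequence seen 10 or more times to a single representative.
#'
#' @param adapter_sequence Adapter to trim from the 3' side.
#' @param retro_tag Optional retrotransposon end tag removed from the 5'
#'   side before anything else; reads not starting with it are discarded.
#'   `NULL` skips tag removal.
#' @param min_qv Minimum mean Phred quality to retain a read. Default 30.
#' @param trim_length Fixed length reads are cut to. Default 50.
#' @param collapse_threshold Multiplicity at or above which identical
#'   sequences collapse to one. Default 10; must be >= 2.
#'
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter_sequence = "AGATCGGAAGAGC",
                              retro_tag = NULL,
                              min_qv = 30,
                              trim_length = 50L,
                              collapse_threshold = 10L) {
  if (trim_length < 1) abort("`trim_length` must be >= 1.")
  if (collapse_threshold < 2) abort("`collapse_threshold` must be >= 2.")
  structure(
    list(adapter_sequence = adapter_sequence, retro_tag = retro_tag,
         min_qv = min_qv, trim_length = as.integer(trim_length),
         collapse_threshold = as.integer(collapse_threshold)),
    class = "preprocess_params"
  )
}

#' Remove the 5' retrotransposon tag
#'
#' Strips `tag` from the start of each read; reads whose prefix differs from
#' the tag at more than `max_mismatch` positions are discarded as off-target.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `quality`, ...).
#' @param tag Tag sequence.
#' @param max_mismatch Mismatches tolerated in the prefix. Default 1.
#' @return The reads with the tag removed, tag-less reads dropped.
#' @export
trim_tag <- function(reads, tag, max_mismatch = 1L) {
  assert_reads(reads)
  if (nrow(reads) == 0L) return(reads)
  tl <- nchar(tag)
  prefix <- substr(reads$sequence, 1, tl)
  mm <- rep(0L, nrow(reads))
  for (j in seq_len(tl)) {
    mm <- mm + (substr(prefix, j, j) != substr(tag, j, j))
  }
  keep <- nchar(reads$sequence) > tl & mm <= max_mismatch
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substr(out$sequence, tl + 1L, nchar(out$sequence))
  out$quality <- substr(out$quality, tl + 1L, nchar(out$quality))
  out
}

#' Trim adapter occurrences from reads
#'
#' Truncates each read at the leftmost occurrence of the full adapter:
#' exact matches always count, and matches with at most one mismatch count
#' when the adapter is at least 8 bases long. Reads without an occurrence
#' pass through unchanged. Partial adapter overhangs shorter than the full
#' adapter are left in place (downstream fixed-length trimming removes them
#' from the analysed prefix).
#'
#' @param reads Read tibble.
#' @param adapter_sequence Adapter string (non-empty).
#' @return The reads with sequences and qualities truncated in step.
#' @export
trim_adapter <- function(reads, adapter_sequence) {
  assert_reads(reads)
  if (!nzchar(adapter_sequence)) abort("`adapter_sequence` must be non-empty.")
  if (nrow(reads) == 0L) return(reads)
  max_mm <- if (nchar(adapter_sequence) >= 8L) 1L else 0L
  subj <- Biostrings::DNAStringSet(reads$sequence)
  hits <- Biostrings::vmatchPattern(adapter_sequence, subj,
                                    max.mismatch = max_mm,
                                    with.indels = FALSE)
  starts <- vapply(Biostrings::startIndex(hits),
                   function(s) if (is.null(s) || length(s) == 0L) NA_integer_
                               else min(s),
                   integer(1))
  cut <- !is.na(starts)
  reads$sequence[cut] <- substr(reads$sequence[cut], 1L, starts[cut] - 1L)
  reads$quality[cut] <- substr(reads$quality[cut], 1L, starts[cut] - 1L)
  reads
}

#' Filter reads on mean quality
#'
#' Retains exactly the reads whose mean Phred quality value is at least
#' `min_qv`. Sequences are never altered.
#'
#' @param reads Read tibble.
#' @param min_qv Minimum mean QV. Default 30.
#' @return The retained reads.
#' @export
quality_filter <- function(reads, min_qv = 30) {
  assert_reads(reads)
  if (min_qv < 0) abort("`min_qv` must be >= 0.")
  if (nrow(reads) == 0L) return(reads)
  reads[nchar(reads$quality) > 0L & mean_qv(reads$quality) >= min_qv, ,
        drop = FALSE]
}

#' Trim reads to a fixed length
#'
#' Cuts every read to its first `trim_length` bases; reads shorter than
#' `trim_length` are discarded.
#'
#' @param reads Read tibble.
#' @param trim_length Target length. Default 50.
#' @return Reads of uniform length `trim_length`.
#' @export
fixed_length_trim <- function(reads, trim_length = 50L) {
  assert_reads(reads)
  if (trim_length < 1) abort("`trim_length` must be >= 1.")
  out <- reads[nchar(reads$sequence) >= trim_length, , drop = FALSE]
  out$sequence <- substr(out$sequence, 1L, trim_length)
  out$quality <- substr(out$quality, 1L, trim_length)
  out
}

#' Collapse highly duplicated reads
#'
#' Counts identical sequences (exact string equality) per cultivar. A
#' sequence observed `m` times keeps multiplicity `m` when
#' `m < collapse_threshold` and collapses to multiplicity 1 otherwise.
#' The operation is idempotent and accepts either raw reads (one row per
#' read) or an already-collapsed table carrying a `multiplicity` column.
#'
#' @param reads Tibble with `sequence` and optionally `cultivar` and
#'   `multiplicity` columns. All sequences must share one length.
#' @param collapse_threshold Collapse threshold. Default 10.
#' @return Tibble with `cultivar` (if present on input), `sequence`,
#'   `multiplicity`, ordered lexicographically by sequence within cultivar.
#' @export
collapse_duplicates <- function(reads, collapse_threshold = 10L) {
  if (!is.data.frame(reads) || !"sequence" %in% names(reads)) {
    abort("`reads` must be a data frame with a `sequence` column.")
  }
  if (collapse_threshold < 2) abort("`collapse_threshold` must be >= 2.")
  has_cv <- "cultivar" %in% names(reads)
  if (nrow(reads) == 0L) {
    out <- tibble(sequence = character(), multiplicity = integer())
    if (has_cv) out <- dplyr::bind_cols(tibble(cultivar = character()), out)
    return(out[, c(if (has_cv) "cultivar", "sequence", "multiplicity")])
  }
  lens <- unique(nchar(reads$sequence))
  if (length(lens) != 1L) {
    abort(paste0("Sequences have unequal lengths (", paste(sort(lens), collapse = ", "),
                 "); run fixed_length_trim() first."))
  }
  w <- if ("multiplicity" %in% names(reads)) reads$multiplicity else
    rep(1L, nrow(reads))
  df <- tibble(
    cultivar = if (has_cv) reads$cultivar else "library",
    sequence = reads$sequence,
    weight = w
  )
  out <- df |>
    dplyr::summarise(m = sum(.data$weight),
                     .by = c("cultivar", "sequence")) |>
    dplyr::mutate(multiplicity = ifelse(.data$m >= collapse_threshold,
                                        1L, as.integer(.data$m))) |>
    dplyr::select(!"m") |>
    dplyr::arrange(.data$cultivar, .data$sequence)
  if (!has_cv) out$cultivar <- NULL
  out
}

#' Run the full read-preprocessing pipeline
#'
#' Applies, in order: 5' tag removal (when `retro_tag` is set), adapter
#' trimming, mean-quality filtering, fixed-length trimming and duplicate
#' collapsing.
#'
#' @param reads Read tibble (e.g. from [generate_reads()] or [read_library()]).
#' @param params A [preprocess_params()].
#' @return Collapsed-read tibble (`cultivar`, `sequence`, `multiplicity`).
#' @export
#' @examples
#' ls <- simulate_landscape(2, 4, seed = 1)
#' cfg <- sim_config(depth = 5, error_rate = 0, seed = 1)
#' reads <- generate_reads(ls, cfg)
#' preprocess_reads(reads, preprocess_params(retro_tag = cfg$retro_tag))
preprocess_reads <- function(reads, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  if (!is.null(params$retro_tag)) {
    reads <- trim_tag(reads, params$retro_tag)
  }
  reads |>
    trim_adapter(params$adapter_sequence) |>
    quality_filter(params$min_qv) |>
    fixed_length_trim(params$trim_length) |>
    collapse_duplicates(params$collapse_threshold)
}
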