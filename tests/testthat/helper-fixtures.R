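# Shared helpers: small in-code fixtures and independent oracles.

# Random binary genotype matrix with labelled cultivars/markers.
rand_gm <- function(n_cultivars, n_markers, p = 0.4, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_cultivars * n_markers, 1, p), nrow = n_cultivars)
  geno <- tibble::as_tibble(m, .name_repair = ~ sprintf("m%02d", seq_len(n_markers)))
  geno <- dplyr::bind_cols(
    tibble::tibble(cultivar = sprintf("cv%02d", seq_len(n_cultivars))), geno)
  genotype_matrix(geno)
}

# Hand-built read tibble.
make_reads <- function(sequences, qv = 38, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(sequences))
  tibble::tibble(
    cultivar = "lib",
    read_id = ids,
    sequence = sequences,
    quality = strrep(intToUtf8(33L + qv, multiple = TRUE), nchar(sequences))
  )
}

random_seq <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), character(1))
}

mutate_at_positions <- function(s, pos) {
  chars <- strsplit(s, "")[[1]]
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  paste(chars, collapse = "")
}

str_hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# Independent minimal-set oracle: enumerate every subset of target-present
# markers as a bitmask and return the smallest unique size (Inf if none).
oracle_min_size <- function(gm, target) {
  m <- as.matrix(gm)
  cand <- colnames(m)[m[target, ] == 1L]
  others <- setdiff(rownames(m), target)
  if (length(cand) == 0L) return(Inf)
  best <- Inf
  for (mask in seq_len(2^length(cand) - 1L)) {
    members <- cand[bitwAnd(mask, 2^(seq_along(cand) - 1L)) > 0L]
    if (length(members) >= best) next
    sub <- m[others, members, drop = FALSE]
    if (!any(rowSums(sub) == length(members))) best <- length(members)
  }
  best
}

# Independent clustering oracle: connected components of the graph whose
# edges join sequences sharing an exact k-mer AND within Hamming distance d.
oracle_components <- function(seqs, k, d) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  kmers <- lapply(seqs, function(s)
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && any(kmers[[i]] %in% kmers[[j]]) &&
          str_hamming(seqs[i], seqs[j]) <= d) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v] == 0L) {
          comp[v] <- cur
          queue <- c(queue, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  comp
}
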