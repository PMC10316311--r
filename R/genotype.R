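#' Construct a presence/absence genotype matrix
#'
#' A `genotype_matrix` holds a binary cultivars-by-markers table (1 =
#' PCR fragment / insertion present) plus optional per-marker metadata.
#' A marker whose metadata `source` is `"positive_control"` must be present
#' in every cultivar.
#'
#' @param genotypes Data frame whose first column (named `cultivar`) holds
#'   unique cultivar labels and whose remaining columns are 0/1 marker
#'   columns with unique names.
#' @param markers Optional metadata: data frame with a `marker` column and
#'   any of `source` (one of `InDel`, `CIRE1`, `Tcs1`, `Tcs2`,
#'   `positive_control`) and `fragment_size` (bp).
#'
#' @return An object of class `genotype_matrix` with elements `genotypes`
#'   (tibble) and `markers` (tibble).
#' @export
#' @examples
#' gm <- genotype_matrix(tibble::tibble(cultivar = c("a", "b"),
#'                                      m1 = c(1, 0), m2 = c(1, 1)))
#' as.matrix(gm)
genotype_matrix <- function(genotypes, markers = NULL) {
  if (!is.data.frame(genotypes) || names(genotypes)[1] != "cultivar") {
    abort("`genotypes` must be a data frame whose first column is `cultivar`.")
  }
  genotypes <- as_tibble(genotypes)
  marker_ids <- names(genotypes)[-1]
  if (anyDuplicated(marker_ids)) abort("Marker ids must be unique.")
  if (anyDuplicated(genotypes$cultivar)) abort("Cultivar ids must be unique.")
  for (m in marker_ids) {
    v <- genotypes[[m]]
    if (!all(v %in% c(0, 1))) {
      abort(sprintf("Marker column '%s' has entries outside {0, 1}.", m))
    }
    genotypes[[m]] <- as.integer(v)
  }
  meta <- tibble(marker = marker_ids, source = NA_character_,
                 fragment_size = NA_real_)
  if (!is.null(markers)) {
    markers <- as_tibble(markers)
    if (!"marker" %in% names(markers)) {
      abort("`markers` metadata needs a `marker` column.")
    }
    markers <- dplyr::distinct(markers, .data$marker, .keep_all = TRUE)
    if ("source" %in% names(markers)) {
      meta$source <- markers$source[match(meta$marker, markers$marker)]
    }
    if ("fragment_size" %in% names(markers)) {
      meta$fragment_size <-
        markers$fragment_size[match(meta$marker, markers$marker)]
    }
    extra <- setdiff(names(markers),
                     c("marker", "source", "fragment_size", "target"))
    for (col in extra) {
      meta[[col]] <- markers[[col]][match(meta$marker, markers$marker)]
    }
  }
  pc <- meta$marker[!is.na(meta$source) & meta$source == "positive_control"]
  for (m in pc) {
    if (!all(genotypes[[m]] == 1L)) {
      abort(sprintf(
        "Positive-control marker '%s' must be present in every cultivar.", m))
    }
  }
  structure(list(genotypes = genotypes, markers = meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$genotypes), " cultivars x ",
      ncol(x$genotypes) - 1L, " markers\n", sep = "")
  print(x$genotypes, ...)
  invisible(x)
}

#' @export
as.matrix.genotype_matrix <- function(x, ...) {
  m <- as.matrix(x$genotypes[, -1, drop = FALSE])
  rownames(m) <- x$genotypes$cultivar
  storage.mode(m) <- "integer"
  m
}

#' Cultivar and marker accessors
#'
#' @param gm A [genotype_matrix()].
#' @return Character vector of labels.
#' @export
cultivars <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$genotypes$cultivar
}

#' @rdname cultivars
#' @export
marker_ids <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  names(gm$genotypes)[-1]
}

# Markers usable for discrimination: positive controls are excluded, as are
# all-present columns (they exclude no cultivar).
candidate_markers <- function(gm) {
  m <- as.matrix(gm)
  pc <- gm$markers$marker[!is.na(gm$markers$source) &
                            gm$markers$source == "positive_control"]
  cand <- setdiff(colnames(m), pc)
  cand[colSums(m[, cand, drop = FALSE]) < nrow(m)]
}

#' Call presence/absence from cluster read counts
#'
#' Applies the read-fraction rule: an insertion is scored absent in a
#' cultivar when its cluster's reads account for less than `threshold`
#' (default 0.1%) of all of that cultivar's post-preprocessing reads, and
#' present otherwise (a fraction exactly equal to the threshold counts as
#' present). Cultivars with zero total reads get an all-zero row and a
#' warning.
#'
#' @param clusters An `insertion_clusters` object from [cluster_reads()].
#' @param threshold Read-fraction cutoff in `(0, 1]`. Default 0.001.
#'
#' @return A [genotype_matrix()] with one marker column per cluster; the
#'   marker metadata carries each cluster's representative sequence.
#' @export
call_presence <- function(clusters, threshold = 0.001) {
  stopifnot(inherits(clusters, "insertion_clusters"))
  if (threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].")
  }
  if (any(clusters$counts$reads < 0)) abort("Negative read counts.")
  cvs <- clusters$totals$cultivar
  ids <- clusters$clusters$cluster_id
  totals <- clusters$totals$total_reads
  cnt <- matrix(0, nrow = length(cvs), ncol = length(ids),
                dimnames = list(cvs, ids))
  if (nrow(clusters$counts)) {
    cnt[cbind(match(clusters$counts$cultivar, cvs),
              match(clusters$counts$cluster_id, ids))] <- clusters$counts$reads
  }
  zero <- totals == 0
  if (any(zero)) {
    warn(paste0("Cultivar(s) with zero reads scored all-absent: ",
                paste(cvs[zero], collapse = ", ")))
  }
  frac <- cnt / ifelse(totals == 0, Inf, totals)
  entries <- matrix(as.integer(!(frac < threshold)), nrow = length(cvs),
                    dimnames = dimnames(cnt))
  entries[zero, ] <- 0L
  geno <- dplyr::bind_cols(tibble(cultivar = cvs), as_tibble(entries))
  genotype_matrix(geno,
                  markers = tibble(marker = ids,
                                   representative =
                                     clusters$clusters$representative))
}

#' Screen cultivar-specific markers
#'
#' Returns the markers present in exactly one cultivar, paired with that
#' cultivar. Positive-control markers are excluded.
#'
#' @param gm A [genotype_matrix()].
#' @return Tibble with columns `marker`, `cultivar`.
#' @export
#' @examples
#' screen_specific(citrus_genotypes())
screen_specific <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- as.matrix(gm)
  pc <- gm$markers$marker[!is.na(gm$markers$source) &
                            gm$markers$source == "positive_control"]
  m <- m[, setdiff(colnames(m), pc), drop = FALSE]
  cs <- colSums(m)
  hits <- colnames(m)[cs == 1L]
  tibble(
    marker = hits,
    cultivar = vapply(hits, function(j) rownames(m)[m[, j] == 1L],
                      character(1), USE.NAMES = FALSE)
  )
}

#' Screen polymorphic markers
#'
#' Returns the markers that are neither all-present nor all-absent across
#' cultivars (monomorphic columns, including any positive control, fall out
#' by construction).
#'
#' @param gm A [genotype_matrix()].
#' @return Tibble with columns `marker`, `n_present`.
#' @export
screen_polymorphic <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- as.matrix(gm)
  cs <- colSums(m)
  keep <- cs > 0L & cs < nrow(m)
  tibble(marker = colnames(m)[keep], n_present = as.integer(cs[keep]))
}
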