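#' Clustering parameters
#'
#' The clusterer is a deterministic greedy seeded-Hamming procedure: a
#' sequence joins the first cluster whose representative shares at least one
#' exact `seed_kmer`-mer with it and lies within `max_mismatch` Hamming
#' distance; otherwise it founds a new cluster. The defaults (8-mer seed,
#' 2 mismatches) mirror the tile-size-8 / one-off-2 settings customary for
#' self-alignment clustering of 50-mers.
#'
#' @param seed_kmer Exact seed k-mer length, in `[1, 50]`. Default 8.
#' @param max_mismatch Maximum Hamming distance to a representative, in
#'   `[0, 5]`. Default 2.
#' @param min_cluster_reads Drop clusters with fewer total reads. Default 1
#'   (keep all).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(seed_kmer = 8L, max_mismatch = 2L,
                           min_cluster_reads = 1L) {
  if (seed_kmer < 1 || seed_kmer > 50) abort("`seed_kmer` must be in [1, 50].")
  if (max_mismatch < 0 || max_mismatch > 5) {
    abort("`max_mismatch` must be in [0, 5].")
  }
  structure(
    list(seed_kmer = as.integer(seed_kmer),
         max_mismatch = as.integer(max_mismatch),
         min_cluster_reads = as.integer(min_cluster_reads)),
    class = "cluster_params"
  )
}

#' Cluster trimmed reads into insertion sites
#'
#' Groups distinct trimmed sequences into clusters, one per putative
#' retrotransposon insertion site, and tallies per-cultivar read counts.
#' Distinct sequences are processed in descending total multiplicity
#' (lexicographic tie-break); each joins the earliest-founded cluster whose
#' representative shares an exact seed k-mer and is within the mismatch
#' budget, else founds a new cluster with itself as representative.
#'
#' @param collapsed Tibble with `cultivar`, `sequence`, `multiplicity`
#'   (output of [collapse_duplicates()] / [preprocess_reads()]). All
#'   sequences must share one length.
#' @param params A [cluster_params()].
#'
#' @return An object of class `insertion_clusters`: list with
#'   `clusters` (tibble: `cluster_id`, `representative`, `n_members`),
#'   `counts` (tibble: `cluster_id`, `cultivar`, `reads`) and
#'   `totals` (tibble: `cultivar`, `total_reads` — all post-preprocessing
#'   reads, including any in dropped clusters).
#' @export
#' @examples
#' x <- tibble::tibble(cultivar = "a",
#'                     sequence = strrep(c("A", "C"), 50),
#'                     multiplicity = c(5L, 3L))
#' cluster_reads(x)
cluster_reads <- function(collapsed, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (!is.data.frame(collapsed) ||
      !all(c("cultivar", "sequence", "multiplicity") %in% names(collapsed))) {
    abort("`collapsed` must have columns `cultivar`, `sequence`, `multiplicity`.")
  }
  totals <- collapsed |>
    dplyr::summarise(total_reads = sum(.data$multiplicity),
                     .by = "cultivar") |>
    dplyr::arrange(.data$cultivar)
  if (nrow(collapsed) == 0L) {
    return(structure(
      list(clusters = tibble(cluster_id = character(),
                             representative = character(),
                             n_members = integer()),
           counts = tibble(cluster_id = character(), cultivar = character(),
                           reads = integer()),
           totals = totals,
           params = params),
      class = "insertion_clusters"))
  }
  lens <- unique(nchar(collapsed$sequence))
  if (length(lens) != 1L) {
    abort(paste0("Sequences have unequal lengths (",
                 paste(sort(lens), collapse = ", "), ")."))
  }
  if (lens < params$seed_kmer) {
    abort("Sequences are shorter than `seed_kmer`.")
  }

  by_seq <- collapsed |>
    dplyr::summarise(total = sum(.data$multiplicity), .by = "sequence") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$sequence)
  seqs <- by_seq$sequence
  k <- params$seed_kmer

  assignment <- integer(length(seqs))
  rep_seqs <- character(0)
  rep_raw <- NULL          # raw matrix of representatives
  kmer_env <- new.env(parent = emptyenv())  # kmer -> integer vector of clusters
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    km <- kmers_of(s, k)
    cand <- integer(0)
    for (kk in km) {
      hit <- kmer_env[[kk]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    target <- 0L
    if (length(cand)) {
      cand <- sort(unique(cand))
      d <- hamming_to_rows(rep_raw[cand, , drop = FALSE], s)
      ok <- cand[d <= params$max_mismatch]
      if (length(ok)) target <- ok[1]   # earliest-founded cluster
    }
    if (target == 0L) {
      rep_seqs <- c(rep_seqs, s)
      rep_raw <- rbind(rep_raw, matrix(charToRaw(s), nrow = 1))
      target <- length(rep_seqs)
      for (kk in km) kmer_env[[kk]] <- c(kmer_env[[kk]], target)
    }
    assignment[i] <- target
  }

  ids <- sprintf("CL%04d", seq_along(rep_seqs))
  seq_cluster <- tibble(sequence = seqs, cluster_id = ids[assignment])
  counts <- collapsed |>
    dplyr::left_join(seq_cluster, by = "sequence") |>
    dplyr::summarise(reads = sum(.data$multiplicity),
                     .by = c("cluster_id", "cultivar")) |>
    dplyr::arrange(.data$cluster_id, .data$cultivar)
  clusters <- tibble(
    cluster_id = ids,
    representative = rep_seqs,
    n_members = as.integer(tabulate(assignment, nbins = length(rep_seqs)))
  )

  if (params$min_cluster_reads > 1L) {
    keep <- counts |>
      dplyr::summarise(n = sum(.data$reads), .by = "cluster_id") |>
      dplyr::filter(.data$n >= params$min_cluster_reads) |>
      dplyr::pull("cluster_id")
    clusters <- clusters[clusters$cluster_id %in% keep, , drop = FALSE]
    counts <- counts[counts$cluster_id %in% keep, , drop = FALSE]
  }

  structure(
    list(clusters = clusters, counts = counts, totals = totals,
         params = params),
    class = "insertion_clusters"
  )
}

#' @export
print.insertion_clusters <- function(x, ...) {
  cat("<insertion_clusters> ", nrow(x$clusters), " clusters across ",
      nrow(x$totals), " cultivars (",
      sum(x$totals$total_reads), " reads)\n", sep = "")
  invisible(x)
}
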