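#' Tidy a genotype matrix into long form
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return Tibble with `cultivar`, `marker`, `present` (integer 0/1) and the
#'   marker's `source`.
#' @exportS3Method
tidy.genotype_matrix <- function(x, ...) {
  x$genotypes |>
    tidyr::pivot_longer(!"cultivar", names_to = "marker",
                        values_to = "present") |>
    dplyr::left_join(x$markers[, c("marker", "source")], by = "marker")
}

#' One-row summary of a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return Tibble with `n_cultivars`, `n_markers`, `n_specific`,
#'   `n_polymorphic`.
#' @exportS3Method
glance.genotype_matrix <- function(x, ...) {
  tibble(
    n_cultivars = nrow(x$genotypes),
    n_markers = ncol(x$genotypes) - 1L,
    n_specific = nrow(screen_specific(x)),
    n_polymorphic = nrow(screen_polymorphic(x))
  )
}

#' Tidy a marker set
#'
#' @param x A `marker_set` (see [minimal_and_set()]).
#' @param ... Unused.
#' @return Tibble with one row per member marker.
#' @exportS3Method
tidy.marker_set <- function(x, ...) {
  tibble(target = x$target,
         marker = if (x$size) x$members else character(0))
}

#' One-row summary of a marker set
#'
#' @param x A `marker_set`.
#' @param ... Unused.
#' @return Tibble with `target`, `size`, `unique`, `n_offending`, `method`.
#' @exportS3Method
glance.marker_set <- function(x, ...) {
  tibble(target = x$target, size = x$size, unique = x$unique,
         n_offending = length(x$offending), method = x$method)
}

#' Tidy cluster read counts
#'
#' @param x An `insertion_clusters` object (see [cluster_reads()]).
#' @param ... Unused.
#' @return Tibble with `cluster_id`, `cultivar`, `reads`, `total_reads` and
#'   `fraction` of the cultivar's reads falling in the cluster.
#' @exportS3Method
tidy.insertion_clusters <- function(x, ...) {
  x$counts |>
    dplyr::left_join(x$totals, by = "cultivar") |>
    dplyr::mutate(fraction = .data$reads / .data$total_reads)
}

#' One-row summary of a clustering
#'
#' @param x An `insertion_clusters` object.
#' @param ... Unused.
#' @return Tibble with `n_clusters`, `n_cultivars`, `n_reads`.
#' @exportS3Method
glance.insertion_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_cultivars = nrow(x$totals),
         n_reads = sum(x$totals$total_reads))
}

#' Tidy a band pattern
#'
#' @param x A `band_pattern` (see [predict_bands()]).
#' @param ... Unused.
#' @return The line table with `target`, `sample` and `verdict` attached.
#' @exportS3Method
tidy.band_pattern <- function(x, ...) {
  dplyr::mutate(x$lines, target = x$target, sample = x$sample,
                verdict = diagnose(x))
}

#' Tidy an insertion landscape
#'
#' @param x An `insertion_landscape` (see [simulate_landscape()]).
#' @param ... Unused.
#' @return Long tibble with `cultivar`, `site_id`, `family`, `present`.
#' @exportS3Method
tidy.insertion_landscape <- function(x, ...) {
  long <- as_tibble(x$truth, rownames = "cultivar") |>
    tidyr::pivot_longer(!"cultivar", names_to = "site_id",
                        values_to = "present")
  dplyr::left_join(long, x$sites[, c("site_id", "family")], by = "site_id")
}
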