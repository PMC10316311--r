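#' Write a simulated library to disk
#'
#' Writes one Sanger (Phred+33) FASTQ file per cultivar, a `truth.tsv`
#' mapping read ids to insertion sites, and (when the landscape is supplied)
#' a `landscape.json` with cultivars, sites and the truth matrix.
#'
#' @param reads Read tibble as returned by [generate_reads()].
#' @param dir Output directory (created if missing).
#' @param landscape Optional `insertion_landscape` to serialise alongside.
#'
#' @return Invisibly, a tibble of the files written (`file`, `n_reads`).
#' @export
write_library <- function(reads, dir, landscape = NULL) {
  assert_reads(reads)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_cv <- split(reads, reads$cultivar)
  files <- purrr::imap(by_cv, function(df, cultivar) {
    path <- file.path(dir, paste0(cultivar, ".fastq"))
    dna <- Biostrings::DNAStringSet(df$sequence)
    names(dna) <- df$read_id
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = Biostrings::BStringSet(df$quality))
    tibble(file = path, n_reads = nrow(df))
  })
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(reads[, c("read_id", "cultivar", "site_id")], truth_path)
  out <- dplyr::bind_rows(files)
  out <- dplyr::bind_rows(out, tibble(file = truth_path, n_reads = nrow(reads)))
  if (!is.null(landscape)) {
    land_path <- file.path(dir, "landscape.json")
    jsonlite::write_json(
      list(cultivar_ids = landscape$cultivar_ids,
           sites = landscape$sites,
           truth = landscape$truth),
      land_path, dataframe = "columns", matrix = "rowmajor")
    out <- dplyr::bind_rows(out, tibble(file = land_path, n_reads = NA_integer_))
  }
  invisible(out)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file (Phred+33).
#' @param cultivar Optional cultivar label attached to every read; defaults
#'   to the file name without extension.
#'
#' @return Tibble with `cultivar`, `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path, cultivar = NULL) {
  cultivar <- cultivar %||% sub("\\.(fastq|fq)$", "", basename(path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(
    cultivar = cultivar,
    read_id = names(x),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Read a directory of per-cultivar FASTQ files
#'
#' @param dir Directory holding `<cultivar>.fastq` files.
#' @return Tibble of reads across all cultivars (possibly empty).
#' @export
read_library <- function(dir) {
  files <- sort_c(list.files(dir, pattern = "\\.(fastq|fq)$",
                             full.names = TRUE))
  if (length(files) == 0L) {
    return(tibble(cultivar = character(), read_id = character(),
                  sequence = character(), quality = character()))
  }
  dplyr::bind_rows(lapply(files, read_fastq))
}

#' Read a presence/absence genotype table
#'
#' Expects a TSV whose header row holds marker ids and whose first column
#' holds cultivar ids. Cells may be `1`/`0` or the gel-scoring symbols
#' `○` (presence) / `×` (absence). Duplicated marker columns are
#' collapsed to a single column when their contents are identical (the
#' published citrus table lists one marker under two target cultivars) and
#' rejected otherwise.
#'
#' @param path TSV file.
#' @param markers Optional marker metadata tibble with a `marker` column and
#'   any of `source`, `fragment_size`; matched by marker id.
#'
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, markers = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2L) abort("Genotype TSV needs a cultivar column and at least one marker column.")
  cultivars <- raw[[1]]
  marker_names <- names(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])

  decode <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("1", "○")] <- 1L
    out[x %in% c("0", "×")] <- 0L
    out
  }
  mat <- apply(cells, 2, decode)
  mat <- matrix(as.integer(mat), nrow = length(cultivars))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-binary genotype cell '%s' at row %d (cultivar '%s'), column '%s'.",
      cells[bad[1], bad[2]], bad[1], cultivars[bad[1]], marker_names[bad[2]]))
  }

  # collapse duplicated marker columns (must be identical)
  keep <- !duplicated(marker_names)
  for (nm in unique(marker_names[duplicated(marker_names)])) {
    cols <- which(marker_names == nm)
    ref <- mat[, cols[1]]
    if (!all(vapply(cols[-1], function(j) identical(mat[, j], ref), logical(1)))) {
      abort(sprintf("Duplicated marker column '%s' has conflicting entries.", nm))
    }
  }
  mat <- mat[, keep, drop = FALSE]
  colnames(mat) <- marker_names[keep]

  geno <- dplyr::bind_cols(tibble(cultivar = cultivars), as_tibble(mat))
  genotype_matrix(geno, markers = markers)
}

#' Write a genotype matrix as TSV
#'
#' Writes `1`/`0` cells with a `cultivar` first column; `read_genotype_tsv()`
#' of the result reproduces the object.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_genotype_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  readr::write_tsv(gm$genotypes, path, progress = FALSE)
  invisible(path)
}

#' Serialise and restore a clustering result
#'
#' Writes (or reads back) three TSV files sharing a path prefix:
#' `<prefix>_clusters.tsv`, `<prefix>_counts.tsv` and `<prefix>_totals.tsv`.
#'
#' @param clusters An `insertion_clusters` object (see [cluster_reads()]).
#' @param prefix Path prefix for the three files.
#' @return `write_clusters()` returns `prefix` invisibly; `read_clusters()`
#'   returns an `insertion_clusters` object.
#' @export
write_clusters <- function(clusters, prefix) {
  stopifnot(inherits(clusters, "insertion_clusters"))
  readr::write_tsv(clusters$clusters, paste0(prefix, "_clusters.tsv"),
                   progress = FALSE)
  readr::write_tsv(clusters$counts, paste0(prefix, "_counts.tsv"),
                   progress = FALSE)
  readr::write_tsv(clusters$totals, paste0(prefix, "_totals.tsv"),
                   progress = FALSE)
  invisible(prefix)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(prefix) {
  structure(
    list(
      clusters = readr::read_tsv(paste0(prefix, "_clusters.tsv"),
                                 col_types = "cci", progress = FALSE),
      counts = readr::read_tsv(paste0(prefix, "_counts.tsv"),
                               col_types = "cci", progress = FALSE),
      totals = readr::read_tsv(paste0(prefix, "_totals.tsv"),
                               col_types = "ci", progress = FALSE),
      params = cluster_params()),
    class = "insertion_clusters"
  )
}

#' Read marker metadata
#'
#' Reads a TSV with columns `marker`, `source`, `fragment_size` and
#' optionally `target` (the cultivar whose kit the row belongs to).
#'
#' @param path TSV file.
#' @return Tibble of marker metadata.
#' @export
read_marker_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    fragment_size = "d", .default = "c"), progress = FALSE)
}
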