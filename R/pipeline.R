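#' Pipeline configuration
#'
#' Collects every stage's parameters plus input/output paths into one
#' object. Exactly one input mode applies, checked in this order:
#' an existing genotype matrix (`matrix_tsv`), a directory of per-cultivar
#' FASTQ files (`fastq_dir`), or a seeded simulation (the default).
#' All randomness flows from `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed used for the simulation stage.
#' @param n_cultivars,n_sites,specific_fraction Landscape parameters for
#'   simulation mode (see [simulate_landscape()]).
#' @param sim A [sim_config()]; its `seed` is overwritten with `seed`.
#' @param preprocess A [preprocess_params()]; when `retro_tag` is unset it is
#'   filled from `sim`.
#' @param cluster A [cluster_params()].
#' @param threshold Presence-calling read fraction (see [call_presence()]).
#' @param max_k Largest marker-set size searched (see [minimal_and_set()]).
#' @param min_separation Fragment-size gap for kit design in bp.
#' @param targets Cultivars to build marker sets (and, when fragment sizes
#'   are known, kits) for; `NULL` means every cultivar.
#' @param matrix_tsv,markers_tsv Optional genotype matrix / marker metadata
#'   TSV paths (matrix mode).
#' @param fastq_dir Optional directory of FASTQ files (read mode).
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            n_cultivars = 26L,
                            n_sites = 100L,
                            specific_fraction = 0.1,
                            sim = sim_config(),
                            preprocess = preprocess_params(),
                            cluster = cluster_params(),
                            threshold = 0.001,
                            max_k = 4L,
                            min_separation = 30,
                            targets = NULL,
                            matrix_tsv = NULL,
                            markers_tsv = NULL,
                            fastq_dir = NULL) {
  sim$seed <- as.integer(seed)
  if (is.null(preprocess$retro_tag)) preprocess$retro_tag <- sim$retro_tag
  if (!identical(preprocess$adapter_sequence, sim$adapter_sequence) &&
      is.null(matrix_tsv) && is.null(fastq_dir)) {
    preprocess$adapter_sequence <- sim$adapter_sequence
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_cultivars = as.integer(n_cultivars),
         n_sites = as.integer(n_sites),
         specific_fraction = specific_fraction,
         sim = sim, preprocess = preprocess, cluster = cluster,
         threshold = threshold, max_k = as.integer(max_k),
         min_separation = min_separation, targets = targets,
         matrix_tsv = matrix_tsv, markers_tsv = markers_tsv,
         fastq_dir = fastq_dir),
    class = "pipeline_config"
  )
}

#' Run the identification pipeline end to end
#'
#' Executes the configured stages — simulate (or load reads / a matrix),
#' preprocess, cluster, genotype, screen, select minimal marker sets, and
#' (when fragment sizes are known) design kits and predict band patterns —
#' writing each stage's output plus MD5 checksums and a run log to
#' `config$out_dir`. Re-running with an identical config reproduces
#' identical data files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `genotypes` ([genotype_matrix()]),
#'   `specific`, `polymorphic`, `marker_sets`, `kits`, `bands`, `landscape`
#'   (or `NULL`) and `files`.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(pipeline_config(tempfile("ck"), seed = 7,
#'                                     n_cultivars = 4, n_sites = 8))
#' out$specific
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(
    sprintf("citruskit pipeline; seed=%d; param_hash=%s",
            config$seed, rlang::hash(config[setdiff(names(config), "out_dir")])))
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  landscape <- NULL
  markers_meta <- if (!is.null(config$markers_tsv)) {
    read_marker_tsv(config$markers_tsv)
  } else NULL

  if (!is.null(config$matrix_tsv)) {
    say("stage=input mode=matrix file=%s", config$matrix_tsv)
    gm <- read_genotype_tsv(config$matrix_tsv, markers = markers_meta)
  } else {
    if (!is.null(config$fastq_dir)) {
      say("stage=input mode=fastq dir=%s", config$fastq_dir)
      reads <- read_library(config$fastq_dir)
    } else {
      say("stage=simulate cultivars=%d sites=%d specific_fraction=%g",
          config$n_cultivars, config$n_sites, config$specific_fraction)
      landscape <- simulate_landscape(
        config$n_cultivars, config$n_sites, config$specific_fraction,
        seed = config$seed)
      reads <- generate_reads(landscape, config$sim)
    }
    say("stage=reads n=%d", nrow(reads))
    if (nrow(reads) == 0L) {
      warn("No input reads; the genotype matrix is empty.")
    }
    collapsed <- preprocess_reads(reads, config$preprocess)
    say("stage=preprocess distinct_sequences=%d reads=%d",
        nrow(collapsed), sum(collapsed$multiplicity))
    clusters <- cluster_reads(collapsed, config$cluster)
    say("stage=cluster clusters=%d", nrow(clusters$clusters))
    gm <- call_presence(clusters, config$threshold)
  }
  say("stage=genotype cultivars=%d markers=%d",
      nrow(gm$genotypes), ncol(gm$genotypes) - 1L)

  specific <- screen_specific(gm)
  polymorphic <- screen_polymorphic(gm)
  say("stage=screen specific=%d polymorphic=%d",
      nrow(specific), nrow(polymorphic))

  targets <- config$targets %||% cultivars(gm)
  marker_sets <- lapply(targets, function(tg)
    minimal_and_set(gm, tg, max_k = config$max_k))
  names(marker_sets) <- targets

  sizes <- gm$markers
  if (!is.null(markers_meta)) sizes <- markers_meta
  kits <- list()
  bands <- NULL
  for (tg in targets) {
    ms <- marker_sets[[tg]]
    known <- if (is.data.frame(sizes)) {
      all(ms$members %in% sizes$marker[!is.na(sizes$fragment_size)])
    } else FALSE
    ctrl_known <- is.data.frame(sizes) &&
      "rbcL" %in% sizes$marker[!is.na(sizes$fragment_size)]
    if (ms$unique && ms$size > 0 && ms$size <= 3 && known && ctrl_known) {
      kit <- tryCatch(design_kit(ms, sizes,
                                 min_separation = config$min_separation),
                      error = function(e) {
                        say("stage=kit target=%s skipped: %s", tg,
                            conditionMessage(e))
                        NULL
                      })
      if (!is.null(kit)) {
        kits[[tg]] <- kit
        db <- diagnose_all(kit, gm)
        db$target <- tg
        bands <- dplyr::bind_rows(bands, db)
      }
    } else {
      say("stage=kit target=%s skipped (unique=%s, sizes_known=%s)",
          tg, ms$unique, known && ctrl_known)
    }
  }
  say("stage=kit kits=%d", length(kits))

  files <- character(0)
  wr <- function(path) files <<- c(files, path)
  wr(write_genotype_tsv(gm, file.path(config$out_dir, "genotype_matrix.tsv")))
  readr::write_tsv(specific, file.path(config$out_dir, "specific_markers.tsv"),
                   progress = FALSE)
  wr(file.path(config$out_dir, "specific_markers.tsv"))
  readr::write_tsv(polymorphic,
                   file.path(config$out_dir, "polymorphic_markers.tsv"),
                   progress = FALSE)
  wr(file.path(config$out_dir, "polymorphic_markers.tsv"))
  jsonlite::write_json(
    lapply(marker_sets, function(ms) ms[c("target", "members", "size",
                                          "unique", "offending")]),
    file.path(config$out_dir, "marker_sets.json"), auto_unbox = TRUE)
  wr(file.path(config$out_dir, "marker_sets.json"))
  jsonlite::write_json(
    lapply(kits, function(k) list(target = k$target, lines = k$lines)),
    file.path(config$out_dir, "kits.json"), auto_unbox = TRUE,
    dataframe = "rows")
  wr(file.path(config$out_dir, "kits.json"))
  if (!is.null(bands)) {
    readr::write_tsv(bands, file.path(config$out_dir, "band_patterns.tsv"),
                     progress = FALSE)
    wr(file.path(config$out_dir, "band_patterns.tsv"))
  }
  if (!is.null(landscape)) {
    jsonlite::write_json(
      list(cultivar_ids = landscape$cultivar_ids, sites = landscape$sites,
           truth = landscape$truth),
      file.path(config$out_dir, "landscape.json"),
      dataframe = "columns", matrix = "rowmajor")
    wr(file.path(config$out_dir, "landscape.json"))
  }

  sums <- tibble(file = basename(files),
                 md5 = unname(tools::md5sum(files)))
  readr::write_tsv(sums, file.path(config$out_dir, "checksums.tsv"),
                   progress = FALSE)
  writeLines(log_lines, log_path)

  invisible(list(genotypes = gm, specific = specific,
                 polymorphic = polymorphic, marker_sets = marker_sets,
                 kits = kits, bands = bands, landscape = landscape,
                 files = files))
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Top-level keys map to [pipeline_config()] arguments; nested `sim`,
#' `preprocess` and `cluster` blocks map to the corresponding parameter
#' constructors.
#'
#' @param path YAML or JSON file.
#' @param out_dir Optional override of the file's `out_dir`.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path, out_dir = NULL) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build <- function(ctor, args) do.call(ctor, args %||% list())
  sim <- build(sim_config, cfg$sim)
  pp <- build(preprocess_params, cfg$preprocess)
  cl <- build(cluster_params, cfg$cluster)
  top <- cfg[setdiff(names(cfg), c("sim", "preprocess", "cluster"))]
  top$sim <- sim; top$preprocess <- pp; top$cluster <- cl
  if (!is.null(out_dir)) top$out_dir <- out_dir
  do.call(pipeline_config, top)
}
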