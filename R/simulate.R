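#' Simulation settings for a transposon-display library
#'
#' Bundles the knobs of the read simulator. Reads mimic single-end 150 bp
#' transposon-display sequences: a retrotransposon end tag, then the genomic
#' flank of the insertion site, then (for short inserts) adapter remnant.
#'
#' @param read_length Read length in bases. Default 150.
#' @param depth Reads generated per present insertion site per cultivar
#'   (before PCR duplication). Default 50.
#' @param error_rate Per-base substitution probability, in `[0, 0.25)`.
#' @param duplicate_lambda Poisson rate of extra identical copies per read;
#'   each read is emitted `1 + rpois(1, duplicate_lambda)` times. `0` disables
#'   duplication.
#' @param adapter_sequence Adapter remnant appended after the insert when the
#'   insert is shorter than the read.
#' @param retro_tag Retrotransposon end sequence that starts every on-target
#'   read.
#' @param qv_pass,qv_fail,qv_pass_rate Constant per-read quality value drawn
#'   from a two-point mixture: `qv_pass` with probability `qv_pass_rate`,
#'   otherwise `qv_fail`. Defaults 38 / 20 / 0.9 so a QV >= 30 filter is
#'   exercised.
#' @param background_fraction Off-target reads added per cultivar, as a
#'   fraction of that cultivar's on-target read count. Default 0.
#' @param seed Integer RNG seed; fixed seed gives byte-identical libraries.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' sim_config(depth = 10, error_rate = 0)
sim_config <- function(read_length = 150L,
                       depth = 50L,
                       error_rate = 0.001,
                       duplicate_lambda = 2,
                       adapter_sequence = "AGATCGGAAGAGC",
                       retro_tag = "TGTTGGAATCCTCAACGATG",
                       qv_pass = 38L,
                       qv_fail = 20L,
                       qv_pass_rate = 0.9,
                       background_fraction = 0,
                       seed = NULL) {
  if (read_length < nchar(retro_tag) + 50L) {
    abort("`read_length` must be at least `nchar(retro_tag)` + 50.")
  }
  if (error_rate < 0 || error_rate >= 0.25) {
    abort("`error_rate` must lie in [0, 0.25).")
  }
  if (depth < 1) abort("`depth` must be >= 1.")
  if (duplicate_lambda < 0) abort("`duplicate_lambda` must be >= 0.")
  if (background_fraction < 0 || background_fraction >= 1) {
    abort("`background_fraction` must lie in [0, 1).")
  }
  if (qv_pass_rate < 0 || qv_pass_rate > 1) {
    abort("`qv_pass_rate` must lie in [0, 1].")
  }
  if (!grepl("^[ACGT]+$", adapter_sequence) || !grepl("^[ACGT]+$", retro_tag)) {
    abort("`adapter_sequence` and `retro_tag` must be non-empty A/C/G/T strings.")
  }
  structure(
    list(read_length = as.integer(read_length),
         depth = as.integer(depth),
         error_rate = error_rate,
         duplicate_lambda = duplicate_lambda,
         adapter_sequence = adapter_sequence,
         retro_tag = retro_tag,
         qv_pass = as.integer(qv_pass),
         qv_fail = as.integer(qv_fail),
         qv_pass_rate = qv_pass_rate,
         background_fraction = background_fraction,
         seed = seed),
    class = "sim_config"
  )
}

#' Simulate an insertion landscape with known truth
#'
#' Draws a set of retrotransposon insertion sites (each with a family label
#' and a random genomic flanking sequence) and a binary cultivars-by-sites
#' truth matrix. A configurable fraction of sites is cultivar-specific
#' (present in exactly one cultivar); the rest are shared by two or more
#' cultivars. Flanking sequences are rejection-sampled so that every pair
#' differs at more than `2 * max_mismatch` positions over their first 50
#' bases, which makes downstream clusters unambiguous.
#'
#' @param n_cultivars Number of cultivars (>= 1).
#' @param n_sites Number of insertion sites (>= 1).
#' @param specific_fraction Fraction of sites present in exactly one cultivar;
#'   `round(specific_fraction * n_sites)` sites are made specific. Default 0.1,
#'   the rate observed across typical citrus retrotransposon libraries.
#' @param flank_length Length of each site's flanking sequence (>= 50).
#'   Default 130, so tag + flank fills a 150 bp read.
#' @param families Retrotransposon family labels sampled per site.
#' @param max_mismatch Clustering mismatch budget the flanks must beat; the
#'   pairwise-distance guarantee is `> 2 * max_mismatch` over the first 50 bp.
#' @param cultivar_ids Optional cultivar labels (length `n_cultivars`).
#' @param seed Integer RNG seed.
#'
#' @return An object of class `insertion_landscape`: a list with
#'   `cultivar_ids` (character), `sites` (tibble: `site_id`, `family`,
#'   `flank`) and `truth` (integer matrix, cultivars x sites, dimnames set).
#' @export
#' @examples
#' ls <- simulate_landscape(4, 10, specific_fraction = 0.2, seed = 1)
#' colSums(ls$truth)
simulate_landscape <- function(n_cultivars,
                               n_sites,
                               specific_fraction = 0.1,
                               flank_length = 130L,
                               families = c("CIRE1", "Tcs1", "Tcs2"),
                               max_mismatch = 2L,
                               cultivar_ids = NULL,
                               seed = NULL) {
  if (n_cultivars < 1 || n_sites < 1) {
    abort("`n_cultivars` and `n_sites` must be >= 1.")
  }
  if (specific_fraction < 0 || specific_fraction > 1) {
    abort("`specific_fraction` must lie in [0, 1].")
  }
  if (flank_length < 50) abort("`flank_length` must be >= 50.")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cultivar_ids)) {
    cultivar_ids <- sprintf("cultivar%02d", seq_len(n_cultivars))
  }
  if (length(cultivar_ids) != n_cultivars || anyDuplicated(cultivar_ids)) {
    abort("`cultivar_ids` must be `n_cultivars` unique labels.")
  }

  min_dist <- 2L * max_mismatch + 1L
  flanks <- character(n_sites)
  prefix_raw <- matrix(raw(0), nrow = 0, ncol = 50)
  max_attempts <- 200L
  for (i in seq_len(n_sites)) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      cand <- random_dna(1, flank_length)
      pre <- substr(cand, 1, 50)
      if (nrow(prefix_raw) == 0L ||
          all(hamming_to_rows(prefix_raw, pre) >= min_dist)) {
        flanks[i] <- cand
        prefix_raw <- rbind(prefix_raw, matrix(charToRaw(pre), nrow = 1))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(paste0(
        "Could not place ", n_sites, " flanking sequences with pairwise ",
        "Hamming distance > ", 2L * max_mismatch, " over their first 50 bp; ",
        "too many sites for this flank length/alphabet."))
    }
  }

  sites <- tibble(
    site_id = sprintf("site%04d", seq_len(n_sites)),
    family = sample(families, n_sites, replace = TRUE),
    flank = flanks
  )

  truth <- matrix(0L, nrow = n_cultivars, ncol = n_sites,
                  dimnames = list(cultivar_ids, sites$site_id))
  n_specific <- round(specific_fraction * n_sites)
  specific_idx <- if (n_specific > 0) sample(n_sites, n_specific) else integer(0)
  for (j in seq_len(n_sites)) {
    if (j %in% specific_idx || n_cultivars == 1L) {
      truth[sample.int(n_cultivars, 1L), j] <- 1L
    } else {
      k <- sample(2:n_cultivars, 1L)
      truth[sample.int(n_cultivars, k), j] <- 1L
    }
  }

  structure(
    list(cultivar_ids = cultivar_ids, sites = sites, truth = truth),
    class = "insertion_landscape"
  )
}

#' @export
print.insertion_landscape <- function(x, ...) {
  cat("<insertion_landscape> ", length(x$cultivar_ids), " cultivars x ",
      nrow(x$sites), " sites (",
      sum(colSums(x$truth) == 1L), " cultivar-specific)\n", sep = "")
  invisible(x)
}

# Apply per-base substitution errors to a character vector of sequences.
mutate_sequences <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  width <- nchar(seqs)
  n_err <- rbinom(length(seqs), width, error_rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(width[i], n_err[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Generate transposon-display reads from a landscape
#'
#' Emits, per cultivar, `depth` reads for every insertion site the truth
#' matrix marks present. Each read is
#' `retro_tag + flank (+ adapter remnant + poly-A fill)` truncated to
#' `read_length`, with per-base substitution errors, a constant per-read
#' quality value from a two-point mixture, and PCR-duplicate copies
#' (identical sequence and quality). Optionally a fraction of off-target
#' background reads (tag + random DNA) is added.
#'
#' @param landscape An `insertion_landscape` from [simulate_landscape()].
#' @param config A [sim_config()].
#' @param out_dir Optional directory; if given, per-cultivar FASTQ files, a
#'   read-to-site truth TSV and a landscape JSON are written via
#'   [write_library()].
#'
#' @return A tibble with one row per read: `cultivar`, `read_id`, `sequence`,
#'   `quality` (Phred+33 string) and `site_id` (`NA` for background reads).
#' @export
#' @examples
#' ls <- simulate_landscape(2, 3, seed = 1)
#' reads <- generate_reads(ls, sim_config(depth = 2, error_rate = 0, seed = 1))
#' table(reads$cultivar)
generate_reads <- function(landscape, config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(landscape, "insertion_landscape"),
            inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  tag <- config$retro_tag
  rl <- config$read_length
  templates <- substr(
    paste0(tag, landscape$sites$flank, config$adapter_sequence,
           strrep("A", rl)),
    1, rl)

  per_cultivar <- lapply(seq_along(landscape$cultivar_ids), function(ci) {
    cultivar <- landscape$cultivar_ids[ci]
    present <- which(landscape$truth[ci, ] == 1L)
    site_idx <- rep(present, each = config$depth)
    seqs <- mutate_sequences(templates[site_idx], config$error_rate)
    site_ids <- landscape$sites$site_id[site_idx]

    n <- length(seqs)
    copies <- if (config$duplicate_lambda > 0) {
      1L + rpois(n, config$duplicate_lambda)
    } else rep(1L, n)

    n_bg <- round(config$background_fraction * sum(copies))
    if (n_bg > 0) {
      bg <- paste0(tag, random_dna(n_bg, rl - nchar(tag)))
      seqs <- c(seqs, bg)
      site_ids <- c(site_ids, rep(NA_character_, n_bg))
      copies <- c(copies, rep(1L, n_bg))
      n <- n + n_bg
    }

    qv <- ifelse(runif(n) < config$qv_pass_rate, config$qv_pass,
                 config$qv_fail)
    quals <- phred_string(qv, rl)

    idx <- rep(seq_len(n), copies)
    tibble(
      cultivar = cultivar,
      read_id = sprintf("%s_r%06d", cultivar, seq_along(idx)),
      sequence = seqs[idx],
      quality = quals[idx],
      site_id = site_ids[idx]
    )
  })
  reads <- dplyr::bind_rows(per_cultivar)

  if (!is.null(out_dir)) write_library(reads, out_dir, landscape = landscape)
  reads
}
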