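#' Assemble a diagnostic strip kit
#'
#' Builds a multiplex-PCR kit for a chromatographic printed-array strip
#' (four detection lines): the positive-control marker — a gene amplifying
#' in every true sample, confirming that PCR itself ran — on line 1, and the
#' cultivar-specific markers on subsequent lines ordered by descending
#' fragment size. Fails if the set needs more than three markers (the strip
#' has four lines including the control) or if any two fragments are closer
#' than `min_separation`, which keeps band calls resolvable on a 2% agarose
#' gel as well.
#'
#' @param marker_set A unique `marker_set` (see [minimal_and_set()]).
#' @param sizes Fragment sizes in bp: a named numeric vector or a data frame
#'   with `marker` and `fragment_size` columns, covering every member and
#'   the control.
#' @param positive_control Positive-control marker id. Default `"rbcL"`.
#' @param min_separation Minimum pairwise fragment-size difference in bp.
#'   Default 30; `0` disables the gel-resolution check.
#'
#' @return An object of class `cpas_kit`: list with `target` and `lines`
#'   (tibble: `line`, `marker`, `role`, `fragment_size`).
#' @export
#' @examples
#' ms <- minimal_and_set(citrus_genotypes(), "Rinoka")
#' design_kit(ms, citrus_markers())
design_kit <- function(marker_set, sizes, positive_control = "rbcL",
                       min_separation = 30) {
  stopifnot(inherits(marker_set, "marker_set"))
  if (!isTRUE(marker_set$unique)) {
    abort("`marker_set` does not uniquely identify its target; refusing to build a kit.")
  }
  if (length(marker_set$members) > 3L) {
    abort(paste0("Marker set of size ", length(marker_set$members),
                 " plus the positive control exceeds the 4 lines of a ",
                 "C-PAS4 strip."))
  }
  if (is.data.frame(sizes)) {
    if (!all(c("marker", "fragment_size") %in% names(sizes))) {
      abort("`sizes` data frame needs `marker` and `fragment_size` columns.")
    }
    # prefer rows recorded for this kit's target, then unambiguous rows
    if ("target" %in% names(sizes)) {
      pref <- sizes[!is.na(sizes$target) & sizes$target == marker_set$target |
                      sizes$marker == positive_control, ]
      rest <- sizes[!sizes$marker %in% pref$marker, ]
      sizes <- rbind(pref, rest)
    }
    sizes <- sizes[!duplicated(sizes$marker), ]
    sizes <- stats::setNames(sizes$fragment_size, sizes$marker)
  }
  need <- c(positive_control, marker_set$members)
  missing <- need[!need %in% names(sizes) | is.na(sizes[need])]
  if (length(missing)) {
    abort(paste0("Fragment size unknown for: ",
                 paste(missing, collapse = ", ")))
  }
  sz <- sizes[need]

  if (min_separation > 0 && length(need) > 1L) {
    pairs <- combn(need, 2, simplify = FALSE)
    for (p in pairs) {
      gap <- abs(sz[p[1]] - sz[p[2]])
      if (gap < min_separation) {
        abort(sprintf(
          "Fragments '%s' (%g bp) and '%s' (%g bp) differ by %g bp, below the %g bp separation needed.",
          p[1], sz[p[1]], p[2], sz[p[2]], gap, min_separation))
      }
    }
  }

  member_order <- marker_set$members[
    order(-sz[marker_set$members], marker_set$members, method = "radix")]
  lines <- tibble(
    line = seq_len(1L + length(member_order)),
    marker = c(positive_control, member_order),
    role = c("positive_control", rep("marker", length(member_order))),
    fragment_size = unname(sz[c(positive_control, member_order)])
  )
  structure(list(target = marker_set$target, lines = lines),
            class = "cpas_kit")
}

#' @export
print.cpas_kit <- function(x, ...) {
  cat("<cpas_kit> target '", x$target, "', ", nrow(x$lines),
      " lines\n", sep = "")
  print(x$lines, ...)
  invisible(x)
}

#' Predict the strip band pattern for a sample
#'
#' The positive-control line lights up for any sample with amplifiable DNA;
#' each marker line lights up when the sample's genotype carries that
#' marker. A no-template control (`sample = NULL`) produces no bands.
#'
#' @param kit A [design_kit()] result.
#' @param gm A [genotype_matrix()] containing the kit's markers.
#' @param sample Cultivar label in `gm`, or `NULL` for a no-template control.
#'
#' @return An object of class `band_pattern`: list with `target`, `sample`,
#'   `lines` (tibble: `line`, `marker`, `role`, `present`) and `band_count`.
#' @export
#' @examples
#' gm <- citrus_genotypes()
#' kit <- citrus_kits()[["Kanpei"]]
#' predict_bands(kit, gm, "Kanpei")
predict_bands <- function(kit, gm, sample) {
  stopifnot(inherits(kit, "cpas_kit"), inherits(gm, "genotype_matrix"))
  if (is.null(sample)) {
    lines <- dplyr::mutate(kit$lines, present = FALSE)
    sample <- "no_template_control"
  } else {
    if (!sample %in% cultivars(gm)) {
      abort(sprintf("Sample '%s' is not in the genotype matrix.", sample))
    }
    markers_needed <- kit$lines$marker
    unknown <- setdiff(markers_needed, marker_ids(gm))
    if (length(unknown)) {
      abort(paste0("Kit marker(s) missing from the matrix: ",
                   paste(unknown, collapse = ", ")))
    }
    m <- as.matrix(gm)
    lines <- dplyr::mutate(
      kit$lines,
      present = ifelse(.data$role == "positive_control", TRUE,
                       m[sample, .data$marker] == 1L))
  }
  structure(
    list(target = kit$target, sample = sample,
         lines = lines[, c("line", "marker", "role", "present")],
         band_count = sum(lines$present)),
    class = "band_pattern"
  )
}

#' @export
print.band_pattern <- function(x, ...) {
  cat("<band_pattern> kit '", x$target, "' on sample '", x$sample, "': ",
      x$band_count, " band(s)\n", sep = "")
  print(x$lines, ...)
  invisible(x)
}

#' Diagnose a sample from its band pattern
#'
#' Three-way verdict: `invalid` when the positive-control line is absent
#' (the PCR itself cannot be trusted), `target` when the control and every
#' marker line are present, `non_target` otherwise. Exactly one verdict
#' applies to every possible line subset.
#'
#' @param pattern A [predict_bands()] result.
#' @return One of `"target"`, `"non_target"`, `"invalid"`.
#' @export
#' @examples
#' gm <- citrus_genotypes()
#' kit <- citrus_kits()[["Rinoka"]]
#' diagnose(predict_bands(kit, gm, "Rinoka"))
diagnose <- function(pattern) {
  stopifnot(inherits(pattern, "band_pattern"))
  ctrl <- pattern$lines$present[pattern$lines$role == "positive_control"]
  if (!all(ctrl)) return("invalid")
  if (all(pattern$lines$present)) return("target")
  "non_target"
}

#' Diagnose every cultivar in a matrix with one kit
#'
#' @param kit A [design_kit()] result.
#' @param gm A [genotype_matrix()].
#' @return Tibble with `cultivar`, `band_count`, `verdict`.
#' @export
diagnose_all <- function(kit, gm) {
  stopifnot(inherits(kit, "cpas_kit"), inherits(gm, "genotype_matrix"))
  purrr::map_dfr(cultivars(gm), function(cv) {
    p <- predict_bands(kit, gm, cv)
    tibble(cultivar = cv, band_count = p$band_count, verdict = diagnose(p))
  })
}
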