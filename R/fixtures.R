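#' Published citrus genotype table
#'
#' The packaged presence/absence table for 26 Japanese citrus cultivars and
#' the 14 unique DNA markers (one chloroplast positive control, `rbcL`, plus
#' 13 InDel and retrotransposon-insertion markers) used to build the eight
#' target cultivar-specific identification kits. Cells were scored from PCR
#' fragment presence on 2% agarose gels; the duplicated `Cp0419-s` column of
#' the source table (listed under two targets) is collapsed on load.
#'
#' @return A [genotype_matrix()] of 26 cultivars by 14 markers.
#' @export
#' @examples
#' gm <- citrus_genotypes()
#' screen_specific(gm)
citrus_genotypes <- function() {
  read_genotype_tsv(
    system.file("extdata", "citrus_genotypes.tsv", package = "citruskit",
                mustWork = TRUE),
    markers = citrus_markers())
}

#' Published citrus marker metadata
#'
#' Marker name, source family (`InDel`, `Tcs1`, `Tcs2` or
#' `positive_control`), PCR fragment size in bp and the target cultivar whose
#' kit each row belongs to. `Cp0419-s` appears twice with the two fragment
#' sizes printed for its two kits; kit assembly uses the row recorded for
#' the kit's own target.
#'
#' @return Tibble with columns `target`, `marker`, `source`, `fragment_size`.
#' @export
citrus_markers <- function() {
  read_marker_tsv(
    system.file("extdata", "citrus_markers.tsv", package = "citruskit",
                mustWork = TRUE))
}

#' The eight target cultivars
#'
#' @return Character vector of the eight cultivars the published kits target.
#' @export
citrus_targets <- function() {
  mk <- citrus_markers()
  unique(mk$target[!is.na(mk$target)])
}

#' Published diagnostic kits
#'
#' Assembles the eight target cultivar-specific strip kits from the packaged
#' marker table: each kit pairs the `rbcL` positive control with the 1-3
#' published markers for its target, using the published fragment sizes.
#'
#' @param min_separation Minimum pairwise fragment-size gap in bp passed to
#'   [design_kit()]. Default 30.
#' @return Named list of [design_kit()] objects, one per target cultivar.
#' @export
#' @examples
#' kits <- citrus_kits()
#' kits[["Kanpei"]]
citrus_kits <- function(min_separation = 30) {
  gm <- citrus_genotypes()
  mk <- citrus_markers()
  targets <- citrus_targets()
  kits <- lapply(targets, function(tg) {
    members <- sort_c(mk$marker[!is.na(mk$target) & mk$target == tg])
    chk <- verify_uniqueness(gm, tg, members)
    ms <- new_marker_set(tg, members, chk$unique, chk$offending, "published")
    design_kit(ms, mk, min_separation = min_separation)
  })
  stats::setNames(kits, targets)
}
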