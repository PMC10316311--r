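new_marker_set <- function(target, members, unique, offending, method) {
  structure(
    list(target = target, members = members, size = length(members),
         unique = unique, offending = offending, method = method),
    class = "marker_set"
  )
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> target '", x$target, "': {",
      paste(x$members, collapse = ", "), "} (size ", x$size,
      if (x$unique) ", unique" else ", NOT unique", ", ", x$method,
      ")\n", sep = "")
  if (!x$unique && length(x$offending)) {
    cat("  still shared with: ", paste(x$offending, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Non-target cultivars carrying every member (AND-rule offenders).
offenders_of <- function(m, target, members) {
  others <- setdiff(rownames(m), target)
  if (length(members) == 0L) return(others)
  sub <- m[others, members, drop = FALSE]
  others[rowSums(sub) == length(members)]
}

#' Minimal AND-combination marker set for a target cultivar
#'
#' Exhaustively searches, by increasing set size, for the smallest set of
#' markers that are all present in the target cultivar and jointly present
#' in no other cultivar (the AND identification rule: a sample is called the
#' target only if every marker in the set amplifies). Candidates are the
#' target-present markers, excluding the positive control. Among minimum-size
#' solutions the lexicographically smallest member list (C byte order) is
#' returned. If no set of size up to `max_k` is unique, the greedy
#' best-covering set is returned with `unique = FALSE`.
#'
#' @param gm A [genotype_matrix()].
#' @param target Cultivar label present in `gm`.
#' @param max_k Largest set size examined. Default 4 (a four-line strip
#'   carries at most three markers plus the control; published sets have
#'   size at most 3).
#'
#' @return An object of class `marker_set` with fields `target`, `members`,
#'   `size`, `unique`, `offending`, `method`.
#' @export
#' @examples
#' minimal_and_set(citrus_genotypes(), "Asumi")
minimal_and_set <- function(gm, target, max_k = 4L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!target %in% cultivars(gm)) {
    abort(sprintf("Target cultivar '%s' is not in the matrix.", target))
  }
  if (max_k < 1) abort("`max_k` must be >= 1.")
  m <- as.matrix(gm)
  cand <- candidate_markers(gm)
  cand <- sort_c(cand[m[target, cand] == 1L])

  for (k in seq_len(min(max_k, length(cand)))) {
    sets <- combn(cand, k, simplify = FALSE)  # lexicographic order
    for (s in sets) {
      if (length(offenders_of(m, target, s)) == 0L) {
        return(new_marker_set(target, s, TRUE, character(0), "exhaustive"))
      }
    }
  }
  best <- greedy_and_set(gm, target)
  new_marker_set(target, best$members, best$unique, best$offending,
                 "exhaustive_fallback_greedy")
}

#' Greedy marker-set construction
#'
#' Scalable fallback for large marker panels: iteratively adds the
#' target-present marker that excludes the most not-yet-excluded non-target
#' cultivars (lexicographic tie-break), stopping when all non-targets are
#' excluded or no marker helps. The result's size is at least the exhaustive
#' minimum.
#'
#' @inheritParams minimal_and_set
#' @return A `marker_set` (with `unique = FALSE` and the offending cultivars
#'   listed when full discrimination is impossible).
#' @export
greedy_and_set <- function(gm, target) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!target %in% cultivars(gm)) {
    abort(sprintf("Target cultivar '%s' is not in the matrix.", target))
  }
  m <- as.matrix(gm)
  cand <- candidate_markers(gm)
  cand <- sort_c(cand[m[target, cand] == 1L])
  remaining <- setdiff(rownames(m), target)
  members <- character(0)
  while (length(remaining) > 0L && length(cand) > 0L) {
    gains <- vapply(cand, function(j) sum(m[remaining, j] == 0L), integer(1))
    if (max(gains) == 0L) break
    pick <- cand[which.max(gains)]   # first max = lexicographic tie-break
    members <- c(members, pick)
    remaining <- remaining[m[remaining, pick] == 1L]
    cand <- setdiff(cand, pick)
  }
  new_marker_set(target, sort_c(members), length(remaining) == 0L,
                 remaining, "greedy")
}

#' Verify that a marker set uniquely identifies its target
#'
#' Checks the AND rule directly: the offending cultivars are the non-targets
#' possessing every member of the set; the set is unique exactly when there
#' are none. An empty member set is offended by every non-target (the empty
#' conjunction holds everywhere).
#'
#' @param gm A [genotype_matrix()].
#' @param target Cultivar label.
#' @param members Character vector of marker ids in `gm`.
#' @return List with `unique` (logical) and `offending` (character).
#' @export
#' @examples
#' verify_uniqueness(citrus_genotypes(), "Kanpei",
#'                   c("Cp0419-s", "IND265-l", "IND44-l"))
verify_uniqueness <- function(gm, target, members) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!target %in% cultivars(gm)) {
    abort(sprintf("Target cultivar '%s' is not in the matrix.", target))
  }
  unknown <- setdiff(members, marker_ids(gm))
  if (length(unknown)) {
    abort(paste0("Unknown marker(s): ", paste(unknown, collapse = ", ")))
  }
  off <- offenders_of(as.matrix(gm), target, members)
  list(unique = length(off) == 0L, offending = off)
}
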