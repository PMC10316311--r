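fake_clusters <- function(counts, totals) {
  # counts: named list cultivar -> named numeric (cluster -> reads)
  ids <- sort(unique(unlist(lapply(counts, names))))
  cnt <- dplyr::bind_rows(lapply(names(counts), function(cv) {
    tibble::tibble(cluster_id = names(counts[[cv]]), cultivar = cv,
                   reads = as.integer(counts[[cv]]))
  }))
  structure(
    list(clusters = tibble::tibble(cluster_id = ids,
                                   representative = strrep("A", 50),
                                   n_members = 1L),
         counts = cnt,
         totals = tibble::tibble(cultivar = names(totals),
                                 total_reads = as.integer(totals)),
         params = cluster_params()),
    class = "insertion_clusters")
}

test_that("the 0.1% fraction rule uses a strict inequality for absence", {
  cl <- fake_clusters(
    list(a = c(CL1 = 9, CL2 = 10, CL3 = 0)),
    c(a = 10000))
  gm <- call_presence(cl, 0.001)
  m <- as.matrix(gm)
  expect_identical(m["a", "CL1"], 0L)  # 0.09% < 0.1% -> absent
  expect_identical(m["a", "CL2"], 1L)  # exactly 0.1% -> present
  expect_identical(m["a", "CL3"], 0L)  # zero reads -> absent
})

test_that("zero-read cultivars are scored all-absent with a warning", {
  cl <- fake_clusters(list(a = c(CL1 = 50)), c(a = 100, b = 0))
  expect_warning(gm <- call_presence(cl), "zero reads")
  expect_identical(unname(as.matrix(gm)["b", ]), 0L)
})

test_that("negative counts and out-of-range thresholds are rejected", {
  cl <- fake_clusters(list(a = c(CL1 = -1)), c(a = 100))
  expect_error(call_presence(cl), "Negative")
  ok <- fake_clusters(list(a = c(CL1 = 5)), c(a = 100))
  expect_error(call_presence(ok, threshold = 0), "threshold")
})

test_that("raising the threshold never turns an absence into a presence", {
  set.seed(8)
  counts <- lapply(1:5, function(i)
    stats::setNames(sample(0:50, 20, replace = TRUE), sprintf("CL%02d", 1:20)))
  names(counts) <- sprintf("cv%d", 1:5)
  cl <- fake_clusters(counts, stats::setNames(rep(5000, 5), names(counts)))
  prev <- NULL
  for (th in c(0.0005, 0.001, 0.002, 0.005, 0.02)) {
    m <- as.matrix(call_presence(cl, th))
    if (!is.null(prev)) expect_true(all(m <= prev))
    prev <- m
  }
})

test_that("specific-marker screening equals a brute-force column scan", {
  for (seed in 1:5) {
    gm <- rand_gm(30, 50, p = 0.12, seed = seed)
    got <- screen_specific(gm)
    m <- as.matrix(gm)
    expected <- colnames(m)[colSums(m) == 1L]
    expect_setequal(got$marker, expected)
    for (r in seq_len(nrow(got))) {
      expect_identical(m[got$cultivar[r], got$marker[r]], 1L)
    }
  }
})

test_that("the published table yields the three known specific markers", {
  gm <- citrus_genotypes()
  sp <- screen_specific(gm)
  expect_identical(sp$cultivar[sp$marker == "IND141-l"], "Rinoka")
  expect_false("rbcL" %in% sp$marker)
  poly <- screen_polymorphic(gm)
  expect_false("rbcL" %in% poly$marker)       # all-present column excluded
  expect_true(all(sp$marker %in% poly$marker)) # specific subset polymorphic
})

test_that("polymorphic status is invariant under column complement", {
  for (seed in 1:5) {
    gm <- rand_gm(12, 20, p = 0.5, seed = seed + 10)
    m <- as.matrix(gm)
    flipped <- m
    j <- (seed %% ncol(m)) + 1L
    flipped[, j] <- 1L - flipped[, j]
    gm2 <- genotype_matrix(dplyr::bind_cols(
      tibble::tibble(cultivar = rownames(m)), tibble::as_tibble(flipped)))
    p1 <- colnames(m)[j] %in% screen_polymorphic(gm)$marker
    p2 <- colnames(m)[j] %in% screen_polymorphic(gm2)$marker
    expect_identical(p1, p2)
  }
})

test_that("genotype matrices validate their invariants", {
  expect_error(genotype_matrix(tibble::tibble(x = 1)), "cultivar")
  expect_error(
    genotype_matrix(tibble::tibble(cultivar = "a", m1 = 2)),
    "outside \\{0, 1\\}")
  expect_error(
    genotype_matrix(tibble::tibble(cultivar = c("a", "b"), m1 = c(1, 0)),
                    markers = tibble::tibble(marker = "m1",
                                             source = "positive_control")),
    "Positive-control")
})

test_that("noise-free end-to-end run recovers the truth matrix exactly", {
  ls <- simulate_landscape(6, 15, specific_fraction = 0.2, seed = 17)
  cfg <- sim_config(depth = 20, error_rate = 0, duplicate_lambda = 2,
                    seed = 17)
  reads <- generate_reads(ls, cfg)
  col <- preprocess_reads(reads, preprocess_params(retro_tag = cfg$retro_tag))
  gm <- call_presence(cluster_reads(col))
  m <- as.matrix(gm)
  site_of <- ls$sites$site_id[match(gm$markers$representative,
                                    substr(ls$sites$flank, 1, 50))]
  colnames(m) <- site_of
  expect_identical(unname(m[ls$cultivar_ids, ls$sites$site_id]),
                   unname(ls$truth))
})
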