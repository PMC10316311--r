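collapsed_tbl <- function(seqs, mult = NULL, cultivar = "lib") {
  if (is.null(mult)) mult <- rep(1L, length(seqs))
  tibble::tibble(cultivar = cultivar, sequence = seqs, multiplicity = mult)
}

test_that("identical reads form a single cluster", {
  s <- random_seq(1, 50)
  cl <- cluster_reads(collapsed_tbl(rep(s, 3), c(4L, 2L, 1L),
                                    cultivar = c("a", "a", "b")))
  expect_identical(nrow(cl$clusters), 1L)
  expect_identical(cl$clusters$representative, s)
  expect_identical(sum(cl$counts$reads), 7L)
})

test_that("sequences beyond the mismatch budget split; within it they join", {
  set.seed(5)
  s1 <- random_seq(1, 50)
  s3 <- mutate_at_positions(s1, c(10, 20, 30))   # Hamming 3 > 2
  cl <- cluster_reads(collapsed_tbl(c(s1, s3), c(5L, 1L)))
  expect_identical(nrow(cl$clusters), 2L)
  s2 <- mutate_at_positions(s1, c(10, 20))       # Hamming 2 <= 2
  cl2 <- cluster_reads(collapsed_tbl(c(s1, s2), c(5L, 1L)))
  expect_identical(nrow(cl2$clusters), 1L)
  expect_identical(cl2$clusters$representative, s1)  # highest multiplicity
})

test_that("error-free simulation recovers one cluster per true site with exact counts", {
  ls <- simulate_landscape(4, 12, seed = 31)
  cfg <- sim_config(depth = 5, error_rate = 0, duplicate_lambda = 0,
                    qv_pass_rate = 1, seed = 31)
  reads <- generate_reads(ls, cfg)
  col <- preprocess_reads(reads, preprocess_params(retro_tag = cfg$retro_tag))
  cl <- cluster_reads(col)
  expect_identical(nrow(cl$clusters), nrow(ls$sites))
  site_of <- ls$sites$site_id[match(cl$clusters$representative,
                                    substr(ls$sites$flank, 1, 50))]
  expect_false(anyNA(site_of))
  counts <- dplyr::left_join(
    cl$counts,
    tibble::tibble(cluster_id = cl$clusters$cluster_id, site_id = site_of),
    by = "cluster_id")
  # depth 5 < collapse threshold 10, so per-cultivar counts equal depth
  expect_true(all(counts$reads == 5L))
  expect_identical(nrow(counts), sum(ls$truth))
  for (r in seq_len(nrow(counts))) {
    expect_identical(ls$truth[counts$cultivar[r], counts$site_id[r]], 1L)
  }
})

test_that("clustering is deterministic and respects totals bookkeeping", {
  set.seed(6)
  base <- random_seq(5, 50)
  seqs <- c(base, vapply(base, function(s)
    mutate_at_positions(s, sample(50, 2)), character(1)))
  inp <- collapsed_tbl(seqs, c(rep(10L, 5), rep(1L, 5)),
                       cultivar = rep(c("a", "b"), 5))
  cl1 <- cluster_reads(inp)
  cl2 <- cluster_reads(inp)
  expect_identical(cl1$clusters, cl2$clusters)
  expect_identical(cl1$counts, cl2$counts)
  per_cv <- dplyr::summarise(cl1$counts, n = sum(reads), .by = cultivar)
  tot <- cl1$totals$total_reads[match(per_cv$cultivar, cl1$totals$cultivar)]
  expect_true(all(per_cv$n <= tot))
})

test_that("greedy clustering matches connected-components oracle on well-separated instances", {
  for (seed in 1:3) {
    set.seed(seed)
    # centers pairwise Hamming >= 9 so 2-mutation satellites cannot bridge
    centers <- character(0)
    while (length(centers) < 8) {
      cand <- random_seq(1, 50)
      if (all(vapply(centers, function(c) str_hamming(c, cand) >= 9,
                     logical(1)))) {
        centers <- c(centers, cand)
      }
    }
    sat <- unlist(lapply(centers, function(c)
      vapply(1:4, function(i) mutate_at_positions(c, sample(50, 2)),
             character(1))))
    seqs <- c(centers, sat)
    mult <- c(rep(10L, 8), rep(1L, 32))
    cl <- cluster_reads(collapsed_tbl(seqs, mult))
    comp <- oracle_components(seqs, k = 8, d = 2)
    expect_identical(nrow(cl$clusters), length(unique(comp)))
    # same partition: each oracle component maps to exactly one cluster
    assign_of <- function(s) {
      d <- vapply(cl$clusters$representative, function(r)
        str_hamming(r, s), numeric(1))
      cl$clusters$cluster_id[which.min(d)]
    }
    ids <- vapply(seqs, assign_of, character(1))
    expect_identical(length(unique(paste(comp, ids))),
                     length(unique(comp)))
  }
})

test_that("tightening the mismatch budget never merges clusters", {
  set.seed(7)
  base <- random_seq(4, 50)
  seqs <- unique(c(base, unlist(lapply(base, function(s)
    lapply(1:3, function(i) mutate_at_positions(s, sample(50, sample(1:4, 1))))))))
  inp <- collapsed_tbl(seqs, rep(1L, length(seqs)))
  sizes <- vapply(0:4, function(mm)
    nrow(cluster_reads(inp, cluster_params(max_mismatch = mm))$clusters),
    integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("ragged or short sequences are rejected", {
  expect_error(cluster_reads(collapsed_tbl(c(random_seq(1, 50),
                                             random_seq(1, 49)))),
               "unequal lengths")
  expect_error(
    cluster_reads(collapsed_tbl(random_seq(1, 5)),
                  cluster_params(seed_kmer = 8)),
    "shorter than")
})

test_that("min_cluster_reads drops sparse clusters but keeps totals", {
  s <- random_seq(2, 50)
  while (str_hamming(s[1], s[2]) <= 4) s <- random_seq(2, 50)
  cl <- cluster_reads(collapsed_tbl(s, c(10L, 1L)),
                      cluster_params(min_cluster_reads = 5))
  expect_identical(nrow(cl$clusters), 1L)
  expect_identical(cl$totals$total_reads, 11L)
})
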