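adapter <- "AGATCGGAAGAGC"

test_that("adapter trimming removes the adapter and everything after it", {
  set.seed(1)
  insert <- random_seq(1, 40)
  clean <- make_reads(random_seq(1, 60))
  expect_identical(trim_adapter(clean, adapter)$sequence, clean$sequence)

  with_ad <- make_reads(paste0(insert, adapter))
  out <- trim_adapter(with_ad, adapter)
  expect_identical(out$sequence, insert)
  expect_identical(nchar(out$quality), nchar(insert))

  # one mismatch tolerated for adapters of length >= 8
  ad1 <- mutate_at_positions(adapter, 5)
  out1 <- trim_adapter(make_reads(paste0(insert, ad1)), adapter)
  expect_identical(out1$sequence, insert)

  # short adapters (< 8) must match exactly
  out2 <- trim_adapter(make_reads(paste0(insert, "ACGTA")), "ACGTT")
  expect_identical(nchar(out2$sequence), 45L)
  out3 <- trim_adapter(make_reads(paste0(insert, "ACGTT")), "ACGTT")
  expect_identical(out3$sequence, insert)
})

test_that("trimmed lengths equal the simulator's insert offsets", {
  set.seed(42)
  offsets <- sample(20:120, 100, replace = TRUE)
  seqs <- vapply(offsets, function(o)
    substr(paste0(random_seq(1, o), adapter, strrep("A", 150)), 1, 150),
    character(1))
  out <- trim_adapter(make_reads(seqs), adapter)
  expect_identical(nchar(out$sequence), as.integer(offsets))
})

test_that("tag removal strips matching prefixes and drops off-target reads", {
  tag <- "TGTTGGAATCCTCAACGATG"
  set.seed(2)
  flank <- random_seq(3, 60)
  reads <- make_reads(c(paste0(tag, flank[1]),
                        paste0(mutate_at_positions(tag, 3), flank[2]),
                        paste0(random_seq(1, 20), flank[3])))
  out <- trim_tag(reads, tag)
  expect_identical(out$sequence, flank[1:2])
})

test_that("quality filtering retains exactly the reads with mean QV at or above the cutoff", {
  hi <- make_reads(random_seq(3, 50), qv = 40)
  lo <- make_reads(random_seq(2, 50), qv = 20, ids = c("x1", "x2"))
  out <- quality_filter(dplyr::bind_rows(hi, lo), 30)
  expect_identical(out$read_id, hi$read_id)
  expect_identical(out$sequence, hi$sequence)  # sequences never altered
  expect_identical(nrow(quality_filter(hi[0, ], 30)), 0L)
})

test_that("quality filter agrees with the simulator's pass/fail mixture", {
  ls <- simulate_landscape(2, 6, seed = 13)
  cfg <- sim_config(depth = 10, error_rate = 0, duplicate_lambda = 0,
                    qv_pass = 38, qv_fail = 20, qv_pass_rate = 0.6,
                    seed = 13)
  reads <- generate_reads(ls, cfg)
  pass_truth <- sum(substr(reads$quality, 1, 1) == intToUtf8(33 + 38))
  expect_identical(nrow(quality_filter(reads, 30)), pass_truth)
})

test_that("fixed-length trimming yields a point mass at the target length", {
  set.seed(3)
  reads <- make_reads(random_seq(20, 150))
  out <- fixed_length_trim(reads, 50)
  expect_true(all(nchar(out$sequence) == 50L))
  expect_identical(out$sequence, substr(reads$sequence, 1, 50))
  short <- make_reads(random_seq(1, 49))
  expect_identical(nrow(fixed_length_trim(short, 50)), 0L)
  mixed <- make_reads(c(random_seq(5, 150), random_seq(3, 30)))
  expect_identical(nrow(fixed_length_trim(mixed, 50)), 5L)
})

test_that("duplicate collapsing applies the multiplicity-10 rule", {
  s <- random_seq(2, 50)
  reads <- make_reads(c(rep(s[1], 12), rep(s[2], 9)),
                      ids = sprintf("r%02d", 1:21))
  out <- collapse_duplicates(reads, 10)
  out <- out[order(match(out$sequence, s)), ]
  expect_identical(out$multiplicity, c(1L, 9L))
  # distinct sequences unchanged by collapsing
  expect_setequal(out$sequence, unique(reads$sequence))
})

test_that("duplicate collapsing is idempotent and rejects ragged input", {
  set.seed(4)
  reads <- make_reads(sample(random_seq(5, 50), 60, replace = TRUE),
                      ids = sprintf("r%03d", 1:60))
  once <- collapse_duplicates(reads, 10)
  twice <- collapse_duplicates(once, 10)
  expect_identical(once, twice)
  ragged <- make_reads(c(random_seq(1, 50), random_seq(1, 40)))
  expect_error(collapse_duplicates(ragged), "unequal lengths")
})

test_that("the full preprocessing chain reproduces simulator truth", {
  ls <- simulate_landscape(3, 8, seed = 21)
  cfg <- sim_config(depth = 12, error_rate = 0, duplicate_lambda = 1,
                    qv_pass_rate = 1, seed = 21)
  reads <- generate_reads(ls, cfg)
  col <- preprocess_reads(reads, preprocess_params(retro_tag = cfg$retro_tag))
  # depth 12 with duplicates >= 12 copies -> every present site collapses to 1
  expect_true(all(col$multiplicity == 1L))
  expect_identical(nrow(col), sum(ls$truth))
  expect_setequal(unique(col$sequence), substr(ls$sites$flank, 1, 50))
})
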