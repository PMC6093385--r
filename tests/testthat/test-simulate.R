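test_that("breakpoint process matches its Bernoulli definition", {
  set.seed(1)
  expect_identical(simulate_breakpoints(1000, 0), integer(0))
  expect_identical(simulate_breakpoints(1, 0.5), integer(0))
  for (i in 1:20) expect_identical(simulate_breakpoints(2, 1), 1L)
  expect_error(simulate_breakpoints(100, -0.1), "non-negative")

  # analytic binomial-mean oracle: E[breaks] = (L-1) * lam
  L <- 10000L; lam <- 1e-3; n <- 10000L
  counts <- replicate(n, length(simulate_breakpoints(L, lam)))
  expected <- (L - 1) * lam
  se <- sqrt((L - 1) * lam * (1 - lam) / n)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # breaks are strictly increasing bond indices in 1..L-1
  for (i in 1:50) {
    b <- simulate_breakpoints(200, 0.05)
    if (length(b)) {
      expect_true(all(diff(b) > 0))
      expect_true(min(b) >= 1 && max(b) <= 199)
    }
  }
})

test_that("fragment capture follows the library chemistry", {
  set.seed(2)
  expect_identical(capture_fragment(integer(0), 500, "oligo_dT", "polyA"),
                   c(1L, 500L))
  expect_identical(capture_fragment(200L, 500, "oligo_dT", "polyA"),
                   c(201L, 500L))
  expect_identical(capture_fragment(c(100L, 300L), 500, "oligo_dT", "polyA"),
                   c(301L, 500L))
  expect_error(capture_fragment(200L, 500, "oligo_dT", "total"),
               "unsupported")
  expect_error(capture_fragment(600L, 500, "oligo_dT", "polyA"), "1..L-1")

  # length-weighted sampling oracle: fragment [1,200] of a 500-bp molecule
  # broken at bond 200 is drawn with probability 200/500
  n <- 4000L
  hits <- sum(replicate(n, {
    iv <- capture_fragment(200L, 500, "random_hexamer", "total")
    iv[1] == 1L
  }))
  p <- 200 / 500
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("closed-form coverage is exact where it can be checked by hand", {
  expect_equal(expected_coverage(37, 1000, 0), 1)
  expect_equal(expected_coverage(500, 500, 0.9), 1)
  expect_equal(expected_coverage(1501, 3001, 1e-3), 0.999^1500)
  expect_equal(expected_coverage(1501, 3001, 1e-3), 0.2231, tolerance = 1e-3)
  expect_error(expected_coverage(0, 100, 0.1), "out of range")
  expect_error(expected_coverage(101, 100, 0.1), "out of range")
  # non-decreasing in x for any positive rate
  x <- 1:2000
  expect_true(all(diff(expected_coverage(x, 2000, 1e-3)) >= 0))
})

test_that("simulated coverage agrees with the closed form", {
  tx <- transcript_set("t1", 2000L)
  des <- cohort_design(list(young = "Y1"))
  mod <- fragmentation_model(lambda_early = 1e-3, lambda_aging = 0,
                             reads_per_sample = 10000L, seed = 42)
  lib <- simulate_library(tx, mod, des)
  d <- depth_from_reads(lib$reads, tx)[["t1"]]
  n <- max(d[, "Y1"])  # every captured read covers the 3' terminus
  grid <- round(seq(200, 1900, length.out = 10))
  z <- vapply(grid, function(x) {
    p <- expected_coverage(x, 2000, 1e-3)
    abs(d[x, "Y1"] / n - p) / sqrt(p * (1 - p) / n)
  }, numeric(1))
  expect_lt(max(z), 4)  # simultaneous bound over the ten correlated points
  # empirical monotonicity after 100-bp smoothing: < 1% violations
  sm <- smooth_moving_window(as.numeric(d[, "Y1"]), 100)
  expect_lt(mean(diff(sm) < 0), 0.01)
})

test_that("break-rate recovery from the coverage profile is accurate", {
  tx <- transcript_set("t1", 2000L)
  des <- cohort_design(list(young = "Y1"))
  for (lam in c(5e-4, 1e-3, 2e-3)) {
    for (seed in 1:3) {
      mod <- fragmentation_model(lambda_early = lam, lambda_aging = 0,
                                 reads_per_sample = 10000L, seed = seed)
      lib <- simulate_library(tx, mod, des)
      d <- depth_from_reads(lib$reads, tx)[["t1"]]
      lam_hat <- estimate_break_rate(d[, "Y1"])
      expect_lt(abs(lam_hat - lam) / lam, 0.10)
    }
  }
})

test_that("library simulation honours design, spike-ins and determinism", {
  tx <- transcript_set(c("t1", "spk"), c(1500L, 800L),
                       is_spike_in = c(FALSE, TRUE))
  des <- ten_sample_design()
  mod <- fragmentation_model(lambda_early = 1e-3, lambda_aging = 2e-3,
                             reads_per_sample = 300L, seed = 9)
  expect_error(simulate_library(tx[0, ], mod, des), "empty")

  lib <- simulate_library(tx, mod, des)
  # spike-ins are never fragmented: all reads span the full molecule
  spk <- lib$reads[lib$reads$transcript_id == "spk", ]
  expect_true(all(spk$start == 1L & spk$end == 800L & spk$n_breaks == 0L))
  # ground truth: young cohort lambda_early, aged adds lambda_aging
  expect_equal(lib$truth$lambda[lib$truth$transcript_id == "t1"],
               c(1e-3, 3e-3)[match(
                 lib$truth$cohort_id[lib$truth$transcript_id == "t1"],
                 c("young", "aged"))])
  expect_true(all(lib$truth$lambda[lib$truth$transcript_id == "spk"] == 0))

  # zero-read library: empty read set, ground truth still present
  mod0 <- fragmentation_model(reads_per_sample = 0L, seed = 9)
  lib0 <- simulate_library(tx, mod0, des)
  expect_identical(nrow(lib0$reads), 0L)
  expect_identical(nrow(lib0$truth), 4L)

  # identical seeds give byte-identical SAM and depth TSV output
  lib2 <- simulate_library(tx, mod, des)
  expect_identical(lib$reads, lib2$reads)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(lib$reads, tx, f1); write_sam(lib2$reads, tx, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  d1 <- tempfile(); d2 <- tempfile()
  write_depth_tsv(depth_from_reads(lib$reads, tx, des$sample_id), d1)
  write_depth_tsv(depth_from_reads(lib2$reads, tx, des$sample_id), d2)
  expect_identical(readBin(d1, "raw", file.size(d1)),
                   readBin(d2, "raw", file.size(d2)))
})

test_that("depth noise respects its configuration", {
  set.seed(5)
  d <- rep(100L, 1000L)
  expect_identical(apply_depth_noise(d, list(kind = "none")), d)
  pois <- apply_depth_noise(d, list(kind = "poisson"))
  expect_lt(abs(mean(pois) - 100), 3 * sqrt(100 / 1000))
  dip <- apply_depth_noise(d, list(kind = "poisson_with_homopolymer_dips",
                                   dip_fraction = 0.2,
                                   dip_depth_multiplier = 0.1))
  # ~200 positions should drop to mean depth 10
  expect_gt(sum(dip < 50), 100)
  expect_error(
    apply_depth_noise(d, list(kind = "poisson_with_homopolymer_dips")),
    "dip_fraction")
})
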