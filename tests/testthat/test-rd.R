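test_that("the analysis window resolves quarter bounds toward the interior", {
  expect_equal(unname(analysis_window(10)), c(3, 7))
  expect_equal(unname(analysis_window(100)), c(25, 75))
  expect_equal(unname(analysis_window(101)), c(26, 75))
  expect_equal(unname(analysis_window(4)), c(1, 3))
  expect_error(analysis_window(1), "too short")
  expect_error(analysis_window(10, lo = 0.8, hi = 0.2), "0 < lo < hi")
})

test_that("RD_ref reproduces the hand-computed worked example", {
  # L = 10, window 3..7, window depths 100,80,60,40,20:
  # (0 + 20 + 40 + 60 + 80) / (10 * 100) = 0.20 exactly
  p <- rep(100, 10)
  p[3:7] <- c(100, 80, 60, 40, 20)
  expect_identical(rd_ref(p), 0.20)

  # intact transcript: zero
  expect_identical(rd_ref(rep(100, 10)), 0)

  # fully degraded bound: 5 window positions * 100 / 1000 = 0.5
  z <- rep(100, 10); z[3:7] <- 0
  expect_identical(rd_ref(z), 0.5)

  expect_error(rd_ref(p, window = c(3, 11)), "window")
})

test_that("RD_delta is the windowed cohort difference and antisymmetric", {
  ref <- rep(100, 10)
  aged <- rep(100, 10)
  aged[3:7] <- c(100, 80, 60, 40, 20)
  expect_identical(rd_delta(ref, aged), 0.20)
  expect_identical(rd_delta(ref, ref), 0)
  expect_identical(rd_delta(aged, ref), -rd_delta(ref, aged))
  expect_error(rd_delta(ref, aged[1:5]), "length")
})

test_that("pipeline RD equals the brute-force summation oracle", {
  set.seed(41)
  design <- ten_sample_design()
  for (i in 1:50) {
    L <- sample(8:200, 1)
    d <- random_depth_matrix(L, design$sample_id)
    prof <- cohort_profiles(d, design)
    win <- analysis_window(L)
    got <- c(rd_ref = rd_ref(prof$young, win),
             rd_delta = rd_delta(prof$young, prof$aged, win))
    expect_equal(got, brute_rd(d, design), tolerance = 1e-12)
  }
})

test_that("RD is invariant to per-sample depth rescaling and bounded", {
  set.seed(42)
  design <- ten_sample_design()
  for (i in 1:10) {
    L <- sample(8:200, 1)
    d <- random_depth_matrix(L, design$sample_id)
    prof <- cohort_profiles(d, design)
    win <- analysis_window(L)
    r1 <- rd_ref(prof$young, win)
    s1 <- rd_delta(prof$young, prof$aged, win)
    # scale each sample by a different positive constant
    scaled <- d
    for (j in seq_len(ncol(d))) scaled[, j] <- d[, j] * j * 3
    prof2 <- cohort_profiles(depth_matrix(scaled, "x"), design)
    expect_equal(rd_ref(prof2$young, win), r1, tolerance = 1e-12)
    expect_equal(rd_delta(prof2$young, prof2$aged, win), s1,
                 tolerance = 1e-12)
    # bound: window size / L <= 0.5 + 1/L
    bound <- (win[2] - win[1] + 1) / L
    expect_lte(r1, bound); expect_gte(r1, 0)
    expect_lte(abs(s1), bound)
    expect_lte(bound, 0.5 + 1 / L)
  }
})

test_that("region classification follows the printed strict inequalities", {
  # the four anchor cases
  expect_equal(as.character(classify_region(0, 0.10)$region), "A")
  expect_equal(classify_region(0, 0.10)$flags, "A,Aprime")
  expect_equal(as.character(classify_region(0.20, 0.10)$region), "B")
  expect_equal(as.character(classify_region(0.12, 0.30)$region),
               "unclassified")
  expect_equal(as.character(classify_region(0.20, 0.45)$region), "C")
  expect_equal(as.character(classify_region(0.05, 0.45)$region), "D")

  # boundaries are strict: points exactly on a printed bound fall outside
  expect_false(grepl("A,", classify_region(0.02, 0.10)$flags))
  expect_equal(as.character(classify_region(0.15, 0.10)$region),
               "unclassified")
  expect_equal(as.character(classify_region(0.05, 0.2)$region),
               "unclassified")
})

test_that("classification over a dense grid is exhaustive and consistent", {
  grid <- expand.grid(delta = seq(-0.05, 0.6, by = 0.01),
                      ref = seq(-0.05, 0.6, by = 0.01))
  cls <- classify_region(grid$delta, grid$ref)
  b <- region_bounds()
  in_A <- grid$delta > b$A["delta_min"] & grid$delta < b$A["delta_max"] &
    grid$ref > b$A["ref_min"] & grid$ref < b$A["ref_max"]
  in_Ap <- grid$delta < 0.1 & grid$ref < 0.2
  in_B <- grid$delta > 0.15 & grid$ref < 0.2
  in_C <- grid$delta > 0.15 & grid$ref > 0.4
  in_D <- grid$delta < 0.1 & grid$ref > 0.4
  expect_identical(cls$region == "A", in_A)
  expect_identical(cls$region == "B", in_B)
  expect_identical(cls$region == "C", in_C)
  expect_identical(cls$region == "D", in_D)
  expect_identical(cls$region == "Aprime", in_Ap & !in_A)
  expect_identical(cls$region == "unclassified",
                   !(in_A | in_Ap | in_B | in_C | in_D))
  # B and C are disjoint; the A box lies inside A'
  expect_false(any(in_B & in_C))
  expect_true(all(!in_A | in_Ap))
  # flags record every satisfied predicate
  expect_identical(grepl("Aprime", cls$flags), in_Ap)
})

test_that("spike-in controls calibrate a box that contains them", {
  two <- data.frame(rd_delta = c(-0.01, 0.01), rd_ref = c(0.07, 0.11))
  b <- derive_spikein_bounds(two)
  expect_equal(unname(b$A), c(-0.01, 0.01, 0.07, 0.11), tolerance = 1e-6)
  expect_error(derive_spikein_bounds(two[1, , drop = FALSE]), "at least 2")

  set.seed(43)
  noisy <- data.frame(rd_delta = rnorm(10, 0, 0.01),
                      rd_ref = runif(10, 0.05, 0.12))
  b <- derive_spikein_bounds(noisy)
  expect_equal(unname(b$A["delta_min"]), min(noisy$rd_delta) - 1e-9)
  expect_equal(unname(b$A["ref_max"]), max(noisy$rd_ref) + 1e-9)
  # every calibrating control classifies as A under its own box
  cls <- classify_region(noisy$rd_delta, noisy$rd_ref, b)
  expect_true(all(cls$region == "A"))
})

test_that("through-origin regression matches its closed form", {
  r <- zero_intercept_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$slope, 1); expect_equal(r$r_squared, 1)
  r <- zero_intercept_regression(c(2, 4), c(1, 2))
  expect_equal(r$slope, 0.5); expect_equal(r$r_squared, 1)
  expect_error(zero_intercept_regression(c(0, 0), c(1, 2)), "all x")

  set.seed(44)
  x <- runif(200, 100, 5000)
  y <- 0.8 * x + rnorm(200, 0, 1e-6)
  r <- zero_intercept_regression(x, y)
  expect_equal(r$slope, 0.8, tolerance = 1e-6)
  expect_equal(r$slope, sum(x * y) / sum(x^2))
  # uncentered variant never exceeds 1 and differs from centered
  r2 <- zero_intercept_regression(x, y, r_squared = "uncentered")
  expect_lte(r2$r_squared, 1)
})

test_that("RD-length fits behave on degenerate and collinear input", {
  rec <- data.frame(length = c(100, 200, 300),
                    rd_ref = c(0.1, 0.1, 0.1),
                    rd_delta = c(0.0, 0.1, 0.2))
  fits <- rd_length_correlation(rec)
  expect_equal(fits$rd_ref$slope, 0)
  expect_equal(fits$rd_delta$r_squared, 1)
  expect_equal(fits$rd_delta$slope, 0.001)
  rec$length <- 100
  expect_error(rd_length_correlation(rec), "degenerate")
})

test_that("storage fragmentation makes RD_delta increase with length", {
  # longer transcripts accumulate more storage breaks, so the aged-vs-young
  # contrast rises with length and its linear fit is strong
  for (seed in 1:3) {
    res <- run_pipeline(study_config(seed, reads_per_sample = 4000L))
    bio <- res$rd[!res$rd$is_spike_in, ]
    fits <- rd_length_correlation(bio)
    expect_gt(fits$rd_delta$slope, 0)
    expect_gt(fits$rd_ref$slope, 0)
    expect_gt(cor(bio$length, bio$rd_delta, method = "spearman"), 0.6)
  }
})

test_that("GC percent counts ambiguity codes in the denominator only", {
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("GGCCN"), 80)
  expect_equal(gc_percent("gg-cc."), 100)
  expect_equal(gc_percent(Biostrings::DNAStringSet(c("ATGC", "GGGG"))),
               c(50, 100))
  expect_error(gc_percent(""), "empty")
})
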