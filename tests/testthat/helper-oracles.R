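# Independent brute-force oracles and fixture builders. These deliberately
# re-derive quantities with the most literal possible code (per-position
# loops) so they share nothing with the package implementation.

# brute-force pileup: count reads covering each position, one position at a
# time
brute_pileup <- function(starts, ends, L) {
  vapply(seq_len(L), function(b) sum(starts <= b & ends >= b), integer(1))
}

# brute-force RD: normalize each replicate by its own max, average cohorts
# position by position, then literal summation over the window
brute_rd <- function(depth, design, lo = 0.25, hi = 0.75) {
  ref <- attr(design, "reference_cohort")
  aged <- setdiff(unique(design$cohort_id), ref)
  L <- nrow(depth)
  norm1 <- function(v) 100 * v / max(v)
  mean_profile <- function(co) {
    reps <- design$sample_id[design$cohort_id == co]
    acc <- numeric(L)
    for (s in reps) acc <- acc + norm1(depth[, s])
    acc / length(reps)
  }
  dref <- mean_profile(ref)
  daged <- mean_profile(aged)
  start <- ceiling(lo * L)
  end <- floor(hi * L)
  s_ref <- 0
  s_delta <- 0
  for (b in start:end) {
    s_ref <- s_ref + (100 - dref[b])
    s_delta <- s_delta + (dref[b] - daged[b])
  }
  c(rd_ref = s_ref / (L * 100), rd_delta = s_delta / (L * 100))
}

# random depth matrix with every sample covered somewhere (presence holds)
random_depth_matrix <- function(L, samples, max_depth = 50L) {
  mat <- matrix(sample.int(max_depth, L * length(samples), replace = TRUE) -
                  sample(0:1, L * length(samples), replace = TRUE) *
                  sample.int(max_depth %/% 2L, L * length(samples),
                             replace = TRUE),
                nrow = L, dimnames = list(NULL, samples))
  mat[mat < 0L] <- 0L
  # guarantee a positive maximum per sample
  mat[1L, ] <- pmax(mat[1L, ], 1L)
  depth_matrix(mat, paste0("rtx", L))
}

ten_sample_design <- function() {
  cohort_design(list(young = paste0("Y", 1:5), aged = paste0("A", 1:5)))
}

# cascade fixture with pre-registered survivor sets:
#   presence 6 -> 4 (cx5, cx6 absent from >= 1 sample)
#   coverage 4 -> 3 (cx4 reference coverage 0.60 <= 0.75)
#   depth    3 -> 2 (cx3 peak depth 19 in sample Y3)
cascade_fixture <- function() {
  design <- ten_sample_design()
  L <- 100L
  samples <- design$sample_id
  full <- function(depth) matrix(depth, nrow = L, ncol = 10L,
                                 dimnames = list(NULL, samples))
  d <- list()
  d$cx1 <- depth_matrix(full(30L), "cx1")
  m <- full(25L); m[50L, ] <- 40L
  d$cx2 <- depth_matrix(m, "cx2")
  m <- full(30L); m[, "Y3"] <- 19L
  d$cx3 <- depth_matrix(m, "cx3")
  m <- full(30L); m[61:100, design$sample_id[design$cohort_id == "young"]] <- 0L
  d$cx4 <- depth_matrix(m, "cx4")
  m <- full(30L); m[, "A5"] <- 0L
  d$cx5 <- depth_matrix(m, "cx5")
  m <- full(30L); m[, c("Y1", "A1", "A2")] <- 0L
  d$cx6 <- depth_matrix(m, "cx6")
  list(depths = d, design = design,
       expect_presence = c("cx1", "cx2", "cx3", "cx4"),
       expect_coverage = c("cx1", "cx2", "cx3"),
       expect_depth = c("cx1", "cx2"))
}

# study conditions of the simulated two-cohort experiment
study_config <- function(seed, reads_per_sample = 10000L) {
  list(seed = seed,
       cohorts = list(young = paste0("Y", 1:5), aged = paste0("A", 1:5)),
       simulate = list(n_transcripts = 300L, n_spike_ins = 10L,
                       lambda_early = 2e-4, lambda_aging = 1.5e-3,
                       reads_per_sample = reads_per_sample))
}
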