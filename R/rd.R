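#' Central analysis window of a transcript
#'
#' RD statistics are computed only over the central 25-75% of the transcript
#' because coverage at transcript ends is unreliable (alignment clipping,
#' adapter trimming, poly(A) junction effects). The window is 1-based
#' inclusive, `[ceil(lo * L), floor(hi * L)]`, so positions exactly at a
#' quarter boundary resolve toward the interior.
#'
#' @param L transcript length, bp (>= 4 for the default fractions).
#' @param lo,hi window fractions, `0 < lo < hi <= 1`; defaults 0.25, 0.75.
#' @return integer `c(start, end)`.
#' @examples
#' analysis_window(10) # 3 7
#' @export
analysis_window <- function(L, lo = 0.25, hi = 0.75) {
  if (!(lo > 0 && lo < hi && hi <= 1)) stop("need 0 < lo < hi <= 1")
  start <- as.integer(ceiling(lo * L))
  end <- as.integer(floor(hi * L))
  if (start > end) {
    stop("transcript too short for the analysis window (L = ", L, ")")
  }
  c(start = start, end = end)
}

#' RD against a perfectly intact transcript (RD_ref)
#'
#' Sums the per-base deficit between the maximum possible normalized depth
#' (100) and the reference cohort's averaged profile over the analysis
#' window, and scales by the degradation of a perfectly intact transcript,
#' transcript length x 100:
#' \deqn{RD_{ref} = \sum_{b=start}^{end} (100 - \bar d_{ref}(b)) / (100 L)}
#' Small values mean high integrity already in the young cohort. Note the
#' denominator uses the full length L while the sum spans about half the
#' bases, so the attainable maximum is about 0.5.
#'
#' @param profile_ref cohort-averaged normalized profile (values in
#'   \[0, 100\]) over positions 1..L.
#' @param window integer `c(start, end)` from [analysis_window()]; default
#'   computed from `length(profile_ref)`.
#' @return dimensionless RD value.
#' @examples
#' p <- rep(100, 10); p[3:7] <- c(100, 80, 60, 40, 20)
#' rd_ref(p) # 0.2
#' @export
rd_ref <- function(profile_ref, window = analysis_window(length(profile_ref))) {
  L <- length(profile_ref)
  if (window[1] < 1 || window[2] > L) stop("window outside profile")
  w <- seq.int(window[1], window[2])
  sum(100 - profile_ref[w]) / (100 * L)
}

#' Additional RD of the aged cohort relative to the reference (RD_delta)
#'
#' Sums the per-base difference between the reference and aged cohorts'
#' averaged normalized profiles over the analysis window, scaled by
#' transcript length x 100:
#' \deqn{RD_\Delta = \sum_{b=start}^{end} (\bar d_{ref}(b) - \bar d_{aged}(b)) / (100 L)}
#' Positive values mean extra depth deficit in the aged cohort (degradation
#' during storage); small negative values occur when the aged profile sits
#' slightly above the reference.
#'
#' @param profile_ref,profile_aged cohort-averaged normalized profiles of
#'   the same transcript.
#' @param window integer `c(start, end)`; default from the profile length.
#' @return dimensionless RD value (sign carries direction).
#' @export
rd_delta <- function(profile_ref, profile_aged,
                     window = analysis_window(length(profile_ref))) {
  L <- length(profile_ref)
  if (length(profile_aged) != L) {
    stop("cohort profiles differ in length")
  }
  if (window[1] < 1 || window[2] > L) stop("window outside profile")
  w <- seq.int(window[1], window[2])
  sum(profile_ref[w] - profile_aged[w]) / (100 * L)
}

#' Default degradation-region bounds in the (RD_delta, RD_ref) plane
#'
#' Region A is the intact box calibrated by spike-in controls; A' a larger
#' intact-ish region; B transcripts intact in the young cohort but degraded
#' with storage; C degraded early and progressively more with storage; D
#' degraded early with little further change. All comparisons are strict
#' inequalities.
#'
#' @return list of class `region_bounds` with elements `A` (delta_min,
#'   delta_max, ref_min, ref_max), `Aprime` (delta_max, ref_max), `B`
#'   (delta_min, ref_max), `C` (delta_min, ref_min), `D` (delta_max,
#'   ref_min).
#' @export
region_bounds <- function() {
  structure(
    list(
      A = c(delta_min = -0.028, delta_max = 0.02,
            ref_min = 0.06, ref_max = 0.12),
      Aprime = c(delta_max = 0.1, ref_max = 0.2),
      B = c(delta_min = 0.15, ref_max = 0.2),
      C = c(delta_min = 0.15, ref_min = 0.4),
      D = c(delta_max = 0.1, ref_min = 0.4)),
    class = "region_bounds")
}

#' Calibrate the intact (region A) box from spike-in controls
#'
#' Spike-in transcripts are intact by construction, so the box spanned by
#' their observed RD values delimits "no degradation": A-box bounds are the
#' min/max of the spike-ins' RD_delta and RD_ref. Other regions keep the
#' bounds of `base`.
#'
#' @param rd_records data.frame with columns `rd_delta` and `rd_ref` for the
#'   spike-in transcripts (>= 2 rows).
#' @param base `region_bounds` to update; default [region_bounds()].
#' @param pad tiny outward padding added to the box so the calibrating
#'   controls themselves satisfy the strict region-A inequalities (the box
#'   is effectively closed at its corners); default `1e-9`, negligible on
#'   the RD scale.
#' @return updated `region_bounds`.
#' @export
derive_spikein_bounds <- function(rd_records, base = region_bounds(),
                                  pad = 1e-9) {
  if (nrow(rd_records) < 2L) {
    stop("need at least 2 spike-in transcripts to derive region A bounds")
  }
  base$A <- c(delta_min = min(rd_records$rd_delta) - pad,
              delta_max = max(rd_records$rd_delta) + pad,
              ref_min = min(rd_records$rd_ref) - pad,
              ref_max = max(rd_records$rd_ref) + pad)
  base
}

region_predicates <- function(rd_delta, rd_ref, bounds) {
  c(A = rd_delta > bounds$A["delta_min"] && rd_delta < bounds$A["delta_max"] &&
      rd_ref > bounds$A["ref_min"] && rd_ref < bounds$A["ref_max"],
    Aprime = rd_delta < bounds$Aprime["delta_max"] &&
      rd_ref < bounds$Aprime["ref_max"],
    B = rd_delta > bounds$B["delta_min"] && rd_ref < bounds$B["ref_max"],
    C = rd_delta > bounds$C["delta_min"] && rd_ref > bounds$C["ref_min"],
    D = rd_delta < bounds$D["delta_max"] && rd_ref > bounds$D["ref_min"])
}

#' Classify transcripts into degradation regions
#'
#' Evaluates every region predicate (strict inequalities) and assigns a
#' primary region: A if inside the spike-in box, otherwise whichever of
#' A', B, C, D holds (they are mutually exclusive under the default
#' bounds), otherwise `"unclassified"` — the bounds deliberately leave gaps,
#' e.g. 0.1 <= RD_delta <= 0.15 belongs to no region.
#'
#' @param rd_delta,rd_ref numeric vectors of RD coordinates.
#' @param bounds a `region_bounds`; default [region_bounds()].
#' @return data.frame with columns `rd_delta`, `rd_ref`, `region` (factor
#'   with levels A, Aprime, B, C, D, unclassified) and `flags`
#'   (comma-separated satisfied regions).
#' @examples
#' classify_region(c(0, 0.2, 0.2), c(0.10, 0.10, 0.45))$region
#' @export
classify_region <- function(rd_delta, rd_ref, bounds = region_bounds()) {
  stopifnot(length(rd_delta) == length(rd_ref),
            all(is.finite(rd_delta)), all(is.finite(rd_ref)))
  lv <- c("A", "Aprime", "B", "C", "D", "unclassified")
  n <- length(rd_delta)
  region <- character(n)
  flags <- character(n)
  for (i in seq_len(n)) {
    sat <- region_predicates(rd_delta[i], rd_ref[i], bounds)
    flags[i] <- paste(names(sat)[sat], collapse = ",")
    region[i] <- if (sat["A"]) {
      "A"
    } else {
      rest <- names(sat)[sat & names(sat) != "A"]
      if (length(rest) == 1L) rest else "unclassified"
    }
  }
  data.frame(rd_delta = rd_delta, rd_ref = rd_ref,
             region = factor(region, levels = lv),
             flags = flags, stringsAsFactors = FALSE)
}

#' Regression through the origin
#'
#' Fits `y = slope * x` by least squares (`slope = sum(xy)/sum(x^2)`), as
#' used to compare sequenced against reference transcript lengths. By
#' default R-squared uses the centered total sum of squares (the convention
#' of common spreadsheet software, comparable across intercept and
#' no-intercept fits); set `r_squared = "uncentered"` for the textbook
#' through-origin definition. The centered form can be negative for poor
#' fits and is reported as computed.
#'
#' @param x,y numeric vectors of equal length (>= 2 points).
#' @param r_squared `"centered"` or `"uncentered"`.
#' @return list with `slope` and `r_squared`.
#' @examples
#' zero_intercept_regression(c(2, 4), c(1, 2)) # slope 0.5, R^2 = 1
#' @export
zero_intercept_regression <- function(x, y,
                                      r_squared = c("centered", "uncentered")) {
  r_squared <- match.arg(r_squared)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sxx <- sum(x^2)
  if (sxx == 0) stop("all x are zero; slope undefined")
  slope <- sum(x * y) / sxx
  rss <- sum((y - slope * x)^2)
  tss <- if (r_squared == "centered") sum((y - mean(y))^2) else sum(y^2)
  list(slope = slope, r_squared = 1 - rss / tss)
}

#' Length dependence of the RD statistics
#'
#' Ordinary least-squares fits of `rd_ref ~ length` and `rd_delta ~ length`.
#' Under random strand fission longer transcripts accumulate more breaks, so
#' both slopes are positive and the aging contrast (rd_delta) is the more
#' strongly length-predicted statistic.
#'
#' @param rd_records data.frame with columns `length`, `rd_ref`, `rd_delta`
#'   (>= 3 rows).
#' @return list with elements `rd_ref` and `rd_delta`, each
#'   `list(slope, intercept, r_squared)`.
#' @export
rd_length_correlation <- function(rd_records) {
  stopifnot(nrow(rd_records) >= 3L)
  if (stats::var(rd_records$length) == 0) {
    stop("degenerate length variance; correlation undefined")
  }
  fit1 <- function(y) {
    f <- stats::lm(y ~ length, data = rd_records)
    list(slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]),
         r_squared = suppressWarnings(summary(f)$r.squared))
  }
  list(rd_ref = fit1(rd_records$rd_ref),
       rd_delta = fit1(rd_records$rd_delta))
}

#' Per-transcript RD table
#'
#' For every depth matrix: normalize replicates, average within cohorts,
#' compute RD_ref (reference cohort vs intact) and RD_delta (reference minus
#' aged) over the central window, and classify the degradation region.
#' Requires exactly two cohorts (reference + one aged).
#'
#' @param depths named list of `depth_matrix` (typically curation
#'   survivors).
#' @param design a `cohort_design` with two cohorts.
#' @param transcripts optional `transcript_set` supplying `gc_fraction` and
#'   `is_spike_in` columns for the output.
#' @param bounds `region_bounds` used for classification.
#' @param lo,hi analysis-window fractions; defaults 0.25 and 0.75.
#' @return data.frame: `transcript_id`, `length`, `gc_percent` (NA without
#'   `transcripts`), `is_spike_in`, `rd_ref`, `rd_delta`, `region`, `flags`.
#' @export
rd_table <- function(depths, design, transcripts = NULL,
                     bounds = region_bounds(), lo = 0.25, hi = 0.75) {
  ref <- reference_cohort(design)
  cohorts <- unique(design$cohort_id)
  aged <- setdiff(cohorts, ref)
  if (length(aged) != 1L) {
    stop("rd_table needs exactly one non-reference cohort, got ",
         length(aged))
  }
  rows <- lapply(names(depths), function(tx) {
    prof <- cohort_profiles(depths[[tx]], design)
    L <- nrow(depths[[tx]])
    win <- analysis_window(L, lo, hi)
    data.frame(
      transcript_id = tx, length = L,
      rd_ref = rd_ref(prof[[ref]], win),
      rd_delta = rd_delta(prof[[ref]], prof[[aged]], win),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cls <- classify_region(out$rd_delta, out$rd_ref, bounds)
  out$region <- cls$region
  out$flags <- cls$flags
  if (!is.null(transcripts)) {
    m <- match(out$transcript_id, transcripts$id)
    out$gc_percent <- 100 * transcripts$gc_fraction[m]
    out$is_spike_in <- transcripts$is_spike_in[m]
  } else {
    out$gc_percent <- NA_real_
    out$is_spike_in <- NA
  }
  out[, c("transcript_id", "length", "gc_percent", "is_spike_in",
          "rd_ref", "rd_delta", "region", "flags")]
}

#' Summarize an RD table by degradation region
#'
#' @param rd data.frame from [rd_table()].
#' @return data.frame with one row per region: transcript count, mean
#'   length, mean GC percent, mean RD values.
#' @export
region_summary <- function(rd) {
  sp <- split(rd, rd$region)
  out <- do.call(rbind, lapply(names(sp), function(rg) {
    d <- sp[[rg]]
    data.frame(region = rg, n = nrow(d),
               mean_length = if (nrow(d)) mean(d$length) else NA_real_,
               mean_gc_percent = if (nrow(d)) mean(d$gc_percent) else NA_real_,
               mean_rd_ref = if (nrow(d)) mean(d$rd_ref) else NA_real_,
               mean_rd_delta = if (nrow(d)) mean(d$rd_delta) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
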