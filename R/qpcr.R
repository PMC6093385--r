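#' Define a two-amplicon transcript-integrity assay
#'
#' The assay compares the qPCR abundance of a 5'-end amplicon with a 3'-end
#' amplicon of the same transcript. In a 3'-anchored cDNA library a
#' fragmented template loses the 5' amplicon first, so the Ct difference
#' between the ends measures integrity.
#'
#' @param transcript_id transcript identifier.
#' @param amplicon_5p,amplicon_3p integer `c(start, end)`, 1-based
#'   inclusive; the 5' amplicon must end before the 3' amplicon starts.
#' @param efficiency amplification factor per cycle, in (1, 2.2\].
#' @param L optional transcript length to validate amplicons against.
#' @return list of class `amplicon_assay`.
#' @export
amplicon_assay <- function(transcript_id, amplicon_5p, amplicon_3p,
                           efficiency = 2, L = NULL) {
  stopifnot(length(amplicon_5p) == 2L, length(amplicon_3p) == 2L)
  if (amplicon_5p[1] > amplicon_5p[2] || amplicon_3p[1] > amplicon_3p[2]) {
    stop("amplicon start must not exceed its end")
  }
  if (amplicon_5p[2] >= amplicon_3p[1]) {
    stop("the 5' amplicon must end before the 3' amplicon starts")
  }
  if (amplicon_5p[1] < 1) stop("amplicons must start at position >= 1")
  if (!is.null(L) && amplicon_3p[2] > L) {
    stop("3' amplicon extends past the transcript end")
  }
  if (efficiency <= 1 || efficiency > 2.2) {
    stop("primer efficiency must lie in (1, 2.2]")
  }
  structure(
    list(transcript_id = as.character(transcript_id),
         amplicon_5p = as.integer(amplicon_5p),
         amplicon_3p = as.integer(amplicon_3p),
         efficiency = efficiency),
    class = "amplicon_assay")
}

#' Transcript integrity as a Ct difference
#'
#' \eqn{\Delta Ct = Ct_{3'} - Ct_{5'}}. A negative value means the 5' end of
#' the transcript is less abundant than the 3' end — the signature of
#' fragmentation in 3'-anchored libraries.
#'
#' @param ct_3p,ct_5p Ct values (cycles) of the 3' and 5' amplicons;
#'   vectorized.
#' @return ΔCt in cycles.
#' @examples
#' delta_ct(18.82, 20.00) # -1.18
#' @export
delta_ct <- function(ct_3p, ct_5p) ct_3p - ct_5p

#' Primer efficiency from a serial-dilution standard curve
#'
#' Regresses Ct on log2 relative input over a 2-fold dilution series. With
#' slope `m`, the per-cycle amplification factor is `E = 2^(-1/m)` (a
#' perfect doubling gives m = -1, E = 2). The QC band 1.93-2.13 is the
#' acceptance window within which Ct values are directly comparable between
#' primer pairs.
#'
#' @param ct Ct values, one per dilution point (>= 3 points).
#' @param log2_input log2 relative template input per point (e.g. `0, -1,
#'   -2, ...` for successive 2-fold dilutions); default assumes consecutive
#'   2-fold dilutions in the given order.
#' @param band numeric `c(lower, upper)` acceptance band for E.
#' @param monotone_tol warn if Ct decreases by more than this between
#'   successive dilutions (cycles).
#' @return list with `efficiency`, `slope`, `pass` (inside the band) and
#'   `r_squared` of the standard curve.
#' @examples
#' efficiency_from_dilution(20 + 0:7)$efficiency # 2
#' @export
efficiency_from_dilution <- function(ct, log2_input = -(seq_along(ct) - 1),
                                     band = c(1.93, 2.13),
                                     monotone_tol = 0.5) {
  stopifnot(length(ct) == length(log2_input))
  if (length(ct) < 3L) stop("need at least 3 dilution points")
  ord <- order(log2_input, decreasing = TRUE)
  steps <- diff(ct[ord])  # should rise as input halves
  if (any(steps < -monotone_tol)) {
    warning("Ct trend is non-monotone across the dilution series; ",
            "standard curve may be unreliable")
  }
  fit <- stats::lm(ct ~ log2_input)
  m <- unname(stats::coef(fit)[2])
  if (m >= 0) stop("non-negative standard-curve slope; no amplification signal")
  e <- 2^(-1 / m)
  list(efficiency = e, slope = m,
       pass = e >= band[1] && e <= band[2],
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Ct of a reaction from its template fraction
#'
#' Standard exponential amplification model: a reaction whose template is a
#' fraction `template_fraction` of the reference amount crosses threshold at
#' `ct_intercept - log(template_fraction)/log(E)` cycles. Optional Gaussian
#' technical noise. Uses the current RNG when `sd_noise > 0`.
#'
#' @param template_fraction fraction of amplifiable template in (0, 1\].
#' @param E amplification factor per cycle (> 1).
#' @param ct_intercept Ct of a full-template reaction.
#' @param sd_noise SD of technical noise in cycles (default 0).
#' @return Ct in cycles (vectorized over `template_fraction`).
#' @examples
#' simulate_ct(0.25, E = 2, ct_intercept = 20) # 22
#' @export
simulate_ct <- function(template_fraction, E, ct_intercept, sd_noise = 0) {
  if (any(template_fraction <= 0)) {
    stop("template_fraction must be positive (no amplifiable template)")
  }
  if (any(template_fraction > 1)) stop("template_fraction must be <= 1")
  if (E <= 1) stop("amplification factor E must exceed 1")
  ct <- ct_intercept - log(template_fraction) / log(E)
  if (sd_noise > 0) ct <- ct + stats::rnorm(length(ct), 0, sd_noise)
  ct
}

#' Closed-form expected ΔCt under the strand-fission model
#'
#' Bridges the fragmentation model to the qPCR readout. In oligo(dT)-primed
#' libraries (poly(A)-selected or total RNA) a cDNA covers an amplicon
#' starting at `s` iff no bond between `s` and the 3' end broke, so the
#' template fraction is `(1-lam)^(L-s)` and
#' \deqn{\Delta Ct = (s_{3'} - s_{5'}) \ln(1-\lambda) / \ln E \le 0.}
#' In random-hexamer total-RNA libraries an amplicon amplifies iff it is
#' internally unbroken, so the template depends only on amplicon length and
#' the cohort contrast vanishes for equal-length amplicons:
#' \deqn{\Delta Ct = (len_{5'} - len_{3'}) \ln(1-\lambda) / \ln E.}
#'
#' @param assay an `amplicon_assay`.
#' @param L transcript length, bp.
#' @param lam per-bond break probability.
#' @param library one of `"polyA_oligodT"`, `"total_oligodT"`,
#'   `"polyA_hexamer"`, `"total_hexamer"`.
#' @return expected ΔCt in cycles.
#' @examples
#' a <- amplicon_assay("tx", c(101, 200), c(901, 1000), efficiency = 2)
#' expected_delta_ct(a, L = 1500, lam = 0.002, library = "polyA_oligodT")
#' @export
expected_delta_ct <- function(assay, L, lam,
                              library = c("polyA_oligodT", "total_oligodT",
                                          "polyA_hexamer", "total_hexamer")) {
  library <- match.arg(library)
  stopifnot(inherits(assay, "amplicon_assay"))
  if (lam < 0 || lam >= 1) stop("lam must lie in [0, 1)")
  if (assay$amplicon_3p[2] > L) stop("assay does not fit transcript length L")
  if (lam == 0) return(0)
  E <- assay$efficiency
  if (grepl("oligodT$", library)) {
    span <- assay$amplicon_3p[1] - assay$amplicon_5p[1]
    span * log(1 - lam) / log(E)
  } else {
    len5 <- diff(assay$amplicon_5p) + 1L
    len3 <- diff(assay$amplicon_3p) + 1L
    (len5 - len3) * log(1 - lam) / log(E)
  }
}

#' Monte-Carlo qPCR of a fragmented transcript pool
#'
#' Simulates `n_molecules` copies of the transcript through the per-bond
#' break process and the library chemistry, counts molecules whose cDNA
#' covers each amplicon, and converts template fractions to Ct values. For
#' oligo(dT) libraries a cDNA is the 3'-terminal fragment and must span the
#' whole amplicon; for random-hexamer libraries an amplicon amplifies iff
#' none of its internal bonds broke. Uses the current RNG.
#'
#' @param assay an `amplicon_assay`.
#' @param L transcript length, bp.
#' @param lam per-bond break probability.
#' @param library library code as in [expected_delta_ct()].
#' @param n_molecules pool size.
#' @param ct_intercept Ct of a full-template reaction.
#' @param sd_noise technical noise SD (cycles).
#' @return list with `ct_5p`, `ct_3p`, `delta_ct`, and the template
#'   fractions `frac_5p`, `frac_3p`.
#' @export
simulate_qpcr <- function(assay, L, lam,
                          library = c("polyA_oligodT", "total_oligodT",
                                      "polyA_hexamer", "total_hexamer"),
                          n_molecules = 1e5, ct_intercept = 20,
                          sd_noise = 0) {
  library <- match.arg(library)
  stopifnot(inherits(assay, "amplicon_assay"))
  if (assay$amplicon_3p[2] > L) stop("assay does not fit transcript length L")
  lam <- min(max(lam, 0), 1)
  if (grepl("oligodT$", library)) {
    # 3'-terminal fragment starts at L - (intact 3' bonds); geometric scan
    k <- if (lam == 0) rep(L - 1L, n_molecules) else
      stats::rgeom(n_molecules, prob = lam)
    start <- pmax(1L, L - pmin(k, L - 1L))
    n5 <- sum(start <= assay$amplicon_5p[1])
    n3 <- sum(start <= assay$amplicon_3p[1])
  } else {
    len5 <- diff(assay$amplicon_5p) + 1L
    len3 <- diff(assay$amplicon_3p) + 1L
    n5 <- sum(stats::rbinom(n_molecules, len5 - 1L, lam) == 0L)
    n3 <- sum(stats::rbinom(n_molecules, len3 - 1L, lam) == 0L)
  }
  f5 <- n5 / n_molecules
  f3 <- n3 / n_molecules
  if (f5 == 0 || f3 == 0) {
    stop("no amplifiable template for one amplicon; increase n_molecules")
  }
  ct5 <- simulate_ct(f5, assay$efficiency, ct_intercept, sd_noise)
  ct3 <- simulate_ct(f3, assay$efficiency, ct_intercept, sd_noise)
  list(ct_5p = ct5, ct_3p = ct3, delta_ct = delta_ct(ct3, ct5),
       frac_5p = f5, frac_3p = f3)
}

#' Aggregate a Ct table into per-cohort ΔCt summaries
#'
#' Technical replicates are averaged within each biological sample first;
#' ΔCt is then computed per sample, library and transcript, and summarized
#' as mean ± SD over biological replicates within each cohort, with a
#' two-sample Welch t-test between cohorts where both have >= 2 replicates.
#'
#' @param ct_table data.frame with columns `sample_id`, `cohort_id`,
#'   `library`, `transcript_id`, `amplicon_end` (`"5p"`/`"3p"`), `ct`, and
#'   optionally `technical_replicate`.
#' @return data.frame with one row per (library, transcript, cohort):
#'   `n`, `mean_delta_ct`, `sd_delta_ct`, plus `p_value` of the
#'   between-cohort comparison (repeated across the two cohort rows).
#' @export
aggregate_delta_ct <- function(ct_table) {
  need <- c("sample_id", "cohort_id", "library", "transcript_id",
            "amplicon_end", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss)) stop("ct_table lacks columns: ", paste(miss, collapse = ", "))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  # mean over technical replicates
  agg <- stats::aggregate(
    ct ~ sample_id + cohort_id + library + transcript_id + amplicon_end,
    data = ct_table, FUN = mean)
  wide <- stats::reshape(
    agg, direction = "wide", timevar = "amplicon_end",
    idvar = c("sample_id", "cohort_id", "library", "transcript_id"))
  if (!all(c("ct.5p", "ct.3p") %in% names(wide))) {
    stop("each sample needs both 5p and 3p amplicon measurements")
  }
  wide$delta_ct <- delta_ct(wide$ct.3p, wide$ct.5p)
  out <- do.call(rbind, lapply(
    split(wide, list(wide$library, wide$transcript_id), drop = TRUE),
    function(d) {
      per <- do.call(rbind, lapply(split(d, d$cohort_id), function(g) {
        data.frame(library = g$library[1], transcript_id = g$transcript_id[1],
                   cohort_id = g$cohort_id[1], n = nrow(g),
                   mean_delta_ct = mean(g$delta_ct),
                   sd_delta_ct = stats::sd(g$delta_ct),
                   stringsAsFactors = FALSE)
      }))
      per$p_value <- NA_real_
      if (length(unique(d$cohort_id)) == 2L && all(per$n >= 2L)) {
        tt <- stats::t.test(delta_ct ~ cohort_id, data = d)
        per$p_value <- tt$p.value
      }
      per
    }))
  rownames(out) <- NULL
  out
}

#' Read / write Ct tables
#'
#' Plain TSV with the columns [aggregate_delta_ct()] expects.
#'
#' @param path TSV path.
#' @return for `read_ct_table`, the Ct data.frame.
#' @export
read_ct_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @param ct_table Ct data.frame.
#' @rdname read_ct_table
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.table(ct_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
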