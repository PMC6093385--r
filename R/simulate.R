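#' Cohort design: samples, cohorts and the reference cohort
#'
#' Describes the sequencing design: which replicate samples belong to which
#' cohort, and which cohort is the reference ("young") one. In a seed-aging
#' study the reference cohort is the recently harvested, fully viable seed
#' lot; every other cohort is treated as aged and receives the additional
#' aging break rate in simulations.
#'
#' @param cohorts named list; each element is a character vector of replicate
#'   sample ids for that cohort.
#' @param reference name of the reference cohort (default: first).
#' @return A `data.frame` of class `cohort_design` with columns `sample_id`
#'   and `cohort_id`, and attribute `reference_cohort`.
#' @examples
#' cohort_design(list(young = paste0("Y", 1:5), aged = paste0("A", 1:5)))
#' @export
cohort_design <- function(cohorts, reference = names(cohorts)[1]) {
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    stop("cohorts must be a named list")
  }
  if (!reference %in% names(cohorts)) {
    stop("reference cohort '", reference, "' is not among the cohorts")
  }
  ids <- unlist(cohorts, use.names = FALSE)
  if (anyDuplicated(ids)) stop("sample ids must be globally unique")
  out <- data.frame(
    sample_id = ids,
    cohort_id = rep(names(cohorts), lengths(cohorts)),
    stringsAsFactors = FALSE
  )
  attr(out, "reference_cohort") <- reference
  class(out) <- c("cohort_design", "data.frame")
  out
}

#' Reference cohort of a design
#' @param design a `cohort_design`.
#' @return the reference cohort id.
#' @export
reference_cohort <- function(design) attr(design, "reference_cohort")

#' Fragmentation model for the strand-fission library simulator
#'
#' Degradation is modeled as molecular fission: each of the `L - 1`
#' phosphodiester bonds of a transcript breaks independently with a small
#' per-bond probability. `lambda_early` applies to molecules in every cohort
#' (damage incurred during maturation, drying and early storage);
#' `lambda_aging` is the additional per-bond rate accumulated by the aged
#' cohort(s) during prolonged dry storage. Spike-in transcripts are never
#' fragmented (they are added intact immediately before library prep).
#'
#' Library chemistry: with `priming = "oligo_dT"` and `selection = "polyA"`
#' only the 3'-terminal fragment of each molecule retains the poly(A) tail
#' and is captured, which produces the characteristic 5'-to-3' increasing
#' coverage of degraded samples. With `priming = "random_hexamer"` and
#' `selection = "total"` one fragment is captured per molecule with
#' probability proportional to its length (priming sites scale with length),
#' giving near-uniform coverage.
#'
#' @param lambda_early per-bond break probability common to all cohorts.
#' @param lambda_aging additional per-bond break probability for non-reference
#'   cohorts.
#' @param priming `"oligo_dT"` or `"random_hexamer"`.
#' @param selection `"polyA"` or `"total"`. Supported combinations are
#'   oligo_dT + polyA and random_hexamer + total.
#' @param reads_per_sample number of captured molecules per sample.
#' @param depth_noise a list describing per-base depth noise:
#'   `list(kind = "none")`, `list(kind = "poisson")`, or
#'   `list(kind = "poisson_with_homopolymer_dips", dip_fraction =, dip_depth_multiplier =)`.
#'   Poisson noise resamples each depth as `rpois(1, depth)`; homopolymer dips
#'   additionally scale expected depth down at a random subset of positions,
#'   mimicking basecaller dropouts in homopolymer stretches.
#' @param seed integer seed; identical seeds give bit-identical libraries.
#' @return a list of class `fragmentation_model`.
#' @export
fragmentation_model <- function(lambda_early = 2e-4, lambda_aging = 1.5e-3,
                                priming = c("oligo_dT", "random_hexamer"),
                                selection = c("polyA", "total"),
                                reads_per_sample = 10000L,
                                depth_noise = list(kind = "none"),
                                seed = 1L) {
  priming <- match.arg(priming)
  selection <- match.arg(selection)
  check_priming_selection(priming, selection)
  if (lambda_early < 0 || lambda_aging < 0) {
    stop("break rates must be non-negative")
  }
  if (reads_per_sample < 0) stop("reads_per_sample must be >= 0")
  if (!is.list(depth_noise) || is.null(depth_noise$kind)) {
    stop("depth_noise must be a list with a 'kind' element")
  }
  if (!depth_noise$kind %in%
      c("none", "poisson", "poisson_with_homopolymer_dips")) {
    stop("unknown depth_noise kind: ", depth_noise$kind)
  }
  structure(
    list(lambda_early = lambda_early, lambda_aging = lambda_aging,
         priming = priming, selection = selection,
         reads_per_sample = as.integer(reads_per_sample),
         depth_noise = depth_noise, seed = as.integer(seed)),
    class = "fragmentation_model"
  )
}

check_priming_selection <- function(priming, selection) {
  ok <- (priming == "oligo_dT" && selection == "polyA") ||
    (priming == "random_hexamer" && selection == "total")
  if (!ok) {
    stop("unsupported priming/selection combination: ",
         priming, " + ", selection)
  }
  invisible(TRUE)
}

#' Simulate break positions along one molecule
#'
#' Each of the `L - 1` inter-base bonds breaks independently with probability
#' `min(lam, 1)`. Equivalently (and how it is sampled here) the number of
#' breaks is binomial with `L - 1` trials and the broken bonds are a uniform
#' random subset; the two formulations have identical distribution, but the
#' binomial route costs O(breaks) rather than O(L) per molecule.
#'
#' Uses the current RNG state.
#'
#' @param L transcript length in bp (>= 1).
#' @param lam per-bond break probability (>= 0; values above 1 act as 1).
#' @return sorted integer vector of broken bond indices in `1..L-1`; bond `b`
#'   separates bases `b` and `b + 1`.
#' @examples
#' simulate_breakpoints(1000, 0)   # integer(0)
#' simulate_breakpoints(2, 1)      # always 1
#' @export
simulate_breakpoints <- function(L, lam) {
  if (lam < 0) stop("break rate lam must be non-negative")
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  if (L == 1L) return(integer(0))
  p <- min(lam, 1)
  m <- stats::rbinom(1L, L - 1L, p)
  if (m == 0L) return(integer(0))
  sort(sample.int(L - 1L, m))
}

#' Capture one sequenced fragment from a broken molecule
#'
#' Under oligo(dT) priming of poly(A)-selected RNA only the 3'-terminal
#' fragment keeps the poly(A) tail, so the captured read is
#' `[last break + 1, L]` (`[1, L]` for an unbroken molecule). Under
#' random-hexamer priming of total RNA one fragment is captured with
#' probability proportional to its length and the read spans that fragment's
#' full extent.
#'
#' @param breaks sorted broken bond indices (from [simulate_breakpoints()]).
#' @param L transcript length, bp.
#' @param priming,selection library chemistry; see [fragmentation_model()].
#' @return integer `c(start, end)`, 1-based inclusive.
#' @export
capture_fragment <- function(breaks, L,
                             priming = c("oligo_dT", "random_hexamer"),
                             selection = c("polyA", "total")) {
  priming <- match.arg(priming)
  selection <- match.arg(selection)
  check_priming_selection(priming, selection)
  L <- as.integer(L)
  if (length(breaks) &&
      (min(breaks) < 1L || max(breaks) > L - 1L)) {
    stop("break positions must lie in 1..L-1")
  }
  if (priming == "oligo_dT") {
    start <- if (length(breaks)) max(breaks) + 1L else 1L
    return(c(as.integer(start), L))
  }
  # random hexamer: fragments between consecutive breaks, length-weighted
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, L)
  lens <- ends - starts + 1L
  i <- if (length(lens) == 1L) 1L else {
    sample.int(length(lens), 1L, prob = lens)
  }
  c(starts[i], ends[i])
}

#' Closed-form expected coverage under 3'-anchored capture
#'
#' For oligo(dT)-primed, poly(A)-selected libraries a captured molecule
#' covers position `x` exactly when no bond between `x` and the 3' end is
#' broken, so the coverage probability is `(1 - lam)^(L - x)` (up to the
#' common capture normalization). This is the analytic oracle the simulator
#' is checked against, and the source of the 5'-to-3' increasing coverage of
#' degraded libraries.
#'
#' @param x position(s), 1-based, in `1..L`.
#' @param L transcript length, bp.
#' @param lam per-bond break probability.
#' @return numeric vector of coverage probabilities.
#' @examples
#' expected_coverage(1501, 3001, 1e-3) # ~0.2231
#' @export
expected_coverage <- function(x, L, lam) {
  if (lam < 0) stop("break rate lam must be non-negative")
  if (any(x < 1 | x > L)) stop("position x out of range 1..L")
  (1 - min(lam, 1))^(L - x)
}

#' Simulate a multi-sample whole-molecule cDNA library
#'
#' Draws `reads_per_sample` molecules per sample with transcript chosen
#' proportionally to abundance, fragments each molecule by the per-bond
#' break process (reference cohort: `lambda_early`; other cohorts:
#' `lambda_early + lambda_aging`; spike-ins: 0), and captures one read per
#' molecule according to the library chemistry. Deterministic given
#' `model$seed`.
#'
#' @param transcripts a `transcript_set`.
#' @param model a `fragmentation_model`.
#' @param design a `cohort_design`.
#' @return list of class `sim_library`:
#'   * `reads`: data.frame (sample_id, transcript_id, start, end, n_breaks)
#'   * `truth`: data.frame of the true per-bond rate per transcript x cohort
#'   * `transcripts`, `design`, `model`: the inputs.
#' @export
simulate_library <- function(transcripts, model, design) {
  stopifnot(inherits(transcripts, "transcript_set"),
            inherits(model, "fragmentation_model"),
            inherits(design, "cohort_design"))
  if (nrow(transcripts) == 0L) stop("empty transcript set")
  set.seed(model$seed)
  ref <- reference_cohort(design)
  n_tx <- nrow(transcripts)
  reads_list <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    lam_cohort <- model$lambda_early +
      if (design$cohort_id[s] == ref) 0 else model$lambda_aging
    n <- model$reads_per_sample
    if (n == 0L) {
      reads_list[[s]] <- data.frame(
        sample_id = character(0), transcript_id = character(0),
        start = integer(0), end = integer(0), n_breaks = integer(0),
        stringsAsFactors = FALSE)
      next
    }
    tx_idx <- sample.int(n_tx, n, replace = TRUE, prob = transcripts$abundance)
    start <- integer(n); end <- integer(n); nb <- integer(n)
    for (r in seq_len(n)) {
      i <- tx_idx[r]
      L <- transcripts$length[i]
      lam <- if (transcripts$is_spike_in[i]) 0 else lam_cohort
      brk <- simulate_breakpoints(L, lam)
      iv <- capture_fragment(brk, L, model$priming, model$selection)
      start[r] <- iv[1]; end[r] <- iv[2]; nb[r] <- length(brk)
    }
    reads_list[[s]] <- data.frame(
      sample_id = design$sample_id[s],
      transcript_id = transcripts$id[tx_idx],
      start = start, end = end, n_breaks = nb,
      stringsAsFactors = FALSE)
  }
  truth <- expand.grid(
    transcript_id = transcripts$id,
    cohort_id = unique(design$cohort_id),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$lambda <- ifelse(
    transcripts$is_spike_in[match(truth$transcript_id, transcripts$id)], 0,
    model$lambda_early +
      ifelse(truth$cohort_id == ref, 0, model$lambda_aging))
  structure(
    list(reads = do.call(rbind, reads_list), truth = truth,
         transcripts = transcripts, design = design, model = model),
    class = "sim_library")
}

#' Recover the per-bond break rate from a coverage profile
#'
#' Under 3'-anchored capture the expected coverage at position `x` is
#' `(1 - lam)^(L - x)`, so regressing `log(coverage)` on `L - x` over the
#' central analysis window gives slope `log(1 - lam)`. The inverse of that
#' relation estimates lambda from an observed depth profile.
#'
#' @param depth per-base depth vector of one transcript in one library
#'   (oligo(dT)/poly(A) chemistry).
#' @param n_reads number of captured reads behind the profile; defaults to
#'   the depth at the 3' terminus, which every captured read covers.
#' @param lo,hi analysis-window fractions (defaults 0.25, 0.75).
#' @return estimated per-bond break probability.
#' @export
estimate_break_rate <- function(depth, n_reads = depth[length(depth)],
                                lo = 0.25, hi = 0.75) {
  L <- length(depth)
  win <- analysis_window(L, lo, hi)
  x <- seq.int(win[1], win[2])
  cov <- depth[x] / n_reads
  if (any(cov <= 0)) {
    stop("zero coverage inside the analysis window; profile too shallow ",
         "to estimate a break rate")
  }
  fit <- stats::lm(log(cov) ~ I(L - x))
  slope <- unname(stats::coef(fit)[2])
  1 - exp(slope)
}

#' Apply configured depth noise to one raw depth vector
#'
#' @param depth integer depth vector.
#' @param depth_noise noise description; see [fragmentation_model()].
#' @return integer depth vector of the same length. Uses the current RNG.
#' @keywords internal
#' @export
apply_depth_noise <- function(depth, depth_noise = list(kind = "none")) {
  kind <- depth_noise$kind
  if (kind == "none") return(depth)
  mu <- as.numeric(depth)
  if (kind == "poisson_with_homopolymer_dips") {
    frac <- depth_noise$dip_fraction
    mult <- depth_noise$dip_depth_multiplier
    if (is.null(frac) || is.null(mult) || frac < 0 || frac > 1 ||
        mult < 0 || mult > 1) {
      stop("homopolymer dips need dip_fraction and dip_depth_multiplier in [0, 1]")
    }
    n_dip <- round(frac * length(mu))
    if (n_dip > 0) {
      at <- sample.int(length(mu), n_dip)
      mu[at] <- mu[at] * mult
    }
  }
  stats::rpois(length(mu), mu)
}

#' Write simulated reads as a minimal SAM file
#'
#' One ungapped primary alignment line per read (`<len>M` CIGAR, `*`
#' sequence), with `@SQ` headers from the transcript set. Output is
#' deterministic given the read table, so fixed-seed simulations round-trip
#' byte-identically.
#'
#' @param reads read table from [simulate_library()] (`$reads`).
#' @param transcripts the `transcript_set` the reads were simulated from.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, transcripts, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", transcripts$id, transcripts$length))
  writeLines(hdr, con, sep = "\n")
  if (nrow(reads)) {
    lines <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                     sprintf("read%06d_%s", seq_len(nrow(reads)),
                             reads$sample_id),
                     reads$transcript_id, reads$start,
                     reads$end - reads$start + 1L)
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write the simulator's ground-truth table as TSV
#'
#' @param truth `$truth` from [simulate_library()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
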