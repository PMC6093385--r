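#' Build a filter report
#'
#' @param stage stage name.
#' @param status data.frame with columns `transcript_id`, `pass` (logical),
#'   `reason` (character, empty for passing transcripts).
#' @return `filter_report` object recording input/output counts and the
#'   per-transcript outcome.
#' @keywords internal
filter_report <- function(stage, status) {
  structure(
    list(stage = stage,
         n_in = nrow(status),
         n_out = sum(status$pass),
         status = status),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: %d -> %d transcripts\n",
              x$stage, x$n_in, x$n_out))
  invisible(x)
}

#' Presence filter: transcript seen in every sample
#'
#' A transcript survives only if every sample of the design contains at
#' least one aligned read for it (maximum depth >= 1 per sample). This is the
#' first curation stage: cohort comparison is meaningless for transcripts
#' absent from some replicate.
#'
#' @param depths named list of `depth_matrix`.
#' @param design a `cohort_design`.
#' @return list with `survivors` (character vector of transcript ids) and
#'   `report` (a `filter_report`).
#' @export
presence_filter <- function(depths, design) {
  status <- do.call(rbind, lapply(names(depths), function(tx) {
    d <- depths[[tx]][, design$sample_id, drop = FALSE]
    seen <- apply(d, 2L, max) >= 1L
    data.frame(
      transcript_id = tx,
      pass = all(seen),
      reason = if (all(seen)) "" else
        paste0("absent in ", paste(design$sample_id[!seen], collapse = ",")),
      stringsAsFactors = FALSE)
  }))
  list(survivors = status$transcript_id[status$pass],
       report = filter_report("presence", status))
}

#' Fraction of transcript positions with any coverage
#'
#' @param depth numeric depth vector over positions 1..L.
#' @return fraction in \[0, 1\] of positions with depth >= 1.
#' @examples
#' coverage_fraction(c(0, 0, 3, 1, 0)) # 0.4
#' @export
coverage_fraction <- function(depth) {
  if (!length(depth)) return(0)
  mean(depth >= 1)
}

#' Observed (sequenced) transcript length
#'
#' The covered span: number of positions with depth >= 1. Regressed against
#' reference length, this quantifies how much of each transcript the library
#' actually represents — a slope below 1 in an aged cohort reflects
#' fragmentation-driven loss of the 5' portion of long transcripts.
#'
#' @param depth depth vector, or a `depth_matrix` (then the mean covered
#'   span across the given samples is returned).
#' @param samples samples to average over when `depth` is a matrix
#'   (default: all).
#' @return observed length in bp (possibly fractional when averaged).
#' @export
observed_length <- function(depth, samples = NULL) {
  if (is.matrix(depth)) {
    if (is.null(samples)) samples <- colnames(depth)
    return(mean(colSums(depth[, samples, drop = FALSE] >= 1)))
  }
  sum(depth >= 1)
}

#' Coverage filter on the reference cohort
#'
#' Survives if reference-cohort coverage exceeds `threshold` (strictly).
#' With `mode = "mean"` (default) the per-replicate covered fractions are
#' averaged; with `mode = "all"` every reference replicate must individually
#' exceed the threshold.
#'
#' @param depths named list of `depth_matrix` (typically presence survivors).
#' @param design a `cohort_design`.
#' @param threshold coverage threshold in (0, 1\]; default 0.75.
#' @param cohort cohort whose coverage is assessed; default the reference.
#' @param mode `"mean"` or `"all"`.
#' @return list with `survivors` and `report`.
#' @export
coverage_filter <- function(depths, design, threshold = 0.75,
                            cohort = reference_cohort(design),
                            mode = c("mean", "all")) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) {
    stop("coverage threshold must lie in (0, 1]")
  }
  reps <- design$sample_id[design$cohort_id == cohort]
  if (!length(reps)) stop("cohort '", cohort, "' has no samples")
  status <- do.call(rbind, lapply(names(depths), function(tx) {
    fr <- vapply(reps, function(s) coverage_fraction(depths[[tx]][, s]),
                 numeric(1))
    ok <- if (mode == "mean") mean(fr) > threshold else all(fr > threshold)
    data.frame(
      transcript_id = tx,
      pass = ok,
      reason = if (ok) "" else
        sprintf("%s coverage %.3f <= %.2f in %s",
                mode, if (mode == "mean") mean(fr) else min(fr),
                threshold, cohort),
      stringsAsFactors = FALSE)
  }))
  list(survivors = status$transcript_id[status$pass],
       report = filter_report("coverage", status))
}

#' Depth filter: deeply sequenced transcripts
#'
#' Survives if the transcript is deeply sequenced: at least one base reaches
#' raw depth `min_max_depth`. With `mode = "per_sample"` (default) this must
#' hold in every sample — the strictest reading, guaranteeing each replicate
#' supports the cohort comparison; with `mode = "pooled"` depths are summed
#' across samples first.
#'
#' @param depths named list of `depth_matrix`.
#' @param design a `cohort_design`.
#' @param min_max_depth required peak depth (>= 1); default 20.
#' @param mode `"per_sample"` or `"pooled"`.
#' @return list with `survivors` and `report`.
#' @export
depth_filter <- function(depths, design, min_max_depth = 20L,
                         mode = c("per_sample", "pooled")) {
  mode <- match.arg(mode)
  if (min_max_depth < 1) stop("min_max_depth must be >= 1")
  status <- do.call(rbind, lapply(names(depths), function(tx) {
    d <- depths[[tx]][, design$sample_id, drop = FALSE]
    if (mode == "per_sample") {
      peaks <- apply(d, 2L, max)
      ok <- all(peaks >= min_max_depth)
      why <- if (ok) "" else
        sprintf("peak depth %d < %d in %s", min(peaks), min_max_depth,
                design$sample_id[which.min(peaks)])
    } else {
      peak <- max(rowSums(d))
      ok <- peak >= min_max_depth
      why <- if (ok) "" else
        sprintf("pooled peak depth %d < %d", peak, min_max_depth)
    }
    data.frame(transcript_id = tx, pass = ok, reason = why,
               stringsAsFactors = FALSE)
  }))
  list(survivors = status$transcript_id[status$pass],
       report = filter_report("depth", status))
}

#' Run the full transcript-curation cascade
#'
#' Applies, in order: presence in all samples, reference-cohort coverage
#' > `coverage_threshold`, and peak depth >= `min_max_depth`. Each stage only
#' sees the previous stage's survivors, so survivor sets are nested and the
#' input count of each stage equals the output count of the one before.
#'
#' @param depths named list of `depth_matrix`.
#' @param design a `cohort_design`.
#' @param coverage_threshold strict coverage threshold; default 0.75.
#' @param min_max_depth peak-depth requirement; default 20.
#' @param coverage_mode,depth_mode see [coverage_filter()] and
#'   [depth_filter()].
#' @return list of class `filter_cascade` with `survivors` (final ids) and
#'   `reports` (list of the three `filter_report`s).
#' @export
filter_cascade <- function(depths, design, coverage_threshold = 0.75,
                           min_max_depth = 20L,
                           coverage_mode = "mean",
                           depth_mode = "per_sample") {
  st1 <- presence_filter(depths, design)
  st2 <- coverage_filter(depths[st1$survivors], design,
                         threshold = coverage_threshold,
                         mode = coverage_mode)
  st3 <- depth_filter(depths[st2$survivors], design,
                      min_max_depth = min_max_depth, mode = depth_mode)
  structure(
    list(survivors = st3$survivors,
         reports = list(presence = st1$report,
                        coverage = st2$report,
                        depth = st3$report)),
    class = "filter_cascade")
}

#' @export
print.filter_cascade <- function(x, ...) {
  for (r in x$reports) print(r)
  invisible(x)
}

#' Write a filter cascade's per-transcript outcomes as TSV
#'
#' @param cascade a `filter_cascade`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(cascade, path) {
  rows <- do.call(rbind, lapply(cascade$reports, function(r) {
    cbind(stage = r$stage, r$status)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
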