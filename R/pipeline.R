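#' Assemble a pipeline configuration
#'
#' A single configuration object drives the whole analysis: either a
#' simulator block (synthetic study) or paths to real inputs (depth TSV or
#' SAM/BAM plus reference FASTA), the sample sheet, curation thresholds,
#' region bounds and the analysis-window fractions. All randomness flows
#' from the one `seed`.
#'
#' @param config a named list, or a path to a YAML file holding one.
#'   Recognized top-level fields:
#'   \describe{
#'     \item{seed}{integer; default 1.}
#'     \item{cohorts}{named list of sample-id vectors; required.}
#'     \item{reference_cohort}{defaults to the first cohort.}
#'     \item{simulate}{optional list with `n_transcripts`, `length_range`,
#'       `n_spike_ins`, `lambda_early`, `lambda_aging`, `priming`,
#'       `selection`, `reads_per_sample`, `depth_noise`.}
#'     \item{depth_tsv, fasta}{inputs when not simulating.}
#'     \item{spike_ins}{character vector (or file of) spike-in ids, used to
#'       derive region-A bounds when present.}
#'     \item{filters}{list: `coverage_threshold` (0.75), `min_max_depth`
#'       (20), `coverage_mode`, `depth_mode`.}
#'     \item{window}{list: `lo` (0.25), `hi` (0.75).}
#'   }
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    # file paths in a YAML config are relative to the config file
    for (fld in c("depth_tsv", "fasta", "spike_ins")) {
      if (!is.null(config[[fld]]) && is.character(config[[fld]]) &&
          length(config[[fld]]) == 1L && !file.exists(config[[fld]])) {
        cand <- file.path(dir, config[[fld]])
        if (file.exists(cand)) config[[fld]] <- cand
      }
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$cohorts) || !length(config$cohorts)) {
    stop("configuration error: no samples — the sample sheet ('cohorts') ",
         "is missing or empty")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$reference_cohort <- config$reference_cohort %||%
    names(config$cohorts)[1]
  f <- config$filters %||% list()
  config$filters <- list(
    coverage_threshold = f$coverage_threshold %||% 0.75,
    min_max_depth = f$min_max_depth %||% 20L,
    coverage_mode = f$coverage_mode %||% "mean",
    depth_mode = f$depth_mode %||% "per_sample")
  w <- config$window %||% list()
  config$window <- list(lo = w$lo %||% 0.25, hi = w$hi %||% 0.75)
  if (!(config$window$lo > 0 && config$window$lo < config$window$hi &&
        config$window$hi <= 1)) {
    stop("window fractions must satisfy 0 < lo < hi <= 1")
  }
  if (is.null(config$simulate) && is.null(config$depth_tsv)) {
    stop("configuration error: provide either a 'simulate' block or a ",
         "'depth_tsv' input")
  }
  class(config) <- c("pipeline_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full degradation-analysis pipeline
#'
#' Stages, in order: simulate (or load depth), curation filter cascade, RD
#' computation, region classification (with the intact box recalibrated from
#' spike-ins when at least two survive curation), and region summary. The
#' run is deterministic given the configuration's seed.
#'
#' @param config a `pipeline_config`, or anything [pipeline_config()]
#'   accepts.
#' @param out_dir optional directory; when given, writes `rd_table.tsv`,
#'   `filter_report.tsv`, `region_summary.tsv` (and, for simulated runs,
#'   `depth.tsv` and `ground_truth.tsv`).
#' @return list of class `rd_pipeline`: `rd` (RD table), `cascade`
#'   (filter reports), `summary` (region summary), `bounds`, `depths`,
#'   `design`, `transcripts` (NULL for TSV input without a transcript set),
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- pipeline_config(config)
  set.seed(config$seed)
  design <- cohort_design(config$cohorts, config$reference_cohort)
  transcripts <- NULL
  sim <- NULL
  if (!is.null(config$simulate)) {
    s <- config$simulate
    transcripts <- random_transcripts(
      n = s$n_transcripts %||% 300L,
      length_range = s$length_range %||% c(300, 7000),
      n_spike_ins = s$n_spike_ins %||% 0L)
    model <- fragmentation_model(
      lambda_early = s$lambda_early %||% 2e-4,
      lambda_aging = s$lambda_aging %||% 1.5e-3,
      priming = s$priming %||% "oligo_dT",
      selection = s$selection %||% "polyA",
      reads_per_sample = s$reads_per_sample %||% 10000L,
      depth_noise = s$depth_noise %||% list(kind = "none"),
      seed = config$seed)
    sim <- simulate_library(transcripts, model, design)
    depths <- depth_from_reads(sim$reads, transcripts,
                               samples = design$sample_id,
                               depth_noise = model$depth_noise)
    spike_ids <- transcripts$id[transcripts$is_spike_in]
  } else {
    if (!is.null(config$fasta)) {
      lengths <- fasta_lengths(config$fasta)
    } else if (!is.null(config$lengths)) {
      lengths <- unlist(config$lengths)
    } else {
      stop("configuration error: transcript lengths require a 'fasta' or ",
           "'lengths' entry")
    }
    depths <- load_depth_tsv(config$depth_tsv, lengths,
                             samples = design$sample_id)
    spike_ids <- config$spike_ins %||% character(0)
    if (length(spike_ids) == 1L && file.exists(spike_ids)) {
      spike_ids <- readLines(spike_ids)
    }
  }
  cascade <- filter_cascade(
    depths, design,
    coverage_threshold = config$filters$coverage_threshold,
    min_max_depth = config$filters$min_max_depth,
    coverage_mode = config$filters$coverage_mode,
    depth_mode = config$filters$depth_mode)
  if (!length(cascade$survivors)) {
    stop("stage 'filter': no transcripts survive curation")
  }
  rd <- rd_table(depths[cascade$survivors], design, transcripts,
                 lo = config$window$lo, hi = config$window$hi)
  bounds <- region_bounds()
  spike_rd <- rd[rd$transcript_id %in% spike_ids, , drop = FALSE]
  if (nrow(spike_rd) >= 2L) {
    bounds <- derive_spikein_bounds(spike_rd, bounds)
    cls <- classify_region(rd$rd_delta, rd$rd_ref, bounds)
    rd$region <- cls$region
    rd$flags <- cls$flags
  }
  summary <- region_summary(rd)
  result <- structure(
    list(rd = rd, cascade = cascade, summary = summary, bounds = bounds,
         depths = depths, design = design, transcripts = transcripts,
         sim = sim, config = config),
    class = "rd_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_plain(rd, file.path(out_dir, "rd_table.tsv"))
    write_filter_report(cascade, file.path(out_dir, "filter_report.tsv"))
    write_tsv_plain(summary, file.path(out_dir, "region_summary.tsv"))
    if (!is.null(sim)) {
      write_depth_tsv(depths, file.path(out_dir, "depth.tsv"))
      write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.tsv"))
    }
  }
  result
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.rd_pipeline <- function(x, ...) {
  cat("<rd_pipeline>\n")
  print(x$cascade)
  cat("RD table:", nrow(x$rd), "transcripts\n")
  print(table(x$rd$region))
  invisible(x)
}

#' Plot cohort coverage profiles with shaded RD areas
#'
#' Draws the cohort-averaged normalized depth of one transcript against
#' position (optionally smoothed for display), shading the area between the
#' reference profile and the intact ceiling of 100 (the RD_ref deficit) and
#' the area between the reference and aged profiles (the RD_delta deficit),
#' both restricted to the central analysis window.
#'
#' @param depth a `depth_matrix` for the transcript.
#' @param design a `cohort_design` with two cohorts.
#' @param w display smoothing window in bp (default 100; smoothing never
#'   feeds the RD computation).
#' @param lo,hi analysis-window fractions.
#' @param file optional output path (png/pdf/svg by extension); when NULL
#'   the ggplot object is returned unprinted.
#' @return the ggplot object, invisibly when `file` is given.
#' @export
render_profile_plot <- function(depth, design, w = 100L,
                                lo = 0.25, hi = 0.75, file = NULL) {
  tx <- attr(depth, "transcript_id")
  prof <- cohort_profiles(depth, design)
  ref <- reference_cohort(design)
  aged <- setdiff(names(prof), ref)[1]
  L <- nrow(depth)
  win <- analysis_window(L, lo, hi)
  sm <- lapply(prof, smooth_moving_window, w = w)
  pos <- seq_len(L)
  df <- data.frame(
    pos = rep(pos, 2L),
    depth = c(sm[[ref]], sm[[aged]]),
    cohort = rep(c(ref, aged), each = L))
  inwin <- pos >= win[1] & pos <= win[2]
  ribbon_ref <- data.frame(pos = pos[inwin],
                           ymin = sm[[ref]][inwin], ymax = 100)
  ribbon_delta <- data.frame(
    pos = pos[inwin],
    ymin = pmin(sm[[ref]][inwin], sm[[aged]][inwin]),
    ymax = sm[[ref]][inwin])
  p <- ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = ribbon_ref,
      ggplot2::aes(x = .data$pos, ymin = .data$ymin, ymax = .data$ymax),
      fill = "grey70", alpha = 0.5) +
    ggplot2::geom_ribbon(
      data = ribbon_delta,
      ggplot2::aes(x = .data$pos, ymin = .data$ymin, ymax = .data$ymax),
      fill = "orange", alpha = 0.5) +
    ggplot2::geom_line(
      data = df,
      ggplot2::aes(x = .data$pos, y = .data$depth,
                   colour = .data$cohort, linetype = .data$cohort)) +
    ggplot2::labs(x = "position (bp)", y = "normalized depth (0-100)",
                  title = tx,
                  subtitle = sprintf(
                    "grey: deficit of %s vs intact (RD_ref); orange: %s vs %s (RD_delta)",
                    ref, ref, aged)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
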