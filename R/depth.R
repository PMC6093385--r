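#' Construct a per-transcript depth matrix
#'
#' The central container for coverage: an integer matrix with one row per
#' base position (1..L) and one column per sample, carrying the transcript id
#' as an attribute. Missing positions are zero depth by construction.
#'
#' @param depth integer matrix, positions x samples; column names are sample
#'   ids.
#' @param transcript_id transcript identifier.
#' @return the matrix with class `depth_matrix`.
#' @export
depth_matrix <- function(depth, transcript_id) {
  depth <- as.matrix(depth)
  if (is.null(colnames(depth))) stop("depth matrix needs sample column names")
  if (any(depth < 0)) stop("depths must be non-negative")
  structure(depth, transcript_id = as.character(transcript_id),
            class = c("depth_matrix", class(depth)))
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat("<depth_matrix> transcript", attr(x, "transcript_id"),
      "-", nrow(x), "bp x", ncol(x), "samples\n")
  invisible(x)
}

#' Per-base depth from read intervals
#'
#' Computes, for every transcript and sample, the number of reads whose
#' aligned span covers each base — the same quantity `samtools depth -a`
#' reports — using a difference-array sweep (add 1 at each read start,
#' subtract 1 past each end, cumulative sum).
#'
#' @param reads data.frame with columns `sample_id`, `transcript_id`,
#'   `start`, `end` (1-based inclusive), e.g. `simulate_library()$reads`.
#' @param lengths named integer vector of transcript lengths (e.g. from
#'   [fasta_lengths()] or a `transcript_set`).
#' @param samples character vector of sample ids defining column order;
#'   defaults to the samples present in `reads`.
#' @param depth_noise optional noise description applied per transcript and
#'   sample; see [fragmentation_model()]. Uses the current RNG.
#' @return named list of `depth_matrix`, one per transcript in `lengths`.
#' @export
depth_from_reads <- function(reads, lengths, samples = NULL,
                             depth_noise = list(kind = "none")) {
  if (inherits(lengths, "transcript_set")) {
    lengths <- stats::setNames(lengths$length, lengths$id)
  }
  if (is.null(samples)) samples <- unique(reads$sample_id)
  bad <- setdiff(unique(reads$transcript_id), names(lengths))
  if (length(bad)) {
    stop("reads reference unknown transcripts: ",
         paste(bad, collapse = ", "))
  }
  out <- vector("list", length(lengths))
  names(out) <- names(lengths)
  by_tx <- split(seq_len(nrow(reads)),
                 factor(reads$transcript_id, levels = names(lengths)))
  for (tx in names(lengths)) {
    L <- as.integer(lengths[[tx]])
    mat <- matrix(0L, nrow = L, ncol = length(samples),
                  dimnames = list(NULL, samples))
    rtx <- reads[by_tx[[tx]], , drop = FALSE]
    by_sample <- split(seq_len(nrow(rtx)),
                       factor(rtx$sample_id, levels = samples))
    for (s in samples) {
      rs <- rtx[by_sample[[s]], , drop = FALSE]
      if (nrow(rs)) {
        if (any(rs$start < 1L | rs$end > L | rs$start > rs$end)) {
          stop("read interval outside 1..L for transcript ", tx)
        }
        diffarr <- numeric(L + 1L)
        add <- tabulate(rs$start, nbins = L)
        sub <- tabulate(rs$end + 1L, nbins = L + 1L)
        diffarr[seq_len(L)] <- add
        diffarr <- diffarr - sub
        mat[, s] <- as.integer(cumsum(diffarr)[seq_len(L)])
      }
      if (depth_noise$kind != "none") {
        mat[, s] <- apply_depth_noise(mat[, s], depth_noise)
      }
    }
    out[[tx]] <- depth_matrix(mat, tx)
  }
  out
}

#' Per-base depth from a SAM/BAM alignment file
#'
#' Reads primary alignments (secondary and supplementary records are
#' dropped: one molecule, one read) with Rsamtools/GenomicAlignments and
#' computes per-base depth against the reference transcriptome. SAM input is
#' converted to BAM on the fly.
#'
#' @param path SAM or BAM file of alignments against the transcriptome.
#' @param lengths named lengths as in [depth_from_reads()], used to validate
#'   reference names and zero-fill uncovered transcripts.
#' @param samples single sample id for this file, or a function mapping read
#'   names to sample ids (the simulator's SAM writer encodes the sample in
#'   the read name as `read<N>_<sample>`).
#' @return named list of `depth_matrix`.
#' @export
depth_from_alignments <- function(path, lengths, samples = NULL) {
  for (p in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(p, quietly = TRUE)) {
      stop("package '", p, "' is required to read alignments")
    }
  }
  if (inherits(lengths, "transcript_set")) {
    lengths <- stats::setNames(lengths$length, lengths$id)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, use.names = TRUE, param = Rsamtools::ScanBamParam(flag = flag))
  refs <- as.character(GenomicAlignments::seqnames(ga))
  bad <- setdiff(unique(refs), names(lengths))
  if (length(bad)) {
    stop("alignment references not in the transcriptome: ",
         paste(bad, collapse = ", "))
  }
  sample_of <- if (is.function(samples)) {
    samples(names(ga))
  } else if (is.null(samples)) {
    sub("^.*_", "", names(ga))
  } else {
    rep(samples[[1]], length(ga))
  }
  reads <- data.frame(
    sample_id = sample_of,
    transcript_id = refs,
    start = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    stringsAsFactors = FALSE)
  depth_from_reads(reads, lengths, samples = sort(unique(sample_of)))
}

#' Read a samtools-depth-style TSV into depth matrices
#'
#' Expects a header line `transcript_id<TAB>pos<TAB><sample>...` followed by
#' one row per covered position (1-based). Positions absent from the file are
#' zero-filled up to the transcript length, so sparse output (samtools depth
#' without `-a`) loads correctly.
#'
#' @param path TSV path.
#' @param lengths named transcript lengths (see [depth_from_reads()]); every
#'   transcript listed here yields a matrix, even if absent from the file.
#' @param samples optional sample ids to select/validate against the sample
#'   sheet; default: all depth columns in the file.
#' @return named list of `depth_matrix`.
#' @export
load_depth_tsv <- function(path, lengths, samples = NULL) {
  if (inherits(lengths, "transcript_set")) {
    lengths <- stats::setNames(lengths$length, lengths$id)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L && ncol(tab) < 3L) {
    # empty file: all-zero matrices still need sample columns
    if (is.null(samples)) stop("empty depth file and no samples given")
    tab <- data.frame(transcript_id = character(0), pos = integer(0))
    for (s in samples) tab[[s]] <- integer(0)
  }
  depth_cols <- setdiff(colnames(tab), c("transcript_id", "pos"))
  if (!is.null(samples)) {
    unknown <- setdiff(samples, depth_cols)
    if (length(unknown)) {
      stop("sample column(s) missing from depth file: ",
           paste(unknown, collapse = ", "))
    }
    depth_cols <- samples
  }
  out <- vector("list", length(lengths))
  names(out) <- names(lengths)
  for (tx in names(lengths)) {
    L <- as.integer(lengths[[tx]])
    rows <- tab[tab$transcript_id == tx, , drop = FALSE]
    if (nrow(rows) && (any(rows$pos < 1L) || any(rows$pos > L))) {
      stop("depth position outside 1..", L, " for transcript ", tx)
    }
    mat <- matrix(0L, nrow = L, ncol = length(depth_cols),
                  dimnames = list(NULL, depth_cols))
    if (nrow(rows)) {
      mat[rows$pos, ] <- as.matrix(rows[, depth_cols, drop = FALSE])
    }
    out[[tx]] <- depth_matrix(mat, tx)
  }
  out
}

#' Write depth matrices as a samtools-depth-style TSV
#'
#' Inverse of [load_depth_tsv()]: a header row, then one row per transcript
#' position with per-sample depth columns. All positions are written
#' (zero-depth rows included) so round-trips are exact.
#'
#' @param depths named list of `depth_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(depths, path) {
  stopifnot(length(depths) > 0)
  samples <- colnames(depths[[1]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("transcript_id", "pos", samples), collapse = "\t"),
             con, sep = "\n")
  for (tx in names(depths)) {
    d <- depths[[tx]]
    stopifnot(identical(colnames(d), samples))
    block <- cbind(tx, seq_len(nrow(d)),
                   matrix(as.character(d), nrow = nrow(d)))
    writeLines(apply(block, 1L, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Normalize a depth profile to 0-100
#'
#' Scales one sample's per-base depth so the deepest position of the full
#' transcript is 100. This removes library-size differences between
#' replicates before cohort averaging and puts every transcript on the scale
#' the RD statistics are defined on.
#'
#' @param depth numeric depth vector over positions 1..L.
#' @return numeric vector in \[0, 100\].
#' @examples
#' normalize_profile(c(1, 2, 4)) # 25 50 100
#' @export
normalize_profile <- function(depth) {
  m <- max(depth)
  if (!is.finite(m) || m <= 0) {
    stop("profile undefined: no positive depth (transcript should have ",
         "been removed by the presence filter)")
  }
  100 * depth / m
}

#' Average normalized replicate profiles within a cohort
#'
#' @param profiles list (or matrix columns) of equal-length normalized
#'   profiles, one per replicate.
#' @return numeric vector: the unweighted per-position mean, with attribute
#'   `n_replicates`.
#' @export
average_cohort <- function(profiles) {
  if (is.list(profiles)) {
    if (length(unique(lengths(profiles))) != 1L) {
      stop("replicate profiles differ in length")
    }
    profiles <- do.call(cbind, profiles)
  }
  out <- rowMeans(profiles)
  attr(out, "n_replicates") <- ncol(profiles)
  out
}

#' Cohort-averaged normalized profiles for one transcript
#'
#' Normalizes each replicate to 0-100 (per-replicate maximum over the full
#' transcript), then averages within each cohort.
#'
#' @param depth a `depth_matrix`.
#' @param design a `cohort_design` whose samples are columns of `depth`.
#' @return named list of cohort profiles (numeric vectors in \[0, 100\]).
#' @export
cohort_profiles <- function(depth, design) {
  missing <- setdiff(design$sample_id, colnames(depth))
  if (length(missing)) {
    stop("samples missing from depth matrix: ",
         paste(missing, collapse = ", "))
  }
  cohorts <- unique(design$cohort_id)
  out <- vector("list", length(cohorts))
  names(out) <- cohorts
  for (co in cohorts) {
    reps <- design$sample_id[design$cohort_id == co]
    normed <- lapply(reps, function(s) normalize_profile(depth[, s]))
    out[[co]] <- average_cohort(normed)
  }
  out
}

#' Centered moving-window average for display
#'
#' Smooths a profile with a centered window of `w` bases, truncated at the
#' transcript ends (positions near an end average over fewer bases). Used
#' only for plotting coverage archetypes; RD statistics are always computed
#' from unsmoothed profiles.
#'
#' @param profile numeric vector.
#' @param w window width in bases (>= 1); for even `w` the window extends
#'   `w/2 - 1` bases left and `w/2` bases right.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_moving_window <- function(profile, w = 100L) {
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("window width w must be >= 1")
  n <- length(profile)
  if (w == 1L || n == 0L) return(profile)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  cs <- cumsum(c(0, profile))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
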