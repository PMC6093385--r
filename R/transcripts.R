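#' Build a transcript set
#'
#' A transcript set describes the reference transcriptome the simulator and
#' the depth/RD machinery operate on: one row per transcript with its length,
#' GC fraction, relative abundance (expected share of sequenced molecules) and
#' a spike-in flag. Spike-in transcripts model ERCC-style synthetic controls
#' added just before library preparation: they are intact by construction and
#' calibrate the "no degradation" region of the RD plane.
#'
#' @param id character vector of unique transcript identifiers.
#' @param length integer vector of transcript lengths in bp (>= 1).
#' @param gc_fraction numeric in \[0, 1\]; GC fraction of each transcript.
#' @param abundance positive relative weight; molecules are drawn with
#'   probability proportional to it.
#' @param is_spike_in logical; spike-ins are never fragmented by the
#'   simulator.
#' @return A `data.frame` of class `transcript_set` with columns
#'   `id`, `length`, `gc_fraction`, `abundance`, `is_spike_in`.
#' @examples
#' transcript_set(c("tx1", "spk1"), c(2000L, 800L),
#'                gc_fraction = c(0.42, 0.5),
#'                is_spike_in = c(FALSE, TRUE))
#' @export
transcript_set <- function(id, length, gc_fraction = 0.42, abundance = 1,
                           is_spike_in = FALSE) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("transcript ids must be unique")
  length <- as.integer(length)
  if (any(length < 1L)) stop("transcript lengths must be >= 1 bp")
  n <- base::length(id)
  gc_fraction <- rep_len(gc_fraction, n)
  if (any(gc_fraction < 0 | gc_fraction > 1)) {
    stop("gc_fraction must lie in [0, 1]")
  }
  abundance <- rep_len(as.numeric(abundance), n)
  if (any(abundance <= 0)) stop("abundance must be positive")
  out <- data.frame(
    id = id, length = length, gc_fraction = gc_fraction,
    abundance = abundance, is_spike_in = rep_len(as.logical(is_spike_in), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' Generate a random transcript set emulating a seed transcriptome
#'
#' Lengths are drawn log-uniformly (typical mRNA length spread over more than
#' an order of magnitude), GC fractions uniformly within the range observed
#' for plant mRNA, and abundances log-uniformly over two decades (the
#' per-transcript read-count distribution of real libraries spans orders of
#' magnitude). Spike-ins get shorter, tighter lengths and high abundance so
#' they are deeply covered, like ERCC controls.
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param n number of biological transcripts.
#' @param length_range length range in bp for log-uniform sampling.
#' @param gc_range GC-fraction range.
#' @param abundance_decades abundances are `10^runif(n, 0, abundance_decades)`.
#' @param n_spike_ins number of intact spike-in controls appended.
#' @param spike_in_length_range length range of the spike-ins, bp.
#' @return A `transcript_set`.
#' @export
random_transcripts <- function(n, length_range = c(300, 7000),
                               gc_range = c(0.35, 0.50),
                               abundance_decades = 2,
                               n_spike_ins = 0,
                               spike_in_length_range = c(500, 2000)) {
  stopifnot(n >= 1, length_range[1] >= 1, length_range[1] <= length_range[2])
  len <- round(exp(stats::runif(n, log(length_range[1]), log(length_range[2]))))
  gc <- stats::runif(n, gc_range[1], gc_range[2])
  ab <- 10^stats::runif(n, 0, abundance_decades)
  id <- sprintf("tx%04d", seq_len(n))
  spike <- rep(FALSE, n)
  if (n_spike_ins > 0) {
    slen <- round(exp(stats::runif(n_spike_ins,
                                   log(spike_in_length_range[1]),
                                   log(spike_in_length_range[2]))))
    id <- c(id, sprintf("spikein%02d", seq_len(n_spike_ins)))
    len <- c(len, slen)
    gc <- c(gc, stats::runif(n_spike_ins, 0.45, 0.55))
    # controls are spiked at the top of the endogenous abundance range so
    # they stay deeply covered in every replicate (as ERCC mixes are)
    ab <- c(ab, rep(2 * 10^abundance_decades, n_spike_ins))
    spike <- c(spike, rep(TRUE, n_spike_ins))
  }
  transcript_set(id, len, gc, ab, spike)
}

#' Percent GC of a nucleotide sequence
#'
#' G and C (upper or lower case) count toward the numerator; every non-gap
#' character, including IUPAC ambiguity codes, counts in the denominator.
#' Gap characters (`-`, `.`) are ignored entirely.
#'
#' @param sequence a character vector of sequences (or a
#'   `Biostrings::DNAStringSet`/`RNAStringSet`).
#' @return numeric vector of GC percentages in \[0, 100\].
#' @examples
#' gc_percent(c("ATGC", "GGCCN")) # 50, 80
#' @export
gc_percent <- function(sequence) {
  if (methods::is(sequence, "XStringSet")) {
    sequence <- as.character(sequence)
  }
  sequence <- as.character(sequence)
  sequence <- gsub("[-.]", "", toupper(sequence))
  if (any(!nzchar(sequence))) stop("empty sequence")
  total <- nchar(sequence)
  gc <- nchar(gsub("[^GC]", "", sequence))
  100 * gc / total
}

#' Write synthetic transcript sequences as FASTA
#'
#' Generates a random sequence per transcript at its stated length and GC
#' fraction and writes a reference FASTA. Sequences are synthetic: they carry
#' the lengths and base composition the rest of the pipeline needs, not real
#' gene sequences. Uses the current RNG state.
#'
#' @param transcripts a `transcript_set`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  stopifnot(inherits(transcripts, "transcript_set"))
  seqs <- vapply(seq_len(nrow(transcripts)), function(i) {
    L <- transcripts$length[i]
    gc <- transcripts$gc_fraction[i]
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- transcripts$id
  Biostrings::writeXStringSet(dna, filepath = path, width = 70L)
  invisible(path)
}

#' Read transcript lengths from a reference FASTA
#'
#' @param path FASTA file of reference transcripts.
#' @return named integer vector of lengths (bp).
#' @export
fasta_lengths <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  stats::setNames(Biostrings::width(dna), names(dna))
}
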