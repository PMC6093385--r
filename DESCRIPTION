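Package: seedRD
Title: Relative Degradation Analysis of mRNA in Dry-Stored Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies mRNA fragmentation in aged, dry-stored seeds from
    whole-molecule cDNA sequencing coverage. Per-base read depth over a
    reference transcriptome is normalized per sample, averaged within
    cohorts, and summarized per transcript by two relative-degradation
    statistics: RD_ref (depth deficit of the young cohort against a
    perfectly intact transcript) and RD_delta (additional deficit of the
    aged cohort against the young cohort), computed over the central
    25-75% of each transcript. Transcripts are classified into degradation
    regions (A, A-prime, B, C, D) in the (RD_delta, RD_ref) plane, with
    the intact box calibrated from ERCC-style spike-in controls. Includes
    the transcript-curation filter cascade (presence in all samples,
    coverage, depth), a random strand-fission library simulator with
    3'-anchored oligo(dT) and random-hexamer chemistry and closed-form
    expected coverage, and a qPCR delta-Ct transcript integrity assay
    with primer-efficiency checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ggplot2,
    methods,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    GenomicAlignments,
    IRanges,
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
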