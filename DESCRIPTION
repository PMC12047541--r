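Package: aschip
Title: Allele-Specific ChIP-seq Analysis in F1 Hybrids with Indel-Aware
    Bias Correction and the Combined Haplotype Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying cis-acting effects of genetic variants
    (SNPs and indels) on transcription-factor occupancy from allele-specific
    ChIP-seq of F1 hybrid crosses. Provides indel-aware removal of reference
    mapping bias by allele-swap read remapping, construction of consensus
    peaks and per-sample total and allele-specific count tables, the combined
    haplotype test (a joint beta-binomial / beta-negative-binomial likelihood
    with a shared allelic-effect parameter), variant-centered motif-disruption
    scanning with allelic-imbalance-based motif reconstruction,
    predictor-based variant prioritisation (predicted allelic imbalance and in
    silico saturation mutagenesis), and a fully seeded synthetic-data
    generator producing genome, phased variant panel, and paired-end reads
    with known ground truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
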