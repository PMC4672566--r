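Package: ldident
Title: Identity Testing for Extremely Low-Coverage Sequencing Data via
    Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether two shotgun DNA sequencing samples derive from the
    same diploid individual when each covers well under one percent of the
    genome and the samples share few or no sites. Single-base observations at
    known SNP positions are compared in pairs at linked sites against a phased
    reference haplotype panel: for each pair the probability of the two bases
    under a one-individual model (which exploits haplotype frequencies, i.e.
    linkage disequilibrium) is compared with a two-individual model (allele
    frequencies only) as a log2 likelihood ratio, and per-pair ratios are
    aggregated genome-wide by sampling one pair per genomic window with a
    bootstrap. Includes panel construction from phased VCF, single-base
    observation extraction from indexed BAM alignments with ancient-DNA-aware
    filtering (transversions only), a coalescent simulation module for power
    studies with relatives and diverged reference populations, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Optional: Python 3 with msprime for the default
    coalescent simulation backend (a pure-R fallback backend is included).
Config/testthat/edition: 3
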