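Package: allelecho
Title: RNA Versus DNA Mutation Allele Frequency Analysis in Tumor Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether somatic point mutations are transcribed in
    proportion to their DNA allele frequency. Provides a seeded simulator of
    tumor genomes with integer copy-number segments and replicate tumor/germline
    DNA and tumor RNA read counts; binomial allele-fraction estimation with
    inverse-variance replicate combination and coverage filters; joint
    maximum-likelihood inference of absolute copy number, mutant multiplicity,
    tumor purity and coverage scaling from the discrete allele-fraction lattice
    and tumor:germline coverage ratios; coding-consequence annotation including
    premature termination codons relative to the last exon (the trigger for
    nonsense-mediated decay); and RNA-DNA allele-frequency imbalance statistics
    with coverage and consequence stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    rtracklayer,
    GenomicRanges,
    ggplot2,
    optparse
Config/testthat/edition: 3
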