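Package: haplodiff
Title: Haplotype-Resolved Diploid Genome Comparison and Allele-Specific
    Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the two haplotype assemblies of a highly heterozygous
    diploid genome: k-mer spectrum estimation of monoploid genome size and
    heterozygosity, collinearity-block detection by unique-seed anchoring and
    collinear chaining, SNP/indel calling inside collinearity blocks,
    five-type structural-variant classification (deletion, insertion,
    duplication, contraction, translocation), variant location and effect
    annotation, allele-pair and haplotype-specific gene cataloguing, and
    allele-specific expression (ASE) and ASE-block analysis with a
    beta-binomial exact test. Ships a synthetic diploid simulator with
    planted truth (SNPs, indels, SVs, allele pairs, ASE effects) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils,
    methods,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
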