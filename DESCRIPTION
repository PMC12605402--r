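Package: lethalscan
Title: Detection of Recessive Lethal Haplotypes from Homozygous Haplotype
    Deficiency in Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for detecting and validating recessive lethal
    haplotypes affecting stillbirth and fertility in dairy cattle
    populations. Implements marker-window haplotyping of phased genotypes,
    homozygous haplotype deficiency statistics under random-mating and
    carrier-mating models, carrier-probability logistic tests for
    stillbirth, mating-type analysis of insemination failure with
    theoretical recessive-lethal expectations, pedigree mixed models
    (A-inverse, AI-REML, BLUP, corrected phenotypes), and a single-marker
    linear mixed-model GWAS with genomic relationship matrices. Includes a
    synthetic-data generator (AI half-sib pedigrees, gene-drop genotypes
    with embedded lethals, calving and insemination records) so the whole
    chain is testable without licensed herd data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
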