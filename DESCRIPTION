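Package: homeobias
Title: Homoeolog Expression Bias and Cis/Trans Regulatory Divergence in
    Hybrids and Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Allele-specific expression analysis for intersubspecific
    hybrids and their derived allopolyploids.  Selects homoeolog-diagnostic
    SNPs from RNA-seq pileup summaries, tabulates per-gene allele counts,
    builds an in silico hybrid by 1:1 mixing of the parental data, tests
    each gene for biased homoeolog expression with an exact binomial test
    under FDR control, classifies genes into seven cis/trans
    regulatory-divergence types, three convergent/divergent/conserved
    regulation groups, and nine bias-inheritance categories, and summarises
    overlaps between samples.  Includes a synthetic allele-count generator
    with explicit cis, trans and ploidy-perturbation architectures so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
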