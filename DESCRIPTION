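Package: GeneConstraint
Title: Gene-Level Mutational Constraint Scoring and Disease Gene Set Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes per-gene Residual Variation Intolerance Scores (RVIS)
    from a quality-filtered single-nucleotide variant catalog by regressing
    each gene's common functional variant count on its total protein-coding
    variant count and taking studentized residuals. Tests disease gene sets
    for constraint (Welch t-tests, logistic regression odds ratios),
    performs Kolmogorov-Smirnov running-sum gene set enrichment with a
    permutation null and hypergeometric over-representation in the most
    constrained tail, and intersects predicted-damaging variants with
    disease variant catalogs after chain-file coordinate liftover. Includes
    a seeded synthetic-catalog generator emulating the statistical structure
    of a primate population variant resource.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
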