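Package: popsimplex
Title: Portable PCA Scoring of Genotypes and Simplex-Based Continental
    Ancestry Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers per-individual proportions of three or four continental
    ancestries from additive-coded SNP genotypes. Principal component
    analysis on a panel of ancestry-informative markers yields reusable
    SNP weights (eigenvector loadings plus training column means) that
    score new samples into a common coordinate system. Labeled reference
    populations define the vertices of an ancestry simplex (a triangle
    for three populations, a tetrahedron for four); each query point is
    classified by its nearest simplex feature and converted to admixture
    proportions with inverse-distance rules. Includes genotype input and
    quality control (allele harmonization against a reference panel,
    missing-rate filtering, mean imputation), a Balding-Nichols genotype
    simulator for FST-differentiated and admixed samples, and a
    command-line interface over the two-step score-then-infer workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
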