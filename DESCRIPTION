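Package: ildtaxa
Title: Taxonomy of Interaural Level Difference Sensitivity Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-step classification pipeline for neuronal interaural
    level difference (ILD) sensitivity functions recorded as spike-count
    vectors over an ILD axis. The pipeline benchmarks seven data
    normalization methods on a synthetic prototype test bench, reduces
    dimensionality with covariance PCA and principled component-count
    selection (scree elbow, Kaiser, Horn's parallel analysis, explained
    variance), selects a distance/linkage pair for agglomerative
    hierarchical clustering by cophenetic correlation over a 6x4 grid,
    cuts the dendrogram by cluster count or inconsistency coefficient,
    and derives per-cluster mean ILD templates classified against the
    four canonical ILD function types. Includes a seeded synthetic-data
    generator of prototypical ILD functions and surrogate surveys with
    planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
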