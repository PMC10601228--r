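Package: treekernel
Title: Kernel Machine Association Tests Within Clinical Covariate Partitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects interpretable interactions between a high-dimensional
    omics pathway and clinical covariates. Subjects are embedded with principal
    components or factor analysis of mixed data (FAMD), hierarchically
    clustered with Ward linkage, and the number of clusters is chosen by the
    highest relative loss of inertia. A semi-parametric kernel machine score
    test (variance-component, mixture-of-chi-square null) is then run within
    each partition, and error across the hierarchy of tests is controlled with
    a tree-structured Benjamini-Hochberg procedure. Includes linear,
    polynomial, Gaussian (median heuristic) and graph-smoothed kernels,
    baseline comparators (F-test on principal components, minimum Simes
    adjusted p-value), pathway (GMT + edge list) input, and synthetic-data
    generators with a power / Type I error experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
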