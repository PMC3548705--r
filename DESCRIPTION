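Package: SeCoClust
Title: Reproducible k-Means Partitions via Separation-Concordance Maps
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects reproducible k-means partitions from large ensembles of
    random initialisations. Each converged run is scored by cluster separation
    (the difference between the total sum of squares and the within-cluster
    sum of squares) and by its stability against the other well-separated
    runs, measured as the median pairwise Cramér's V of the cluster label
    assignments. The two scores form a separation-concordance (SeCo) map from
    which a single partition that is both well separated and reproducible is
    selected. Includes the batch-then-online k-means engine the scores are
    computed from, partition agreement statistics (chi-square, Cramér's V,
    the Hubert-Arabie adjusted Rand index), a ten-component trivariate
    Gaussian-mixture benchmark generator with c-separation diagnostics,
    accuracy and affinity evaluation against reference partitions, and a
    partition tree tracing cohort membership across consecutive cluster
    numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
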