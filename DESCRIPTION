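Package: shapescale
Title: Shape-Complexity Scaling Factors for Distance-Based Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Determines per-dimension scaling factors for distance-based
    cluster analysis (k-means in particular) by optimizing the shape
    complexity of the scaled data cloud, a scale-invariant functional of
    all pairwise distances that balances the stretching of large
    distances against the shrinking of small ones.  Provides the shape
    complexity function and its analytic gradient, a multi-start solver
    for the associated constrained nonlinear program on the sphere of
    scaling factors, an alternative box-constrained shape-complexity
    maximization, chance-corrected external partition indices (an
    adjusted Rand index under a fixed-number-of-clusters null based on
    Stirling numbers, and adjusted mutual information normalized by the
    maximum entropy), an end-to-end scaling/clustering/evaluation
    pipeline, and a synthetic Gaussian-mixture benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
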