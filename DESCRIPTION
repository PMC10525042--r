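Package: csfclust
Title: Cluster Structure Functions for Compression-Based Estimation of the
    Number of Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the number of clusters in a multiset of byte strings,
    images, or numeric points with the cluster structure function, an
    algorithmic-statistics construction that scores each candidate partition
    by the optimality deficiencies of its parts as models of their members.
    Kolmogorov complexities are approximated by off-the-shelf compressors;
    pairwise similarity uses the normalized compression distance, clustering
    uses classic spectral clustering, and the number of clusters is read off
    the curve with a one-standard-deviation drop rule or a uniform-reference
    log-ratio. Also provides Gap statistic, AIC and BIC baselines, an
    ensemble cell-segmentation scorer that greedily selects non-overlapping
    candidate nuclei by convexity, boundary and background efficiencies, and
    seeded synthetic-data generators for strings, Gaussian mixtures and
    nuclear images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
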