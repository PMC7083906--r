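Package: smlmclust
Title: Machine-Learning Cluster Analysis of Single-Molecule Localization
    Microscopy Point Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Supervised cluster analysis for single-molecule localization
    microscopy (SMLM) point data.  Simulates ground-truth clustered
    localization fields inside irregular cell-like boundaries, converts
    every localization into its sequence of nearest-neighbour distances,
    trains small sequential neural networks (dense, convolutional and
    recurrent layers) to classify points as clustered or not clustered,
    and segments the clustered points into discrete clusters with
    disc-union outline shapes and per-cluster statistics (count, area,
    points per cluster, density).  Works on 2D and 3D localization
    tables and includes a batch-capable command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
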