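Package: spikeDTW
Title: Dynamic Time Warping Analysis of Neural Synchrony in Rodent
    Prefrontal Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies neural network synchronicity in multi-electrode
    recordings of spike trains and local field potentials using
    parameter-free dynamic time warping (DTW). Pairwise DTW dissimilarity
    matrices are summarised by a graph-connectivity threshold statistic
    (the minimum edge-weight threshold at which the DTW graph becomes
    connected), which feeds a non-parametric statistical battery over the
    study/rat/session/trial hierarchy: Shapiro-Wilk normality screens,
    Kruskal-Wallis and ANOVA variance screens, Boschloo exact proportion
    comparisons, same- versus different-electrode distribution tests with
    ROC/AUC, distance-stratified bootstrap medians, and Mantel permutation
    tests of before- versus after-decision matrices. Includes a
    coupon-collector sample-size calculator for experiment design and a
    synthetic session generator with cluster-correlated Poisson spiking
    and oscillation-plus-noise field potentials for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests:
    igraph,
    vegan,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
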