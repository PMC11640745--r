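Package: nardlnet
Title: Asymmetric Lag-Dependency Brain Networks, Information-Theoretic
    Features and Explainable Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds subject-level weighted functional networks from region-of-interest
    (ROI) time series by scoring every ROI pair with a nonlinear autoregressive
    distributed lag (NARDL) combined-dependency statistic, filters each network to its
    planar maximally filtered graph (PMFG), and extracts weighted centralities together
    with information-theoretic descriptors (network entropy, statistical complexity on
    the complexity-entropy plane, and a sampled integrated-information Phi). Includes a
    synthetic cohort generator with known asymmetric lagged couplings, a group-level
    statistical battery (Shapiro-Wilk, Levene, Mann-Whitney with rank-biserial effect
    sizes, Bonferroni correction, SMOTE balancing), compact convolutional and recurrent
    neural classifiers trained under stratified cross-validation, and exact Shapley and
    LIME attributions of the fitted classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
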