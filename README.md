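# nardlnet

Functional brain-network analysis from ROI time series: asymmetric
lag-dependency (NARDL) connectivity, planar maximally filtered graphs,
information-theoretic network descriptors, a group statistical battery, and
compact, explainable neural classifiers.  Written for researchers comparing
two cohorts (e.g. healthy controls vs a patient group) who have per-subject
ROI time-series tables and want a tested, reproducible route from raw series
to group-level findings — including a synthetic cohort generator, since real
cohorts of this kind are typically controlled-access.

## The method in brief

For every ordered ROI pair, a nonlinear autoregressive distributed-lag
regression separates the driver's increases and decreases:

    y_t = α + Σ_{i=1..p} φ_i y_{t−i} + Σ_{i=0..p} β⁺_i x⁺_{t−i} + Σ_{i=0..p} β⁻_i x⁻_{t−i} + ε_t

with x⁺ = max(Δx, 0), x⁻ = min(Δx, 0).  Short-run sums SP = Σβ⁺, SN = Σβ⁻
and long-run ratios LP = SP/(1−Σφ), LN = SN/(1−Σφ) aggregate into the
**combined dependency** CD = (SP + LP) − (SN + LN), the edge weight of a
symmetric, per-subject min-max-normalised network.  Each network is reduced
to its **PMFG** (greedy highest-weight edge insertion under a planarity
constraint, at most 3(n−2) edges), on which seven features are computed:
mean weighted degree, closeness, betweenness and eigenvector centrality,
network entropy H = −Σ p_ij log p_ij, statistical complexity C = H·D
(D = distance of the edge-probability distribution from uniformity), and a
sampled integrated-information Φ over random bipartitions of the binarised
network.  Groups are compared feature-wise (Shapiro–Wilk, Levene,
Mann–Whitney with rank-biserial effect size, Bonferroni; SMOTE for class
imbalance) and classified by small CNN / RNN / LSTM models under stratified
10-fold cross-validation, with exact Shapley values and LIME surrogates
attributing the decisions to features.

See `vignettes/nardlnet-methods.Rmd` for assumptions, parameter defaults and
design rationale.

## Worked example

Fit one dependency, then run a small synthetic cohort end to end:

```r
library(nardlnet)

tr  <- nardl_truth(phi = c(0.3, 0.1), bpos = c(0.8, 0.3, 0), bneg = c(-0.5, 0, -0.2))
sim <- simulate_nardl_pair(tr, n = 1000, seed = 1)
nardl(sim$y, sim$x, p = 2)
#> Asymmetric distributed-lag (NARDL) fit
#>   lag order p = 2, increment partial sums, n_eff = 997
#>   alpha    phi1    phi2   bpos0   bpos1   bpos2   bneg0   bneg1   bneg2
#>  0.1405  0.2964  0.1057  0.8352  0.2835 -0.0343 -0.4077  0.0219 -0.0231
#>   SP = 1.0844  SN = -0.4089  LP = 1.8136  LN = -0.6838
#>   Combined dependency CD = 3.9906
```

The estimates sit close to the generating coefficients (true CD = 4.8 at
infinite sample; at n = 1000 this draw gives 3.99) and the asymmetry is
recovered: increases in the driver push the response up (β⁺₀ ≈ 0.84),
decreases pull it down (β⁻₀ ≈ −0.41).

```r
coh <- simulate_cohort(cohort_spec(n_hc = 6, n_pd = 6, n_rois = 8, n_time = 210,
                                   group_effect = "strong", seed = 1))
ft  <- cohort_features(coh, phi_samples = 2000, seed = 1)
ft[c(1, 2, 7, 8), c("subject_id", "group", "mean_degree", "network_entropy", "complexity")]
#>  subject_id group mean_degree network_entropy complexity
#>     sub-001    HC       2.360           3.491      0.460
#>     sub-002    HC       2.245           3.466      0.482
#>     sub-007    PD       2.670           3.523      0.439
#>     sub-008    PD       2.824           3.508      0.439

run_group_tests(as.matrix(ft[, feature_names()]), ft$group)
#> Group statistical battery: HC (n=6) vs PD (n=6), alpha = 0.05
#>
#> Mann-Whitney (Bonferroni-adjusted):
#>           feature  U        p p_bonferroni effect_size significant constant
#>       mean_degree  0 0.002165      0.01515     1.00000        TRUE    FALSE
#>    mean_closeness  0 0.002165      0.01515     1.00000        TRUE    FALSE
#>  mean_betweenness 34 0.012127      0.08489    -0.88889       FALSE    FALSE
#>  mean_eigenvector 19 0.937229      1.00000    -0.05556       FALSE    FALSE
#>   network_entropy  0 0.002165      0.01515     1.00000        TRUE    FALSE
#>        complexity 36 0.002165      0.01515    -1.00000        TRUE    FALSE
#>               phi 23 0.484848      1.00000    -0.27778       FALSE    FALSE
```

Under the "strong" group effect (patient couplings nearly removed), degree,
closeness, entropy and complexity separate the groups completely (|effect
size| = 1) and survive Bonferroni correction; eigenvector centrality and Φ
do not discriminate at this cohort size.  Classification and attribution
continue from the same table:

```r
cv <- train_evaluate_cv(as.matrix(ft[, feature_names()]), factor(ft$group),
                        model_spec("cnn", seed = 1), folds = 3, seed = 1)
sh <- exact_shapley(train_network(zscore_standardize(as.matrix(ft[, feature_names()]))$X,
                                  factor(ft$group), model_spec("cnn", seed = 1)),
                    zscore_standardize(as.matrix(ft[, feature_names()]))$X[1, ],
                    zscore_standardize(as.matrix(ft[, feature_names()]))$X)
```

A command-line front end over the same functions (simulate / connect /
features / stats / classify) is installed at `inst/scripts/nardlnet.R`.

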