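---
title: "Methods: asymmetric lag-dependency networks, information-theoretic features and explainable classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: asymmetric lag-dependency networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nardlnet)
```

## The problem

Resting-state functional imaging yields, per subject, a multivariate time
series: one signal per region of interest (ROI).  Group studies (here:
healthy controls, HC, versus a patient group, PD) ask whether the *network*
of dependencies between regions differs systematically between groups.
`nardlnet` implements one complete route from ROI time series to that
answer: an asymmetric lag-dependency score for every ROI pair, a planarity
filter that keeps only the strongest backbone of each subject's network,
seven subject-level network descriptors, a non-parametric statistical
battery, and small neural classifiers whose decisions are attributed back to
the features by exact Shapley values and LIME surrogates.

## Pairwise dependency: the NARDL combined-dependency score

For an ordered ROI pair with driver $x_t$ and response $y_t$, the package
fits, by ordinary least squares,

$$y_t = \alpha + \sum_{i=1}^{p}\phi_i\,y_{t-i}
 + \sum_{i=0}^{p}\beta^{+}_i x^{+}_{t-i}
 + \sum_{i=0}^{p}\beta^{-}_i x^{-}_{t-i} + \epsilon_t ,$$

where $x^{+}_t = \max(\Delta x_t, 0)$ and $x^{-}_t = \min(\Delta x_t, 0)$
split the driver's movements into increases and decreases, so positive and
negative influences get separate coefficients (the asymmetry that ordinary
linear cross-correlation cannot express).  The default lag order is $p = 2$;
the first $p + 1$ time points are dropped for alignment and never padded.
The fit requires at least three observations per parameter
($n - p - 1 \ge 3(3p + 3)$).

From the fitted coefficients the dependency aggregates are

* short-run: $SP = \sum_i \beta^{+}_i$, $SN = \sum_i \beta^{-}_i$;
* long-run: $LP = SP/(1 - \sum_i \phi_i)$, $LN = SN/(1 - \sum_i \phi_i)$;
* combined dependency: $CD = (SP + LP) - (SN + LN)$.

Two genuinely open design points are exposed as arguments rather than hidden:

* **Sign convention.** `cd_form = "text"` (default) aggregates the positive
  terms and subtracts the aggregated negative terms, which is the reading
  consistent with $CD$ being large when positive influence dominates;
  `"literal"` computes $SP + LP - SN + LN$.
* **Partial-sum mode.** `mode = "increment"` (default) uses the raw
  increments exactly as defined above; `mode = "cumulative"` uses their
  running sums, the convention common in the distributed-lag literature.

Near-unit-root fits make the long-run denominator $1-\sum\phi_i$ collapse;
below a floor of $10^{-3}$ the ratio is computed against the floor, clipped
at $\pm 10^{3}$, and flagged, so a single unstable pair cannot dominate a
network.  Rank-deficient designs (for example a constant driver) are not
errors: the fit is flagged degenerate, its $CD$ is 0, and the flag travels
into the network's per-edge QC table.

Both ordered directions are fitted for every unordered pair and combined —
by their mean by default (`symmetrization = "max"` is available), since the
downstream graph is declared undirected and the mean is order-independent
and unbiased between the two directions.  The raw matrix is then min-max
scaled over its off-diagonal entries into $[0,1]$ per subject, which removes
inter-subject differences in overall dependency scale (and, deliberately,
in sign: the minimum, possibly negative, raw score maps to 0).

```{r nardl-example}
tr <- nardl_truth(phi = c(0.3, 0.1), bpos = c(0.8, 0.3, 0), bneg = c(-0.5, 0, -0.2))
sim <- simulate_nardl_pair(tr, n = 1000, seed = 1)
fit <- nardl(sim$y, sim$x, p = 2)
fit
```

## Network filtration: the planar backbone

The planar maximally filtered graph (PMFG) keeps the strongest edges that
can still be drawn in the plane without crossings: candidate edges are
sorted by descending normalised weight (ties broken lexicographically on the
index pair, for reproducibility) and inserted greedily, each insertion being
accepted only if the graph remains planar; insertion stops once $3(n-2)$
edges — the planar maximum — are retained.  Zero-weight edges carry no
dependency signal (and would have infinite traversal cost below), so they
are never candidates.

Planarity is decided by Demoucron's incremental face-embedding algorithm run
per biconnected component; when a graph is not planar, an explicit
Kuratowski obstruction (a $K_5$ or $K_{3,3}$ subdivision) is extracted by
edge-minimal reduction.  Graphs with fewer than nine edges are accepted
without testing ($K_{3,3}$, the smallest obstruction, has nine).  The test
suite replays every logged rejection into the final graph and cross-checks
the tester against an independent planarity implementation.

## Network metrics

On the filtered weighted graph (weights are strengths; traversal cost of an
edge is $1/w$):

* weighted degree — row sums of the adjacency;
* weighted closeness — reciprocal of the summed shortest-path distances;
* weighted betweenness — shortest-path pass-through fractions over
  unordered pairs, unnormalised;
* weighted eigenvector centrality — the principal eigenvector, computed by
  power iteration (tolerance $10^{-10}$, at most $10^4$ iterations, dense
  eigendecomposition fallback), returned nonnegative with unit Euclidean
  norm.

Metrics are computed on the PMFG backbone by default (`source = "full"`
switches to the dense matrix; both are legitimate readings and the choice is
tagged in every output).  On a disconnected graph closeness sums distances
within the node's component and betweenness counts only connected pairs —
both flagged — because infinite distances would otherwise make Eq.-style
closeness identically zero; PMFG backbones are connected in practice.

All entropies use natural logarithms, one base everywhere.

## Information-theoretic descriptors

The normalised weights define a probability distribution over ordered node
pairs, $p_{ij} = W'_{ij} / \sum_{kl} W'_{kl}$, from which the package
computes:

* **Network entropy** $H = -\sum_{ij} p_{ij}\log p_{ij}$ (ordered double
  sum; for a symmetric matrix this exceeds the per-edge entropy by exactly
  $\log 2$ — an identity the tests assert).
* **Disequilibrium** $D$, the Euclidean distance between $(p_{ij})$ and the
  uniform distribution $1/n^2$ over all cells.  The distance is a true
  Euclidean norm (with the square root); the worked value for a single unit
  cell on a $2\times2$ grid is $\sqrt{0.75}\approx0.866$.
* **Statistical complexity** $C = H \times D$, the vertical coordinate of
  the complexity–entropy (H–C) plane.  Maximally ordered and maximally
  random networks both have low $C$; structured-but-diverse networks sit
  high.
* **Integrated information $\Phi$**, on a binarised matrix: a cell survives
  if $p_{ij} \ge \theta \cdot p_{\max}$ (default $\theta = 0.001$, which on
  typical networks keeps essentially every positive cell — the descriptor
  is then a purely topological one; $\theta$ is exposed for sensitivity
  analysis).  For a node subset $S$, the subsystem information $I(G_S)$ is
  the entropy of the within-$S$ connection distribution renormalised to sum
  one; on a binary graph that is $\log$ of the number of within-$S$ edges,
  with the empty subsystem contributing 0.  Edges are counted as unordered
  units in the $\Phi$ computation, under which a one-edge graph carries
  zero information and $\Phi$ vanishes identically for every bipartition —
  the sane degenerate limit.  For a bipartition $\{S, S'\}$,
  $\Phi_{\text{part}} = I(G) - [I(G_S) + I(G_{S'})]$, and the estimator
  averages $\Phi_{\text{part}}$ over $N$ random bipartitions (default
  $N = 10{,}000$): a size $k$ uniform on $1..n-1$, then a uniform
  $k$-subset.  This sampling measure is size-stratified, *not* uniform over
  bipartitions; the exhaustive oracle (`exhaustive_phi()`, $n \le 14$)
  weights every bipartition exactly as the sampler draws it, so the sampler
  is unbiased for the oracle's value, and each estimate reports a
  per-sample standard error.

```{r info-example}
W <- make_fixture_network("two_cliques", 8)
p <- edge_probability_distribution(W)
c(H = network_entropy(p), D = disequilibrium(p),
  C = statistical_complexity(network_entropy(p), disequilibrium(p)))
estimate_phi(binarize_probability(p), n_samples = 2000, seed = 1)
```

## The subject feature vector

Each subject is summarised by seven numbers: the node means of the four
centralities, the network entropy $H$, the complexity $C$ and the sampled
$\Phi$ (with its standard error carried alongside).  `cohort_features()`
derives every subject's $\Phi$ seed deterministically from one base seed, so
a cohort table is reproducible bit for bit.

## Group statistics

The battery runs per feature: Shapiro–Wilk within each group (network
features are rarely normal), Levene's variance-homogeneity test
(mean-centred, i.e. the classical form), and a two-sided Mann–Whitney U test
with the rank-biserial effect size $r = 1 - 2U/(n_1 n_2)$ and Bonferroni
adjustment $\min(1, m\,p)$ over the $m = 7$ features.  Exact p-values are
used for tie-free samples with both groups of size at most eight, the
normal approximation with tie correction otherwise.  Constant features are
flagged rather than tested.

Class imbalance is handled by SMOTE: synthetic minority rows
$x_i + \delta (x_{nn} - x_i)$, $\delta \sim U(0,1)$, with $x_{nn}$ one of
the $k = 5$ Euclidean nearest minority neighbours, generated until the
classes balance.  `group_battery()` reports the tests **both** before and
after balancing: the post-balance table mirrors analyses that test after
SMOTE, but synthetic rows are interpolations, not independent observations,
so the pre-balance report is the statistically sound default and the
package's type-I-error calibration (a rejection rate near the nominal 5% on
exchangeable synthetic cohorts) is asserted on the pre-balance path only.

## Classification

Three compact neural classifiers consume the standardised 7-feature vector
as a length-7 single-channel sequence:

* CNN — 32 filters of width 5, same padding, ReLU, dropout 0.3, then the
  flattened activation map feeds a single sigmoid unit.  A
  global-pooling head was considered and rejected: pooling over positions
  makes the model nearly permutation-invariant across features, destroying
  the identity of individual descriptors; the flatten-plus-dense head is
  the MLP-like reading of the architecture.
* RNN — 64 tanh units over the 7 steps, dropout 0.3 on the final hidden
  state, sigmoid head.
* LSTM — 128 units with the standard three-gate cell (forget-gate bias
  initialised open), dropout 0.4, sigmoid head.

All train with Adam (learning rate $10^{-3}$) on the binary cross-entropy
for 50 epochs with batch size 16; initialisation, shuffling and dropout are
all governed by one seed.  The implementations are plain base-R matrix code;
their analytic gradients are verified against numerical differentiation to
$\sim 10^{-10}$ in the test suite, and parameter counts against closed
forms (e.g. the LSTM's $4(d\,u + u^2 + u)$ gate parameters).

Evaluation is stratified 10-fold cross-validation with strict leakage
hygiene: standardisation parameters ($\mu_j$, population $\sigma_j$) are
estimated on the training rows only, SMOTE is applied to the training rows
only, and the untouched test fold is scored at threshold 0.5
(accuracy, precision, recall, F1, plus summed confusion counts).  A fold
that would lack a class aborts with a stratification error.

## Attribution

* **Exact Shapley values.**  With $d = 7$ features all $2^7$ coalitions are
  enumerated; a coalition's value is the model's mean output over a
  background sample with the coalition's features fixed to the explained
  instance (marginal masking).  Retraining a model per coalition — the
  other literal reading — is available nowhere: it is unstable at these
  sample sizes and masking is the standard operationalisation.  Efficiency
  ($\sum_j \phi_j = f(x) - \text{baseline}$) and symmetry hold by
  construction and are asserted to $10^{-6}$; for a linear model the
  implementation reproduces the closed form
  $\phi_j = \beta_j (x_j - \bar b_j)$ exactly.
* **LIME.**  Gaussian perturbations around the instance ($\sigma = 1$ on
  standardised features), proximity weights
  $\exp(-\lVert z - x\rVert^2 / w^2)$ with $w = 0.75\sqrt d$, and an
  L1-penalised weighted linear surrogate solved by coordinate descent on
  the stated objective itself (default $\lambda = 10^{-3}$;
  $\lambda = 0$ reduces to weighted least squares, against which the solver
  is cross-checked).  Per-instance coefficients are aggregated into
  per-feature means and population standard deviations.

## The synthetic cohort generator

Real cohorts of this kind are controlled-access, so the generator is a
first-class module, not a test fixture.  It emulates what the pipeline
needs to be exercised end to end: ROIs are organised as driver/target
pairs; drivers are stationary AR(1) series (coefficient 0.5 — persistent
enough that both positive and negative increments occur, so both asymmetric
branches are active); targets follow the generating recurrence above with
Gaussian innovations; 200 burn-in steps are discarded so nothing depends on
start-up values.  Group structure: the patient group's branch coefficients
are attenuated and its innovation scale mildly inflated
(`attenuation = 0.5`, `noise_inflation = 1.25` by default), making patient
networks more random than control networks.  The `"strong"` preset is
defined by its purpose — a clearly separable cohort — and uses near-total
decoupling (`attenuation = 0.05`) with the same mild noise inflation;
experimentation during design showed that heavy extra noise blurs rather
than sharpens the contrast, so the strong effect is decoupling, not noise.
`"none"` makes the groups exchangeable for null calibration.  The default
cohort is 20 HC / 60 PD, a desk-scale version of the 142/1537 imbalance the
package targets, with 48 ROIs and 210 time points (a typical resting-state
scan length); all of these are plain `cohort_spec()` arguments.

What the generator does **not** emulate: haemodynamics, scanner or motion
artefacts, spatially structured noise, non-Gaussian innovations, or any
empirical calibration to real ROI series (no public characterisation of
those series exists).  Passing tests therefore demonstrate that the
pipeline recovers known structure under its own model class — estimator
consistency, filtration correctness, calibrated test levels, separability
when separation truly exists — not that any specific clinical effect size
would be detected in real data.

## Numerical and scale choices

* Natural log everywhere; power iteration tolerance $10^{-10}$; probability
  normalisation asserted to $10^{-12}$; Shapley efficiency to $10^{-6}$.
* Weight ties in the PMFG are broken lexicographically; equal shortest
  paths are counted with multiplicity.
* Degenerate inputs (constant series, all-zero or constant weight
  matrices, empty subsystems, near-unit-root fits) are flagged or produce
  defined values rather than errors wherever a network-scale computation
  must continue.
* Test and acceptance runs use deliberately desk-scale problem sizes chosen
  as the package's own defaults for its validation experiments: 50
  simulated pairs of length 2000 for estimator recovery; up-to-15-node
  graphs for filtration checks; $N = 2000$ sampled bipartitions (against
  exhaustive oracles at $n \in \{6, 10\}$); 200 replicate 8-vs-8 null
  cohorts with 6 ROIs and 120 time points for type-I calibration; and a
  20/60-subject, 16-ROI, 210-time-point cohort for the classification
  experiments.  The method defaults themselves (48 ROIs,
  $N = 10{,}000$, $\theta = 0.001$) are unchanged.

## Known limitations

* The combined dependency is a regression-based score, not a causal
  estimate; symmetrising the two directions deliberately discards
  directionality (the per-direction scores remain in the QC table).
* $\Phi$ here is the average-over-bipartitions surrogate on a binarised
  edge distribution — a network-topology descriptor, not a full
  integrated-information computation with cause–effect repertoires.
* With $\theta = 0.001$ the binarised distribution is near-uniform over
  surviving cells, so $\Phi$ mostly reflects edge-count topology; raise
  $\theta$ to probe weight structure.
* Statistical tests after SMOTE treat interpolated rows as observations;
  the package reports that path for comparability but calibrates only the
  pre-balance path.
* The classifiers are deliberately small and trained on handfuls of
  subjects; their cross-validated metrics on synthetic cohorts say nothing
  about clinical performance.
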