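---
title: "Simulating untargeted metabolomics data and benchmarking multiclass classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating untargeted metabolomics data and benchmarking multiclass classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Why simulate metabolomics data?

Untargeted metabolomics yields wide abundance tables (p >> n) whose columns are
strongly correlated within biological processes: metabolites linked as
substrates, intermediates and products of shared reactions co-vary, and
regulatory mechanisms such as feedback inhibition induce higher-order *partial*
correlations. Judging classifiers for phenotype discrimination on one or two
real datasets gives high-variance answers; `metabobench` instead generates many
independent studies with stochastically varied covariance structures, effect
sizes, and data artifacts, so that relative classifier performance can be
estimated with known ground truth.

# The data-generating model

## Block covariance via random C-vines

Each study draws `n_blocks = 40` blocks of `block_size = 25` metabolites
(p = 1000). A block's rows are multivariate normal with a **random correlation
matrix** generated by the canonical-vine (C-vine) construction of Lewandowski,
Kurowicka and Joe: the d(d-1)/2 partial correlations
rho[k,i; 1..k-1] are organised in layers; the Beta shape parameter starts at
`eta + (d-1)/2` and is decremented by 1/2 at each layer; each partial is drawn
Beta(beta, beta) on (0,1) and rescaled to (-1,1). Inverting the
partial-correlation recursion

    rho[ij;L] = rho[ij;kL] * sqrt((1 - rho[ik;L]^2)(1 - rho[jk;L]^2)) + rho[ik;L] rho[jk;L]

layer by layer yields a guaranteed positive-definite correlation matrix. With
`eta = 1` the distribution over correlation matrices is uniform; larger `eta`
concentrates near the identity. The rescaling of the Beta draws to (-1, 1) is
essential — partial correlations live on (-1, 1), and without it all
correlations would be non-negative and the uniform-at-`eta = 1` property would
fail. Note that the layer-wise shape parameter is
`beta_k = eta + (d - 1 - k)/2`: the *deepest* layer (k = d-1) is the uniform
one at `eta = 1`, while layer 1 draws Beta(eta + (d-2)/2, ·) — the tests verify
both layer laws and the implied single-correlation marginal density
proportional to (1 - rho^2)^(eta - 1 + d/2 - 1).

`eta` has no canonical value in this design; the package
defaults to `eta = 1` (uniform over correlation matrices) and exposes it in
`sim_config()`.

## Phenotype effects

Three phenotypes are simulated hierarchically. The reference phenotype has
mean zero everywhere. Each comparator phenotype perturbs a discrete-uniform
1-5 of the 40 blocks; each perturbed block receives an effect
`theta ~ Exp(rate 1/2)` (mean 2) whose sign flips with probability 1/2, and the
block's per-metabolite means are drawn N(theta, 1). Effects are therefore
*localised* to a small fraction of blocks, the defining feature of
differential abundance in this setting. "Exp(1/2)" is read as rate 1/2
(mean 2); the alternative mean-1/2 reading would produce much weaker effects.

## Realistic artifacts

The *baseline* scenario stops there: complete, Gaussian, balanced
(40/40/40 of `n_samples = 120`). The *realistic* scenario adds, in order:

1. **Biological outliers** — per (sample, block) with probability 0.02 the
   whole block of that sample shifts by 4 per-metabolite SDs (random sign).
2. **Technical outliers** — per (sample, metabolite) with probability 0.01 a
   single value shifts by 6 SDs.
3. **Non-normal marginals** — per block one shape `kappa ~ Unif(-0.4, 0.4)`
   (scale `alpha = 1`) is drawn and every metabolite is mapped through the
   generalized Gaussian quantile function of its rescaled empirical CDF rank
   `rank/(n+1)`; `x = (alpha/kappa)(1 - exp(-kappa z))`, the Gaussian limit at
   `kappa = 0`. The map is monotone, so within-block Spearman correlations are
   exactly preserved — skew is added without destroying the dependence
   structure.
4. **Limit-of-detection missingness** — per metabolite, values below the
   pooled 5% quantile become missing. Because censoring depends on the
   unobserved value itself, the mechanism is missing-not-at-random; the
   pre-masking matrix is retained so tests can audit it.
5. **Unbalanced allocation** — class proportions ~ Dirichlet(4, 4, 4), counts
   multinomial, redrawn until every class keeps at least 10 samples.

The artifact intensities (rates, magnitudes, `kappa` range, LOD quantile,
Dirichlet concentration) have no canonical values in this design; the
defaults above were chosen once as values a practitioner would
call realistic — visible skew with finite variance, a few percent outliers,
mild censoring — and are all exposed in `sim_config()`. A consequence worth
stating plainly: at these intensities the realistic scenario degrades
classifiers only moderately, so absolute error magnitudes at this
parameterisation are smaller than ones produced under harsher (unknown)
intensities; relative orderings are the quantity of interest.

`n_samples` defaults to 120 per study, split 60 train / 60 test, so that
test-set misclassification moves in steps of 1/60. It is configurable.

## Missing-value handling

All classifiers receive identically preprocessed data: missing entries are
replaced by half the observed minimum of their metabolite (the conventional
below-LOD stand-in), with fill values always computed on training samples and
re-applied to test samples. With location-zero marginals a metabolite's
observed minimum can be negative, in which case "half the minimum" moves
toward zero and can exceed the censoring threshold; for nonnegative
(abundance-scale) metabolites the usual bound `fill <= threshold` holds, and
the tests assert exactly that.

# Significance filtering

Univariate dimension reduction before classification: for each metabolite all
G(G-1)/2 pairwise two-sample tests are run — Welch t-tests in the baseline
scenario, Wilcoxon rank-sum in the realistic one — and the metabolite is kept
if *any* pairwise p-value is below the raw `alpha = 0.025`. The "any pair"
reading was chosen because a metabolite separating even one phenotype pair is
informative for multiclass discrimination. No multiplicity correction is
applied (the threshold is deliberately a raw level). Constant metabolites get
p = 1; if nothing survives, the 10 smallest-p metabolites are kept with a
warning so downstream fits remain possible.

# The classifiers

All seven expose one contract — `f(X_train, y_train, X_new)` returning a
per-class probability matrix — which is what makes tuning and evaluation
classifier-agnostic.

* **PLS-DA** (authored here): NIPALS iterations (`w = X'u/u'u`, normalise,
  `t = Xw`, `c = Y't/t't`, normalise, `u = Yc`) against a centred class
  indicator matrix, converging when `w` changes by < 1e-8 (cap 500
  iterations); loadings by least squares; deflation of both matrices by the
  score. The fixed point of the iteration is the leading left singular vector
  of X'Y, which the tests verify against a dense SVD. Class prediction is
  nearest centroids in score space, converted to probabilities by softmax of
  negative squared distances — the simplest discriminant consistent with the
  model that yields the probabilities cross-entropy needs. Columns are
  centred and unit-scaled; the largest-magnitude entry of each weight vector
  is forced positive so output is deterministic.
* **sparse PLS-DA** (authored here): per deflation, the leading singular
  vectors (f, g) of X_h' Y_h are computed; f is soft-thresholded entrywise at
  `lambda * max|f|` and renormalised, so metabolites drop out of the
  component. Interpreting `lambda` as a fraction of the largest absolute
  weight keeps the 0.1-0.9 tuning grid scale-free across datasets. At
  `lambda = 0` the procedure is exactly PLS-DA (tested to 1e-8).
* **SVM** (delegated to e1071/libsvm): Gaussian kernel
  `exp(-gamma ||x - x'||^2)`, one-against-one multiclass, Platt-scaled
  probabilities. Only `gamma` is tuned; the soft-margin cost is fixed at 1.
* **Random Forest** (delegated to randomForest): 1000 trees, probability =
  vote fractions (exact multiples of 1/1000), `mtry` tuned. The backend
  splits on Gini impurity rather than raw misclassification error; this is
  accepted as the operative criterion since the difference is empirically
  minor and tree induction is deliberately not re-implemented.
* **Neural network** (authored here): fully connected feedforward net, one or
  two logistic hidden layers, softmax output, trained full-batch by resilient
  backpropagation (iRPROP-) minimising cross-entropy. RPROP adapts a
  per-weight step from the gradient *sign* only (x1.2 on agreement, x0.5 on a
  flip, steps clipped to [1e-6, 50]), making training robust to gradient
  scale. Inputs are standardised internally; training stops after 150 epochs
  or 10 stalled epochs (relative improvement < 1e-6); divergence triggers up
  to 3 re-initialisations, then uniform probabilities with a warning. No
  installed backend offers this exact contract (two hidden layers + RPROP +
  cross-entropy), which is why it is implemented here.
* **Naive Bayes** (authored here): Gaussian class-conditionals per metabolite,
  maximum-likelihood estimates (variance denominator = class size), empirical
  class-frequency priors, log-space accumulation. Variances are floored at
  1e-9 x pooled variance so constant-within-class metabolites cannot
  produce degenerate densities.
* **k-NN** (authored here): Euclidean neighbourhoods; the class posterior is
  the neighbourhood class fraction, an exact multiple of 1/k. Distance ties
  at the k-th neighbour resolve to the lowest training index (stable radix
  order) for determinism. Zero probabilities are left at zero — flooring is
  the loss function's responsibility, which is precisely why k-NN's
  cross-entropy is floor-dominated (below).

# Tuning

Hyperparameters are selected per study (and per filter arm) by minimising
cross-validated cross-entropy over the benchmark's reference grids:
components 1-15
(PLS-DA, sPLS-DA), `lambda` 0.1-0.9 by 0.1, `mtry` at 25 points over [5, p],
`gamma` at 1000 log-spaced points over 10^[-5, -1] before filtering and
10^[-2, 0] after, k = 1-20, and networks of 1-2 layers x 15-100 nodes by 5
(two-layer networks use equal widths: the grid definition lists axes, and the
equal-width product rule is this package's choice). Stratified folds (default 5) are shared across grid
points. The raw loss surface is then smoothed by Nadaraya-Watson regression
with a Gaussian product kernel — log10 coordinates for the `gamma` and
`lambda` axes, bandwidth 1.5x the median grid spacing per axis (the smoothing
kernel and bandwidth are declared package defaults, not inferred facts) — and
the smoothed argmin is selected, ties going to the smallest parameter values.
Smoothing is a convex combination of raw losses, so it can never leave their
range.

Two computational shortcuts change nothing statistically: component grids are
scored by fitting one model per fold at the largest component count and
truncating (exact, because deflation makes components sequential — tested
against per-point refits), and k-NN reuses one distance ranking per fold.
`coarse = TRUE` subsamples each grid to at most 25 points (log-uniform on log
axes) for scaled-down runs; k values exceeding the smallest training part are
skipped as unfittable at that sample size.

# Losses and protocols

The 0-1 empirical risk (misclassification rate, argmax prediction with
lowest-index tie-break) and the cross-entropy
`-(1/N) sum log p_hat(true class)` in nats. Cross-entropy distinguishes a
49%-confidence miss from a 0.1%-confidence miss where 0-1 loss cannot.
Predicted probabilities are floored at `1e-15` inside the log; since k-NN and
naive Bayes can emit exact zeros, their cross-entropy *magnitudes* are direct
functions of this floor — comparisons of those magnitudes across
implementations are floor-dependent and documented as such.

`run_study()` applies a stratified 60/60 train/test split; everything
data-dependent (imputation fills, the kept-metabolite set, tuning) is fitted
on the training half only — tests audit that corrupting held-out rows or
shuffling test labels changes nothing. For small real datasets,
`repeated_double_cv()` nests the whole pipeline inside outer folds (defaults
5 outer folds, 10 repeats; the fold and repeat counts are package defaults
for studies of a few dozen samples).

# Batch runs and aggregation

`run_studies()` derives an independent seed per study from one master seed, so
results are reproducible and order-independent. `aggregate_summary()` reports
mean, SD, median and IQR (type-7 quantiles, declared so aggregates are
reproducible) of both losses per technique x scenario x filter arm, with
misclassification on the 0-100% scale; failed cells are excluded pairwise and
counted, so one diverging fit does not discard a study.
`pairwise_win_matrix()` gives the proportion of studies in which one technique
beat another, ties counting 0.5 to each side.

# Problem sizes used in the shipped checks

The benchmark's full reference protocol (1000 studies, full grids, both
arms) is hours of
CPU. The package's own acceptance checks use the sizes chosen for routine
verification: 25-30 realistic studies, post-filter arm, 3-fold inner CV over
coarse (<= 8 point) grids. At that scale the expected ranking of techniques by
median misclassification (SVM, RF, NB, sPLS-DA, NNet, PLS-DA, k-NN) is
asserted pairwise, with a swap excused when the two interquartile intervals
overlap — at 25 studies the within-scenario spread is large relative to
median gaps, which is exactly why the full protocol aggregates medians over
1000 studies.

# What passing tests do and do not show

The generator emulates block-correlated, skewed, outlier-contaminated,
partially censored, unbalanced abundance data with localised effects. It does
not emulate platform-specific artifacts (batch effects, drift, peak-picking
errors), correlations *between* biological processes (blocks are independent
by construction), or effect structures other than mean shifts. Benchmarks
that pass here therefore speak to relative classifier behaviour under the
modelled artifacts, not to any specific instrument or cohort.
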