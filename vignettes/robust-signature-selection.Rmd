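---
title: "Robust signature selection by two-fold subsampling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust signature selection by two-fold subsampling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robsig)
```

## The problem

Prognostic gene signatures selected from expression cohorts by penalized
regression are notoriously unstable: refit the same method on a slightly
different patient subsample and a substantially different feature list
comes back. With cohort sizes of one or two hundred patients and tens of
thousands of candidate features, a single lasso-Cox or preconditioned
lasso fit sits far from the asymptotic regime in which selection
consistency can be expected. `robsig` implements a two-fold subsampling
framework that (a) stabilizes each fitted model by ensembling, and (b)
quantifies, rather than assumes, the stability of the resulting
signatures.

## Model and procedure

Survival follows the Cox proportional hazards model: for a patient with
feature vector $x \in \mathbb{R}^p$, the hazard is
$h(t \mid x) = h_0(t)\, e^{x^\top \beta}$, so risk comparisons between
patients reduce to comparing linear predictors $x^\top \beta$. Penalized
maximum partial likelihood (lasso $\alpha = 1$, ridge $\alpha = 0$,
elastic net in between) estimates a sparse $\beta$; the preconditioned
lasso (PL) first converts the censored outcome into real-valued
pseudo-outcomes $\hat y$ via supervised principal components — rank
features by the magnitude of their univariate Cox score statistic, keep
those above a CV-chosen threshold, regress on the leading PCs — and then
solves a lasso least-squares problem
$\min_\beta \tfrac12\lVert \hat y - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1$
on **all** features of the working universe, not only the screened ones.

The robust-selection (RS) wrapper runs two nested subsampling loops,
both with 63.2%/36.8% splits chosen to mimic the effective sample ratio
of bootstrapping:

* **Inner loop** (per train set $I$): draw $T_{in}$ random sub-train
  sets $J \subset I$ (63.2% of $I$), fit the base learner (PL or
  CV-tuned lasso-Cox, hyperparameters retuned on each $J$) on every $J$,
  average the coefficient vectors, and *shrink* the average by
  thresholding: over a grid of $K$ thresholds spanning the nonzero
  coefficient magnitudes, keep the threshold whose truncated model
  maximizes mean concordance on the held-out tuning sets (ties go to the
  sparser model). Surviving coefficients keep their averaged values; no
  refit, because the object of interest is the aggregated vector itself.
* **Outer loop**: split the cohort $T_{out}$ times into train (63.2%)
  and test sets. Each method is fit on each train set and its linear
  predictor is scored on the untouched test set by Harrell's
  concordance index. The selection probability $\hat\pi_k$ of feature
  $k$ is the fraction of outer trials whose fitted support contains it,
  and the robust signature at level $\pi$ is
  $\{k : \hat\pi_k \ge \pi\}$. The same splits are reused for all
  methods so method contrasts are paired.

Stability is reported as the mean pairwise Jaccard index of the
per-trial signatures; for equal-size signatures (obtained by the *extra
shrinkage* step, truncation to the top-$G$ coefficient magnitudes) the
chance-corrected Kuncheva index and a Canberra-type rank distance are
combined into the rank-penalized Kuncheva index
$\max(K, 0) / C$, which is $0$ at or below chance-level overlap and
$\infty$ for identical ranked lists.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `t_in`, `t_out` | 100, 100 | inner/outer subsample counts; more trials sharpen $\hat\pi_k$ at linear cost |
| `subtrain_fraction`, `train_fraction` | 0.632 | split ratios (bootstrap-effective sample share) |
| `prefilter_percentile` | 0 | SD percentile below which features are dropped per train set; 90–99 is typical for raw microarray universes |
| `threshold_grid_size` | 50 | shrinkage grid resolution (linear spacing over nonzero magnitudes) |
| `pi_threshold` | 0.5 | robust-signature probability cutoff; cohort-specific anchors (e.g. the selection probability of a known covariate) can be supplied by the caller |
| `n_top` | 100 | screening-list size of the Dev/Cor baselines |
| `k_folds` | 5 | internal CV folds, stratified by event indicator |

Penalty weights are never user-set in the pipeline: the lasso-Cox and
lasso-LS steps tune $\lambda$ by stratified cross-validation over the
solver's regularization path, and the SPC preconditioner tunes its score
threshold (20 quantiles between the 50th and 99th percentile of the
score distribution) jointly with the number of components
$m \in \{1,2,3\}$ by held-out concordance.

## Numerical choices

* **Ties.** The Cox partial likelihood and the baseline hazard use the
  Breslow convention (all events at a tied time share the risk set).
  In the concordance index, a pair with tied *predictions* stays in the
  denominator and contributes nothing to the numerator — the literal
  order-indicator-product rule. A pair with tied *event* times is not
  comparable. The Cor baseline, by contrast, ranks features by
  $|c - 0.5|$ with tied predictions counted as $1/2$, so a constant
  feature scores exactly $c = 0.5$ and ranks last rather than appearing
  maximally anti-concordant.
* **Standardization.** Features are standardized internally before any
  penalized fit (penalties are scale-sensitive) and coefficients are
  reported on the original scale.
* **Exact zeros.** Solver outputs below 1e-9 in magnitude are truncated
  to zero so `support()` is well-defined; fixed-penalty lasso-LS solves
  are polished by coordinate descent until the KKT subgradient residual
  is below 1e-8.
* **Determinism.** Every stochastic step (splits, folds, Monte-Carlo
  normalizers) is seeded; per-trial seeds are derived from the master
  seed by a fixed affine substream map, so increasing `t_out` never
  perturbs earlier trials. PC sign indeterminacy is fixed by making the
  largest-magnitude loading positive. The Canberra normalizer (the
  expected distance of two independent random top-$k$ lists, 10000
  Monte-Carlo draws) uses a fixed internal seed and is cached per
  $(k, p)$.
* **Degenerate inputs.** Constant features get score 0 (not an error);
  a constant pseudo-outcome yields a warned null model; zero-event
  likelihoods, empty risk sets, all-constant feature matrices, and
  comparable-pair-free concordance calls are hard errors; inner/outer
  splits lacking events on either side are redrawn up to 100 times.
  Shrinkage threshold ties prefer the sparser model.

## The synthetic generator

`simulate_dataset()` draws features from a block-exchangeable Gaussian
(unit variance, correlation `block_rho = 0.3` within blocks of 10,
independent across blocks), plants `s` true coefficients of magnitude
`effect_size` with alternating signs — one per block, so each signal
feature has correlated inactive neighbours that exercise the lasso's
correlated-feature behavior — and generates event times by inverse
transform from the Cox model with an exponential baseline
(`baseline_rate = 0.2`). Censoring times are exponential with a rate
calibrated by bisection so the population censoring probability
$\mathbb{E}[c/(c + r_i)]$ matches `target_censoring`; the default 0.3
reflects a typical overall-survival cohort. `target_censoring = 0` is
the valid uncensored limit. The generator reproduces the structural
regime the framework targets — $p \gg n$, sparse linear risk,
independent censoring — but *not* microarray probe-level noise, batch
effects, or covariate-dependent censoring; tests passing on it certify
the algorithmic contracts, not clinical transportability.

The end-to-end recovery study used by the test suite and the acceptance
script runs a cohort of $n = 150$, $p = 300$, $s = 5$, effect 1.5, 30%
censoring with $T_{out} = T_{in} = 20$ — the full two-fold procedure at
a problem size a laptop handles in minutes, with the subsample counts
scaled down from the 100/100 defaults. At these settings the planted
features reach selection probability near 1 for both RS-PL and RS-L
while off-support features stay far lower, and RS-L signatures are at
least as stable (pairwise Jaccard) as plain lasso-Cox signatures.

## Design choices on genuinely open points

* The SPC ranking statistic is the absolute univariate Cox score
  statistic — the standard supervised-PC choice for censored outcomes —
  rather than a literal correlation coefficient, which is undefined
  under censoring.
* Base-learner hyperparameters are retuned on every inner sub-train set
  $J$ (not once per $I$): each inner fit is a fresh realization of the
  full learner, which is what the ensemble is meant to average over.
* The preconditioned outcomes $\hat y$ are computed on the full
  sub-train set the SPC model was fit on, not fold-wise; the lasso step
  then runs its own CV for $\lambda$.
* The shrinkage tuning criterion is the concordance index, the same
  metric used for test evaluation, since "best prediction" is otherwise
  unspecified; the threshold grid is linear in coefficient magnitude.
* `prefilter_percentile` defaults to 0 because SD screening is only
  informative when features differ meaningfully in variability (as raw
  probe-level universes do; the synthetic generator's features are
  exchangeable in variance). The operation itself follows the
  keep-`p - floor(pq/100)` arithmetic exactly and is intended to be
  switched on (90–99) for microarray-scale inputs.
* The rank-penalized Kuncheva index is defined here as
  $\max(K, 0)/C$ with $C$ the Canberra top-$k$ distance under the
  rank-$(k{+}1)$ convention for unselected features, normalized by its
  random-list expectation. The ratio's qualitative contract — 0 at
  chance overlap, $\infty$ at perfect ranked agreement — is what the
  index is used for; the normalization constant is a documented
  convention.
* "Paired Welch test" names a one-sided *paired* t-test on per-split
  metric differences (pairing over shared splits is what the design
  supports; an unpaired unequal-variance test would discard it).

## Known limitations

* Only right censoring, Breslow ties, and time-fixed covariates are
  supported; no competing risks, no IPCW-corrected concordance.
* The concordance index is computed by $O(n^2)$ pair logic — fine for
  cohort-scale test sets, not for $n \gtrsim 10^4$.
* Selection probabilities are estimated from `t_out` trials and are
  therefore multiples of `1/t_out`; small `t_out` quantizes
  `pi_threshold` comparisons accordingly.
* RS shrinkage keeps averaged coefficient values; when a sparse final
  model with refit coefficients is wanted, refit on the robust
  signature downstream.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(n = 150, p = 300, s = 5,
                                   effect_size = 1.5,
                                   target_censoring = 0.3, seed = 101))
res <- run_evaluation(sim$dataset,
                      outer_config(t_out = 20, methods = c("RS-L", "L"),
                                   seed = 101),
                      rs_config(t_in = 20, seed = 101))
robust_signature(res$profiles[["RS-L"]], pi_threshold = 0.9)
```

See the package README for the printed output of this analysis and
`scripts/acceptance.R` for the full reproduction pipeline.
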