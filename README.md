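# robsig — robust gene-signature selection for censored survival outcomes

Prognostic signatures picked from expression cohorts by a single
penalized Cox or preconditioned-lasso fit are fragile: a modest change
in the patient sample often changes most of the selected genes. For
cohorts where n (patients) is far below p (features), `robsig`
implements a two-fold subsampling framework that stabilizes the fitted
models and measures — instead of assuming — how reproducible the
resulting signatures are. It is aimed at biostatisticians and
computational biologists building survival signatures from preprocessed
expression matrices (e.g. log2 probeset summaries) plus a clinical
table with right-censored survival.

## The method in brief

Survival follows the Cox model h(t|x) = h0(t)·exp(x'β). The core
estimator, RS-PL (robust selection with the preconditioned lasso),
works per training set I:

1. **Prefilter** features whose training-set SD falls below a chosen
   percentile (keeping exactly p − floor(p·q/100) features).
2. **Inner subsampling**: draw T_in sub-train sets J (63.2% of I,
   the bootstrap-effective ratio). On each J, fit the base learner —
   preconditioned lasso (supervised principal components produce
   pseudo-outcomes ŷ; then min_β ½‖ŷ − Xβ‖² + λ‖β‖₁ over all
   features) or CV-tuned lasso-Cox.
3. **Aggregate** the T_in coefficient vectors by averaging, then
   **shrink** the average by thresholding, the threshold tuned to
   maximize concordance on the inner tuning sets.

An **outer subsampling** loop (T_out random 63.2%/36.8% train/test
splits, shared across methods) estimates each feature's selection
probability π̂_k = (trials selecting k)/T_out, the held-out concordance
index of every method, and signature stability (Jaccard; and for
equal-size top-G signatures, the Kuncheva index, a Canberra rank
distance, and their ratio, the rank-penalized Kuncheva index). The
robust signature at level π is {k : π̂_k ≥ π}. Baselines: plain PL and
lasso-Cox (L), SD screening + ridge Cox (Dev), univariate-concordance
screening + ridge Cox (Cor), and clinical-covariates-only Cox (Cli).

## Worked example

```r
library(robsig)

sim <- simulate_dataset(sim_config(n = 150, p = 300, s = 5,
                                   effect_size = 1.5,
                                   target_censoring = 0.3, seed = 101))
sim$dataset
#> rs_dataset: 300 features x 150 samples; 110 events (26.7% censored)
sim$dataset$feature_ids[sim$truth$support]
#> [1] "f0001" "f0011" "f0021" "f0031" "f0041"

res <- run_evaluation(sim$dataset,
                      outer_config(t_out = 20, methods = c("RS-L", "L"),
                                   seed = 101),
                      rs_config(t_in = 20, seed = 101))

aggregate(test_concordance ~ method, res$trials, function(x) round(mean(x), 3))
#>   method test_concordance
#> 1      L            0.858
#> 2   RS-L            0.844

head(robust_signature(res$profiles[["RS-L"]], pi_threshold = 0.9), 10)
#> [1] "f0021" "f0041" "f0031" "f0001" "f0011" "f0140" "f0173" "f0101" "f0233" "f0039"

jaccard_stability(lapply(res$signatures[["RS-L"]], names))  # 0.293
jaccard_stability(lapply(res$signatures[["L"]], names))     # 0.272
```

All five planted risk features head the robust signature — each was
selected in ≥ 90% of the 20 outer trials — and the RS-wrapped lasso's
signatures overlap more across trials (Jaccard 0.293 vs 0.272, a 7%
stability gain) at essentially the same held-out concordance.

A command-line driver wrapping the same functions ships in
`inst/cli/robsig.R` with subcommands `simulate`, `evaluate`, and
`signature`; see `Rscript <path>/robsig.R <subcommand> --help`.

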