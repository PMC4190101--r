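# The parameter-recovery study shared by the end-to-end tests: a cohort
# of n = 150 with p = 300 candidate features, 5 true risk features of
# magnitude 1.5, 30% censoring; 20 outer trials with 20 inner subsamples
# (the full procedure, scaled down from 100/100 to keep the suite fast).
# Computed once per test run and cached.
.recovery_env <- new.env(parent = emptyenv())

recovery_run <- function() {
  if (!is.null(.recovery_env$res)) return(.recovery_env$res)
  sim <- simulate_dataset(sim_config(n = 150, p = 300, s = 5,
                                     effect_size = 1.5,
                                     target_censoring = 0.3, seed = 101))
  cfg <- outer_config(t_out = 20, methods = c("RS-PL", "RS-L", "L"),
                      seed = 101)
  rcfg <- rs_config(t_in = 20, seed = 101)
  res <- run_evaluation(sim$dataset, cfg, rcfg)
  .recovery_env$res <- list(sim = sim, res = res)
  .recovery_env$res
}
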