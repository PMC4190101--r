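eval_fixture <- function(seed = 51) {
  sim <- simulate_dataset(sim_config(n = 60, p = 25, s = 2, effect_size = 1.5,
                                     seed = seed))
  d <- sim$dataset
  d$clinical <- data.frame(age = rnorm(60, 60, 8),
                           grade = factor(rep(c("lo", "hi"), 30)))
  rownames(d$clinical) <- d$sample_ids
  list(d = d, truth = sim$truth)
}

test_that("outer splits are seed-stable, sized by the train fraction, and event-guarded", {
  ev <- rep(c(1, 1, 0), length.out = 100)
  sp <- outer_splits(100, t_out = 10, fraction = 0.632, seed = 4, event = ev)
  expect_length(sp, 10)
  for (s in sp) {
    expect_length(s$train, 63)
    expect_length(intersect(s$train, s$test), 0)
    expect_gt(sum(ev[s$train]), 0)
    expect_gt(sum(ev[s$test]), 0)
  }
  expect_identical(sp, outer_splits(100, 10, 0.632, seed = 4, event = ev))
})

test_that("the evaluation harness pairs methods on shared splits and counts selections exactly", {
  fx <- eval_fixture()
  cfg <- outer_config(t_out = 5, methods = c("L", "Dev"), n_top = 10, seed = 9)
  res <- run_evaluation(fx$d, cfg, rs_config(t_in = 2, seed = 9))
  expect_equal(nrow(res$trials), 10)   # 5 trials x 2 methods
  expect_setequal(unique(res$trials$method), c("L", "Dev"))
  # both methods were fit/tested on the same splits
  expect_length(res$splits, 5)
  for (s in res$splits)
    expect_length(intersect(s$train, s$test), 0)
  # selection probabilities are exactly counts / t_out
  for (m in c("L", "Dev")) {
    prof <- res$profiles[[m]]
    counts <- vapply(prof$feature_id, function(f)
      sum(vapply(res$signatures[[m]], function(sig) f %in% names(sig),
                 logical(1))), numeric(1))
    expect_equal(prof$selection_probability, unname(counts) / 5)
    expect_true(all(prof$selection_probability %in% ((0:5) / 5)))
  }
  # deterministic given the seed
  res2 <- run_evaluation(fx$d, cfg, rs_config(t_in = 2, seed = 9))
  expect_identical(res$trials, res2$trials)
})

test_that("robust signatures are monotone in the probability threshold", {
  prof <- data.frame(feature_id = c("a", "b", "c", "d"),
                     selection_probability = c(1, 0.6, 0.4, 0),
                     mean_coefficient = c(0.5, -1, 0.2, 0))
  expect_identical(robust_signature(prof, 0), c("a", "b", "c"))
  expect_identical(robust_signature(prof, 1), "a")
  s_hi <- robust_signature(prof, 0.9)
  s_lo <- robust_signature(prof, 0.5)
  expect_true(all(s_hi %in% s_lo))
  expect_error(robust_signature(prof, 1.2), "pi_threshold")
  # ordering: probability desc, then |mean coefficient|
  prof2 <- data.frame(feature_id = c("x", "y"),
                      selection_probability = c(0.5, 0.5),
                      mean_coefficient = c(0.1, -2))
  expect_identical(robust_signature(prof2, 0.1), c("y", "x"))
})

test_that("extra shrinkage returns ranked top-G features and flags short supports", {
  beta <- c(a = 0.5, b = -2, c = 0, d = 1)
  top1 <- extra_shrinkage(beta, 1)
  expect_identical(top1$features, "b")
  expect_false(top1$flagged)
  top2 <- extra_shrinkage(beta, 2)
  expect_identical(top2$features, c("b", "d"))
  expect_identical(top2$ranks, 1:2)
  big <- extra_shrinkage(beta, 10)
  expect_identical(big$features, c("b", "d", "a"))
  expect_true(big$flagged)
  # magnitude ties: lower feature id wins
  tied <- extra_shrinkage(c(z = 1, a = -1, m = 0.5), 1)
  expect_identical(tied$features, "a")
})

test_that("variance screening ignores the outcome and keeps the top-SD features", {
  fx <- eval_fixture(seed = 52)
  X <- t(fx$d$expression)
  b <- fit_dev(X, fx$d$time, fx$d$event, n_top = 10, seed = 1)
  expect_lte(sum(b != 0), 10)
  sds <- apply(X, 2, sd)
  expect_true(names(which.max(sds)) %in% names(which(b != 0)))
  # permuting outcomes leaves the selected set unchanged
  set.seed(1)
  perm <- sample(60)
  b2 <- fit_dev(X, fx$d$time[perm], fx$d$event[perm], n_top = 10, seed = 1)
  expect_setequal(names(which(b != 0)), names(which(b2 != 0)))
})

test_that("concordance screening is symmetric in risk direction and drops constants", {
  fx <- eval_fixture(seed = 53)
  X <- t(fx$d$expression)
  risk <- as.numeric(X %*% fx$truth$beta)
  X[, 1] <- -risk                      # perfectly anti-concordant
  X[, 2] <- 7                          # constant
  colnames(X)[1:2] <- c("antirisk", "const")
  cvals <- robsig:::univariate_concordances(X, fx$d$time, fx$d$event)
  expect_equal(unname(cvals["const"]), 0.5)
  ranks <- rank(-abs(cvals - 0.5), ties.method = "min")
  expect_equal(unname(ranks["antirisk"]), 1)
  expect_equal(unname(ranks["const"]), ncol(X))
  b <- fit_cor(X, fx$d$time, fx$d$event, n_top = 5, seed = 1)
  expect_lte(sum(b != 0), 5)
  expect_true("antirisk" %in% names(which(b != 0)))
})

test_that("the clinical baseline uses only covariates and is scale-equivariant", {
  set.seed(60)
  n <- 80
  grp <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, rate = ifelse(grp == 1, 3, 1))
  event <- rep(1, n)
  clin <- data.frame(grp = grp)
  b <- fit_cli(clin, time, event)
  expect_gt(b["grp"], 0)               # group 1 is the higher-risk group
  expect_identical(names(b), "grp")    # expression features never enter
  clin2 <- data.frame(grp = grp * 2)
  b2 <- fit_cli(clin2, time, event)
  expect_equal(unname(b2["grp"]), unname(b["grp"]) / 2, tolerance = 1e-6)
})

test_that("requesting Cli without clinical data is a clear error", {
  sim <- small_sim(seed = 54, n = 60, p = 10, s = 1)
  cfg <- outer_config(t_out = 2, methods = "Cli", seed = 1)
  expect_error(run_evaluation(sim$dataset, cfg), "clinical")
})
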