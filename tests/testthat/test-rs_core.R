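test_that("SD prefiltering retains exactly p - floor(p*q/100) features", {
  set.seed(10)
  X <- matrix(rnorm(10 * 20), 10, 20) * (1:10)   # distinct row SDs
  expect_equal(length(prefilter_by_sd(X, 90)), 1)
  expect_equal(prefilter_by_sd(X, 90), 10)        # largest-SD row
  expect_equal(prefilter_by_sd(X, 0), 1:10)
  # SDs must come from the given (training) samples only: restricting the
  # columns changes the ranking accordingly
  X2 <- X; X2[1, 1:10] <- X2[1, 1:10] * 100
  expect_equal(prefilter_by_sd(X2[, 1:10, drop = FALSE], 90), 1)
})

test_that("prefilter ties at the cutoff keep the lower feature index", {
  X <- rbind(c(0, 2), c(0, 2), c(0, 1))   # rows 1 and 2 tie on SD
  expect_equal(prefilter_by_sd(X, 50), c(1, 2))  # keep 3 - floor(1.5) = 2
  expect_equal(prefilter_by_sd(X, 67), 1)        # keep 1; tie -> lower index
  expect_error(prefilter_by_sd(matrix(1, 3, 4), 50), "constant")
})

test_that("inner splits partition the train set with the 63.2% ratio", {
  idx <- 1:100
  ev <- rep(c(1, 0), 50)
  sp <- inner_splits(idx, t_in = 20, fraction = 0.632, seed = 3, event = ev)
  expect_length(sp, 20)
  for (s in sp) {
    expect_length(s$sub_train, 63)
    expect_length(intersect(s$sub_train, s$tuning), 0)
    expect_setequal(c(s$sub_train, s$tuning), idx)
    expect_gt(sum(ev[s$sub_train]), 0)
  }
  sp2 <- inner_splits(idx, t_in = 20, fraction = 0.632, seed = 3, event = ev)
  expect_identical(sp, sp2)
})

test_that("inner splits redraw until the sub-train set contains an event", {
  ev <- c(1, rep(0, 19))    # a single event in the train set
  sp <- inner_splits(1:20, t_in = 30, fraction = 0.5, seed = 8, event = ev)
  expect_true(all(vapply(sp, function(s) 1 %in% s$sub_train, logical(1))))
})

test_that("aggregation averages coefficient vectors and records supports", {
  b1 <- c(1, 0, 0); b2 <- c(0, 1, 0)
  agg <- aggregate_models(list(b1, b2))
  expect_equal(agg$beta_bar, c(0.5, 0.5, 0))
  expect_equal(agg$component_supports, list(1L, 2L))
  expect_equal(aggregate_models(list(b1, b1))$beta_bar, b1)
  # exact cancellation empties that coordinate
  expect_equal(aggregate_models(list(c(1, 0), c(-1, 0)))$beta_bar, c(0, 0))
  expect_error(aggregate_models(list(b1, c(1, 2))), "differ in length")
})

test_that("threshold shrinkage keeps everything at the lower grid end and prefers sparsity on ties", {
  sim <- small_sim(seed = 41, n = 60, p = 10, s = 2)
  d <- sim$dataset
  X <- t(d$expression)
  tuning <- list(1:20, 21:40)
  beta_bar <- c(2, 1, 0.5, rep(0, 7))
  names(beta_bar) <- colnames(X)
  sh <- shrink_model(beta_bar, X, d$time, d$event, tuning, K = 10)
  expect_s3_class(sh, "shrunken_model")
  # the argmax contract: the chosen threshold attains the curve maximum
  expect_equal(max(sh$tuning_curve$mean_cindex),
               sh$tuning_curve$mean_cindex[sh$tuning_curve$threshold ==
                                             sh$theta_star])
  # at the smallest grid value nothing is shrunk
  b_keep <- beta_bar; b_keep[abs(b_keep) < min(abs(b_keep[b_keep != 0]))] <- 0
  expect_equal(sum(abs(beta_bar) >= sh$tuning_curve$threshold[1]), 3)

  # a coefficient on a feature that never moves the tuning predictions
  # produces a flat tie; the sparser model must win
  X0 <- X; X0[, 3] <- 0
  sh2 <- shrink_model(c(2, 1e-6, rep(0, 8)), X0, d$time, d$event,
                      list(1:30), K = 2)
  curve <- sh2$tuning_curve$mean_cindex
  if (curve[1] == curve[2]) expect_equal(sh2$theta_star, 2)

  expect_warning(sh0 <- shrink_model(rep(0, 10), X, d$time, d$event, tuning),
                 "all-zero")
  expect_true(all(sh0$beta_tilde == 0))
})

test_that("shrunken support is monotone non-increasing along the threshold grid", {
  beta_bar <- c(-2, 1.5, 1, -0.6, 0.3, 0.1, rep(0, 4))
  grid <- seq(0.1, 2, length.out = 25)
  supp <- vapply(grid, function(th) sum(abs(beta_bar) >= th), numeric(1))
  expect_true(all(diff(supp) <= 0))
})

test_that("rs_fit is seed-deterministic and degenerates cleanly at t_in = 1", {
  sim <- small_sim(seed = 42, n = 70, p = 25, s = 2)
  cfg <- rs_config(t_in = 4, base_learner = "lasso-cox",
                   threshold_grid_size = 10, seed = 5)
  f1 <- rs_fit(sim$dataset, cfg)
  f2 <- rs_fit(sim$dataset, cfg)
  expect_identical(f1$beta_tilde, f2$beta_tilde)
  expect_length(f1$beta_tilde, 25)
  # support of the shrunken model is within the aggregated support
  expect_true(all(names(which(f1$beta_tilde != 0)) %in%
                    names(which(f1$beta_bar != 0))))

  cfg1 <- rs_config(t_in = 1, base_learner = "lasso-cox",
                    threshold_grid_size = 5, seed = 6)
  f_single <- rs_fit(sim$dataset, cfg1)
  expect_length(f_single$beta_tilde, 25)
})

test_that("rs_fit reports coefficients as zero outside the prefiltered universe", {
  sim <- small_sim(seed = 43, n = 70, p = 30, s = 2)
  # make the true-signal rows also high-SD so filtering keeps signal
  d <- sim$dataset
  d$expression[sim$truth$support, ] <- d$expression[sim$truth$support, ] * 3
  cfg <- rs_config(t_in = 3, base_learner = "lasso-cox",
                   prefilter_percentile = 50, threshold_grid_size = 5,
                   seed = 2)
  fit <- rs_fit(d, cfg)
  keep <- prefilter_by_sd(d$expression, 50)
  expect_true(all(fit$beta_tilde[setdiff(1:30, keep)] == 0))
  expect_equal(fit$retained_features, keep)
})
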