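test_that("partial log-likelihood matches hand values and the enumeration oracle", {
  # beta = 0: every exp(eta) is 1, so the value is -sum(log |R_i|)
  time <- c(1, 2, 2, 4, 5); event <- c(1, 1, 1, 0, 1)
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(partial_log_likelihood(X, time, event, c(0, 0)),
               -(log(5) + log(4) + log(4) + log(1)))

  # n = 2, single event, scalar x = (1, 0), beta = 1 -> 1 - log(e + 1)
  expect_equal(partial_log_likelihood(matrix(c(1, 0), 2, 1),
                                      time = c(1, 2), event = c(1, 0),
                                      beta = 1),
               1 - log(exp(1) + 1))

  # random fixtures with ties against the naive double loop
  for (s in 1:10) {
    fx <- random_surv_fixture(12, s)
    Xr <- matrix(rnorm(36), 12, 3)
    beta <- rnorm(3) / 2
    expect_equal(partial_log_likelihood(Xr, fx$time, fx$event, beta),
                 naive_pll(Xr, fx$time, fx$event, beta))
  }
})

test_that("partial likelihood is invariant to shifting all feature vectors", {
  fx <- random_surv_fixture(15, 4)
  X <- matrix(rnorm(30), 15, 2)
  beta <- c(0.7, -1.2)
  expect_equal(partial_log_likelihood(X + 5, fx$time, fx$event, beta),
               partial_log_likelihood(X, fx$time, fx$event, beta))
  expect_error(partial_log_likelihood(X, fx$time, rep(0, 15), beta),
               "zero events")
})

test_that("penalized Cox honors the full-shrinkage and unpenalized limits", {
  sim <- small_sim(seed = 21, n = 200, p = 3, s = 1, effect = 1.2)
  X <- t(sim$dataset$expression)
  ti <- sim$dataset$time; ev <- sim$dataset$event

  b_null <- fit_penalized_cox(X, ti, ev, lambda = 10, alpha = 1)
  expect_true(all(b_null == 0))

  # lambda = 0, p << n: matches the unpenalized fit from survival::coxph
  b0 <- fit_penalized_cox(X, ti, ev, lambda = 0, alpha = 1)
  cox <- survival::coxph(survival::Surv(ti, ev) ~ X)
  expect_lt(max(abs(b0 - coef(cox))), 1e-4)
})

test_that("ridge coefficient norms shrink monotonically in lambda", {
  sim <- small_sim(seed = 22, n = 100, p = 10, s = 2)
  X <- t(sim$dataset$expression)
  lambdas <- c(0.01, 0.05, 0.2, 1)
  norms <- vapply(lambdas, function(l)
    sqrt(sum(fit_penalized_cox(X, sim$dataset$time, sim$dataset$event,
                               lambda = l, alpha = 0)^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("the returned solution beats the null model on the penalized objective", {
  sim <- small_sim(seed = 23, n = 100, p = 20, s = 3)
  X <- t(sim$dataset$expression)
  ti <- sim$dataset$time; ev <- sim$dataset$event
  for (al in c(1, 0.5)) {
    b <- fit_penalized_cox(X, ti, ev, lambda = 0.05, alpha = al)
    obj_fit <- robsig:::penalized_cox_objective(X, ti, ev, b, 0.05, al)
    obj_null <- robsig:::penalized_cox_objective(X, ti, ev, numeric(20), 0.05, al)
    expect_gte(obj_fit, obj_null - 1e-6)
  }
})

test_that("lasso support is non-increasing along a decreasing penalty path", {
  sim <- small_sim(seed = 27, n = 120, p = 30, s = 3)
  X <- t(sim$dataset$expression)
  lam <- c(0.4, 0.2, 0.1, 0.05, 0.02)
  supp <- vapply(lam, function(l)
    sum(fit_penalized_cox(X, sim$dataset$time, sim$dataset$event,
                          lambda = l, alpha = 1) != 0), numeric(1))
  expect_true(all(diff(supp) >= 0))   # lam is decreasing, support grows
})

test_that("cross-validated lambda selection behaves at the grid edges and finds signal", {
  sim <- small_sim(seed = 24, n = 200, p = 10, s = 1, effect = 1.5)
  X <- t(sim$dataset$expression)
  ti <- sim$dataset$time; ev <- sim$dataset$event

  one <- cv_select_lambda(X, ti, ev, lambda_grid = 0.3, seed = 1)
  expect_equal(one$lambda, 0.3)

  hits <- vapply(1:5, function(s) {
    spec <- cv_select_lambda(X, ti, ev, alpha = 1, seed = s)
    b <- fit_penalized_cox(X, ti, ev, lambda = spec$lambda, alpha = 1)
    sim$truth$support %in% which(b != 0)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("pure-noise data drives the selected lambda toward the null end", {
  set.seed(88)
  X <- matrix(rnorm(80 * 30), 80, 30)
  ti <- rexp(80); ev <- rbinom(80, 1, 0.8)
  upper <- vapply(1:5, function(s) {
    spec <- cv_select_lambda(X, ti, ev, alpha = 1, seed = s)
    spec$lambda >= stats::median(spec$grid)
  }, logical(1))
  expect_gte(sum(upper), 4)
})

test_that("baseline hazard reduces to Nelson-Aalen at beta = 0", {
  # distinct times, all events: increments 1/3, 1/2, 1
  X <- matrix(0, 3, 1)
  bl <- estimate_baseline_hazard(X, c(1, 2, 3), c(1, 1, 1), 0)
  expect_equal(bl$increments, c(1/3, 1/2, 1))
  expect_equal(bl$event_counts, c(1, 1, 1))

  # tied events and censoring: d_i / |R_i|
  time <- c(1, 2, 2, 3, 4); event <- c(1, 1, 1, 0, 1)
  bl2 <- estimate_baseline_hazard(matrix(0, 5, 1), time, event, 0)
  expect_equal(bl2$event_times, c(1, 2, 4))
  expect_equal(bl2$increments, c(1/5, 2/4, 1/1))

  # doubling every relative risk halves every increment
  x <- matrix(rnorm(5), 5, 1)
  b1 <- estimate_baseline_hazard(x, time, event, 1)
  b2 <- estimate_baseline_hazard(x + log(2), time, event, 1)
  expect_equal(b2$increments, b1$increments / 2)
})

test_that("survival curves start at 1, decrease, and match the hand value", {
  # single event, |R| = 2, beta = 0: S(1) = exp(-1/2)
  bl <- estimate_baseline_hazard(matrix(0, 2, 1), c(1, 2), c(1, 0), 0)
  expect_equal(survival_function(bl, 0, 0, 0.5), 1)
  expect_equal(survival_function(bl, 0, 0, 1), exp(-0.5))

  sim <- small_sim(seed = 25, n = 60, p = 5, s = 2)
  X <- t(sim$dataset$expression)
  b <- fit_penalized_cox(X, sim$dataset$time, sim$dataset$event,
                         lambda = 0.05, alpha = 0)
  bl2 <- estimate_baseline_hazard(X, sim$dataset$time, sim$dataset$event, b)
  ts <- seq(0, max(sim$dataset$time), length.out = 30)
  s_lo <- survival_function(bl2, b, X[1, ], ts)
  expect_true(all(diff(s_lo) <= 1e-12))
  # a higher-risk profile is pointwise below a lower-risk one
  riskier <- X[which.max(as.numeric(X %*% b)), ]
  safer <- X[which.min(as.numeric(X %*% b)), ]
  expect_true(all(survival_function(bl2, b, riskier, ts) <=
                    survival_function(bl2, b, safer, ts) + 1e-12))
})

test_that("linear predictors difference equals the log hazard ratio", {
  beta <- c(0.5, -1)
  X <- matrix(rnorm(10), 5, 2)
  lp <- linear_predictor(beta, X)
  expect_equal(lp[1] - lp[2], sum((X[1, ] - X[2, ]) * beta))
  expect_equal(linear_predictor(c(0, 0), X), rep(0, 5))
  perm <- c(3, 1, 2, 5, 4)
  expect_equal(linear_predictor(beta, X[perm, ]), lp[perm])
})
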