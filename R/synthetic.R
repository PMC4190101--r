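#' Configuration for the synthetic survival-data generator
#'
#' The generator emulates the regime the selection framework targets:
#' far more candidate features than patients, a sparse linear risk, and
#' independent right-censoring. Features are correlated Gaussian with an
#' exchangeable block structure; event times follow a Cox model with an
#' exponential baseline hazard; censoring times are exponential with a
#' rate calibrated to a target censored fraction.
#'
#' @param n Number of samples.
#' @param p Number of features.
#' @param s True-support size (number of nonzero risk coefficients),
#'   `s <= p`.
#' @param effect_size Magnitude of each nonzero true coefficient
#'   (log-hazard units per SD of the feature).
#' @param block_rho Within-block feature correlation in `[0, 1)`.
#' @param block_size Features per correlation block.
#' @param baseline_rate Exponential baseline hazard rate (> 0), events per
#'   time unit at x = 0.
#' @param target_censoring Desired censored fraction in `[0, 1)`; 0 turns
#'   censoring off.
#' @param sign_pattern `"alternating"` (default) or `"random"` signs for
#'   the true coefficients.
#' @param seed Integer RNG seed; the dataset is a pure function of the
#'   config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 150, p = 300, s = 5, effect_size = 1.5,
                       block_rho = 0.3, block_size = 10,
                       baseline_rate = 0.2, target_censoring = 0.3,
                       sign_pattern = c("alternating", "random"),
                       seed = 1L) {
  sign_pattern <- match.arg(sign_pattern)
  stopifnot(n >= 2, p >= 1, s >= 0, s <= p,
            effect_size >= 0, block_rho >= 0, block_rho < 1,
            block_size >= 1, baseline_rate > 0)
  if (target_censoring < 0 || target_censoring >= 1)
    stop("target_censoring must lie in [0, 1)")
  structure(list(n = as.integer(n), p = as.integer(p), s = as.integer(s),
                 effect_size = effect_size, block_rho = block_rho,
                 block_size = as.integer(block_size),
                 baseline_rate = baseline_rate,
                 target_censoring = target_censoring,
                 sign_pattern = sign_pattern, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a survival dataset with known sparse linear risk
#'
#' Draws features from a block-exchangeable Gaussian (unit marginal
#' variance, correlation `block_rho` within blocks of `block_size`,
#' independent across blocks). The true coefficient vector has `s`
#' nonzero entries of magnitude `effect_size`, one per block (so each
#' signal feature has correlated but inactive neighbours). Event times
#' are inverse-transform draws from the Cox model with exponential
#' baseline: T = -log(U) / (baseline_rate * exp(x'beta)). Censoring times
#' are Exp(c) with c found by bisection so that the average analytic
#' censoring probability E[c / (c + rate_i)] matches `target_censoring`.
#'
#' @param config A [sim_config()].
#' @return A list with `dataset` (an `rs_dataset`) and `truth` (list with
#'   `beta` (named p-vector) and `support` (integer indices)).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n; p <- config$p; s <- config$s
  n_blocks <- ceiling(p / config$block_size)
  block_of <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(p)]
  # exchangeable within-block correlation: shared block factor + noise
  z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  eps <- matrix(stats::rnorm(n * p), n, p)
  rho <- config$block_rho
  X <- sqrt(rho) * z[, block_of, drop = FALSE] + sqrt(1 - rho) * eps
  feature_ids <- sprintf("f%04d", seq_len(p))
  colnames(X) <- feature_ids

  beta <- numeric(p)
  support <- integer(0)
  if (s > 0) {
    # first feature of the first s blocks; falls back to arbitrary spread
    # if there are fewer blocks than signals
    firsts <- match(seq_len(n_blocks), block_of)
    support <- firsts[seq_len(min(s, n_blocks))]
    if (length(support) < s)
      support <- c(support, setdiff(seq_len(p), support)[seq_len(s - length(support))])
    support <- sort(support)
    signs <- switch(config$sign_pattern,
                    alternating = rep_len(c(1, -1), s),
                    random = sample(c(-1, 1), s, replace = TRUE))
    beta[support] <- signs * config$effect_size
  }

  lp <- as.numeric(X %*% beta)
  rate <- config$baseline_rate * exp(lp)
  t_event <- -log(stats::runif(n)) / rate

  if (config$target_censoring == 0) {
    time <- t_event
    event <- rep(1, n)
  } else {
    c_rate <- calibrate_censoring_rate(rate, config$target_censoring)
    t_cens <- stats::rexp(n, rate = c_rate)
    time <- pmin(t_event, t_cens)
    event <- as.numeric(t_event <= t_cens)
  }

  dataset <- new_rs_dataset(t(X), time, event)
  names(beta) <- feature_ids
  list(dataset = dataset,
       truth = list(beta = beta, support = support,
                    config = config))
}

# For exponential censoring Exp(c) independent of T_i ~ Exp(rate_i),
# P(censored | x_i) = c / (c + rate_i); bisect on the population average.
calibrate_censoring_rate <- function(event_rates, target, tol = 1e-10) {
  frac <- function(c) mean(c / (c + event_rates))
  lo <- 1e-12
  hi <- max(event_rates)
  while (frac(hi) < target) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < tol * hi) break
  }
  (lo + hi) / 2
}

#' Tiny deterministic fixtures with hand-checkable risk orderings
#'
#' Registered fixtures for metric unit tests:
#' \describe{
#'   \item{`perfect_order`}{8 patients, all events, distinct times;
#'     predictions equal to minus the survival time, so every comparable
#'     pair is concordant (c-index 1).}
#'   \item{`tied_events`}{two patients share an event time (that pair is
#'     not comparable), plus censored patients.}
#'   \item{`binary_pred`}{a binary risk predictor over two outcome groups
#'     with all events, so the c-index reduces to a two-sample AUC.}
#' }
#'
#' @param name Fixture name.
#' @return A list with `time`, `event`, `predictions`, and a small
#'   `rs_dataset` in `dataset`.
#' @export
make_fixture <- function(name) {
  fx <- switch(
    name,
    perfect_order = {
      time <- c(1, 2, 3, 4, 5, 6, 7, 8)
      list(time = time, event = rep(1, 8), predictions = -time)
    },
    tied_events = {
      # patients 1 and 2 share event time 2; 5 and 6 censored
      time <- c(2, 2, 4, 5, 3, 6, 7, 1)
      event <- c(1, 1, 1, 1, 0, 0, 1, 1)
      list(time = time, event = event,
           predictions = c(3.0, 2.5, 1.0, 0.5, 2.0, 0.2, 0.1, 4.0))
    },
    binary_pred = {
      # short-survivors (cases) vs long-survivors; predictor imperfect
      time <- c(1, 1, 1, 1, 10, 10, 10, 10)
      event <- rep(1, 8)
      list(time = time, event = event,
           predictions = c(1, 1, 1, 0, 0, 0, 1, 0))
    },
    stop("unknown fixture: ", name)
  )
  n <- length(fx$time)
  expr <- matrix(fx$predictions, nrow = 1,
                 dimnames = list("pred", paste0("s", seq_len(n))))
  fx$dataset <- new_rs_dataset(expr, fx$time, fx$event)
  fx
}
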