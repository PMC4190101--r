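#' Cox partial log-likelihood (Breslow ties)
#'
#' Evaluates the log partial likelihood
#' sum over events i of [ eta_i - log sum_{j in R_i} exp(eta_j) ],
#' where eta = X beta and R_i is the risk set at event i's time (all
#' patients with observed time >= t_i). Tied event times are handled with
#' the Breslow approximation: every event at a tied time uses the same
#' risk set.
#'
#' @param X n x p design matrix (samples in rows).
#' @param time,event Survival times and 0/1 event flags, length n.
#' @param beta Coefficient vector, length p.
#' @return The partial log-likelihood (a finite scalar).
#' @export
partial_log_likelihood <- function(X, time, event, beta) {
  stopifnot(nrow(X) == length(time), length(time) == length(event),
            ncol(X) == length(beta))
  if (sum(event) == 0) stop("partial likelihood undefined with zero events")
  eta <- as.numeric(X %*% beta)
  eta_c <- eta - max(eta)                       # overflow guard
  ord <- order(time, decreasing = TRUE)
  # cumulative sum over the reverse-time ordering gives risk-set sums
  cum <- cumsum(exp(eta_c[ord]))
  risk_log <- numeric(length(time))
  # for sample i, risk set = {j : time_j >= time_i}; with ties all tied
  # samples share the largest cumulative sum among them
  tt <- time[ord]
  # positions sharing a time must all use the cum value at the last (deepest)
  # position of that tie group in the descending ordering
  grp <- cumsum(!duplicated(tt))
  cum_by_grp <- tapply(cum, grp, max)
  risk_log[ord] <- log(cum_by_grp[grp]) + max(eta)
  sum((eta - risk_log)[event == 1])
}

#' Fit a penalized Cox regression (lasso / ridge / elastic net)
#'
#' Thin, contract-enforcing wrapper around [glmnet::glmnet()] with
#' `family = "cox"`. The objective is the per-observation partial
#' log-likelihood minus `lambda * P_alpha(beta)`, with
#' `P_alpha(beta) = alpha * ||beta||_1 + (1 - alpha)/2 * ||beta||_2^2`.
#' Features are standardized internally before penalization (penalties
#' are scale-sensitive); coefficients are returned on the original scale.
#' With `alpha = 1`, excluded features get exact zeros.
#'
#' @param X n x p design matrix.
#' @param time,event Survival outcome vectors.
#' @param lambda Regularization weight (>= 0, glmnet per-observation
#'   scale).
#' @param alpha Elastic-net mixing in `[0, 1]`; 1 = lasso, 0 = ridge.
#' @param standardize Standardize features before fitting (default TRUE).
#' @param thresh Solver convergence threshold.
#' @return Named coefficient vector of length p.
#' @export
fit_penalized_cox <- function(X, time, event, lambda, alpha = 1,
                              standardize = TRUE, thresh = 1e-10) {
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1, nrow(X) >= 2,
            sum(event) >= 1)
  y <- survival::Surv(time, event)
  path <- lambda_path_to(X, y, lambda, alpha, family = "cox")
  fit <- glmnet::glmnet(X, y, family = "cox", alpha = alpha,
                        lambda = path, standardize = standardize,
                        thresh = thresh, maxit = 1e6)
  if (!all(fit$jerr == 0) || length(fit$lambda) < length(path))
    stop("penalized Cox solver did not converge for lambda = ", lambda,
         " (returned ", length(fit$lambda), "/", length(path), " path points)")
  beta <- as.numeric(fit$beta[, length(path)])
  beta[abs(beta) < 1e-9] <- 0     # exact-zero contract for support()
  names(beta) <- colnames(X)
  beta
}

# Warm-start path ending exactly at the requested lambda (glmnet is far
# more reliable along a decreasing path than at a cold single value).
lambda_path_to <- function(X, y, lambda, alpha, family) {
  init <- glmnet::glmnet(X, y, family = family, alpha = alpha, nlambda = 5)
  lmax <- max(init$lambda)
  if (lambda >= lmax * 0.999) return(lambda)   # at/above lambda_max: null model
  lo <- max(lambda, lmax * 1e-4)
  path <- exp(seq(log(lmax), log(lo), length.out = 25))
  if (lambda < lo) path <- c(path, lambda) else path[length(path)] <- lambda
  path
}

#' Select lambda by stratified cross-validation
#'
#' K-fold CV with folds stratified by the event indicator (so small event
#' counts spread evenly). The criterion is either the partial-likelihood
#' deviance (default, minimized) or Harrell's concordance (maximized) on
#' held-out folds.
#'
#' @param X,time,event Training data.
#' @param alpha Elastic-net mixing.
#' @param k_folds Number of folds (default 5).
#' @param lambda_grid Optional lambda sequence; default is glmnet's
#'   100-point log-spaced path from lambda_max down.
#' @param seed RNG seed for the fold assignment.
#' @param criterion `"deviance"` or `"concordance"`.
#' @return A list (`penalty_spec`): `lambda`, `alpha`, plus the evaluated
#'   `grid`, criterion values `cv_mean`, and `foldid`.
#' @export
cv_select_lambda <- function(X, time, event, alpha = 1, k_folds = 5,
                             lambda_grid = NULL, seed = 1L,
                             criterion = c("deviance", "concordance")) {
  criterion <- match.arg(criterion)
  stopifnot(k_folds >= 2)
  foldid <- stratified_folds(event, k_folds, seed)
  if (fold_lacks_events(foldid, event)) {
    foldid <- stratified_folds(event, k_folds, seed + 1L)
    if (fold_lacks_events(foldid, event))
      stop("cross-validation folds with zero events after refolding")
  }
  if (!is.null(lambda_grid) && length(lambda_grid) == 1) {
    return(list(lambda = lambda_grid, alpha = alpha, grid = lambda_grid,
                cv_mean = NA_real_, foldid = foldid, criterion = criterion))
  }
  y <- survival::Surv(time, event)
  type <- if (criterion == "deviance") "deviance" else "C"
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = alpha,
                          foldid = foldid, lambda = lambda_grid,
                          type.measure = type, standardize = TRUE)
  list(lambda = cv$lambda.min, alpha = alpha, grid = cv$lambda,
       cv_mean = cv$cvm, foldid = foldid, criterion = criterion)
}

stratified_folds <- function(event, k, seed) {
  set.seed(seed)
  foldid <- integer(length(event))
  for (lev in unique(event)) {
    idx <- which(event == lev)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

fold_lacks_events <- function(foldid, event) {
  any(tapply(event, foldid, sum) == 0)
}

#' Linear risk predictor
#'
#' Returns `x' beta` per sample. Differences of scores are log hazard
#' ratios under the proportional-hazards model; the baseline hazard
#' cancels, so ranking patients by risk needs only these scores.
#'
#' @param beta Coefficient vector (length p, optionally named).
#' @param X n x p design matrix.
#' @return Numeric vector of n risk scores (higher = higher hazard).
#' @export
linear_predictor <- function(beta, X) {
  stopifnot(ncol(X) == length(beta))
  as.numeric(X %*% beta)
}

#' Baseline hazard increments (Cox--Oakes / Breslow estimator)
#'
#' At each distinct event time t_i the hazard mass is
#' d_i / sum_{j in R_i} exp(x_j' beta), with d_i the number of events at
#' t_i and R_i the risk set. With beta = 0 this reduces to the
#' Nelson--Aalen increments d_i / |R_i|.
#'
#' @param X,time,event Training data.
#' @param beta Fitted coefficient vector.
#' @return A `baseline_hazard` list: `event_times` (strictly increasing),
#'   `increments`, `event_counts`.
#' @export
estimate_baseline_hazard <- function(X, time, event, beta) {
  stopifnot(sum(event) >= 1)
  eta <- linear_predictor(beta, X)
  w <- exp(eta - max(eta))
  et <- sort(unique(time[event == 1]))
  d <- vapply(et, function(t) sum(event == 1 & time == t), numeric(1))
  denom <- vapply(et, function(t) sum(w[time >= t]), numeric(1))
  if (any(denom <= 0)) stop("empty risk set at an event time")
  structure(list(event_times = et,
                 increments = d / (denom * exp(max(eta))),
                 event_counts = d),
            class = "baseline_hazard")
}

#' Survival probability from a fitted Cox model
#'
#' `S(t | x) = exp(-H0(t) * exp(x' beta))` with `H0` the cumulative sum
#' of baseline-hazard increments up to `t`. S(0) = 1 and S is
#' non-increasing in t.
#'
#' @param baseline A [estimate_baseline_hazard()] result.
#' @param beta Coefficient vector.
#' @param x Single feature vector (length p).
#' @param t Time point(s), >= 0.
#' @return Survival probabilities, same length as `t`.
#' @export
survival_function <- function(baseline, beta, x, t) {
  stopifnot(inherits(baseline, "baseline_hazard"), all(t >= 0))
  H <- cumsum(baseline$increments)
  H_at <- vapply(t, function(tt) {
    k <- sum(baseline$event_times <= tt)
    if (k == 0) 0 else H[k]
  }, numeric(1))
  exp(-H_at * exp(sum(x * beta)))
}

# Penalized per-observation Cox objective used by optimality checks:
# (1/n) * pl(beta) - lambda * P_alpha(beta).
penalized_cox_objective <- function(X, time, event, beta, lambda, alpha) {
  pen <- alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2)
  partial_log_likelihood(X, time, event, beta) / nrow(X) - lambda * pen
}
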