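#' Univariate Cox score statistics per feature
#'
#' Ranks features by the magnitude of the standardized univariate Cox
#' score statistic evaluated at beta = 0 (Breslow risk sets): for feature
#' k, `U_k = sum over events of (x_ik - riskset mean)` and
#' `V_k = sum over events of the riskset variance`; the score is
#' `|U_k| / sqrt(V_k)`. Constant features score 0. This is the feature
#' ranking behind supervised principal components.
#'
#' @param X n x p design matrix.
#' @param time,event Survival outcome vectors.
#' @return Named nonnegative score vector of length p.
#' @export
rank_features <- function(X, time, event) {
  stopifnot(nrow(X) == length(time), sum(event) >= 1)
  n <- nrow(X); p <- ncol(X)
  ord <- order(time, decreasing = TRUE)
  Xo <- X[ord, , drop = FALSE]
  to <- time[ord]
  # reverse-time cumulative sums give risk-set sums at each depth
  cs1 <- apply(Xo, 2, cumsum)
  cs2 <- apply(Xo^2, 2, cumsum)
  if (p == 1) { cs1 <- matrix(cs1, ncol = 1); cs2 <- matrix(cs2, ncol = 1) }
  et <- sort(unique(time[event == 1]))
  U <- numeric(p); V <- numeric(p)
  for (t in et) {
    depth <- sum(to >= t)            # risk set size, ties share the set
    m <- cs1[depth, ] / depth
    v <- cs2[depth, ] / depth - m^2
    v <- pmax(v, 0)
    ev_idx <- which(time == t & event == 1)
    d <- length(ev_idx)
    xsum <- if (d == 1) X[ev_idx, ] else colSums(X[ev_idx, , drop = FALSE])
    U <- U + (xsum - d * m)
    V <- V + d * v
  }
  score <- ifelse(V > 1e-12, abs(U) / sqrt(V), 0)
  names(score) <- colnames(X)
  score
}

#' Fit a supervised principal components model
#'
#' The preconditioning step: features are scored with [rank_features()],
#' and a score threshold and a number of leading principal components m
#' are chosen jointly by stratified k-fold cross-validation. For each
#' (threshold, m) grid point, the fold-training submatrix of features at
#' or above the threshold is centered/scaled, its first m PCs are
#' extracted, a Cox model is fit on the PC scores, and held-out
#' concordance of the linear predictor is recorded; the grid point with
#' the best mean held-out concordance (ties: larger threshold, then
#' smaller m) is refit on all samples.
#'
#' @param X,time,event Training data.
#' @param m_grid Candidate numbers of components (default 1:3).
#' @param threshold_grid Candidate score thresholds; default 20 quantiles
#'   of the score distribution between the 50th and 99th percentiles.
#' @param k_folds CV folds (default 5), stratified by event.
#' @param seed Fold-assignment seed.
#' @return An `spc_model` list: `selected_features`, `score_threshold`,
#'   `m`, `feature_scores`, `center`, `scale`, `loadings` (selected x m,
#'   largest-|loading| entry positive per component), `gamma` (PC Cox
#'   coefficients), and the evaluated `tuning_grid`.
#' @export
fit_spc <- function(X, time, event, m_grid = 1:3, threshold_grid = NULL,
                    k_folds = 5, seed = 1L) {
  scores <- rank_features(X, time, event)
  if (is.null(threshold_grid)) {
    threshold_grid <- unique(stats::quantile(
      scores, probs = seq(0.50, 0.99, length.out = 20), names = FALSE))
  }
  stopifnot(length(threshold_grid) >= 1, length(m_grid) >= 1)
  foldid <- stratified_folds(event, k_folds, seed)
  grid <- expand.grid(threshold = threshold_grid, m = m_grid)
  m_max <- max(m_grid)
  cmat <- matrix(NA_real_, nrow(grid), k_folds)
  for (f in seq_len(k_folds)) {
    tr <- which(foldid != f); te <- which(foldid == f)
    if (sum(event[tr]) == 0 || sum(event[te]) == 0) next
    for (thr in threshold_grid) {
      sel <- which(scores >= thr)
      if (length(sel) == 0) next
      # one SVD per (fold, threshold); sliced for each candidate m
      basis <- tryCatch(spc_basis(X[tr, sel, drop = FALSE], m_max),
                        error = function(e) NULL)
      if (is.null(basis)) next
      pcs_tr <- basis$pcs
      Xc_te <- sweep(sweep(X[te, sel, drop = FALSE], 2, basis$center),
                     2, basis$scale, "/")
      pcs_te <- Xc_te %*% basis$loadings
      for (m in m_grid[m_grid <= basis$m_eff]) {
        gamma <- tryCatch(
          coxph_pc_coef(pcs_tr[, seq_len(m), drop = FALSE], time[tr], event[tr]),
          error = function(e) NULL)
        if (is.null(gamma)) next
        lp_te <- as.numeric(pcs_te[, seq_len(m), drop = FALSE] %*% gamma)
        g <- which(grid$threshold == thr & grid$m == m)
        cmat[g, f] <- tryCatch(concordance_index(lp_te, time[te], event[te]),
                               error = function(e) NA_real_)
      }
    }
  }
  grid$mean_cindex <- ifelse(rowSums(!is.na(cmat)) > 0,
                             rowMeans(cmat, na.rm = TRUE), NA_real_)
  if (all(is.na(grid$mean_cindex)))
    stop("no SPC grid point could be evaluated (all thresholds empty or degenerate)")
  best <- which(grid$mean_cindex == max(grid$mean_cindex, na.rm = TRUE))
  # ties: sparser selection first (larger threshold), then fewer PCs
  best <- best[order(-grid$threshold[best], grid$m[best])][1]
  thr <- grid$threshold[best]; m <- grid$m[best]
  sel <- which(scores >= thr)
  comp <- spc_components(X[, sel, drop = FALSE], time, event, m)
  structure(list(selected_features = colnames(X)[sel],
                 score_threshold = thr, m = comp$m,
                 feature_scores = scores,
                 center = comp$center, scale = comp$scale,
                 loadings = comp$loadings, gamma = comp$gamma,
                 tuning_grid = grid),
            class = "spc_model")
}

# Centering/scaling and the first m_max PC loadings of a
# (samples x selected-features) block; m is capped by the block's rank.
spc_basis <- function(Xs, m_max) {
  n <- nrow(Xs)
  center <- colMeans(Xs)
  scale <- sqrt(pmax(colSums(Xs^2) - n * center^2, 0) / (n - 1))
  scale[scale < 1e-12] <- 1
  Xc <- sweep(sweep(Xs, 2, center), 2, scale, "/")
  m_eff <- min(m_max, n - 1, ncol(Xs))
  if (m_eff < 1) stop("degenerate SPC block")
  sv <- svd(Xc, nu = 0, nv = m_eff)
  V <- sv$v[, seq_len(m_eff), drop = FALSE]
  # deterministic sign: the largest-|loading| entry of each PC positive
  for (j in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, j]))
    if (V[piv, j] < 0) V[, j] <- -V[, j]
  }
  list(center = center, scale = scale, loadings = V, m_eff = m_eff,
       pcs = Xc %*% V)
}

# Unpenalized Cox coefficients of PC scores via the fast fitter.
coxph_pc_coef <- function(pcs, time, event) {
  fit <- survival::coxph.fit(pcs, survival::Surv(time, event),
                             strata = NULL, offset = NULL, init = NULL,
                             control = survival::coxph.control(),
                             weights = NULL, method = "efron",
                             rownames = NULL)
  gamma <- fit$coefficients
  if (anyNA(gamma)) stop("PC Cox regression produced NA coefficients")
  gamma
}

spc_components <- function(Xs, time, event, m) {
  basis <- spc_basis(Xs, m)
  gamma <- coxph_pc_coef(basis$pcs[, seq_len(basis$m_eff), drop = FALSE],
                         time, event)
  list(center = basis$center, scale = basis$scale,
       loadings = basis$loadings, gamma = gamma, m = basis$m_eff)
}

spc_linear_predictor <- function(comp, Xs_new) {
  Xc <- sweep(sweep(Xs_new, 2, comp$center), 2, comp$scale, "/")
  as.numeric(Xc %*% comp$loadings %*% comp$gamma)
}

#' Preconditioned outcomes from a fitted SPC model
#'
#' Produces the real-valued pseudo-outcome y-hat for each sample: the
#' linear predictor of the PC Cox regression evaluated on the sample's
#' selected-feature block. These scalars replace the censored (time,
#' event) pair in the subsequent lasso step.
#'
#' @param spc_model A fitted [fit_spc()] model.
#' @param X n x p design matrix over the model's feature universe
#'   (columns matched by name).
#' @return Numeric vector of preconditioned outcomes.
#' @export
precondition <- function(spc_model, X) {
  stopifnot(inherits(spc_model, "spc_model"))
  sel <- spc_model$selected_features
  missing <- setdiff(sel, colnames(X))
  if (length(missing) > 0)
    stop("X lacks selected features: ", paste(utils::head(missing, 5), collapse = ", "))
  spc_linear_predictor(spc_model, X[, sel, drop = FALSE])
}

#' Lasso least squares on preconditioned outcomes
#'
#' Minimizes `(1/2) ||y - X beta||^2 + lambda ||beta||_1`. With
#' `lambda = NULL` the penalty weight is chosen by k-fold
#' cross-validation over the regularization path; a numeric `lambda` is
#' used as given (on the objective scale above). Off-support coefficients
#' are exact zeros. When a fixed lambda is requested without
#' standardization/intercept, the solution is polished by coordinate
#' descent until the lasso KKT subgradient residual falls below `kkt_tol`.
#'
#' @param X n x p design matrix.
#' @param y_hat Real-valued (preconditioned) outcomes.
#' @param lambda `NULL` for CV selection, or a nonnegative number.
#' @param k_folds CV folds for lambda selection.
#' @param seed Fold seed.
#' @param standardize,intercept Passed to the solver (defaults TRUE, as
#'   usual for penalized regression on raw expression scales).
#' @param kkt_tol Target KKT residual for fixed-lambda solves.
#' @return Named coefficient vector (attribute `lambda` records the
#'   penalty used, attribute `intercept` the fitted intercept).
#' @export
fit_lasso_ls <- function(X, y_hat, lambda = NULL, k_folds = 5, seed = 1L,
                         standardize = TRUE, intercept = TRUE,
                         kkt_tol = 1e-8) {
  stopifnot(all(is.finite(y_hat)), nrow(X) == length(y_hat))
  if (stats::sd(y_hat) < 1e-12) {
    warning("degenerate (constant) preconditioned outcome; returning null model")
    beta <- stats::setNames(numeric(ncol(X)), colnames(X))
    attr(beta, "lambda") <- Inf
    attr(beta, "intercept") <- mean(y_hat)
    return(beta)
  }
  n <- nrow(X)
  if (is.null(lambda)) {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(k_folds), n))
    cv <- glmnet::cv.glmnet(X, y_hat, family = "gaussian", alpha = 1,
                            foldid = foldid, standardize = standardize,
                            intercept = intercept)
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    b0 <- as.numeric(stats::coef(cv, s = "lambda.min"))[1]
    lam_obj <- cv$lambda.min * n
  } else {
    stopifnot(lambda >= 0)
    lam_g <- lambda / n                   # glmnet per-observation scale
    path <- lambda_path_to(X, y_hat, lam_g, alpha = 1, family = "gaussian")
    fit <- glmnet::glmnet(X, y_hat, family = "gaussian", alpha = 1,
                          lambda = path, standardize = standardize,
                          intercept = intercept, thresh = 1e-14,
                          maxit = 1e7)
    beta <- as.numeric(fit$beta[, length(path)])
    b0 <- fit$a0[length(path)]
    if (!standardize && !intercept) {
      beta <- cd_polish(X, y_hat, beta, lambda, kkt_tol)
      b0 <- 0
    }
    lam_obj <- lambda
  }
  beta[abs(beta) < 1e-10] <- 0
  names(beta) <- colnames(X)
  attr(beta, "lambda") <- lam_obj
  attr(beta, "intercept") <- b0
  beta
}

# Cyclic coordinate descent on (1/2)||y - X b||^2 + lambda ||b||_1,
# run until the KKT subgradient residual meets tol.
cd_polish <- function(X, y, beta, lambda, tol, max_sweeps = 500) {
  xtx <- colSums(X^2)
  r <- y - as.numeric(X %*% beta)
  for (sweep_i in seq_len(max_sweeps)) {
    if (lasso_kkt_residual(X, y, beta, lambda, r = r) < tol) break
    for (j in seq_len(ncol(X))) {
      if (xtx[j] < 1e-12) next
      rho <- sum(X[, j] * r) + xtx[j] * beta[j]
      bj <- sign(rho) * max(abs(rho) - lambda, 0) / xtx[j]
      if (bj != beta[j]) {
        r <- r + X[, j] * (beta[j] - bj)
        beta[j] <- bj
      }
    }
  }
  beta
}

#' Lasso KKT subgradient residual
#'
#' Optimality certificate for `(1/2)||y - X beta||^2 + lambda||beta||_1`:
#' the largest violation of `|x_j'(y - X beta)| <= lambda` (inactive
#' coordinates) and `x_j'(y - X beta) = lambda * sign(beta_j)` (active
#' coordinates). Zero at the exact solution.
#'
#' @param X,y Design and response.
#' @param beta Candidate solution.
#' @param lambda Penalty on the `(1/2)RSS + lambda*L1` scale.
#' @param r Optional precomputed residual `y - X beta`.
#' @return The maximal KKT violation.
#' @export
lasso_kkt_residual <- function(X, y, beta, lambda, r = NULL) {
  if (is.null(r)) r <- y - as.numeric(X %*% beta)
  g <- as.numeric(crossprod(X, r))
  active <- beta != 0
  viol_in <- if (any(!active)) max(pmax(abs(g[!active]) - lambda, 0)) else 0
  viol_ac <- if (any(active)) max(abs(g[active] - lambda * sign(beta[active]))) else 0
  max(viol_in, viol_ac)
}

#' Preconditioned lasso (PL) fit
#'
#' The two-step procedure: (1) preconditioning — supervised principal
#' components turn the censored outcome into real-valued pseudo-outcomes
#' y-hat; (2) lasso step — lasso least squares of y-hat on all features
#' of the (prefiltered) universe, with the penalty weight tuned by
#' cross-validation. Features discarded by the SPC screen can therefore
#' still enter the final model.
#'
#' @param X,time,event Training data (X: n x p).
#' @param m_grid,threshold_grid,k_folds See [fit_spc()].
#' @param seed RNG seed controlling the fold assignments.
#' @return Named coefficient vector over the p features (exact zeros off
#'   support).
#' @export
pl_fit <- function(X, time, event, m_grid = 1:3, threshold_grid = NULL,
                   k_folds = 5, seed = 1L) {
  spc <- fit_spc(X, time, event, m_grid = m_grid,
                 threshold_grid = threshold_grid, k_folds = k_folds,
                 seed = seed)
  y_hat <- precondition(spc, X)
  suppressWarnings(
    fit_lasso_ls(X, y_hat, lambda = NULL, k_folds = k_folds, seed = seed))
}
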