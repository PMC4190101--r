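#' Configuration for the robust-selection inner loop
#'
#' @param t_in Number of inner subsamples (default 100).
#' @param subtrain_fraction Fraction of the train set used as the inner
#'   sub-train set J (default 0.632, the effective bootstrap ratio).
#' @param prefilter_percentile SD-percentile q for [prefilter_by_sd()];
#'   0 disables prefiltering (typical values for microarray-scale inputs
#'   are 90--99).
#' @param threshold_grid_size Number K of shrinkage thresholds.
#' @param base_learner `"PL"` (preconditioned lasso) or `"lasso-cox"`.
#' @param k_folds Folds for the base learner's internal tuning.
#' @param seed Master seed; each inner fit draws a derived substream.
#' @return An `rs_config` list.
#' @export
rs_config <- function(t_in = 100, subtrain_fraction = 0.632,
                      prefilter_percentile = 0, threshold_grid_size = 50,
                      base_learner = c("PL", "lasso-cox"), k_folds = 5,
                      seed = 1L) {
  base_learner <- match.arg(base_learner)
  stopifnot(t_in >= 1, subtrain_fraction > 0, subtrain_fraction < 1,
            prefilter_percentile >= 0, prefilter_percentile < 100,
            threshold_grid_size >= 2, k_folds >= 2)
  structure(list(t_in = as.integer(t_in),
                 subtrain_fraction = subtrain_fraction,
                 prefilter_percentile = prefilter_percentile,
                 threshold_grid_size = as.integer(threshold_grid_size),
                 base_learner = base_learner,
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "rs_config")
}

# Deterministic per-task substream seed below 2^31, so changing the
# number of trials never perturbs earlier trials.
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 + 104729 * as.double(index)) %%
               2147483647)
}

#' Prefilter features by standard deviation percentile
#'
#' Drops low-variability features: with p features and percentile q, the
#' `floor(p * q / 100)` features with the smallest training-set SD are
#' removed and the rest retained (so with distinct SDs the retained count
#' is exactly `p - floor(p * q / 100)`). Ties at the cutoff keep the
#' lower feature index. SDs must be computed on training samples only.
#'
#' @param X_train Features x samples numeric matrix (training samples
#'   only).
#' @param percentile_q Percentile in `[0, 100)`; 0 retains everything.
#' @return Sorted integer indices of retained features.
#' @export
prefilter_by_sd <- function(X_train, percentile_q) {
  stopifnot(percentile_q >= 0, percentile_q < 100)
  p <- nrow(X_train)
  if (percentile_q == 0) return(seq_len(p))
  sds <- row_sds(X_train)
  if (all(sds < 1e-12)) stop("all features are constant; nothing to retain")
  n_keep <- p - floor(p * percentile_q / 100)
  ord <- order(-sds, seq_len(p))      # ties broken by lower feature index
  sort(ord[seq_len(n_keep)])
}

row_sds <- function(X) {
  n <- ncol(X)
  if (n < 2) stop("need at least 2 samples to compute SDs")
  m <- rowMeans(X)
  sqrt(pmax(rowSums(X^2) - n * m^2, 0) / (n - 1))
}

#' Inner subsampling splits of a train set
#'
#' Draws `t_in` independent random partitions of the train index set I
#' into a sub-train set J of size `round(fraction * |I|)` and a tuning
#' set (the remainder). A draw whose J contains zero events is redrawn
#' (up to 100 attempts).
#'
#' @param train_index Integer indices of the train set I.
#' @param t_in Number of splits.
#' @param fraction Sub-train fraction (default 0.632).
#' @param seed RNG seed.
#' @param event Event flags aligned with `train_index` positions (i.e.
#'   `event[train_index]` are the train events); used for the
#'   zero-event redraw rule.
#' @return List of `t_in` lists with elements `sub_train` and `tuning`
#'   (disjoint index vectors partitioning `train_index`).
#' @export
inner_splits <- function(train_index, t_in, fraction = 0.632, seed = 1L,
                         event = NULL) {
  stopifnot(length(train_index) >= 10, t_in >= 1,
            fraction > 0, fraction < 1)
  set.seed(seed)
  n_sub <- round(fraction * length(train_index))
  lapply(seq_len(t_in), function(t) {
    for (attempt in 1:100) {
      sub <- sort(sample(train_index, n_sub))
      if (is.null(event) || sum(event[sub]) > 0)
        return(list(sub_train = sub, tuning = setdiff(train_index, sub)))
    }
    stop("could not draw an inner sub-train set containing an event")
  })
}

#' Aggregate coefficient vectors by averaging
#'
#' The ensemble step: the mean of the inner-fit coefficient vectors.
#' Its support is the union of the component supports (minus exact
#' cancellations, which are possible but measure-zero in practice).
#'
#' @param beta_list List of equal-length numeric coefficient vectors.
#' @return A list with `beta_bar` (the mean vector) and
#'   `component_supports` (list of integer support index vectors).
#' @export
aggregate_models <- function(beta_list) {
  stopifnot(length(beta_list) >= 1)
  dims <- lengths(beta_list)
  if (length(unique(dims)) != 1) stop("coefficient vectors differ in length")
  beta_bar <- Reduce(`+`, beta_list) / length(beta_list)
  list(beta_bar = beta_bar,
       component_supports = lapply(beta_list, function(b) which(b != 0)))
}

#' Shrink an aggregated model by CV-tuned thresholding
#'
#' Sweeps K evenly spaced thresholds between the smallest and largest
#' nonzero |coefficient| of the aggregated vector; at each threshold,
#' coefficients below it (in magnitude) are zeroed and the mean
#' concordance of the resulting linear predictor over the inner tuning
#' sets is recorded. The threshold maximizing mean tuning concordance
#' wins; ties go to the larger threshold (the sparser model). Surviving
#' coefficients keep their averaged values — no refit.
#'
#' @param beta_bar Aggregated coefficient vector (over the same feature
#'   universe as the columns of `X`).
#' @param X n x p design matrix holding at least all tuning samples.
#' @param time,event Outcome vectors aligned with `X` rows.
#' @param tuning_sets List of row-index vectors (the inner tuning sets).
#' @param K Number of thresholds (default 50).
#' @return A `shrunken_model` list: `beta_tilde`, `theta_star`,
#'   `tuning_curve` (threshold vs mean tuning concordance), `beta_bar`.
#' @export
shrink_model <- function(beta_bar, X, time, event, tuning_sets, K = 50) {
  stopifnot(K >= 2)
  nz <- abs(beta_bar[beta_bar != 0])
  if (length(nz) == 0) {
    warning("all-zero aggregated model; nothing to shrink")
    return(structure(list(beta_tilde = beta_bar, theta_star = NA_real_,
                          tuning_curve = NULL, beta_bar = beta_bar),
                     class = "shrunken_model"))
  }
  grid <- seq(min(nz), max(nz), length.out = K)
  curve <- vapply(grid, function(theta) {
    b <- beta_bar
    b[abs(b) < theta] <- 0
    vals <- vapply(tuning_sets, function(idx) {
      lp <- as.numeric(X[idx, , drop = FALSE] %*% b)
      tryCatch(concordance_index(lp, time[idx], event[idx]),
               error = function(e) NA_real_)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  curve[is.nan(curve)] <- -Inf
  best <- max(curve)
  theta_star <- max(grid[curve == best])   # ties: sparser model
  beta_tilde <- beta_bar
  beta_tilde[abs(beta_tilde) < theta_star] <- 0
  structure(list(beta_tilde = beta_tilde, theta_star = theta_star,
                 tuning_curve = data.frame(threshold = grid,
                                           mean_cindex = curve),
                 beta_bar = beta_bar),
            class = "shrunken_model")
}

#' Robust-selection fit on a train set
#'
#' The inner subsampling procedure: prefilter features by train-set SD,
#' draw `t_in` sub-train/tuning splits, fit the base learner
#' (preconditioned lasso or CV-tuned lasso-Cox, hyperparameters retuned
#' on each sub-train set) on every sub-train set, average the coefficient
#' vectors, and shrink the average by tuning-set-tuned thresholding.
#'
#' @param dataset An `rs_dataset` restricted to the train samples.
#' @param config An [rs_config()].
#' @return A `shrunken_model` whose `beta_tilde`/`beta_bar` live on the
#'   full feature universe (zeros for prefiltered-out features), plus
#'   `retained_features`, `n_failed`, and the config.
#' @export
rs_fit <- function(dataset, config) {
  stopifnot(inherits(dataset, "rs_dataset"), inherits(config, "rs_config"))
  keep <- prefilter_by_sd(dataset$expression, config$prefilter_percentile)
  X <- t(dataset$expression[keep, , drop = FALSE])
  n <- nrow(X)
  splits <- inner_splits(seq_len(n), config$t_in, config$subtrain_fraction,
                         seed = config$seed, event = dataset$event)
  fits <- vector("list", config$t_in)
  failures <- character(0)
  for (t in seq_len(config$t_in)) {
    J <- splits[[t]]$sub_train
    sub_seed <- substream_seed(config$seed, t)
    fits[[t]] <- tryCatch(
      fit_base_learner(X[J, , drop = FALSE], dataset$time[J],
                       dataset$event[J], config, sub_seed),
      error = function(e) {
        failures <<- c(failures, paste0("fit ", t, ": ", conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (mean(!ok) > 0.10) {
    stop("more than 10% of inner fits failed:\n",
         paste(utils::head(failures, 5), collapse = "\n"))
  }
  agg <- aggregate_models(fits[ok])
  shrunk <- shrink_model(agg$beta_bar, X, dataset$time, dataset$event,
                         lapply(splits[ok], `[[`, "tuning"),
                         K = config$threshold_grid_size)
  # report on the full feature universe
  p_full <- length(dataset$feature_ids)
  embed <- function(b) {
    out <- stats::setNames(numeric(p_full), dataset$feature_ids)
    out[keep] <- b
    out
  }
  shrunk$beta_tilde <- embed(shrunk$beta_tilde)
  shrunk$beta_bar <- embed(shrunk$beta_bar)
  shrunk$retained_features <- keep
  shrunk$n_failed <- sum(!ok)
  shrunk$config <- config
  shrunk
}

fit_base_learner <- function(X, time, event, config, seed) {
  if (config$base_learner == "PL") {
    pl_fit(X, time, event, k_folds = config$k_folds, seed = seed)
  } else {
    fit_lasso_cox_cv(X, time, event, k_folds = config$k_folds, seed = seed)
  }
}

# CV-tuned lasso-Cox in one pass (stratified folds; coefficients at
# lambda.min). The building blocks cv_select_lambda / fit_penalized_cox
# expose the same model; this fuses them to avoid a redundant refit.
fit_lasso_cox_cv <- function(X, time, event, k_folds = 5, seed = 1L) {
  foldid <- stratified_folds(event, k_folds, seed)
  if (fold_lacks_events(foldid, event))
    foldid <- stratified_folds(event, k_folds, seed + 1L)
  y <- survival::Surv(time, event)
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 1, foldid = foldid,
                          type.measure = "deviance", standardize = TRUE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  beta[abs(beta) < 1e-9] <- 0
  names(beta) <- colnames(X)
  beta
}
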