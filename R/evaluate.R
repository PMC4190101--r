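#' Configuration for the outer evaluation loop
#'
#' @param t_out Number of outer train/test splits (default 100).
#' @param train_fraction Train fraction per split (default 0.632).
#' @param methods Methods to run: any of `"RS-PL"` (robust selection with
#'   preconditioned lasso), `"RS-L"` (robust selection with lasso-Cox),
#'   `"PL"`, `"L"`, `"Dev"` (top-SD screening + ridge Cox), `"Cor"`
#'   (top-concordance screening + ridge Cox), `"Cli"` (clinical-only
#'   unpenalized Cox).
#' @param pi_threshold Baseline selection probability for
#'   [robust_signature()].
#' @param extra_shrinkage_sizes Integer vector of signature sizes G for
#'   the extra-shrinkage stability curves.
#' @param n_top Screening-list size for Dev and Cor (default 100).
#' @param seed Master seed.
#' @return An `outer_config` list.
#' @export
outer_config <- function(t_out = 100, train_fraction = 0.632,
                         methods = c("RS-PL", "RS-L", "PL", "L"),
                         pi_threshold = 0.5,
                         extra_shrinkage_sizes = integer(0),
                         n_top = 100, seed = 1L) {
  known <- c("RS-PL", "RS-L", "PL", "L", "Dev", "Cor", "Cli")
  if (!all(methods %in% known))
    stop("unknown methods: ", paste(setdiff(methods, known), collapse = ", "))
  stopifnot(t_out >= 1, train_fraction > 0, train_fraction < 1,
            pi_threshold >= 0, pi_threshold <= 1)
  structure(list(t_out = as.integer(t_out), train_fraction = train_fraction,
                 methods = methods, pi_threshold = pi_threshold,
                 extra_shrinkage_sizes = as.integer(extra_shrinkage_sizes),
                 n_top = as.integer(n_top), seed = as.integer(seed)),
            class = "outer_config")
}

#' Outer train/test splits
#'
#' Draws `t_out` independent random splits of the cohort into a train
#' set I (`fraction`, default 63.2%) and a disjoint test set. The same
#' split list is reused for every method so comparisons are paired.
#' Splits whose train or test part has zero events are redrawn (up to
#' 100 attempts).
#'
#' @param n Cohort size (>= 20).
#' @param t_out Number of splits.
#' @param fraction Train fraction.
#' @param seed RNG seed.
#' @param event Event flags (length n) for the redraw rule.
#' @return List of `t_out` lists with `train` and `test` index vectors.
#' @export
outer_splits <- function(n, t_out, fraction = 0.632, seed = 1L,
                         event = NULL) {
  stopifnot(n >= 20, t_out >= 1, fraction > 0, fraction < 1)
  set.seed(seed)
  n_train <- round(fraction * n)
  lapply(seq_len(t_out), function(t) {
    for (attempt in 1:100) {
      tr <- sort(sample(n, n_train))
      te <- setdiff(seq_len(n), tr)
      if (is.null(event) ||
          (sum(event[tr]) > 0 && sum(event[te]) > 0))
        return(list(train = tr, test = te))
    }
    stop("could not draw an outer split with events on both sides")
  })
}

#' Run the outer evaluation of one or more methods
#'
#' For every outer split and every requested method: fit on the train
#' set (with method-appropriate internal tuning; expression-based
#' baselines see the same SD-prefiltered feature universe as the RS
#' methods), compute the held-out concordance of the linear predictor on
#' the never-seen test samples, and record the support as that trial's
#' signature. Selection probabilities per feature are the fraction of
#' trials in which the feature was selected.
#'
#' @param dataset An `rs_dataset`.
#' @param config An [outer_config()].
#' @param rs_cfg An [rs_config()] used by the RS methods (its
#'   `prefilter_percentile` also governs the baselines' feature
#'   universe).
#' @return A list with `trials` (data.frame: trial, method,
#'   test_concordance, support_size), `profiles` (per-method
#'   [selection_profile()] data.frame), `signatures` (per-method list of
#'   per-trial named nonzero-coefficient vectors), `splits`, and the
#'   configs.
#' @export
run_evaluation <- function(dataset, config, rs_cfg = rs_config()) {
  stopifnot(inherits(dataset, "rs_dataset"), inherits(config, "outer_config"))
  n <- length(dataset$sample_ids)
  splits <- outer_splits(n, config$t_out, config$train_fraction,
                         seed = config$seed, event = dataset$event)
  methods <- config$methods
  if ("Cli" %in% methods && is.null(dataset$clinical))
    stop("method Cli requested but the dataset has no clinical covariates")
  cli_mm <- if ("Cli" %in% methods)
    clinical_model_matrix(dataset$clinical) else NULL

  trials <- list()
  signatures <- stats::setNames(
    lapply(methods, function(m) vector("list", config$t_out)), methods)
  failures <- stats::setNames(numeric(length(methods)), methods)

  for (t in seq_len(config$t_out)) {
    tr <- splits[[t]]$train
    te <- splits[[t]]$test
    d_train <- subset_samples(dataset, tr)
    trial_seed <- substream_seed(config$seed, t)
    keep <- prefilter_by_sd(d_train$expression, rs_cfg$prefilter_percentile)
    X_tr <- t(d_train$expression[keep, , drop = FALSE])
    X_te <- t(dataset$expression[keep, te, drop = FALSE])
    for (m in methods) {
      res <- tryCatch(
        run_one_method(m, dataset, d_train, X_tr, X_te, tr, te, keep,
                       cli_mm, config, rs_cfg, trial_seed),
        error = function(e) {
          warning("trial ", t, ", method ", m, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(res)) {
        failures[m] <- failures[m] + 1
        next
      }
      trials[[length(trials) + 1]] <- data.frame(
        trial = t, method = m, test_concordance = res$cindex,
        support_size = length(res$signature))
      signatures[[m]][[t]] <- res$signature
    }
  }
  bad <- failures / config$t_out > 0.10
  if (any(bad))
    stop("more than 10% of trials failed for: ",
         paste(names(failures)[bad], collapse = ", "))
  trials <- do.call(rbind, trials)
  universes <- lapply(stats::setNames(methods, methods), function(m) {
    if (m == "Cli") colnames(cli_mm) else dataset$feature_ids
  })
  profiles <- lapply(stats::setNames(methods, methods), function(m)
    selection_profile(signatures[[m]], universes[[m]], config$t_out))
  list(trials = trials, profiles = profiles, signatures = signatures,
       splits = splits, config = config, rs_config = rs_cfg)
}

run_one_method <- function(m, dataset, d_train, X_tr, X_te, tr, te, keep,
                           cli_mm, config, rs_cfg, trial_seed) {
  time_tr <- d_train$time; event_tr <- d_train$event
  if (m == "Cli") {
    beta <- fit_cli(dataset$clinical[tr, , drop = FALSE], time_tr, event_tr,
                    mm = cli_mm[tr, , drop = FALSE])
    lp_te <- as.numeric(cli_mm[te, , drop = FALSE] %*% beta)
    sig <- beta[beta != 0]
  } else {
    beta <- switch(
      m,
      "RS-PL" = ,
      "RS-L" = {
        cfg <- rs_cfg
        cfg$base_learner <- if (m == "RS-PL") "PL" else "lasso-cox"
        cfg$seed <- trial_seed
        fit <- rs_fit(d_train, cfg)
        fit$beta_tilde[keep]
      },
      "PL" = pl_fit(X_tr, time_tr, event_tr, k_folds = rs_cfg$k_folds,
                    seed = trial_seed),
      "L" = fit_lasso_cox_cv(X_tr, time_tr, event_tr,
                             k_folds = rs_cfg$k_folds, seed = trial_seed),
      "Dev" = fit_dev(X_tr, time_tr, event_tr, n_top = config$n_top,
                      k_folds = rs_cfg$k_folds, seed = trial_seed),
      "Cor" = fit_cor(X_tr, time_tr, event_tr, n_top = config$n_top,
                      k_folds = rs_cfg$k_folds, seed = trial_seed))
    lp_te <- as.numeric(X_te %*% beta)
    sig <- beta[beta != 0]
  }
  list(cindex = concordance_index(lp_te, dataset$time[te], dataset$event[te]),
       signature = sig)
}

#' Per-feature selection probabilities over outer trials
#'
#' @param trial_signatures List of per-trial named coefficient vectors
#'   (nonzero entries only; NULL for failed trials).
#' @param universe Character vector of all candidate feature ids.
#' @param t_out Number of outer trials (the probability denominator).
#' @return Data frame with `feature_id`, `selection_probability`
#'   (multiples of 1/t_out), and `mean_coefficient` (mean over the
#'   trials in which the feature was selected; 0 if never).
#' @export
selection_profile <- function(trial_signatures, universe, t_out) {
  counts <- stats::setNames(numeric(length(universe)), universe)
  sums <- counts
  for (sig in trial_signatures) {
    if (is.null(sig) || length(sig) == 0) next
    counts[names(sig)] <- counts[names(sig)] + 1
    sums[names(sig)] <- sums[names(sig)] + sig
  }
  data.frame(feature_id = universe,
             selection_probability = as.numeric(counts) / t_out,
             mean_coefficient = ifelse(counts > 0, sums / pmax(counts, 1), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Robust signature at a baseline selection probability
#'
#' Features whose estimated selection probability reaches the threshold
#' pi, ordered by decreasing probability (ties by decreasing
#' |mean coefficient|, then feature id).
#'
#' @param profile A [selection_profile()] data.frame.
#' @param pi_threshold Baseline probability in `[0, 1]`.
#' @return Character vector of feature ids (possibly empty).
#' @export
robust_signature <- function(profile, pi_threshold) {
  stopifnot(pi_threshold >= 0, pi_threshold <= 1)
  hit <- profile[profile$selection_probability >= pi_threshold &
                   profile$selection_probability > 0, , drop = FALSE]
  ord <- order(-hit$selection_probability, -abs(hit$mean_coefficient),
               hit$feature_id)
  hit$feature_id[ord]
}

#' Extra shrinkage: top-G features by coefficient magnitude
#'
#' Truncates a fitted coefficient vector to its G largest-magnitude
#' features (ranks 1..G, rank 1 = largest). If the support holds fewer
#' than G features the full support is returned and the result is
#' flagged, so size-G stability curves can exclude the trial. Magnitude
#' ties are broken by lower feature id.
#'
#' @param beta Named coefficient vector.
#' @param G Target signature size (>= 1).
#' @return List with `features` (ranked character vector), `ranks`, and
#'   `flagged` (TRUE when support < G).
#' @export
extra_shrinkage <- function(beta, G) {
  stopifnot(G >= 1, !is.null(names(beta)))
  nz <- beta[beta != 0]
  ord <- order(-abs(nz), names(nz))
  feats <- names(nz)[ord][seq_len(min(G, length(nz)))]
  list(features = feats, ranks = seq_along(feats),
       flagged = length(nz) < G)
}

#' Variance-screening baseline (Dev)
#'
#' Selects the `n_top` features with the largest SD across training
#' samples — entirely unsupervised, hence very stable — then fits a
#' CV-tuned ridge Cox regression on them. All other coefficients are
#' zero.
#'
#' @param X,time,event Training data (X: n x p).
#' @param n_top Screening-list size (default 100; `p >= n_top`).
#' @param k_folds,seed Ridge CV settings.
#' @return Named coefficient vector of length p.
#' @export
fit_dev <- function(X, time, event, n_top = 100, k_folds = 5, seed = 1L) {
  stopifnot(ncol(X) >= n_top)
  sds <- row_sds(t(X))
  top <- sort(order(-sds, seq_len(ncol(X)))[seq_len(n_top)])
  ridge_on_subset(X, time, event, top, k_folds, seed)
}

#' Concordance-screening baseline (Cor)
#'
#' Scores each feature by its univariate concordance with the outcome
#' and keeps the `n_top` features with the largest |c - 0.5| (so
#' strongly protective features rank as high as strongly hazardous
#' ones), then fits CV-tuned ridge Cox on them. For this ranking, tied
#' predictions contribute 1/2 so a constant feature scores exactly
#' c = 0.5 and ranks last.
#'
#' @inheritParams fit_dev
#' @return Named coefficient vector of length p.
#' @export
fit_cor <- function(X, time, event, n_top = 100, k_folds = 5, seed = 1L) {
  stopifnot(ncol(X) >= n_top)
  cvals <- univariate_concordances(X, time, event)
  top <- sort(order(-abs(cvals - 0.5), seq_len(ncol(X)))[seq_len(n_top)])
  ridge_on_subset(X, time, event, top, k_folds, seed)
}

# Per-feature c-index with the ties-as-1/2 convention used for ranking.
univariate_concordances <- function(X, time, event) {
  D <- survival_order_matrix(time, event)
  ut <- upper.tri(D)
  comparable <- ut & D != 0
  n_comp <- sum(comparable)
  if (n_comp == 0) stop("no comparable pairs")
  apply(X, 2, function(x) {
    P <- sign(outer(x, x, FUN = function(a, b) b - a))
    agree <- comparable & (D * P == 1)
    tied <- comparable & (P == 0)
    (sum(agree) + 0.5 * sum(tied)) / n_comp
  })
}

ridge_on_subset <- function(X, time, event, subset_idx, k_folds, seed) {
  foldid <- stratified_folds(event, k_folds, seed)
  if (fold_lacks_events(foldid, event))
    foldid <- stratified_folds(event, k_folds, seed + 1L)
  cv <- glmnet::cv.glmnet(X[, subset_idx, drop = FALSE],
                          survival::Surv(time, event), family = "cox",
                          alpha = 0, foldid = foldid,
                          type.measure = "deviance")
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta[subset_idx] <- as.numeric(stats::coef(cv, s = "lambda.min"))
  beta
}

#' Clinical-covariates-only Cox baseline (Cli)
#'
#' Unpenalized Cox regression on the clinical covariates alone
#' (categoricals one-hot encoded against a reference level); expression
#' features never enter.
#'
#' @param clinical Covariate data.frame (training rows).
#' @param time,event Training outcome.
#' @param mm Optional precomputed model matrix for the same rows (used
#'   by the evaluation harness so train and test encodings share factor
#'   levels).
#' @return Named coefficient vector over the model-matrix columns.
#' @export
fit_cli <- function(clinical, time, event, mm = NULL) {
  if (is.null(mm)) mm <- clinical_model_matrix(clinical)
  fit <- survival::coxph(survival::Surv(time, event) ~ mm)
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("clinical Cox regression failed (NA coefficients; separation or collinearity)")
  names(beta) <- colnames(mm)
  beta
}

clinical_model_matrix <- function(clinical) {
  mm <- stats::model.matrix(~ ., data = clinical)
  mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
}
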