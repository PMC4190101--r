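#' Read an expression matrix from TSV/CSV
#'
#' Reads a delimited text file holding real-valued expression summaries
#' (e.g. log2 probeset intensities) into the canonical features-by-samples
#' orientation. The first column holds feature identifiers and the header
#' row holds sample identifiers (or the transpose, with
#' `orientation = "samples_in_rows"`). Orientation is never auto-detected:
#' when p is close to n, guessing from shape is unsafe.
#'
#' @param path Path to the file. Delimiter is taken from the extension
#'   (`.tsv`/`.txt` = tab, `.csv` = comma) unless `sep` is given.
#' @param orientation `"features_in_rows"` (default, microarray convention)
#'   or `"samples_in_rows"`.
#' @param sep Optional delimiter override.
#' @param na_action What to do with missing/non-finite values:
#'   `"error"` (default) or `"drop"` (drop offending feature rows).
#' @return A numeric matrix (features x samples) with unique rownames
#'   (feature ids) and colnames (sample ids).
#' @export
read_expression <- function(path,
                            orientation = c("features_in_rows", "samples_in_rows"),
                            sep = NULL,
                            na_action = c("error", "drop")) {
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("expression file needs an id column plus data columns")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate row identifiers in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  num <- df[, -1, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    # locate the first offending cell for the error message
    col <- names(num)[which(bad)[1]]
    raw <- num[[which(bad)[1]]]
    row <- which(is.na(suppressWarnings(as.numeric(raw))) & !is.na(raw))[1]
    stop("non-numeric expression value in column '", col, "', row ",
         if (is.na(row)) "?" else ids[row])
  }
  mat <- as.matrix(num)
  rownames(mat) <- ids
  if (orientation == "samples_in_rows") mat <- t(mat)
  cdup <- unique(colnames(mat)[duplicated(colnames(mat))])
  if (length(cdup) > 0) {
    stop("duplicate column identifiers: ", paste(utils::head(cdup, 5), collapse = ", "))
  }
  keep_finite_features(mat, na_action)
}

sniff_delimiter <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

keep_finite_features <- function(mat, na_action) {
  ok <- rowSums(!is.finite(mat)) == 0
  if (all(ok)) return(mat)
  if (na_action == "error") {
    stop("non-finite expression values in features: ",
         paste(utils::head(rownames(mat)[!ok], 5), collapse = ", "))
  }
  message("dropping ", sum(!ok), " features with missing/non-finite values")
  mat[ok, , drop = FALSE]
}

#' Read a clinical table with survival annotation
#'
#' Parses a CSV with one row per sample. The named time column must hold
#' strictly positive survival times (one unit throughout, e.g. years); the
#' event column is 1 = event observed, 0 = right-censored, or any labels
#' given via `event_map`. Remaining columns are kept as covariates;
#' character columns become factors and their level encoding is stored in
#' `attr(, "covariate_levels")`.
#'
#' @param path CSV file path (first column or `id_col` = sample id).
#' @param time_col,event_col Column names for survival time and event flag.
#' @param id_col Sample id column; defaults to the first column.
#' @param event_map Optional named map from labels to 0/1, e.g.
#'   `c(no = 0, yes = 1)`.
#' @param sep Delimiter, default comma.
#' @return A data.frame with columns `sample_id`, `time`, `event`, then
#'   covariates.
#' @export
read_clinical <- function(path, time_col = "time", event_col = "event",
                          id_col = NULL, event_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  if (is.null(id_col)) id_col <- names(df)[1]
  for (col in c(id_col, time_col, event_col)) {
    if (!col %in% names(df)) stop("clinical table lacks column '", col, "'")
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in clinical table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  times <- suppressWarnings(as.numeric(df[[time_col]]))
  if (anyNA(times) || any(!is.finite(times)))
    stop("non-numeric survival times in column '", time_col, "'")
  if (any(times <= 0))
    stop("survival times must be strictly positive; offending samples: ",
         paste(utils::head(ids[times <= 0], 5), collapse = ", "))
  raw_event <- df[[event_col]]
  if (!is.null(event_map)) {
    keys <- as.character(raw_event)
    unknown <- setdiff(unique(keys), names(event_map))
    if (length(unknown) > 0)
      stop("event labels outside mapping: ", paste(unknown, collapse = ", "))
    events <- as.numeric(event_map[keys])
  } else {
    events <- suppressWarnings(as.numeric(raw_event))
  }
  if (anyNA(events) || !all(events %in% c(0, 1)))
    stop("event column '", event_col, "' must be 0/1 (or provide event_map)")
  covars <- df[, setdiff(names(df), c(id_col, time_col, event_col)), drop = FALSE]
  levels_rec <- list()
  for (nm in names(covars)) {
    if (is.character(covars[[nm]]) || is.logical(covars[[nm]])) {
      covars[[nm]] <- factor(covars[[nm]])
    }
    if (is.factor(covars[[nm]])) levels_rec[[nm]] <- levels(covars[[nm]])
  }
  out <- data.frame(sample_id = ids, time = times, event = events,
                    covars, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "covariate_levels") <- levels_rec
  out
}

#' Bundle expression and clinical data into an aligned dataset
#'
#' Restricts both inputs to the intersection of their sample ids, ordered
#' by sorted id for determinism, and returns the container used by all
#' downstream fitting and evaluation functions.
#'
#' @param expression Features-by-samples numeric matrix with dimnames.
#' @param clinical Data frame from [read_clinical()], or any data frame
#'   with `sample_id`, `time`, `event` columns.
#' @return An object of class `rs_dataset`: a list with `expression`
#'   (p x n matrix), `time`, `event` (length-n vectors), `sample_ids`,
#'   `feature_ids`, and `clinical` (covariate data.frame or NULL).
#' @export
align_dataset <- function(expression, clinical) {
  stopifnot(is.matrix(expression), !is.null(colnames(expression)))
  common <- sort(intersect(colnames(expression), clinical$sample_id))
  if (length(common) == 0) stop("no samples shared between expression and clinical data")
  dropped <- (ncol(expression) - length(common)) +
    (nrow(clinical) - length(common))
  if (dropped > 0) message("align_dataset: dropped ", dropped,
                           " unmatched sample records")
  expr <- expression[, common, drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  covars <- cl[, setdiff(names(cl), c("sample_id", "time", "event")),
               drop = FALSE]
  if (ncol(covars) == 0) covars <- NULL else rownames(covars) <- common
  new_rs_dataset(expr, cl$time, cl$event, covars)
}

#' Construct an `rs_dataset` directly from components
#'
#' @param expression p x n numeric matrix with feature rownames and sample
#'   colnames.
#' @param time,event Survival times (> 0) and 0/1 event flags, length n,
#'   ordered as the matrix columns.
#' @param clinical Optional covariate data.frame with n rows.
#' @return An `rs_dataset` object.
#' @export
new_rs_dataset <- function(expression, time, event, clinical = NULL) {
  stopifnot(is.matrix(expression),
            length(time) == ncol(expression),
            length(event) == ncol(expression))
  if (is.null(rownames(expression)))
    rownames(expression) <- paste0("f", seq_len(nrow(expression)))
  if (is.null(colnames(expression)))
    colnames(expression) <- paste0("s", seq_len(ncol(expression)))
  if (anyDuplicated(rownames(expression)) || anyDuplicated(colnames(expression)))
    stop("feature and sample identifiers must be unique")
  if (any(!is.finite(expression))) stop("expression values must be finite")
  if (any(time <= 0) || any(!is.finite(time))) stop("times must be positive and finite")
  if (!all(event %in% c(0, 1))) stop("events must be 0/1")
  structure(list(expression = expression,
                 time = as.numeric(time),
                 event = as.numeric(event),
                 sample_ids = colnames(expression),
                 feature_ids = rownames(expression),
                 clinical = clinical),
            class = "rs_dataset")
}

#' @exportS3Method base::print
print.rs_dataset <- function(x, ...) {
  cat("rs_dataset: ", nrow(x$expression), " features x ",
      ncol(x$expression), " samples; ", sum(x$event), " events (",
      round(100 * (1 - mean(x$event)), 1), "% censored)",
      if (!is.null(x$clinical)) paste0("; ", ncol(x$clinical), " clinical covariates"),
      "\n", sep = "")
  invisible(x)
}

#' Subset an `rs_dataset` by sample index
#'
#' @param dataset An `rs_dataset`.
#' @param idx Integer sample indices to keep.
#' @return The restricted `rs_dataset`.
#' @export
subset_samples <- function(dataset, idx) {
  new_rs_dataset(dataset$expression[, idx, drop = FALSE],
                 dataset$time[idx], dataset$event[idx],
                 if (is.null(dataset$clinical)) NULL
                 else dataset$clinical[idx, , drop = FALSE])
}

#' Write evaluation results to disk
#'
#' Emits the standard result artifacts: `signature.tsv` (per-feature
#' selection probability and mean coefficient, sorted by probability,
#' ties by |mean coefficient| then feature id), `metrics.json` (per-trial
#' test metrics), and `config.json` (the resolved configuration including
#' seeds, so a run can be replayed).
#'
#' @param profile Data frame with `feature_id`, `selection_probability`,
#'   `mean_coefficient` (one method's [selection_profile()] output).
#' @param metrics Per-trial metrics data.frame (e.g. `$trials` from
#'   [run_evaluation()]).
#' @param config Named list of configuration values.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(profile, metrics, config, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  ord <- order(-profile$selection_probability,
               -abs(profile$mean_coefficient), profile$feature_id)
  profile <- profile[ord, , drop = FALSE]
  sig_path <- file.path(out_dir, "signature.tsv")
  utils::write.table(profile, sig_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  met_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, met_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(signature = sig_path, metrics = met_path, config = cfg_path))
}

#' Write an `rs_dataset` as a TSV/CSV pair
#'
#' Companion to [read_expression()] / [read_clinical()]: writes
#' `<prefix>_expression.tsv` (features x samples) and
#' `<prefix>_clinical.csv` (sample_id, time, event, covariates).
#'
#' @param dataset An `rs_dataset`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, prefix) {
  expr_path <- paste0(prefix, "_expression.tsv")
  clin_path <- paste0(prefix, "_clinical.csv")
  expr_df <- data.frame(feature_id = rownames(dataset$expression),
                        dataset$expression, check.names = FALSE)
  utils::write.table(expr_df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clin <- data.frame(sample_id = dataset$sample_ids,
                     time = dataset$time, event = dataset$event,
                     check.names = FALSE)
  if (!is.null(dataset$clinical)) clin <- cbind(clin, dataset$clinical)
  utils::write.table(clin, clin_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = expr_path, clinical = clin_path))
}
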