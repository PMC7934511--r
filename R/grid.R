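# Grid-search model tuning: stratified 10-fold cross-validation over
# (feature-selection x algorithm x parameter) combinations, ranked by
# mean CV auROC with ties broken by lower Brier loss, then fewer
# features, then the lexicographic spec label. Feature selection is
# fitted inside each training fold only.

#' Stratified cross-validation folds
#'
#' Assigns fold ids so that every fold's class ratio is within one sample
#' of the global ratio.
#'
#' @param y binary labels.
#' @param folds number of folds.
#' @param seed shuffling seed.
#' @return integer vector of fold ids in `1:folds`.
#' @export
stratified_folds <- function(y, folds = 10L, seed = 1L) {
  y <- check_labels(y)
  if (min(table(y)) < folds)
    stop_ngsqc("a class has fewer members (", min(table(y)),
               ") than folds (", folds, ")")
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

average_precision <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  tp <- cumsum(lab == 1)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / sum(lab == 1)
}

fold_metrics <- function(p, y) {
  pred <- as.numeric(p >= 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  c(auroc = auroc(p, y), auprc = average_precision(p, y),
    accuracy = mean(pred == y), f1 = f1, brier = brier(p, y))
}

#' A model specification
#'
#' @param algorithm one of [qc_algorithms()].
#' @param params named list of algorithm parameters.
#' @param selection feature-selection method (`"none"`, `"chi2"`,
#'   `"rfe"`, `"stability"`).
#' @param k_fraction retained feature fraction, one of 0.25/0.5/0.75/1.
#' @return a `qc_model_spec` list.
#' @export
model_spec <- function(algorithm, params = list(), selection = "none",
                       k_fraction = 1) {
  if (!algorithm %in% qc_algorithms())
    stop_ngsqc("unknown algorithm: ", algorithm)
  if (!k_fraction %in% c(0.25, 0.5, 0.75, 1))
    stop_ngsqc("k_fraction must be one of 0.25, 0.5, 0.75, 1")
  structure(list(algorithm = algorithm, params = params,
                 selection = selection, k_fraction = k_fraction),
            class = "qc_model_spec")
}

spec_label <- function(spec) {
  ps <- if (length(spec$params))
    paste(names(spec$params),
          vapply(spec$params, function(v) paste(v, collapse = "."), ""),
          sep = "=", collapse = ",") else "default"
  sprintf("%s[%s] sel=%s k=%d%%", spec$algorithm, ps, spec$selection,
          as.integer(100 * spec$k_fraction))
}

#' The default tuning grid
#'
#' Reads the grid configuration shipped with the package
#' (`inst/extdata/default_grid.json`): nine classifier families (the
#' regularized extreme-gradient-boosting variant is registered but not in
#' the default grid) crossed with feature-selection settings. Users can
#' supply their own JSON configuration via [read_grid_config()].
#'
#' @param reduced logical; `TRUE` returns the reduced grid used for quick
#'   tuning runs (a subset of families and one selection setting).
#' @return list of `qc_model_spec`.
#' @export
qc_default_grid <- function(reduced = FALSE) {
  path <- system.file("extdata",
                      if (reduced) "reduced_grid.json" else
                        "default_grid.json",
                      package = "ngsqc", mustWork = TRUE)
  read_grid_config(path)
}

#' Read a grid configuration file
#'
#' @param path JSON file: an array of objects with fields `algorithm`,
#'   optional `params`, and optional `selection` (array of
#'   `{method, k_fraction}` objects, crossed with the algorithm entries).
#' @return list of `qc_model_spec`.
#' @export
read_grid_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  sels <- cfg$selection %||% list(list(method = "none", k_fraction = 1))
  specs <- list()
  for (entry in cfg$algorithms) {
    grids <- entry$params %||% list(list())
    for (params in grids) {
      for (sel in sels) {
        specs[[length(specs) + 1L]] <- model_spec(
          entry$algorithm, params = params,
          selection = sel$method %||% "none",
          k_fraction = sel$k_fraction %||% 1)
      }
    }
  }
  specs
}

#' Grid-search model tuning
#'
#' Scores every specification by stratified k-fold cross-validation:
#' within each fold, feature selection is fitted on the training split
#' only, the classifier is trained on the selected columns, and held-out
#' probabilities are scored (auROC, auPRC, accuracy, F1, Brier; mean and
#' sd over folds). Ranking is by mean auROC, ties by lower Brier, then
#' fewer retained features, then the spec label.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y binary labels (1 = low quality).
#' @param grid list of `qc_model_spec` (default [qc_default_grid()]).
#' @param folds number of CV folds (default 10).
#' @param seed seed controlling folds, selection subsampling and fits.
#' @return a `qc_grid_result`: `table` (ranked data frame of metrics),
#'   `specs` (ranked list), `best` (top spec), `folds`, `seed`.
#' @export
grid_search <- function(x, y, grid = qc_default_grid(), folds = 10L,
                        seed = 1L) {
  stopifnot(length(grid) >= 1L)
  y <- check_labels(y)
  x <- as.matrix(x)
  fold <- stratified_folds(y, folds, seed)
  rows <- vector("list", length(grid))
  for (s in seq_along(grid)) {
    spec <- grid[[s]]
    per_fold <- matrix(NA_real_, nrow = folds, ncol = 5L,
                       dimnames = list(NULL, c("auroc", "auprc",
                                               "accuracy", "f1", "brier")))
    n_feat <- integer(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      sel <- select_features(x[tr, , drop = FALSE], y[tr],
                             method = spec$selection,
                             k_fraction = spec$k_fraction,
                             seed = child_seed(seed, s * 100L + f))
      cl <- fit_classifier(spec$algorithm, sel$x, y[tr],
                           params = spec$params,
                           seed = child_seed(seed, s * 100L + f))
      p <- predict_classifier(cl, x[te, sel$selected, drop = FALSE])
      per_fold[f, ] <- fold_metrics(p, y[te])
      n_feat[f] <- length(sel$selected)
    }
    mu <- colMeans(per_fold, na.rm = TRUE)
    sdv <- apply(per_fold, 2L, stats::sd, na.rm = TRUE)
    rows[[s]] <- data.frame(
      spec = spec_label(spec), algorithm = spec$algorithm,
      selection = spec$selection, k_fraction = spec$k_fraction,
      n_features = as.integer(round(mean(n_feat))),
      auroc = mu[["auroc"]], auroc_sd = sdv[["auroc"]],
      auprc = mu[["auprc"]], accuracy = mu[["accuracy"]],
      f1 = mu[["f1"]], brier = mu[["brier"]], brier_sd = sdv[["brier"]],
      folds = folds, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  o <- order(-tab$auroc, tab$brier, tab$n_features, tab$spec)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, specs = grid[o], best = grid[[o[1L]]],
                 folds = folds, seed = seed),
            class = "qc_grid_result")
}

#' @export
print.qc_grid_result <- function(x, n = 5L, ...) {
  cat("Grid search over", nrow(x$table), "specifications,",
      x$folds, "-fold CV\n", sep = " ")
  print(utils::head(x$table[, c("spec", "auroc", "brier", "n_features")], n))
  invisible(x)
}

#' Train a final model on all rows
#'
#' Applies the spec's feature selection to the full table, fits the
#' classifier on every row, and packages the fitted state with its spec,
#' seed, column order and a training-set fingerprint so predictions are
#' reproducible and training provenance is checkable.
#'
#' @param x numeric feature matrix.
#' @param y binary labels.
#' @param spec a `qc_model_spec`.
#' @param seed fitting seed.
#' @param cv_metrics optional row of CV metrics to store alongside.
#' @return a `qc_model`.
#' @export
train_final <- function(x, y, spec, seed = 1L, cv_metrics = NULL) {
  if (!inherits(spec, "qc_model_spec"))
    stop_ngsqc("spec must be a qc_model_spec")
  y <- check_labels(y)
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  sel <- select_features(x, y, method = spec$selection,
                         k_fraction = spec$k_fraction,
                         seed = child_seed(seed, 1L))
  cl <- fit_classifier(spec$algorithm, sel$x, y, params = spec$params,
                       seed = child_seed(seed, 2L))
  structure(list(spec = spec, classifier = cl, columns = sel$selected,
                 input_columns = colnames(x), seed = seed,
                 cv_metrics = cv_metrics,
                 train_ids = rownames(x),
                 fingerprint = matrix_fingerprint(x, y)),
            class = "qc_model")
}

matrix_fingerprint <- function(x, y) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(unname(x), unname(y)), f)
  unname(tools::md5sum(f))
}

#' @export
print.qc_model <- function(x, ...) {
  cat("Tuned quality model:", spec_label(x$spec), "\n")
  cat("  trained on", length(x$train_ids %||% character()), "samples,",
      length(x$columns), "features\n")
  if (!is.null(x$cv_metrics))
    cat(sprintf("  CV auROC %.3f, Brier %.3f\n",
                x$cv_metrics$auroc, x$cv_metrics$brier))
  invisible(x)
}

#' Predict low-quality probabilities
#'
#' @param object a `qc_model` from [train_final()].
#' @param newdata numeric matrix (or single named vector) whose columns
#'   cover the model's training schema; missing or extra columns raise an
#'   error listing them.
#' @param ... unused.
#' @return data frame with `sample_id` and `P_low` in [0, 1].
#' @export
predict.qc_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  missing_cols <- setdiff(object$columns, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$input_columns)
  if (length(missing_cols) || length(extra))
    stop_ngsqc("feature schema mismatch; missing: [",
               paste(missing_cols, collapse = ", "), "]; extra: [",
               paste(extra, collapse = ", "), "]")
  p <- predict_classifier(object$classifier,
                          newdata[, object$columns, drop = FALSE])
  data.frame(sample_id = rownames(newdata) %||%
               paste0("sample_", seq_len(nrow(newdata))),
             P_low = p, stringsAsFactors = FALSE)
}

#' Save / load a tuned model
#'
#' The fitted state is serialized to `path` and a human-readable JSON
#' sidecar (`<path>.json`) records the spec, seed, column order and CV
#' metrics.
#'
#' @param model a `qc_model`.
#' @param path output file path (RDS).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "qc_model"))
  saveRDS(model, path)
  sidecar <- list(spec = unclass(model$spec), seed = model$seed,
                  columns = model$columns,
                  fingerprint = model$fingerprint,
                  cv_metrics = model$cv_metrics)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "qc_model"))
    stop_ngsqc("file does not contain a qc_model: ", path)
  model
}
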