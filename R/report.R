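# Decision-support report: reference statistics of a training set per
# feature and class, and precision/recall/F1 across probability
# thresholds from cross-validated predictions.

#' Reference statistics of a training table
#'
#' Per feature and quality class, the minimum, median and maximum of the
#' training values, so a user can compare a new sample's features to the
#' reference low- and high-quality populations.
#'
#' @param x numeric feature matrix.
#' @param y binary labels (1 = low quality).
#' @return data frame with columns `feature`, `class`, `min`, `median`,
#'   `max`, plus the training-set size in the `n_samples` attribute.
#' @export
reference_statistics <- function(x, y) {
  y <- check_labels(y)
  x <- as.matrix(x)
  rows <- list()
  for (cl in c("high" = 0, "low" = 1)) {
    sub <- x[y == cl, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      feature = colnames(x) %||% paste0("feature_", seq_len(ncol(x))),
      class = names(which(c(high = 0, low = 1) == cl)),
      min = apply(sub, 2L, min),
      median = apply(sub, 2L, stats::median),
      max = apply(sub, 2L, max),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_samples") <- nrow(x)
  out
}

#' Precision/recall/F1 across probability thresholds
#'
#' For each threshold t, samples with `P_low >= t` are called low
#' quality and precision, recall and F1 are computed against the labels.
#' When no sample is called positive, precision (and F1) are undefined
#' and reported as `NA` (serialized as null), not 0. Recall is
#' non-increasing in t.
#'
#' @param p_low cross-validated low-quality probabilities in [0, 1].
#' @param labels binary labels.
#' @param thresholds probability thresholds (default 0.05 ... 0.95 in
#'   steps of 0.05).
#' @return data frame `threshold`, `precision`, `recall`, `f1`.
#' @export
threshold_table <- function(p_low, labels,
                            thresholds = seq(0.05, 0.95, by = 0.05)) {
  labels <- check_labels(labels, require_both = FALSE)
  if (any(p_low < 0 | p_low > 1))
    stop_ngsqc("probabilities must lie in [0, 1]")
  rows <- lapply(thresholds, function(t) {
    called <- p_low >= t
    tp <- sum(called & labels == 1)
    prec <- if (sum(called) > 0) tp / sum(called) else NA_real_
    rec <- if (sum(labels == 1) > 0) tp / sum(labels == 1) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    data.frame(threshold = t, precision = prec, recall = rec, f1 = f1)
  })
  do.call(rbind, rows)
}

#' Build the decision-support report
#'
#' Combines [reference_statistics()] of the training table with a
#' [threshold_table()] from cross-validated predictions of the supplied
#' spec, without mutating any model or training file.
#'
#' @param x training feature matrix.
#' @param y binary labels.
#' @param spec `qc_model_spec` used for the cross-validated predictions.
#' @param folds CV folds.
#' @param seed seed.
#' @return list with `reference`, `thresholds`, `cv_auroc`.
#' @export
qc_report <- function(x, y, spec, folds = 10L, seed = 1L) {
  y <- check_labels(y)
  x <- as.matrix(x)
  fold <- stratified_folds(y, folds, seed)
  p <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- train_final(x[tr, , drop = FALSE], y[tr], spec,
                         seed = child_seed(seed, f))
    p[!tr] <- predict(model, x[!tr, , drop = FALSE])$P_low
  }
  list(reference = reference_statistics(x, y),
       thresholds = threshold_table(p, y),
       cv_auroc = auroc(p, y))
}
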