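# Evaluation protocols: within-experiment leave-out analysis,
# cross-species generalization, Cistrome-style quality-flag validation,
# and PCA/Dunn-index outlier screening on expression matrices.

#' Within-experiment leave-out evaluation
#'
#' For every experiment containing both low- and high-quality files, the
#' model is retrained on all samples outside the experiment and the
#' held-out members are scored. Per experiment the mean difference
#' `delta = mean(P_low | low) - mean(P_low | high)` summarises how well
#' the model separates quality inside a replicate group it never saw
#' during training.
#'
#' @param x numeric feature matrix.
#' @param y binary labels.
#' @param experiment character vector of experiment ids, one per row.
#' @param spec a `qc_model_spec` used for every retraining.
#' @param seed training seed.
#' @return a `qc_within_experiment` list: `per_file` (sample id,
#'   experiment, label, P_low), `per_experiment` (experiment, delta, n),
#'   and `models` training fingerprints.
#' @export
within_experiment_eval <- function(x, y, experiment, spec, seed = 1L) {
  y <- check_labels(y)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  experiment <- as.character(experiment)
  if (length(unique(experiment)) < 2L)
    stop_ngsqc("need at least two experiments")
  mixed <- names(Filter(function(v) length(unique(v)) == 2L,
                        split(y, experiment)))
  if (!length(mixed))
    stop_ngsqc("no experiment contains both low- and high-quality files")
  per_file <- list(); per_exp <- list(); fingerprints <- list()
  for (e in mixed) {
    hold <- experiment == e
    model <- train_final(x[!hold, , drop = FALSE], y[!hold], spec,
                         seed = child_seed(seed, match(e, mixed)))
    pr <- predict(model, x[hold, , drop = FALSE])
    fingerprints[[e]] <- model$train_ids
    per_file[[e]] <- data.frame(
      sample_id = rownames(x)[hold], experiment = e, label = y[hold],
      P_low = pr$P_low, stringsAsFactors = FALSE)
    delta <- mean(pr$P_low[y[hold] == 1]) - mean(pr$P_low[y[hold] == 0])
    per_exp[[e]] <- data.frame(experiment = e, delta = delta,
                               n = sum(hold), stringsAsFactors = FALSE)
  }
  structure(list(per_file = do.call(rbind, per_file),
                 per_experiment = do.call(rbind, per_exp),
                 train_ids = fingerprints),
            class = "qc_within_experiment")
}

#' @export
print.qc_within_experiment <- function(x, ...) {
  cat("Within-experiment evaluation:", nrow(x$per_experiment),
      "mixed experiments; mean delta",
      sprintf("%.3f", mean(x$per_experiment$delta)), "\n")
  invisible(x)
}

#' Cross-group (cross-species) generalization
#'
#' Outer stratified 5-fold protocol: for each outer fold of the training
#' group, a grid search with inner 10-fold CV picks the best spec on the
#' outer-training split; the resulting model is evaluated on the
#' held-out fold of the same group (within) and on the corresponding
#' fold of the other group (cross). Both directions are run.
#'
#' @param tables named list of exactly two groups, each a list with
#'   elements `x` (matrix) and `y` (labels).
#' @param grid tuning grid for the inner search.
#' @param outer_folds outer folds (default 5).
#' @param inner_folds inner CV folds (default 10).
#' @param seed seed.
#' @return data frame with columns `train_group`, `eval_type`
#'   (within/cross), `auroc` (mean over outer folds), plus per-fold values
#'   in the `folds` attribute.
#' @export
cross_species_eval <- function(tables, grid = qc_default_grid(reduced = TRUE),
                               outer_folds = 5L, inner_folds = 10L,
                               seed = 1L) {
  stopifnot(length(tables) == 2L)
  nms <- names(tables) %||% c("group1", "group2")
  for (g in 1:2) {
    tables[[g]]$y <- check_labels(tables[[g]]$y)
    tables[[g]]$x <- as.matrix(tables[[g]]$x)
  }
  fold_ids <- lapply(1:2, function(g)
    stratified_folds(tables[[g]]$y, outer_folds, child_seed(seed, g)))
  out <- list(); per_fold <- list()
  for (g in 1:2) {
    other <- 3L - g
    a_within <- a_cross <- numeric(outer_folds)
    for (f in seq_len(outer_folds)) {
      tr <- fold_ids[[g]] != f
      gs <- grid_search(tables[[g]]$x[tr, , drop = FALSE],
                        tables[[g]]$y[tr], grid = grid,
                        folds = inner_folds,
                        seed = child_seed(seed, g * 10L + f))
      model <- train_final(tables[[g]]$x[tr, , drop = FALSE],
                           tables[[g]]$y[tr], gs$best,
                           seed = child_seed(seed, g * 100L + f))
      te_w <- fold_ids[[g]] == f
      p_w <- predict(model, tables[[g]]$x[te_w, , drop = FALSE])$P_low
      a_within[f] <- auroc(p_w, tables[[g]]$y[te_w])
      te_c <- fold_ids[[other]] == f
      p_c <- predict(model, tables[[other]]$x[te_c, , drop = FALSE])$P_low
      a_cross[f] <- auroc(p_c, tables[[other]]$y[te_c])
    }
    out[[length(out) + 1L]] <- data.frame(
      train_group = nms[g], eval_type = c("within", "cross"),
      auroc = c(mean(a_within), mean(a_cross)), stringsAsFactors = FALSE)
    per_fold[[nms[g]]] <- list(within = a_within, cross = a_cross)
  }
  res <- do.call(rbind, out)
  attr(res, "folds") <- per_fold
  res
}

#' Cistrome quality metric thresholds
#'
#' A metric counts as a bad-quality flag when strictly below its
#' recommended threshold: median base quality < 25, uniquely mapped
#' reads < 60%, PBC < 80%, FRiP < 1%, union DHS overlap < 70%.
#' @export
CISTROME_THRESHOLDS <- c(median_base_quality = 25, uniquely_mapped_pct = 60,
                         pbc_pct = 80, frip_pct = 1,
                         union_dhs_overlap_pct = 70)

#' Count bad and good quality flags
#'
#' @param metrics named numeric vector (or one-row data frame) with any
#'   of the five metrics named in [CISTROME_THRESHOLDS]; absent metrics
#'   may be missing or `NA`.
#' @return named integer vector `c(bad, good)`; `bad + good` equals the
#'   number of metrics present.
#' @export
cistrome_flags <- function(metrics) {
  if (is.data.frame(metrics)) metrics <- unlist(metrics[1L, , drop = TRUE])
  metrics <- metrics[names(metrics) %in% names(CISTROME_THRESHOLDS)]
  metrics <- metrics[!is.na(metrics)]
  if (!length(metrics)) stop_ngsqc("no quality metrics present")
  th <- CISTROME_THRESHOLDS[names(metrics)]
  bad <- sum(metrics < th)
  c(bad = bad, good = length(metrics) - bad)
}

#' Label a sample from its quality flags
#'
#' High quality iff more than 3 metrics carry a good flag; at least four
#' of the five metrics must be present.
#'
#' @inheritParams cistrome_flags
#' @return `"high"` or `"low"`.
#' @export
atac_label <- function(metrics) {
  if (is.data.frame(metrics)) metrics <- unlist(metrics[1L, , drop = TRUE])
  present <- sum(!is.na(metrics[names(metrics) %in%
                                  names(CISTROME_THRESHOLDS)]))
  if (present < 4L)
    stop_ngsqc("need at least 4 quality metrics to label (have ",
               present, ")")
  fl <- cistrome_flags(metrics)
  if (fl[["good"]] > 3L) "high" else "low"
}

#' Correlate predicted probabilities with bad-flag counts
#'
#' Standard Pearson correlation between a model's low-quality
#' probabilities and the number of bad quality flags per sample.
#'
#' @param p_low numeric vector of probabilities.
#' @param bad_counts integer vector of bad-flag counts.
#' @return Pearson r in [-1, 1].
#' @export
flag_correlation <- function(p_low, bad_counts) {
  if (length(p_low) != length(bad_counts))
    stop_ngsqc("vectors must have equal length")
  if (length(p_low) < 3L) stop_ngsqc("need at least 3 samples")
  if (stats::sd(p_low) == 0 || stats::sd(bad_counts) == 0)
    stop_ngsqc("constant input vector")
  stats::cor(p_low, bad_counts, method = "pearson")
}

#' Dunn cluster-validity index
#'
#' Minimum between-cluster point-pair distance divided by the maximum
#' within-cluster diameter (Euclidean). Scale-invariant; returns `Inf`
#' when every cluster has zero diameter but clusters are distinct, and 0
#' when distinct clusters touch.
#'
#' @param points numeric matrix (n x d).
#' @param groups cluster labels, one per row, at least two groups.
#' @return the Dunn index.
#' @export
dunn_index <- function(points, groups) {
  points <- as.matrix(points)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop_ngsqc("need at least two groups")
  d <- as.matrix(stats::dist(points))
  same <- outer(groups, groups, "==")
  diag(same) <- NA
  inter <- d[!is.na(same) & !same]
  intra <- d[!is.na(same) & same]
  max_diam <- if (length(intra)) max(intra) else 0
  min_inter <- min(inter)
  if (max_diam == 0) {
    if (min_inter > 0) return(Inf)
    return(0)
  }
  min_inter / max_diam
}

#' PCA/Dunn outlier-removal evaluation
#'
#' Expression values are log2(TPM + 1) transformed and standardized per
#' gene, the samples are projected onto the first two principal
#' components, and group separation is scored by the Dunn index. The
#' `per_group` samples with the highest low-quality probability in each
#' group are then removed, the projection recomputed on the remaining
#' samples, and the index compared: a positive difference means the
#' clustering improved after removing the putative outliers.
#'
#' @param expression genes x samples numeric matrix of TPM values.
#' @param groups group label per sample (exactly two groups).
#' @param p_low low-quality probability per sample.
#' @param per_group number of samples removed per group (default 2).
#' @param pseudo_count added before log2 (default 1).
#' @return a `qc_outlier_eval` list: `dunn_before`, `dunn_after`,
#'   `delta_dunn`, `removed` sample ids, and both projections.
#' @export
outlier_removal_eval <- function(expression, groups, p_low, per_group = 2L,
                                 pseudo_count = 1) {
  expression <- as.matrix(expression)
  if (is.null(colnames(expression)))
    colnames(expression) <- paste0("sample_", seq_len(ncol(expression)))
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(expression),
            length(p_low) == ncol(expression))
  if (length(unique(groups)) != 2L)
    stop_ngsqc("exactly two groups are required")
  sizes <- table(groups)
  if (any(sizes <= per_group))
    stop_ngsqc("every group must have more than per_group (=", per_group,
               ") samples")
  project <- function(mat) {
    lg <- log2(mat + pseudo_count)
    sds <- apply(lg, 1L, stats::sd)
    z <- (lg[sds > 1e-12, , drop = FALSE] -
            rowMeans(lg[sds > 1e-12, , drop = FALSE])) / sds[sds > 1e-12]
    pr <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
    pr$x[, 1:2, drop = FALSE]
  }
  before <- project(expression)
  dunn_before <- dunn_index(before, groups)
  removed <- unlist(lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    idx[order(-p_low[idx])[seq_len(per_group)]]
  }))
  keep <- setdiff(seq_len(ncol(expression)), removed)
  after <- project(expression[, keep, drop = FALSE])
  dunn_after <- dunn_index(after, groups[keep])
  structure(list(dunn_before = dunn_before, dunn_after = dunn_after,
                 delta_dunn = dunn_after - dunn_before,
                 removed = colnames(expression)[removed],
                 projection_before = before, projection_after = after),
            class = "qc_outlier_eval")
}

#' @export
print.qc_outlier_eval <- function(x, ...) {
  cat(sprintf(
    "Dunn index %.3f -> %.3f (delta %+.3f); removed: %s\n",
    x$dunn_before, x$dunn_after, x$delta_dunn,
    paste(x$removed, collapse = ", ")))
  invisible(x)
}
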