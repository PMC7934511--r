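# One-feature probabilistic baseline: ROC/auROC with the label-inversion
# rule, ordinal flag encoding, and the Brier calibration loss.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability with half credit
#' for ties (equivalent to the trapezoidal ROC area): the probability that
#' a randomly chosen low-quality sample scores above a randomly chosen
#' high-quality one.
#'
#' @param scores numeric scores (higher = more likely low quality).
#' @param labels binary labels, 1 = low quality, 0 = high quality.
#' @return area in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels))
    stop_ngsqc("scores and labels must have equal length")
  if (length(scores) < 2L) stop_ngsqc("need at least two samples")
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-feature auROC with label inversion
#'
#' Uses a single feature's values directly as probabilities of low
#' quality. Because some features increase and others decrease with
#' quality, the ROC is evaluated under both the default and the inverted
#' labels and the maximum area is reported, so the result always lies in
#' [0.5, 1]. Invariant under any strictly monotone transform of the
#' scores.
#'
#' @inheritParams auroc
#' @return a `qc_roc` list: `auroc` (in [0.5, 1]), `orientation`
#'   (`"direct"` if higher scores indicate low quality won, else
#'   `"inverted"`), and the ROC `curve` points of the winning orientation.
#' @export
one_feature_auroc <- function(scores, labels) {
  labels <- check_labels(labels)
  a <- auroc(scores, labels)
  orientation <- if (a >= 1 - a) "direct" else "inverted"
  s <- if (orientation == "direct") scores else -scores
  structure(list(auroc = max(a, 1 - a), orientation = orientation,
                 curve = roc_points(s, labels)),
            class = "qc_roc")
}

#' @export
print.qc_roc <- function(x, ...) {
  cat(sprintf("one-feature auROC %.4f (%s orientation)\n",
              x$auroc, x$orientation))
  invisible(x)
}

roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == 1); fp <- cumsum(labels[o] == 0)
  keep <- !duplicated(scores[o][seq_along(o)], fromLast = TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(labels == 0)),
             tpr = c(0, tp[keep] / sum(labels == 1)))
}

#' Encode quality flags as low-quality scores
#'
#' Ordinal map Pass -> 0, Warning -> 0.5, Fail -> 1, turning a categorical
#' report flag into the scalar "probability of low quality" the
#' one-feature ROC construction requires. Monotone: replacing a flag by a
#' more severe one never decreases the score.
#'
#' @param flags vector of flags (`Pass`/`Warning`/`Fail`).
#' @return numeric vector in \{0, 0.5, 1\}.
#' @export
encode_flag_scores <- function(flags) {
  f <- quality_flag(as.character(flags))
  c(Pass = 0, Warning = 0.5, Fail = 1)[as.character(f)]
}

#' Brier loss
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better calibrated.
#'
#' @param probabilities predicted probabilities in [0, 1].
#' @param labels binary outcomes.
#' @return loss in [0, 1].
#' @export
brier <- function(probabilities, labels) {
  labels <- check_labels(labels, require_both = FALSE)
  if (length(probabilities) != length(labels))
    stop_ngsqc("probabilities and labels must have equal length")
  if (any(probabilities < 0 | probabilities > 1))
    stop_ngsqc("probabilities must lie in [0, 1]")
  mean((probabilities - labels)^2)
}
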