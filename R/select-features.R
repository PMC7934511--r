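# Feature selection: top-k by chi-squared statistic, recursive feature
# elimination with a ridge-logistic ranking model, and stability selection
# (selection frequency over subsampled chi-squared fits). Always fitted on
# training data only; grid search applies it inside each CV fold.

#' Chi-squared feature scores
#'
#' The scikit-learn-style chi-squared statistic for non-negative features
#' against binary labels: per feature, observed class-wise value sums are
#' compared to expectations proportional to the class frequencies.
#'
#' @param x numeric matrix with non-negative entries.
#' @param y binary labels.
#' @return numeric vector of per-column scores.
#' @export
chi2_scores <- function(x, y) {
  y <- check_labels(y)
  if (any(x < 0)) stop_ngsqc("chi2 requires non-negative feature values")
  obs <- rbind(colSums(x[y == 0, , drop = FALSE]),
               colSums(x[y == 1, , drop = FALSE]))
  total <- colSums(x)
  p <- c(mean(y == 0), mean(y == 1))
  expd <- outer(p, total)
  contrib <- (obs - expd)^2 / expd
  contrib[expd == 0] <- 0
  colSums(contrib)
}

#' Select features
#'
#' Retains `ceiling(k_fraction * ncol(x))` columns by one of three
#' methods: `chi2` (top scores, ties broken by column order), `rfe`
#' (recursive elimination, dropping the 10% of remaining columns with the
#' smallest ridge-logistic coefficient magnitudes on standardized
#' features until k remain), or `stability` (selection frequency of the
#' chi2 top-k over `n_subsamples` stratified half-subsamples, ranked by
#' frequency then mean score). `none` or `k_fraction = 1` is the identity.
#' Deterministic under a fixed seed.
#'
#' @param x numeric feature matrix.
#' @param y binary labels.
#' @param method one of `"none"`, `"chi2"`, `"rfe"`, `"stability"`.
#' @param k_fraction fraction of columns to retain, in \{0.25, 0.5,
#'   0.75, 1\} by convention (any value in (0, 1] is accepted).
#' @param seed seed for the stability subsampling.
#' @param n_subsamples number of stability subsamples.
#' @return list with `x` (reduced matrix), `selected` (column names),
#'   `method`, `k`.
#' @export
select_features <- function(x, y, method = c("none", "chi2", "rfe",
                                             "stability"),
                            k_fraction = 1, seed = 1L,
                            n_subsamples = 100L) {
  method <- match.arg(method)
  stopifnot(k_fraction > 0, k_fraction <= 1)
  p <- ncol(x)
  k <- min(p, as.integer(ceiling(k_fraction * p)))
  if (method == "none" || k == p) {
    return(list(x = x, selected = colnames(x), method = method, k = p))
  }
  y <- check_labels(y)
  sel_idx <- switch(method,
    chi2 = order(-chi2_scores(x, y))[seq_len(k)],
    rfe = rfe_select(x, y, k),
    stability = stability_select(x, y, k, seed, n_subsamples))
  sel_idx <- sort(sel_idx)
  list(x = x[, sel_idx, drop = FALSE],
       selected = colnames(x)[sel_idx], method = method, k = k)
}

rfe_select <- function(x, y, k) {
  remaining <- seq_len(ncol(x))
  while (length(remaining) > k) {
    xs <- scale_safely(x[, remaining, drop = FALSE])
    fit <- glmnet::glmnet(xs, factor(y), family = "binomial", alpha = 0,
                          lambda = 0.01, standardize = FALSE)
    w <- abs(as.numeric(fit$beta))
    n_drop <- min(length(remaining) - k,
                  max(1L, floor(0.1 * length(remaining))))
    drop <- order(w, decreasing = FALSE)[seq_len(n_drop)]
    remaining <- remaining[-drop]
  }
  remaining
}

stability_select <- function(x, y, k, seed, n_subsamples) {
  p <- ncol(x)
  freq <- numeric(p); score_sum <- numeric(p)
  i0 <- which(y == 0); i1 <- which(y == 1)
  for (b in seq_len(n_subsamples)) {
    idx <- with_seed(child_seed(seed, b), {
      c(sample(i0, max(2L, floor(length(i0) / 2))),
        sample(i1, max(2L, floor(length(i1) / 2))))
    })
    sc <- chi2_scores(x[idx, , drop = FALSE], y[idx])
    top <- order(-sc)[seq_len(k)]
    freq[top] <- freq[top] + 1
    score_sum <- score_sum + sc
  }
  order(-freq, -score_sum)[seq_len(k)]
}

# Standardize, leaving zero-variance columns at zero.
scale_safely <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  sdev[sdev < 1e-12] <- 1
  scale(x, center = mu, scale = sdev)
}
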