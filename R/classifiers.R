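# Classifier registry: the ten model families explored by the tuning
# grid. Each family provides fit(x, y, params, seed) and a probability
# predictor returning P(low quality). Families needing scale-invariance
# (knn, svm, mlp, logistic) standardize inside fit using training
# statistics only.
#
# Backends: rpart (decision tree; Gini or information/entropy splitting),
# ranger (random forest), xgboost (gradient boosting in classical-GBM
# configuration, and the regularized extreme-gradient-boosting variant,
# which the default grid excludes), an in-package discrete AdaBoost over
# rpart stumps, nnet (multilayer perceptron, one hidden layer), e1071
# (Gaussian naive Bayes, SVM), class::knn, and glmnet ridge for logistic
# regression.

safe_names <- function(nm) make.names(nm, unique = TRUE)

#' Names of the supported classifier families
#' @export
qc_algorithms <- function() {
  c("logistic_regression", "decision_tree", "random_forest",
    "gradient_boosting", "adaboost", "mlp", "naive_bayes", "knn", "svm",
    "xgboost")
}

fit_classifier <- function(algorithm, x, y, params = list(), seed = 1L) {
  if (!algorithm %in% qc_algorithms())
    stop_ngsqc("unknown algorithm: ", algorithm)
  y <- check_labels(y)
  x <- as.matrix(x)
  orig_cols <- colnames(x)
  colnames(x) <- safe_names(orig_cols)
  scaled_algos <- c("logistic_regression", "mlp", "knn", "svm")
  scale_info <- NULL
  if (algorithm %in% scaled_algos) {
    mu <- colMeans(x)
    sdev <- apply(x, 2L, stats::sd)
    sdev[sdev < 1e-12] <- 1
    scale_info <- list(center = mu, scale = sdev)
    x <- scale(x, center = mu, scale = sdev)
  }
  fit <- with_seed(seed, switch(algorithm,
    logistic_regression = fit_logistic(x, y, params),
    decision_tree = fit_tree(x, y, params),
    random_forest = fit_forest(x, y, params, seed),
    gradient_boosting = fit_gbm(x, y, params, regularized = FALSE),
    xgboost = fit_gbm(x, y, params, regularized = TRUE),
    adaboost = fit_adaboost(x, y, params),
    mlp = fit_mlp(x, y, params),
    naive_bayes = fit_nb(x, y, params),
    knn = fit_knn(x, y, params, seed),
    svm = fit_svm(x, y, params)))
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 scale = scale_info, columns = orig_cols, seed = seed),
            class = "qc_classifier")
}

predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "qc_classifier"))
  x <- as.matrix(x)
  colnames(x) <- safe_names(colnames(x))
  if (!is.null(model$scale))
    x <- scale(x, center = model$scale$center, scale = model$scale$scale)
  p <- switch(model$algorithm,
    logistic_regression = predict_logistic(model$fit, x),
    decision_tree = predict(model$fit, as.data.frame(x), type = "prob")[, "1"],
    random_forest = predict(model$fit, data.frame(x,
                            check.names = FALSE))$predictions[, "1"],
    gradient_boosting = ,
    xgboost = predict(model$fit, xgboost::xgb.DMatrix(x)),
    adaboost = predict_adaboost(model$fit, x),
    mlp = as.numeric(predict(model$fit, x)),
    naive_bayes = predict_nb(model$fit, x),
    knn = predict_knn(model$fit, x),
    svm = predict_svm(model$fit, x))
  pmin(1, pmax(0, as.numeric(p)))
}

## -- family implementations -------------------------------------------

fit_logistic <- function(x, y, params) {
  lambda <- params$lambda %||% 1e-3
  glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                 alpha = 0, lambda = lambda, standardize = FALSE)
}

predict_logistic <- function(fit, x) {
  as.numeric(predict(fit, newx = x, type = "response"))
}

fit_tree <- function(x, y, params) {
  df <- data.frame(x, check.names = FALSE)
  df$.y <- factor(y, levels = c(0, 1))
  rpart::rpart(.y ~ ., data = df, method = "class",
               parms = list(split = params$criterion %||% "gini"),
               control = rpart::rpart.control(
                 cp = params$cp %||% 0.01,
                 maxdepth = params$maxdepth %||% 30L,
                 minsplit = params$minsplit %||% 20L))
}

fit_forest <- function(x, y, params, seed) {
  mtry_opt <- params$max_features %||% "sqrt"
  mtry <- if (identical(mtry_opt, "sqrt")) {
    max(1L, floor(sqrt(ncol(x))))
  } else if (identical(mtry_opt, "log2")) {
    max(1L, floor(log2(ncol(x))))
  } else {
    max(1L, min(ncol(x), as.integer(mtry_opt)))
  }
  ranger::ranger(x = data.frame(x, check.names = FALSE),
                 y = factor(y, levels = c(0, 1)),
                 probability = TRUE,
                 num.trees = params$n_estimators %||% 1000L,
                 mtry = mtry,
                 min.node.size = params$min_node_size %||% 1L,
                 max.depth = params$max_depth %||% 0L,
                 splitrule = params$criterion_rule %||% "gini",
                 seed = seed, num.threads = 1L)
}

fit_gbm <- function(x, y, params, regularized) {
  base <- if (regularized) {
    list(eta = params$eta %||% 0.3, lambda = 1, alpha = 0)
  } else {
    # classical gradient boosting: no shrinkage regularization terms
    list(eta = params$eta %||% 0.1, lambda = 0, alpha = 0)
  }
  xgboost::xgb.train(
    params = c(base, list(objective = "binary:logistic",
                          max_depth = params$max_depth %||% 3L,
                          subsample = params$subsample %||% 1,
                          nthread = 1L)),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = params$n_estimators %||% 100L, verbose = 0)
}

# Discrete AdaBoost (SAMME) over depth-limited rpart learners.
fit_adaboost <- function(x, y, params) {
  n_estimators <- params$n_estimators %||% 50L
  learn_rate <- params$learning_rate %||% 1
  maxdepth <- params$max_depth %||% 1L
  n <- nrow(x)
  w <- rep(1 / n, n)
  yf <- ifelse(y == 1, 1, -1)
  df <- data.frame(x, check.names = FALSE)
  df$.y <- factor(y, levels = c(0, 1))
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = -1, minsplit = 2L,
                          xval = 0L))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != yf])
    if (err <= 1e-10) {
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break
    a <- learn_rate * 0.5 * log((1 - err) / err)
    w <- w * exp(-a * yf * pred)
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, a)
  }
  if (!length(stumps))
    stop_ngsqc("adaboost found no better-than-chance weak learner")
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  f <- numeric(nrow(df))
  for (t in seq_along(fit$stumps)) {
    pred <- ifelse(predict(fit$stumps[[t]], df, type = "class") == "1", 1, -1)
    f <- f + fit$alphas[[t]] * pred
  }
  1 / (1 + exp(-2 * f / max(sum(fit$alphas), 1e-9)))
}

fit_mlp <- function(x, y, params) {
  nnet::nnet(x = x, y = y, size = params$hidden_size %||% 8L,
             decay = params$decay %||% 1e-3,
             maxit = params$maxit %||% 300L,
             entropy = TRUE, trace = FALSE, MaxNWts = 10000L)
}

fit_nb <- function(x, y, params) {
  keep <- apply(x, 2L, stats::sd) > 1e-12
  fit <- e1071::naiveBayes(x = data.frame(x[, keep, drop = FALSE],
                                          check.names = FALSE),
                           y = factor(y, levels = c(0, 1)))
  list(fit = fit, keep = keep)
}

predict_nb <- function(model, x) {
  p <- predict(model$fit, data.frame(x[, model$keep, drop = FALSE],
                                     check.names = FALSE), type = "raw")
  p[, "1"]
}

fit_knn <- function(x, y, params, seed = 1L) {
  list(train = x, y = factor(y, levels = c(0, 1)),
       k = params$k %||% 5L, seed = seed)
}

predict_knn <- function(fit, x) {
  with_seed(fit$seed, {
    pred <- class::knn(fit$train, x, fit$y, k = fit$k, prob = TRUE)
    pr <- attr(pred, "prob")
    ifelse(pred == "1", pr, 1 - pr)
  })
}

fit_svm <- function(x, y, params) {
  e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
             kernel = params$kernel %||% "radial",
             cost = params$cost %||% 1,
             gamma = params$gamma %||% (1 / ncol(x)),
             probability = TRUE)
}

predict_svm <- function(fit, x) {
  p <- predict(fit, x, probability = TRUE)
  attr(p, "probabilities")[, "1"]
}
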