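# Evaluation protocols.

test_that("within-experiment differences separate under strong signal", {
  tab <- simulate_feature_table(n_samples = 200, n_informative = 3,
                                n_noise = 5, effect_size = 2, seed = 7)
  spec <- model_spec("logistic_regression")
  res <- within_experiment_eval(tab$x, tab$y, tab$experiment, spec,
                                seed = 7)
  expect_true(all(res$per_experiment$delta > 0.3))
  expect_true(all(res$per_experiment$delta <= 1))
  # the evaluated experiment's files are never in the training set
  for (e in names(res$train_ids)) {
    held <- rownames(tab$x)[tab$experiment == e]
    expect_length(intersect(res$train_ids[[e]], held), 0L)
  }
})

test_that("within-experiment differences vanish under the null", {
  tab <- simulate_feature_table(n_samples = 200, n_informative = 0,
                                n_noise = 8, effect_size = 0, seed = 71)
  res <- within_experiment_eval(tab$x, tab$y, tab$experiment,
                                model_spec("logistic_regression"),
                                seed = 72)
  expect_lt(abs(mean(res$per_experiment$delta)), 0.12)
})

test_that("within-experiment input validation", {
  tab <- simulate_feature_table(n_samples = 40, seed = 73)
  expect_error(within_experiment_eval(tab$x, tab$y,
                                      rep("exp1", 40),
                                      model_spec("naive_bayes")),
               "at least two experiments")
  # two experiments but each single-label: no mixed experiment
  y <- rep(c(0, 1), each = 20)
  ex <- rep(c("a", "b"), each = 20)
  expect_error(within_experiment_eval(tab$x, y, ex,
                                      model_spec("naive_bayes")),
               "no experiment contains both")
})

test_that("cross-group evaluation is symmetric for identical populations", {
  t1 <- simulate_feature_table(n_samples = 100, n_informative = 2,
                               n_noise = 4, effect_size = 1.5, seed = 74)
  t2 <- simulate_feature_table(n_samples = 100, n_informative = 2,
                               n_noise = 4, effect_size = 1.5, seed = 75)
  res <- cross_species_eval(
    list(human = list(x = t1$x, y = t1$y),
         mouse = list(x = t2$x, y = t2$y)),
    grid = list(model_spec("logistic_regression")),
    outer_folds = 5, inner_folds = 5, seed = 76)
  for (grp in c("human", "mouse")) {
    w <- res$auroc[res$train_group == grp & res$eval_type == "within"]
    cr <- res$auroc[res$train_group == grp & res$eval_type == "cross"]
    expect_lt(abs(w - cr), 0.1)
  }
})

test_that("an inverted feature-label relation shows up as cross failure", {
  t1 <- simulate_feature_table(n_samples = 120, n_informative = 3,
                               n_noise = 3, effect_size = 2.5, seed = 77)
  t2 <- simulate_feature_table(n_samples = 120, n_informative = 3,
                               n_noise = 3, effect_size = 2.5, seed = 78)
  res <- cross_species_eval(
    list(a = list(x = t1$x, y = t1$y),
         b = list(x = t2$x, y = 1 - t2$y)),
    grid = list(model_spec("logistic_regression")),
    outer_folds = 5, inner_folds = 5, seed = 79)
  expect_gt(res$auroc[res$train_group == "a" &
                        res$eval_type == "within"], 0.9)
  expect_lt(res$auroc[res$train_group == "a" &
                        res$eval_type == "cross"], 0.5)

  single_class <- list(x = t1$x[t1$y == 1, ], y = t1$y[t1$y == 1])
  expect_error(cross_species_eval(
    list(a = list(x = t1$x, y = t1$y), b = single_class),
    grid = list(model_spec("naive_bayes"))), "both quality classes")
})

test_that("quality metric flags follow the recommended thresholds", {
  m <- c(median_base_quality = 20, uniquely_mapped_pct = 70, pbc_pct = 85,
         frip_pct = 0.5, union_dhs_overlap_pct = 75)
  expect_equal(cistrome_flags(m), c(bad = 2L, good = 3L))

  at_thresholds <- c(median_base_quality = 25, uniquely_mapped_pct = 60,
                     pbc_pct = 80, frip_pct = 1, union_dhs_overlap_pct = 70)
  expect_equal(cistrome_flags(at_thresholds)[["bad"]], 0L)

  four_good <- c(median_base_quality = 30, uniquely_mapped_pct = 80,
                 pbc_pct = 90, frip_pct = 5)
  expect_equal(cistrome_flags(four_good), c(bad = 0L, good = 4L))

  expect_error(cistrome_flags(c(other_metric = 5)), "no quality metrics")

  # monotone: decreasing any metric never decreases the bad count
  set.seed(80)
  for (i in 1:20) {
    v <- c(median_base_quality = runif(1, 10, 40),
           uniquely_mapped_pct = runif(1, 30, 95),
           pbc_pct = runif(1, 50, 99), frip_pct = runif(1, 0, 5),
           union_dhs_overlap_pct = runif(1, 40, 95))
    j <- sample(names(v), 1)
    v2 <- v; v2[j] <- v[j] - runif(1, 0, 20)
    expect_gte(cistrome_flags(v2)[["bad"]], cistrome_flags(v)[["bad"]])
    fl <- cistrome_flags(v)
    expect_equal(fl[["bad"]] + fl[["good"]], 5L)
  }
})

test_that("labels require more than 3 good flags for high quality", {
  base <- c(median_base_quality = 30, uniquely_mapped_pct = 80,
            pbc_pct = 90, frip_pct = 5, union_dhs_overlap_pct = 80)
  expect_equal(atac_label(base), "high")               # 5 good
  base["union_dhs_overlap_pct"] <- 60                  # 4 good
  expect_equal(atac_label(base), "high")
  base["pbc_pct"] <- 70                                # 3 good
  expect_equal(atac_label(base), "low")
  expect_error(atac_label(base[1:3]), "at least 4")
})

test_that("flag correlation behaves like Pearson r", {
  bad <- c(0, 1, 2, 3, 4, 5)
  expect_equal(flag_correlation(bad / 5, bad), 1)
  set.seed(81)
  p <- runif(200); b <- sample(0:5, 200, replace = TRUE)
  expect_lt(abs(flag_correlation(p, b)), 0.2)
  expect_error(flag_correlation(c(0.2, 0.4), c(1, 2)), "at least 3")
  expect_error(flag_correlation(rep(0.5, 5), 1:5), "constant")
})

test_that("the Dunn index matches its exhaustive oracle", {
  expect_equal(dunn_index(matrix(c(0, 1, 10, 11)), c("a", "a", "b", "b")),
               9)
  expect_equal(dunn_index(matrix(c(0, 1, 0, 1)), c("a", "a", "b", "b")), 0)
  expect_equal(dunn_index(matrix(c(0, 0, 5, 5)), c("a", "a", "b", "b")),
               Inf)
  for (s in 1:10) {
    set.seed(s)
    pts <- matrix(rnorm(24), ncol = 2)
    grp <- sample(c("a", "b", "c"), 12, replace = TRUE)
    if (length(unique(grp)) < 2) next
    expect_equal(dunn_index(pts, grp), oracle_dunn(pts, grp))
    expect_equal(dunn_index(pts * 3.7, grp), dunn_index(pts, grp))
  }
  expect_error(dunn_index(matrix(rnorm(10)), rep("a", 10)),
               "at least two groups")
})

make_expression <- function(n_per_group = 8, n_genes = 60, sep = 4,
                            noise_samples = 2, seed = 82) {
  set.seed(seed)
  n <- 2 * n_per_group
  base <- matrix(rexp(n_genes * n, 0.1), nrow = n_genes,
                 dimnames = list(paste0("gene", seq_len(n_genes)),
                                 paste0("s", seq_len(n))))
  grp <- rep(c("control", "disease"), each = n_per_group)
  base[seq_len(n_genes / 2), grp == "disease"] <-
    base[seq_len(n_genes / 2), grp == "disease"] * sep
  p_low <- runif(n, 0, 0.3)
  if (noise_samples > 0) {
    noisy <- c(seq_len(noise_samples),
               n_per_group + seq_len(noise_samples))
    for (j in noisy) base[, j] <- rexp(n_genes, 0.1) * 5
    p_low[noisy] <- runif(length(noisy), 0.8, 1)
  }
  list(x = base, groups = grp, p_low = p_low)
}

test_that("removing flagged outliers improves the Dunn index", {
  e <- make_expression()
  res <- outlier_removal_eval(e$x, e$groups, e$p_low, per_group = 2)
  expect_gt(res$delta_dunn, 0)
  expect_length(res$removed, 4L)

  clean <- make_expression(noise_samples = 0, seed = 83)
  res0 <- outlier_removal_eval(clean$x, clean$groups, clean$p_low,
                               per_group = 2)
  expect_lt(abs(res0$delta_dunn), 0.5)

  small <- make_expression(n_per_group = 2, noise_samples = 0, seed = 84)
  expect_error(outlier_removal_eval(small$x, small$groups, small$p_low,
                                    per_group = 2), "more than per_group")
})
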