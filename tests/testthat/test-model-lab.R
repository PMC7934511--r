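# Feature assembly, feature selection, grid search, final models.

test_that("feature rows have the documented cardinalities", {
  fq <- simulate_fastq(degradation_profile(), n_reads = 2000, seed = 50)
  raw <- raw_features(fq)

  row_raw <- assemble_features(raw = raw, subset = "RAW")
  expect_length(row_raw, 33L)
  # one-hot groups sum to 1 per module
  groups <- matrix(row_raw, ncol = 3L, byrow = TRUE)
  expect_true(all(rowSums(groups) == 1))

  g <- make_genome(seed = 51, n_genes = 4, chrom_length = 1.2e5)
  aln <- simulate_alignments(g, mapping_profile(), n_reads = 800, seed = 52)
  map <- parse_alignment_log(aln$log)
  m <- parse_gtf(g$gtf)
  a <- sample_alignments(aln$sam, n = 500, seed = 53)
  loc <- loc_features(a, build_region_index(m))
  tss <- tss_features(a, tss_list(m))

  row_all <- assemble_features(raw = raw, map = map, loc = loc, tss = tss)
  fs <- attr(row_all, "feature_set")
  expect_equal(sum(fs == "RAW"), 33L)
  expect_equal(sum(fs == "MAP"), 5L)  # 4 single-end percentages + layout
  expect_equal(sum(fs == "LOC"), 9L)
  expect_equal(sum(fs == "TSS"), 10L)
  expect_length(row_all, 33L + 4L + 9L + 10L + 1L)

  expect_error(assemble_features(raw = raw, subset = "LOC"), "absent")
  expect_error(assemble_features(raw = raw, subset = "BOGUS"), "unknown")
})

test_that("rows from both layouts align into one masked schema", {
  g <- make_genome(seed = 54, n_genes = 3, chrom_length = 1.2e5)
  aln_s <- simulate_alignments(g, mapping_profile(), n_reads = 400,
                               seed = 55, layout = "single")
  aln_p <- simulate_alignments(g, mapping_profile(), n_reads = 400,
                               seed = 56, layout = "paired")
  r1 <- assemble_features(map = parse_alignment_log(aln_s$log),
                          subset = "MAP")
  r2 <- assemble_features(map = parse_alignment_log(aln_p$log),
                          subset = "MAP")
  m <- bind_feature_rows(list(r1, r2), sample_ids = c("se", "pe"))
  expect_equal(ncol(m), 4L + 8L + 1L)
  expect_false(anyNA(m))
  expect_equal(unname(m[, "MAP_is_paired"]), c(0, 1))
  # the absent layout's columns are zero-filled
  expect_true(all(m["se", grepl("_paired$", colnames(m))] == 0))
})

test_that("selection keeps the ceiling rule and finds signal", {
  x <- matrix(runif(40 * 8), nrow = 40,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(0:1, 20)
  sel <- select_features(x, y, method = "chi2", k_fraction = 0.25)
  expect_length(sel$selected, 2L)
  expect_identical(select_features(x, y, method = "none")$x, x)
  expect_identical(
    select_features(x, y, method = "chi2", k_fraction = 1)$selected,
    colnames(x))

  neg <- x; neg[1, 1] <- -1
  expect_error(select_features(neg, y, method = "chi2", k_fraction = 0.5),
               "non-negative")

  # one informative column among 39 noise columns survives chi2 at k=25%
  hits <- 0L
  for (s in 1:20) {
    tab <- simulate_feature_table(n_samples = 80, n_informative = 1,
                                  n_noise = 39, effect_size = 2, seed = s)
    sel <- select_features(tab$x, tab$y, method = "chi2",
                           k_fraction = 0.25)
    hits <- hits + ("informative_1" %in% sel$selected)
  }
  expect_gte(hits, 19L)
})

test_that("rfe and stability selection recover the informative block", {
  tab <- simulate_feature_table(n_samples = 120, n_informative = 2,
                                n_noise = 10, effect_size = 2, seed = 60)
  for (method in c("rfe", "stability")) {
    sel <- select_features(tab$x, tab$y, method = method,
                           k_fraction = 0.25, seed = 61)
    expect_length(sel$selected, 3L)
    expect_true(all(c("informative_1", "informative_2") %in% sel$selected),
                label = method)
  }
  # deterministic under a fixed seed
  s1 <- select_features(tab$x, tab$y, "stability", 0.5, seed = 3)
  s2 <- select_features(tab$x, tab$y, "stability", 0.5, seed = 3)
  expect_identical(s1$selected, s2$selected)
})

small_grid <- function() {
  list(model_spec("logistic_regression"),
       model_spec("random_forest", params = list(n_estimators = 300)),
       model_spec("naive_bayes"))
}

test_that("grid search separates separable tables and ranks deterministically", {
  tab <- simulate_feature_table(n_samples = 100, n_informative = 4,
                                n_noise = 4, effect_size = 3, seed = 62)
  gs <- grid_search(tab$x, tab$y, grid = small_grid(), folds = 10, seed = 5)
  expect_gte(gs$table$auroc[1], 0.99)
  expect_equal(nrow(gs$table), 3L)
  gs2 <- grid_search(tab$x, tab$y, grid = small_grid(), folds = 10, seed = 5)
  expect_identical(gs$table, gs2$table)
  expect_error(grid_search(tab$x[1:12, ], tab$y[1:12],
                           grid = small_grid(), folds = 10),
               "fewer members")
})

test_that("stratified folds keep class ratios within one sample", {
  y <- rep(c(0, 1), c(37, 23))
  fold <- stratified_folds(y, folds = 10, seed = 8)
  for (f in 1:10) {
    n1 <- sum(y[fold == f] == 1)
    expect_true(abs(n1 - 2.3) <= 1)
  }
})

test_that("selection inside folds prevents leakage from noise columns", {
  set.seed(63)
  n <- 100
  x <- matrix(runif(n * 1000), nrow = n,
              dimnames = list(NULL, paste0("noise", 1:1000)))
  y <- rep(0:1, n / 2)
  gs <- grid_search(x, y,
                    grid = list(model_spec("logistic_regression",
                                           selection = "chi2",
                                           k_fraction = 0.25)),
                    folds = 5, seed = 64)
  expect_lte(gs$table$auroc[1], 0.65)
})

test_that("tuned models beat the one-feature baseline on synthetic tables", {
  tab <- simulate_feature_table(n_samples = 150, n_informative = 3,
                                n_noise = 7, effect_size = 1.5, seed = 65)
  best_single <- max(vapply(seq_len(ncol(tab$x)), function(j)
    one_feature_auroc(tab$x[, j], tab$y)$auroc, 0))
  gs <- grid_search(tab$x, tab$y, grid = small_grid(), folds = 10,
                    seed = 66)
  expect_gte(gs$table$auroc[1], best_single - 0.05)
})

test_that("final models are reproducible, serializable and schema-checked", {
  tab <- simulate_feature_table(n_samples = 80, n_informative = 2,
                                n_noise = 4, effect_size = 2, seed = 67)
  spec <- model_spec("random_forest", params = list(n_estimators = 200))
  m1 <- train_final(tab$x, tab$y, spec, seed = 9)
  m2 <- train_final(tab$x, tab$y, spec, seed = 9)
  p1 <- predict(m1, tab$x); p2 <- predict(m2, tab$x)
  expect_identical(p1$P_low, p2$P_low)
  expect_true(all(p1$P_low >= 0 & p1$P_low <= 1))

  f <- tempfile(fileext = ".rds")
  save_model(m1, f)
  expect_true(file.exists(paste0(f, ".json")))
  m3 <- load_model(f)
  expect_identical(predict(m3, tab$x)$P_low, p1$P_low)

  # clearly low-quality row scores above 0.5
  low_row <- tab$x[which(tab$y == 1)[1], , drop = FALSE]
  expect_gt(predict(m1, low_row)$P_low, 0.5)

  # identical rows give identical predictions
  two <- tab$x[c(1, 1), ]
  expect_equal(predict(m1, two)$P_low[1], predict(m1, two)$P_low[2])

  bad <- tab$x[, -1, drop = FALSE]
  expect_error(predict(m1, bad), "schema mismatch")
  expect_error(model_spec("quantum_forest"), "unknown algorithm")
  expect_error(train_final(tab$x, tab$y, structure(list(), class = "list")),
               "qc_model_spec")
})

test_that("the canonical reference configuration is in the default grid", {
  grid <- qc_default_grid()
  labels <- vapply(grid, function(s)
    paste(s$algorithm, s$params$n_estimators %||% "",
          s$params$max_features %||% "", s$selection, s$k_fraction), "")
  expect_true(any(labels == "random_forest 1000 sqrt none 1"))
  expect_gt(length(grid), 50L)
  # families cover the registry minus the excluded regularized booster
  expect_setequal(unique(vapply(grid, `[[`, "", "algorithm")),
                  setdiff(qc_algorithms(), "xgboost"))
})
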