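test_that("AUROC follows the rank/pair formulation", {
  expect_equal(auroc(c(10, 9, 2, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
  expect_error(auroc(1:3, c(0, 1)), "lengths differ")
})

test_that("AUROC agrees exactly with pair counting and is antisymmetric", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    scores <- sample(1:40, n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(auroc(scores, labels), auroc_pairs(scores, labels))
    expect_equal(auroc(scores, labels), 1 - auroc(-scores, labels))
  }
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("stratified folds partition subjects with both classes per fold", {
  y <- rep(c("HC", "PD"), c(23, 17))
  for (r in 1:4) {
    fold <- pdspeech:::make_stratified_folds(y, 5, r)
    expect_equal(sort(unique(fold)), 1:5)
    expect_equal(length(fold), 40)
    for (f in 1:5) {
      expect_true(all(table(y[fold == f]) >= 1))
    }
    # every subject in exactly one fold
    expect_equal(sum(table(fold)), 40)
  }
  expect_error(pdspeech:::make_stratified_folds(rep(c("HC", "PD"), c(3, 37)), 5, 1),
               "per class")
})

test_that("cross-validated classification is deterministic and calibrated", {
  tbl <- small_cohort_table(seed = 3, n = 15, D = 32, planted = 1:8, effect = 3)
  ev1 <- cv_classify(tbl, "random_forest", folds = 5, repeats = 2, seed = 9)
  ev2 <- cv_classify(tbl, "random_forest", folds = 5, repeats = 2, seed = 9)
  expect_identical(ev1$fold_auroc, ev2$fold_auroc)
  expect_gte(ev1$mean_auroc, 0.95)
  expect_equal(sum(ev1$confusion), nrow(tbl))

  # permuted labels give chance-level performance on average
  noise <- make_noise_table(n = 40, p = 10, seed = 1)
  aucs <- sapply(1:20, function(s) {
    shuffled <- noise
    shuffled$class <- pdspeech:::with_seed(s, sample(noise$class))
    cv_classify(shuffled, "logistic", folds = 5, repeats = 1,
                seed = s)$mean_auroc
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("all three classifier backends run and separate a planted effect", {
  tbl <- small_cohort_table(seed = 5, n = 20, D = 24, planted = 1:6, effect = 4)
  for (m in c("random_forest", "gradient_boosting", "logistic")) {
    ev <- cv_classify(tbl, m, folds = 5, repeats = 1, seed = 2)
    expect_gt(ev$mean_auroc, 0.85)
  }
})

test_that("label permutation null of the AUROC statistic is centred", {
  set.seed(31)
  scores <- rnorm(44)
  labels <- rep(c(0, 1), 22)
  nulls <- sapply(1:100, function(i) auroc(scores, sample(labels)))
  expect_lt(abs(mean(nulls) - 0.5), 0.05)
})

test_that("cross-corpus evaluation transfers iff planted channels are shared", {
  shared <- 1:10
  a <- small_cohort_table(seed = 11, n = 15, D = 64, planted = shared,
                          effect = 3, name = "corpusA")
  b <- small_cohort_table(seed = 12, n = 15, D = 64, planted = shared,
                          effect = 3, name = "corpusB")
  c_ <- small_cohort_table(seed = 13, n = 15, D = 64, planted = 21:30,
                           effect = 3, name = "corpusC")
  expect_gte(crossdb_classify(a, b, "logistic", seed = 1)$mean_auroc, 0.9)
  # a random forest leans on the planted channels only, so a cohort whose
  # signal lives elsewhere is classified at chance
  no_transfer <- crossdb_classify(a, c_, "random_forest", seed = 1)$mean_auroc
  expect_gte(no_transfer, 0.3)
  expect_lte(no_transfer, 0.7)

  expect_error(crossdb_classify(a, a, "logistic"), "unseen")
  dup <- b
  dup$subject_id <- a$subject_id
  expect_error(crossdb_classify(a, dup, "logistic"), "share subject ids")
  small <- drop_half_features(b)
  expect_error(crossdb_classify(small, a, "logistic"), "identical across tables")
})

test_that("the scenario grid enumerates 15 rows in four families", {
  g <- scenario_grid(c("pa", "italian", "english"))
  expect_equal(nrow(g), 15)
  expect_equal(as.integer(table(g$scenario)), c(3L, 3L, 6L, 3L))
  # cross rows never leak the test dataset into training
  cross <- g[g$protocol == "cross", ]
  for (i in seq_len(nrow(cross))) {
    expect_false(cross$test[i] %in% strsplit(cross$train[i], ",")[[1]])
  }
  # intra and mixed rows evaluate what they train on
  cv <- g[g$protocol == "cv", ]
  expect_true(all(cv$train == cv$test))
})

test_that("regression metrics match their definitions", {
  expect_equal(unname(metric_suite(1:5, 1:5)), c(1, 1, 0))
  y <- c(2, 4, 6, 8)
  expect_warning(m <- metric_suite(y, rep(mean(y), 4)), "constant")
  expect_true(is.na(m["rho"]))
  expect_equal(unname(m["r2"]), 0)
  expect_equal(unname(m["mae"]), mean(abs(y - mean(y))))
  expect_equal(unname(metric_suite(c(0, 1, 2), c(0, 1, 4))["mae"]), 2 / 3)
  expect_equal(unname(metric_suite(c(1, 2, 3), c(3, 1, 2))["rho"]), -0.5)
  expect_error(metric_suite(1:3, 1:4), "length mismatch")
  expect_error(metric_suite(1:2, 1:2), "at least 3")
})

test_that("lasso regression recovers a planted linear target", {
  spec <- cohort_spec("reg", c(HC = 20, PD = 20), n_channels = 64,
                      frames_per_subject = c(20, 30),
                      planted_targets = list(
                        y = list(channels = 1:5, weights = rep(2, 5),
                                 intercept = 10, noise_sd = 0.3)),
                      seed = 8)
  tbl <- pooled_feature_table(generate_embedding_cohort(spec))
  res <- cv_regress(tbl, "y", seed = 4)
  expect_gte(res$means[["rho"]], 0.9)
  res2 <- cv_regress(tbl, "y", seed = 4)
  expect_identical(res$per_fold, res2$per_fold)

  # a target unrelated to the features has no out-of-sample signal
  r2s <- sapply(1:20, function(s) {
    tbl$noise_target <- pdspeech:::with_seed(1000 + s, rnorm(nrow(tbl)))
    cv_regress(tbl, "noise_target", seed = s)$means[["r2"]]
  })
  expect_lte(mean(r2s), 0.1)

  tbl$const <- 5
  expect_error(cv_regress(tbl, "const"), "constant target")
  expect_error(cv_regress(tbl, "absent"), "not found")
})
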