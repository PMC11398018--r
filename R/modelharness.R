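#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' scores above a random negative, counting ties as one half. Equivalent
#' to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels 0/1, logical, or factor with the positive class last
#'   (e.g. HC/PD with PD positive).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop2("scores and labels lengths differ")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop2("both classes must be present to compute AUROC")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.character(labels)
    lev <- sort(unique(labels))
    if (all(lev %in% c("HC", "PD"))) {
      as.integer(labels == "PD")
    } else {
      if (length(lev) > 2L) stop2("labels must be binary")
      as.integer(labels == lev[length(lev)])
    }
  } else {
    as.integer(as.logical(labels))
  }
}

# Empirical ROC curve points (FPR, TPR) at every distinct threshold.
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(1 - y) / sum(1 - y))
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(fpr = fpr[c(TRUE, keep)], tpr = tpr[c(TRUE, keep)])
}

confusion_at <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  pred <- as.integer(scores > threshold)
  c(tn = sum(pred == 0 & y == 0), fp = sum(pred == 1 & y == 0),
    fn = sum(pred == 0 & y == 1), tp = sum(pred == 1 & y == 1))
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin, so every fold holds both classes whenever each class
# has at least `folds` members.
make_stratified_folds <- function(y, folds, seed) {
  y <- as_binary_labels(y)
  if (min(table(y)) < folds) {
    stop2("need at least ", folds, " subjects per class for ", folds,
          "-fold stratified CV")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

make_plain_folds <- function(n, folds, seed) {
  with_seed(seed, {
    fold <- integer(n)
    fold[sample(n)] <- rep_len(seq_len(folds), n)
    fold
  })
}

# One classifier behind a common fit/score interface. Linear models get
# train-fold standardization; the tree ensembles are scale-invariant.
fit_classifier <- function(model, x, y, seed) {
  y <- as_binary_labels(y)
  switch(model,
    random_forest = {
      fit <- with_seed(seed, randomForest::randomForest(
        x, factor(y, levels = c(0, 1)), ntree = 100))
      list(fit = fit,
           score = function(newx) unname(stats::predict(fit, newx,
                                                        type = "prob")[, "1"]))
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      fit <- with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eval_metric = "logloss",
                      nthread = 1),
        data = dtrain, nrounds = 100, verbose = 0))
      list(fit = fit,
           score = function(newx) {
             stats::predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1))
           })
    },
    logistic = {
      std <- standardize_fit(x)
      fit <- glmnet::glmnet(std$x, y, family = "binomial", alpha = 0,
                            lambda = 0.01, standardize = FALSE)
      list(fit = fit,
           score = function(newx) {
             as.numeric(stats::predict(fit, standardize_apply(newx, std),
                                       type = "response"))
           })
    },
    stop2("unknown model '", model, "'")
  )
}

new_eval_result <- function(scenario, train, test, feature_set, model,
                            fold_auroc, scores, labels) {
  structure(list(
    scenario = scenario, train = train, test = test,
    feature_set = feature_set, model = model,
    fold_auroc = fold_auroc,
    mean_auroc = mean(fold_auroc),
    roc = roc_points(scores, labels),
    confusion = confusion_at(scores, labels),
    scores = scores, labels = as_binary_labels(labels)
  ), class = "pd_eval")
}

#' @export
print.pd_eval <- function(x, ...) {
  cat(sprintf("<pd_eval %s: train=%s test=%s model=%s features=%s>\n",
              x$scenario, x$train, x$test, x$model, x$feature_set))
  cat(sprintf("  mean AUROC = %.3f over %d fold-fits\n",
              x$mean_auroc, length(x$fold_auroc)))
  invisible(x)
}

#' @export
plot.pd_eval <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s -> %s (AUROC %.2f)", x$train, x$test,
                                x$mean_auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Repeated stratified cross-validated classification
#'
#' Evaluates a binary HC-vs-PD classifier with k-fold stratified
#' cross-validation repeated several times. All scores are out-of-fold;
#' AUROC is computed per fold and per repeat and averaged. Deterministic
#' for a given seed (per-repeat and per-fit seeds are derived from it).
#'
#' @param table A [feature_table()] with a binary `class` column.
#' @param model `"random_forest"` (100 trees, Gini), `"gradient_boosting"`
#'   (binary logistic objective) or `"logistic"` (ridge-stabilised
#'   logistic regression on standardized features).
#' @param folds,repeats CV geometry (default 5 x 5).
#' @param seed Master seed.
#' @return A `pd_eval` object; `mean_auroc` aggregates all fold-repeat
#'   AUROCs, `roc`/`confusion` summarise the first repeat's out-of-fold
#'   scores at threshold 0.5.
#' @export
cv_classify <- function(table, model = c("random_forest", "gradient_boosting",
                                         "logistic"),
                        folds = 5, repeats = 5, seed = 1) {
  model <- match.arg(model)
  x <- feature_matrix(table)
  y <- as_binary_labels(table$class)
  fold_auroc <- matrix(NA_real_, repeats, folds)
  oof_first <- numeric(length(y))
  for (r in seq_len(repeats)) {
    fold <- make_stratified_folds(y, folds, derive_seed(seed, r))
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- fit_classifier(model, x[tr, , drop = FALSE], y[tr],
                            derive_seed(seed, r * 100 + f))
      sc <- fit$score(x[!tr, , drop = FALSE])
      fold_auroc[r, f] <- auroc(sc, y[!tr])
      if (r == 1L) oof_first[!tr] <- sc
    }
  }
  ds <- unique(as.character(table$dataset))
  new_eval_result("intra", paste(ds, collapse = "+"),
                  paste(ds, collapse = "+"),
                  feature_set_name(table), model,
                  fold_auroc, oof_first, y)
}

feature_set_name <- function(table) {
  f <- feature_names(table)
  # common prefix of feature names, e.g. "emb_mean"
  sub("_[0-9]+$", "", f[1])
}

#' Cross-corpus classification
#'
#' Fits the model once on the concatenated rows of the training tables and
#' scores every row of the held-out table — the external-validation
#' protocol for cross-database rows (no cross-validation).
#'
#' @param train_tables A [feature_table()] or list of them (identical
#'   feature columns).
#' @param test_table A [feature_table()] from a dataset absent from the
#'   training tables; overlapping subject ids are an error.
#' @param model As in [cv_classify()].
#' @param seed Seed for the single fit.
#' @return A `pd_eval` with a single AUROC.
#' @export
crossdb_classify <- function(train_tables, test_table,
                             model = c("random_forest", "gradient_boosting",
                                       "logistic"),
                             seed = 1) {
  model <- match.arg(model)
  if (inherits(train_tables, "feature_table")) train_tables <- list(train_tables)
  feats <- feature_names(test_table)
  for (tt in train_tables) {
    if (!identical(feature_names(tt), feats)) {
      stop2("feature columns must be identical across tables")
    }
  }
  train_ds <- unique(unlist(lapply(train_tables, function(t) as.character(t$dataset))))
  test_ds <- unique(as.character(test_table$dataset))
  if (any(test_ds %in% train_ds)) {
    stop2("test dataset must be unseen (it appears among the training datasets)")
  }
  train_ids <- unlist(lapply(train_tables, function(t) as.character(t$subject_id)))
  if (any(as.character(test_table$subject_id) %in% train_ids)) {
    stop2("train and test tables share subject ids")
  }
  x_tr <- do.call(rbind, lapply(train_tables, feature_matrix))
  y_tr <- unlist(lapply(train_tables, function(t) as_binary_labels(t$class)))
  fit <- fit_classifier(model, x_tr, y_tr, derive_seed(seed, 1))
  sc <- fit$score(feature_matrix(test_table))
  y_te <- as_binary_labels(test_table$class)
  new_eval_result("cross", paste(train_ds, collapse = "+"),
                  paste(test_ds, collapse = "+"),
                  feature_set_name(test_table), model,
                  matrix(auroc(sc, y_te), 1, 1), sc, y_te)
}

#' Scenario grid for three datasets
#'
#' Enumerates the 15 train/test rows of the four scenario families:
#' 3 intra-dataset rows (CV on one dataset), 3 mixed rows (CV on a pooled
#' pair), 6 single-dataset cross rows (train on one, test on another) and
#' 3 pair-cross rows (train on a pooled pair, test on the remaining one).
#'
#' @param datasets Character vector of three dataset names.
#' @return A data.frame with columns `scenario` (1-4), `train`, `test`
#'   (comma-separated dataset names) and `protocol` (`"cv"` or `"cross"`).
#' @export
scenario_grid <- function(datasets = c("pa", "italian", "english")) {
  stopifnot(length(datasets) == 3L)
  d <- datasets
  pairs <- list(c(d[2], d[3]), c(d[2], d[1]), c(d[3], d[1]))
  rows <- list()
  for (x in d) rows[[length(rows) + 1L]] <- list(1L, x, x, "cv")
  for (p in pairs) {
    nm <- paste(p, collapse = ",")
    rows[[length(rows) + 1L]] <- list(2L, nm, nm, "cv")
  }
  for (x in d) for (y in setdiff(d, x)) {
    rows[[length(rows) + 1L]] <- list(3L, x, y, "cross")
  }
  for (x in d) {
    tr <- setdiff(d, x)
    rows[[length(rows) + 1L]] <- list(4L, paste(tr, collapse = ","), x, "cross")
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(scenario = r[[1]], train = r[[2]], test = r[[3]],
               protocol = r[[4]], stringsAsFactors = FALSE)
  }))
  out
}

# Pool feature tables row-wise (identical feature columns assumed/checked).
rbind_tables <- function(tables) {
  feats <- feature_names(tables[[1]])
  for (t in tables) {
    if (!identical(feature_names(t), feats)) {
      stop2("feature columns must be identical across tables")
    }
  }
  cols <- Reduce(intersect, lapply(tables, names))
  out <- do.call(rbind, lapply(tables, function(t) t[, cols, drop = FALSE]))
  class(out) <- c("feature_table", "data.frame")
  attr(out, "features") <- feats
  out
}

#' Evaluate the full scenario grid
#'
#' Runs every row of [scenario_grid()] over a named list of per-dataset
#' feature tables: CV rows via [cv_classify()], cross rows via
#' [crossdb_classify()].
#'
#' @param tables Named list of three [feature_table()]s (names are the
#'   dataset labels).
#' @param model,folds,repeats,seed As in [cv_classify()].
#' @return A tidy data.frame: one row per scenario with columns
#'   `scenario`, `train`, `test`, `feature_set`, `model`, `auroc`.
#' @export
evaluate_scenarios <- function(tables, model = "random_forest",
                               folds = 5, repeats = 5, seed = 1) {
  grid <- scenario_grid(names(tables))
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tr_names <- strsplit(g$train, ",")[[1]]
    if (g$protocol == "cv") {
      tbl <- if (length(tr_names) == 1L) tables[[tr_names]] else
        rbind_tables(tables[tr_names])
      ev <- cv_classify(tbl, model, folds, repeats, derive_seed(seed, i))
    } else {
      ev <- crossdb_classify(tables[tr_names], tables[[g$test]], model,
                             derive_seed(seed, i))
    }
    res[[i]] <- data.frame(scenario = g$scenario, train = g$train,
                           test = g$test, feature_set = ev$feature_set,
                           model = model, auroc = ev$mean_auroc,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Regression metric suite
#'
#' Spearman correlation, coefficient of determination
#' (`1 - SSE/SST`) and mean absolute error. A constant prediction vector
#' has no defined rank correlation; `rho` is then `NA` with a warning.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 3.
#' @return Named numeric vector `c(rho, r2, mae)`.
#' @export
metric_suite <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop2("length mismatch")
  if (length(y_true) < 3L) stop2("need at least 3 observations")
  rho <- if (stats::sd(y_pred) == 0 || stats::sd(y_true) == 0) {
    warning("constant vector: Spearman rho undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(y_true, y_pred, method = "spearman")
  }
  sse <- sum((y_true - y_pred)^2)
  sst <- sum((y_true - mean(y_true))^2)
  c(rho = rho, r2 = 1 - sse / sst, mae = mean(abs(y_true - y_pred)))
}

#' Cross-validated lasso regression
#'
#' Fits the lasso (L1 penalty 0.01 on standardized features) to a
#' quantitative target with k-fold cross-validation and reports Spearman
#' rho, r-squared and MAE per fold plus their means. Folds are
#' unstratified; standardization statistics come from the training folds
#' only.
#'
#' @param table A [feature_table()] containing the target column.
#' @param target Target column name (e.g. `"age"`, `"chps"`, `"lrd"`).
#' @param lambda L1 penalty (default 0.01).
#' @param folds Number of folds (default 5).
#' @param seed Master seed.
#' @return A `pd_reg` object with per-fold metrics, their means, and the
#'   out-of-fold predictions.
#' @export
cv_regress <- function(table, target, lambda = 0.01, folds = 5, seed = 1) {
  if (!target %in% names(table)) stop2("target column '", target, "' not found")
  y <- table[[target]]
  if (!is.numeric(y)) stop2("target must be numeric")
  if (stats::sd(y) == 0) stop2("constant target: Spearman rho undefined")
  x <- feature_matrix(table)
  fold <- make_plain_folds(length(y), folds, derive_seed(seed, 1))
  per_fold <- matrix(NA_real_, folds, 3,
                     dimnames = list(NULL, c("rho", "r2", "mae")))
  oof <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    std <- standardize_fit(x[tr, , drop = FALSE])
    fit <- glmnet::glmnet(std$x, y[tr], family = "gaussian", alpha = 1,
                          lambda = lambda, standardize = FALSE)
    pred <- as.numeric(stats::predict(fit, standardize_apply(x[!tr, , drop = FALSE], std)))
    oof[!tr] <- pred
    per_fold[f, ] <- suppressWarnings(metric_suite(y[!tr], pred))
  }
  structure(list(target = target, per_fold = as.data.frame(per_fold),
                 means = colMeans(per_fold, na.rm = TRUE),
                 predictions = oof, truth = y, lambda = lambda),
            class = "pd_reg")
}

#' @export
print.pd_reg <- function(x, ...) {
  cat(sprintf("<pd_reg target=%s lasso(lambda=%g)>\n", x$target, x$lambda))
  cat(sprintf("  mean rho = %.3f, r2 = %.3f, MAE = %.3f over %d folds\n",
              x$means["rho"], x$means["r2"], x$means["mae"],
              nrow(x$per_fold)))
  invisible(x)
}

#' @export
plot.pd_reg <- function(x, ...) {
  graphics::plot(x$truth, x$predictions, xlab = paste("observed", x$target),
                 ylab = "out-of-fold prediction",
                 main = sprintf("%s (rho=%.2f)", x$target, x$means["rho"]), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
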