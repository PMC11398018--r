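#' Importance rankings
#'
#' An `importance_ranking` is a data.frame with one row per feature:
#' `index` (1-based feature id), `feature` (name), `score` (importance
#' magnitude, finite) and `rank` (1 = most important). Ties are broken
#' deterministically by (score descending, index ascending). Attributes
#' record the scoring `method`, the `task` and the fitted `model` tag.
#'
#' @name importance_ranking
NULL

new_ranking <- function(scores, features, method, task, model = method,
                        extra = list()) {
  if (any(!is.finite(scores))) stop2("importance scores must be finite")
  p <- length(scores)
  if (is.null(features)) features <- sprintf("f%03d", seq_len(p))
  ord <- order(-scores, seq_len(p))
  rk <- integer(p)
  rk[ord] <- seq_len(p)
  out <- data.frame(index = seq_len(p), feature = features,
                    score = as.numeric(scores), rank = rk,
                    stringsAsFactors = FALSE)
  class(out) <- c("importance_ranking", "data.frame")
  attr(out, "method") <- method
  attr(out, "task") <- task
  attr(out, "model") <- model
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
print.importance_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<importance_ranking: %d features, method=%s, task=%s>\n",
              nrow(x), attr(x, "method"), attr(x, "task")))
  top <- x[order(x$rank), ][seq_len(min(n, nrow(x))), ]
  print.data.frame(top, row.names = FALSE)
  invisible(x)
}

#' Linear-coefficient importance from standardized logistic regression
#'
#' Fits a logistic model on standardized features and scores each feature
#' by the absolute value of its coefficient. The feature matrix must
#' already be standardized (mean 0, unit variance) so coefficients are
#' comparable; unstandardized input is an error.
#'
#' When the unpenalized fit is unavailable (more features than subjects,
#' collinear or duplicated columns, or complete separation) a small ridge
#' penalty is applied instead, with a note; this keeps every coefficient
#' finite and the ranking deterministic.
#'
#' @param x Standardized numeric feature matrix (subjects x features).
#' @param labels Binary class labels (HC/PD, 0/1 or logical).
#' @param lambda Ridge penalty used when regularization is needed
#'   (default 0.01).
#' @param task Task tag stored on the ranking.
#' @return An [importance_ranking].
#' @export
rank_linear <- function(x, labels, lambda = 0.01, task = "classification") {
  x <- as.matrix(x)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop2("both classes must be present")
  mu <- colMeans(x)
  sg <- apply(x, 2, stats::sd)
  if (max(abs(mu)) > 1e-6 || max(abs(sg - 1)) > 1e-4) {
    stop2("features must be standardized (mean 0, sd 1) before rank_linear")
  }
  coefs <- NULL
  if (ncol(x) < nrow(x)) {
    fit <- withCallingHandlers(
      stats::glm.fit(cbind(1, x), y, family = stats::binomial()),
      warning = function(w) invokeRestart("muffleWarning")
    )
    cf <- fit$coefficients[-1]
    if (all(is.finite(cf)) && fit$converged && max(abs(cf)) < 1e3) coefs <- cf
  }
  if (is.null(coefs)) {
    message("rank_linear: applying ridge regularization (lambda = ", lambda,
            ") to obtain finite coefficients")
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    coefs <- as.numeric(fit$beta)
  }
  new_ranking(abs(coefs), colnames(x), "linear_coef", task, "logistic")
}

#' Monte-Carlo Shapley attribution
#'
#' Approximates per-instance Shapley values of a prediction function by
#' permutation sampling: for each instance, `samples_per_feature` random
#' feature orderings are drawn; along each ordering the instance's
#' features replace a random background row's features one at a time, and
#' a feature's marginal contribution is the change in prediction when it
#' is switched in. Attributions are averaged over orderings; within one
#' ordering the marginals telescope, so per-instance attributions sum
#' exactly to the prediction minus the mean prediction over the sampled
#' background rows (Shapley efficiency).
#'
#' The global score of a feature is the mean absolute attribution over all
#' instances.
#'
#' @param predict_fn Function mapping a numeric matrix of rows to a
#'   numeric prediction vector.
#' @param x Instance matrix (rows to explain).
#' @param background Background matrix (default `x`) supplying reference
#'   rows.
#' @param samples_per_feature Number of sampled orderings per instance
#'   (>= 1).
#' @param seed Seed; the attribution is deterministic given it.
#' @param task Task tag stored on the ranking.
#' @return An [importance_ranking] with attributes `attributions` (an
#'   instances x features matrix), `mc_baseline` (per-instance mean
#'   prediction over the sampled background rows) and `baseline` (mean
#'   prediction over the full background).
#' @export
shapley_mc <- function(predict_fn, x, background = x,
                       samples_per_feature = 32, seed = 1,
                       task = "regression") {
  x <- as.matrix(x)
  background <- as.matrix(background)
  if (samples_per_feature < 1L) stop2("samples_per_feature must be >= 1")
  n <- nrow(x)
  p <- ncol(x)
  n_perm <- as.integer(samples_per_feature)
  phi <- matrix(0, n, p)
  mc_base <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      acc <- numeric(p)
      base_i <- 0
      for (k in seq_len(n_perm)) {
        perm <- sample.int(p)
        z <- background[sample.int(nrow(background), 1L), ]
        # chain of p+1 states: background row morphing into instance i
        states <- matrix(z, p + 1L, p, byrow = TRUE)
        for (j in seq_len(p)) {
          states[(j + 1L):(p + 1L), perm[j]] <- x[i, perm[j]]
        }
        v <- predict_fn(states)
        acc[perm] <- acc[perm] + diff(v)
        base_i <- base_i + v[1L]
      }
      phi[i, ] <- acc / n_perm
      mc_base[i] <- base_i / n_perm
    }
  })
  colnames(phi) <- colnames(x)
  new_ranking(colMeans(abs(phi)), colnames(x), "shapley_mc", task,
              "predict_fn",
              extra = list(attributions = phi, mc_baseline = mc_base,
                           baseline = mean(predict_fn(background))))
}

#' Impurity-based random-forest importance
#'
#' Mean decrease in Gini impurity (classification) or node purity
#' (regression) from a 100-tree random forest, as a third global
#' importance method for the repeated-overlap stability experiments.
#'
#' @param x Feature matrix.
#' @param y Class labels (factor/binary) or numeric target.
#' @param seed Seed controlling the forest.
#' @param ntree Trees (default 100).
#' @return An [importance_ranking].
#' @export
rank_impurity <- function(x, y, seed = 1, ntree = 100) {
  x <- as.matrix(x)
  is_class <- !is.numeric(y) || length(unique(y)) == 2L && all(y %in% c(0, 1))
  fit <- with_seed(seed, {
    if (is_class) {
      randomForest::randomForest(x, factor(as_binary_labels(y)), ntree = ntree)
    } else {
      randomForest::randomForest(x, y, ntree = ntree)
    }
  })
  imp <- randomForest::importance(fit)[, 1]
  new_ranking(as.numeric(imp), colnames(x), "impurity",
              if (is_class) "classification" else "regression",
              "random_forest")
}

#' Top-k feature set of a ranking
#'
#' @param ranking An [importance_ranking].
#' @param k Number of features (0 <= k <= number of features).
#' @return Integer vector of the k highest-scoring feature indices, most
#'   important first; ties broken by (score descending, index ascending).
#' @export
top_k <- function(ranking, k = 30) {
  stopifnot(inherits(ranking, "importance_ranking"))
  k <- as.integer(k)
  if (k < 0L || k > nrow(ranking)) stop2("k must be in [0, n_features]")
  ranking$index[order(ranking$rank)][seq_len(k)]
}

#' Convenience: importance ranking for a feature table task
#'
#' Standardizes features and dispatches to the requested importance
#' method: `"linear_coef"` (logistic coefficients; classification only),
#' `"impurity"` (random forest), or `"shapley_mc"` (Monte-Carlo Shapley on
#' a random-forest regressor; regression only).
#'
#' @param table A [feature_table()].
#' @param task `"classification"` (uses the `class` column) or the name of
#'   a numeric target column.
#' @param method Importance method.
#' @param seed Seed.
#' @param shap_samples Orderings per instance for `"shapley_mc"`.
#' @param shap_background Background rows subsampled for `"shapley_mc"`
#'   (default 25).
#' @return An [importance_ranking].
#' @export
rank_features <- function(table, task = "classification",
                          method = c("linear_coef", "impurity", "shapley_mc"),
                          seed = 1, shap_samples = 8, shap_background = 25) {
  method <- match.arg(method)
  x <- feature_matrix(table)
  if (task == "classification") {
    y <- as_binary_labels(table$class)
  } else {
    if (!task %in% names(table)) stop2("target column '", task, "' not found")
    y <- table[[task]]
  }
  switch(method,
    linear_coef = {
      if (task != "classification") stop2("linear_coef requires a classification task")
      rank_linear(standardize_fit(x)$x, y, task = task)
    },
    impurity = rank_impurity(x, y, seed = seed),
    shapley_mc = {
      if (task == "classification") stop2("shapley_mc here targets regression tasks")
      fit <- with_seed(derive_seed(seed, 1),
                       randomForest::randomForest(x, y, ntree = 100))
      bg <- x
      if (nrow(bg) > shap_background) {
        bg <- bg[with_seed(derive_seed(seed, 2),
                           sample.int(nrow(bg), shap_background)), , drop = FALSE]
      }
      r <- shapley_mc(function(m) as.numeric(stats::predict(fit, m)),
                      x, bg, samples_per_feature = shap_samples,
                      seed = derive_seed(seed, 3), task = task)
      attr(r, "model") <- "random_forest"
      r
    }
  )
}
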