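#' Exact overlap distribution of two random subsets
#'
#' When two subsets of sizes `k1` and `k2` are drawn uniformly at random
#' from a pool of `N` features, the size of their intersection is
#' hypergeometric: fixing the first set, the second set draws `k2`
#' features of which `X` fall among the `k1` "marked" ones,
#' \deqn{P(X = i) = \binom{k1}{i}\binom{N-k1}{k2-i} / \binom{N}{k2}.}
#' `hypergeom_tail()` returns the exact upper tail `P(X >= m)` — the
#' one-sided Fisher exact p-value of the 2x2 overlap table — accumulated
#' in log space for numerical stability at large `N`.
#'
#' @param N Pool size.
#' @param k1,k2 Sizes of the two sets (each in `[0, N]`).
#' @param m Observed overlap (in `[0, min(k1, k2)]`).
#' @return `P(X >= m)`, exactly 1 when `m <= max(0, k1 + k2 - N)`.
#' @examples
#' hypergeom_tail(4, 2, 2, 2)        # 1/6
#' hypergeom_tail(512, 30, 30, 5)    # ~0.0246
#' @export
hypergeom_tail <- function(N, k1, k2, m) {
  check_overlap_counts(N, k1, k2, m)
  lo <- max(0L, k1 + k2 - N)
  if (m <= lo) return(1)
  hi <- min(k1, k2)
  i <- m:hi
  exp(logsumexp(lchoose(k1, i) + lchoose(N - k1, k2 - i) - lchoose(N, k2)))
}

check_overlap_counts <- function(N, k1, k2, m) {
  if (N < 0 || k1 < 0 || k2 < 0 || k1 > N || k2 > N) {
    stop2("need 0 <= k1, k2 <= N")
  }
  if (m < 0 || m > min(k1, k2)) stop2("need 0 <= m <= min(k1, k2)")
  invisible(TRUE)
}

# Exact pmf over the full support, in probability space.
overlap_pmf <- function(N, k1, k2) {
  lo <- max(0L, k1 + k2 - N)
  hi <- min(k1, k2)
  i <- lo:hi
  p <- exp(lchoose(k1, i) + lchoose(N - k1, k2 - i) - lchoose(N, k2))
  stats::setNames(p, i)
}

#' One-sided overlap significance test for two feature sets
#'
#' Tests whether two top-k important-feature sets share more features than
#' two random subsets of the same sizes would: the observed overlap
#' `m = |A intersect B|` is referred to the exact hypergeometric upper
#' tail [hypergeom_tail()]. A Bonferroni-style `correction` factor
#' multiplies the p-value (capped at 1) before comparison with `alpha`.
#'
#' @param set_a,set_b Integer feature ids, each a subset of `1:N` without
#'   duplicates.
#' @param N Feature pool size.
#' @param alpha Significance level (default 0.05).
#' @param correction Multiplicative correction factor (default 1; use the
#'   number of pairwise tests in the reported family, e.g. 3 for a
#'   three-set Venn diagram).
#' @return An object of class `overlap_test` (also `htest`-like in
#'   content): pool size, set sizes, observed overlap `m`, one-sided
#'   `p.value`, `correction`, `p.corrected = min(1, correction * p)` and
#'   `significant` at `alpha`.
#' @examples
#' overlap_test(1:30, 26:55, N = 512, correction = 3)
#' @export
overlap_test <- function(set_a, set_b, N, alpha = 0.05, correction = 1) {
  set_a <- unique(as.integer(set_a))
  set_b <- unique(as.integer(set_b))
  if (length(set_a) && (min(set_a) < 1L || max(set_a) > N)) {
    stop2("set A is not within the pool 1..N")
  }
  if (length(set_b) && (min(set_b) < 1L || max(set_b) > N)) {
    stop2("set B is not within the pool 1..N")
  }
  m <- length(intersect(set_a, set_b))
  p <- hypergeom_tail(N, length(set_a), length(set_b), m)
  p_corr <- min(1, correction * p)
  structure(list(N = N, k1 = length(set_a), k2 = length(set_b), m = m,
                 p.value = p, correction = correction,
                 p.corrected = p_corr, alpha = alpha,
                 significant = p_corr < alpha,
                 method = "one-sided exact hypergeometric overlap test"),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  pool N = %d, |A| = %d, |B| = %d, overlap m = %d\n",
              x$N, x$k1, x$k2, x$m))
  cat(sprintf("  p = %.4g, corrected (x%g) = %.4g -> %ssignificant at alpha = %g\n",
              x$p.value, x$correction, x$p.corrected,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Monte-Carlo null distribution of the overlap statistic
#'
#' Draws two independent uniform k-subsets of `1:N` in each of `runs`
#' simulation runs and records their intersection size, giving an
#' empirical null for percentile-based significance thresholds — the
#' simulation counterpart of the exact hypergeometric null.
#'
#' @param N Pool size.
#' @param k Subset size (both sets).
#' @param runs Simulation runs (default 10000).
#' @param seed Seed; the histogram is deterministic given it.
#' @param percentiles Percentiles to report (default c(0.5, 0.95, 0.99)).
#' @return Object of class `overlap_null`: `counts` (named histogram over
#'   0..k summing to `runs`), `mean`, `percentiles` (empirical, inverse
#'   CDF convention), plus the call parameters.
#' @examples
#' null <- mc_null(512, 30, runs = 2000, seed = 1)
#' null$mean     # close to 30^2/512 = 1.758
#' @export
mc_null <- function(N, k, runs = 10000, seed = 1,
                    percentiles = c(0.5, 0.95, 0.99)) {
  if (k > N) stop2("k must not exceed N")
  if (runs < 1) stop2("runs must be >= 1")
  draws <- with_seed(seed, {
    vapply(seq_len(runs), function(i) {
      length(intersect(sample.int(N, k), sample.int(N, k)))
    }, integer(1))
  })
  counts <- tabulate(draws + 1L, nbins = k + 1L)
  names(counts) <- 0:k
  q <- stats::quantile(draws, percentiles, type = 1, names = FALSE)
  structure(list(N = N, k = k, runs = runs, seed = seed,
                 counts = counts, mean = mean(draws),
                 percentiles = stats::setNames(q, percentiles)),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf("<overlap_null: N = %d, k = %d, %d runs>\n", x$N, x$k, x$runs))
  cat(sprintf("  mean overlap = %.3f (analytic k^2/N = %.3f)\n",
              x$mean, x$k^2 / x$N))
  cat("  percentiles:",
      paste(sprintf("%s%% = %d", 100 * as.numeric(names(x$percentiles)),
                    x$percentiles), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.overlap_null <- function(x, ...) {
  graphics::barplot(x$counts / x$runs, xlab = "overlap size",
                    ylab = "relative frequency",
                    main = sprintf("Null overlap, N = %d, k = %d", x$N, x$k),
                    ...)
  invisible(x)
}

#' Minimum significant overlap
#'
#' The smallest overlap `m*` between two k-subsets of an N-pool whose
#' (corrected) one-sided exact p-value falls below `alpha`:
#' `min { m : correction * P(X >= m) < alpha }`. This reproduces the
#' per-column significance thresholds of the repeated-overlap experiment
#' tables. With `alpha >= 1` every overlap is trivially "significant" and
#' 0 is returned (degenerate boundary).
#'
#' @param N Pool size.
#' @param k Subset size (k <= N).
#' @param alpha Significance level (default 0.05).
#' @param correction Multiplicative p-value correction (default 1).
#' @return Integer `m*`, or `NA` (with a warning) when even complete
#'   overlap is not significant.
#' @examples
#' min_significant_overlap(512, 30)                  # 5
#' min_significant_overlap(512, 30, correction = 3)  # 6
#' @export
min_significant_overlap <- function(N, k, alpha = 0.05, correction = 1) {
  if (k > N) stop2("k must not exceed N")
  if (alpha >= 1) return(0L)
  for (m in 0:k) {
    if (correction * hypergeom_tail(N, k, k, m) < alpha) return(m)
  }
  warning("no overlap m <= k reaches significance", call. = FALSE)
  NA_integer_
}

#' Pairwise overlap tests and Venn regions for several rankings
#'
#' Runs the one-sided overlap test on every pair of top-k sets from a
#' list of importance rankings over the same feature pool, with the
#' Bonferroni factor defaulting to the number of pairs, and computes the
#' exclusive/shared Venn region counts (up to three sets).
#'
#' @param rankings Named list of [importance_ranking] objects over the
#'   same pool.
#' @param k Top-k set size (default 30).
#' @param N Pool size; defaults to the number of features in the
#'   rankings, which must agree.
#' @param alpha Significance level.
#' @param correction p-value multiplier; default = number of pairs.
#' @return Object of class `overlap_matrix`: `pairs` (data.frame with
#'   `a`, `b`, `m`, `p`, `p_corrected`, `significant`), `tests` (list of
#'   [overlap_test()] results), `venn` (named region counts), `sets`.
#' @export
overlap_matrix <- function(rankings, k = 30, N = NULL, alpha = 0.05,
                           correction = NULL) {
  if (length(rankings) < 2L) stop2("need at least two rankings")
  if (is.null(names(rankings))) {
    names(rankings) <- paste0("model", seq_along(rankings))
  }
  pools <- vapply(rankings, nrow, integer(1))
  if (length(unique(pools)) != 1L) {
    stop2("rankings cover different feature pools")
  }
  if (is.null(N)) N <- pools[[1]]
  if (any(pools != N)) stop2("rankings cover different feature pools")
  sets <- lapply(rankings, top_k, k = k)
  nm <- names(sets)
  pair_idx <- utils::combn(length(sets), 2)
  if (is.null(correction)) correction <- ncol(pair_idx)
  tests <- list()
  rows <- list()
  for (j in seq_len(ncol(pair_idx))) {
    a <- pair_idx[1, j]; b <- pair_idx[2, j]
    tst <- overlap_test(sets[[a]], sets[[b]], N, alpha, correction)
    tests[[paste(nm[a], nm[b], sep = ":")]] <- tst
    rows[[j]] <- data.frame(a = nm[a], b = nm[b], m = tst$m,
                            p = tst$p.value, p_corrected = tst$p.corrected,
                            significant = tst$significant,
                            stringsAsFactors = FALSE)
  }
  venn <- venn_regions(sets)
  structure(list(pairs = do.call(rbind, rows), tests = tests,
                 venn = venn, sets = sets, k = k, N = N,
                 alpha = alpha, correction = correction),
            class = "overlap_matrix")
}

# Exclusive region counts for up to 3 sets.
venn_regions <- function(sets) {
  nm <- names(sets)
  if (length(sets) == 2L) {
    ab <- length(intersect(sets[[1]], sets[[2]]))
    out <- c(length(sets[[1]]) - ab, length(sets[[2]]) - ab, ab)
    names(out) <- c(nm[1], nm[2], paste(nm, collapse = "&"))
    return(out)
  }
  if (length(sets) != 3L) stop2("Venn regions support 2 or 3 sets")
  a <- sets[[1]]; b <- sets[[2]]; c_ <- sets[[3]]
  abc <- length(Reduce(intersect, sets))
  ab <- length(intersect(a, b)) - abc
  ac <- length(intersect(a, c_)) - abc
  bc <- length(intersect(b, c_)) - abc
  out <- c(length(a) - ab - ac - abc,
           length(b) - ab - bc - abc,
           length(c_) - ac - bc - abc,
           ab, ac, bc, abc)
  names(out) <- c(nm, paste(nm[1], nm[2], sep = "&"),
                  paste(nm[1], nm[3], sep = "&"),
                  paste(nm[2], nm[3], sep = "&"),
                  paste(nm, collapse = "&"))
  out
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix: k = %d, N = %d, correction = %g>\n",
              x$k, x$N, x$correction))
  print.data.frame(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Repeated-overlap stability experiment
#'
#' Quantifies how stably two tasks share important features: the
#' importance model for each task is refitted `repeats` times with
#' derived seeds, the top-k sets are extracted at each `k` in `k_list`,
#' and the per-repeat overlap counts are summarised as mean and standard
#' deviation. Each column's significance threshold `m*` comes from
#' [min_significant_overlap()]; a column is flagged `"**"` when the mean
#' overlap reaches `m*` (significant on average) and `"*"` when
#' `mean + sd` reaches it (significant at least within one standard
#' deviation).
#'
#' @param table_a,table_b [feature_table()]s over the same feature pool.
#' @param task_a,task_b `"classification"` or a numeric target column
#'   name, for the respective table.
#' @param method Importance method passed to [rank_features()] (default
#'   `"impurity"`, the random-forest variant whose refits differ across
#'   repeats).
#' @param k_list Top-k sizes (default c(10, 20, 30, 50)).
#' @param repeats Refits (default 30, >= 2).
#' @param alpha,correction Passed to [min_significant_overlap()].
#' @param seed Master seed.
#' @return Object of class `overlap_repeat`: data.frame `summary` with
#'   columns `k`, `m_star`, `mean`, `sd`, `flag`, plus the per-repeat
#'   overlap matrix in `$overlaps`.
#' @export
repeated_overlap_experiment <- function(table_a, table_b,
                                        task_a = "classification",
                                        task_b = "classification",
                                        method = "impurity",
                                        k_list = c(10, 20, 30, 50),
                                        repeats = 30, alpha = 0.05,
                                        correction = 1, seed = 1) {
  if (repeats < 2L) stop2("need at least 2 repeats")
  p_a <- length(feature_names(table_a))
  p_b <- length(feature_names(table_b))
  if (p_a != p_b) stop2("tables cover different feature pools")
  N <- p_a
  if (any(k_list > N)) stop2("k exceeds the feature pool size")
  ov <- matrix(NA_real_, repeats, length(k_list),
               dimnames = list(NULL, paste0("k", k_list)))
  for (r in seq_len(repeats)) {
    ra <- rank_features(table_a, task_a, method, seed = derive_seed(seed, 2 * r))
    rb <- rank_features(table_b, task_b, method, seed = derive_seed(seed, 2 * r + 1))
    for (j in seq_along(k_list)) {
      ov[r, j] <- length(intersect(top_k(ra, k_list[j]), top_k(rb, k_list[j])))
    }
  }
  m_star <- vapply(k_list, min_significant_overlap, integer(1),
                   N = N, alpha = alpha, correction = correction)
  mu <- colMeans(ov)
  sdv <- apply(ov, 2, stats::sd)
  flag <- ifelse(mu >= m_star, "**", ifelse(mu + sdv >= m_star, "*", ""))
  structure(list(summary = data.frame(k = k_list, m_star = m_star,
                                      mean = mu, sd = sdv, flag = flag,
                                      row.names = NULL),
                 overlaps = ov, N = N, repeats = repeats, method = method,
                 tasks = c(task_a, task_b), seed = seed),
            class = "overlap_repeat")
}

#' @export
print.overlap_repeat <- function(x, ...) {
  cat(sprintf("<overlap_repeat: %s vs %s, %d repeats, pool %d, method=%s>\n",
              x$tasks[1], x$tasks[2], x$repeats, x$N, x$method))
  s <- x$summary
  s$value <- sprintf("%s%.1f (+/-%.1f)", ifelse(s$flag == "", "",
                                                paste0(s$flag, " ")),
                     s$mean, s$sd)
  print.data.frame(s[, c("k", "m_star", "value")], row.names = FALSE)
  invisible(x)
}
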