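# Internal helpers shared across modules.

#' pdspeech: speech-embedding feature analysis and overlap testing
#'
#' See the package vignette for the statistical methodology; the main
#' entry points are [make_three_dataset_suite()], [cv_classify()],
#' [crossdb_classify()], [cv_regress()], [rank_features()],
#' [overlap_test()], [mc_null()], [min_significant_overlap()] and
#' [run_pipeline()].
#'
#' @keywords internal
"_PACKAGE"

# Deterministic child seeds from one master seed. Keeps every derived seed a
# positive 32-bit integer so set.seed() never overflows.
derive_seed <- function(master, index) {
  master <- as.numeric(master)
  index <- as.numeric(index)
  as.integer((master * 10007 + index * 7919) %% 2147483561 + 1)
}

# Run expr with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise standardization; returns list(x, center, scale) so test folds can
# reuse train-fold statistics. Zero-variance columns get scale 1.
standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < .Machine$double.eps] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

standardize_apply <- function(x, fit) {
  sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
}

# Tiny FNV-1a hash of a character scalar, used to stamp output tables with a
# config fingerprint without a heavyweight digest dependency.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop2 <- function(...) stop(..., call. = FALSE)
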