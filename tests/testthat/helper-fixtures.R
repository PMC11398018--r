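# Fixtures are built in code: small cohorts and feature tables shared by
# several test files.

# Balanced two-class table of pure-noise features.
make_noise_table <- function(n = 40, p = 10, seed = 1) {
  x <- pdspeech:::with_seed(seed, matrix(rnorm(n * p), n, p))
  meta <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    dataset = "noise",
    class = rep(c("HC", "PD"), length.out = n),
    stringsAsFactors = FALSE
  )
  feature_table(meta, x, sprintf("f%03d", seq_len(p)))
}

# Small planted-signal cohort pooled to a classification feature table.
small_cohort_table <- function(seed = 1, n = 15, D = 64, planted = 1:8,
                               effect = 3, frames = c(10, 20),
                               name = "mini") {
  spec <- cohort_spec(name, c(HC = n, PD = n), n_channels = D,
                      frames_per_subject = frames,
                      planted_class_channels = planted,
                      effect_size = effect, seed = seed)
  pooled_feature_table(generate_embedding_cohort(spec),
                       classification_only = TRUE)
}

# Brute-force loud-region duration: explicit loops over every window
# position, no vectorized rolling machinery.
lrd_bruteforce <- function(w, window) {
  a <- abs(w$samples)
  b <- as.integer(a > mean(a))
  n <- length(b)
  total <- 0
  for (i in seq_len(n - window + 1L)) {
    total <- total + sum(b[i:(i + window - 1L)]) / window
  }
  total / w$rate
}

# O(n^2) pair-counting AUROC oracle.
auroc_pairs <- function(scores, labels) {
  y <- pdspeech:::as_binary_labels(labels)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Feature table with only the first half of its feature columns kept.
drop_half_features <- function(tbl) {
  f <- feature_names(tbl)[seq_len(length(feature_names(tbl)) %/% 2)]
  out <- tbl[, c(setdiff(names(tbl), feature_names(tbl)), f)]
  class(out) <- c("feature_table", "data.frame")
  attr(out, "features") <- f
  out
}

# Exact overlap tail by full enumeration: fix A = 1..k1 (exchangeability),
# enumerate every k2-subset B and tally |A intersect B| >= m.
tail_enumeration <- function(N, k1, k2, m) {
  sets <- utils::combn(N, k2)
  hits <- sum(apply(sets, 2, function(b) sum(b <= k1) >= m))
  hits / ncol(sets)
}
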