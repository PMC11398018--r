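test_that("loud-region binarization uses a strict threshold", {
  expect_identical(binarize_loud(waveform(rep(0, 8), 8)), rep(0L, 8))
  # |x| equal to the mean everywhere: strict > never fires
  expect_identical(binarize_loud(waveform(c(1, -1, 1, -1), 4)), rep(0L, 4))
  expect_identical(binarize_loud(waveform(c(2, -2, 0, 0), 4)), c(1L, 1L, 0L, 0L))
  expect_error(waveform(numeric(0), 4), "at least one sample")
  expect_error(waveform(c(1, NA), 4), "finite")
})

test_that("loud-region duration matches hand-computed and brute-force values", {
  w <- waveform(c(2, -2, 0, 0), 4)
  expect_equal(as.numeric(loud_region_duration(w, window = 1)), 0.5)
  expect_equal(as.numeric(loud_region_duration(w, window = 2)), 0.375)
  expect_equal(attr(loud_region_duration(w, window = 2), "raw_sum"), 1.5)
  expect_equal(as.numeric(loud_region_duration(waveform(rep(0, 100), 10),
                                               window = 10)), 0,
               tolerance = 1e-12)
  expect_error(loud_region_duration(w, window = 5), "exceeds signal length")

  # exact agreement with an explicit-loop oracle on random signals
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(500:2000, 1)
    w <- waveform(rnorm(n) * rbinom(n, 1, 0.3), 1000)
    for (win in c(1, 3, 50)) {
      expect_equal(as.numeric(loud_region_duration(w, win)),
                   lrd_bruteforce(w, win), tolerance = 1e-12)
    }
  }
})

test_that("duration is bounded by the recording length in both edge modes", {
  set.seed(7)
  w <- waveform(rnorm(5000), 1000)
  for (mode in c("trailing", "same")) {
    d <- as.numeric(loud_region_duration(w, 100, edge = mode))
    expect_gte(d, 0)
    expect_lte(d, duration(w))
  }
})

test_that("frame aggregation statistics are exact and permutation-invariant", {
  fm1 <- frame_matrix(matrix(c(3, 1, 4), 1), 100)
  expect_equal(aggregate_frames(fm1, "mean"), c(3, 1, 4))
  expect_equal(aggregate_frames(fm1, "std"), c(0, 0, 0))
  fm <- frame_matrix(rbind(c(1, 2), c(3, 6)), 100)
  expect_equal(aggregate_frames(fm, "sum"), c(4, 8))
  expect_equal(aggregate_frames(fm, "mean"), c(2, 4))
  expect_equal(aggregate_frames(fm, "std"), c(1, 2))  # population divisor
  expect_error(aggregate_frames(fm, "median"))

  set.seed(11)
  for (i in 1:5) {
    x <- matrix(rnorm(30 * 7), 30, 7)
    fm <- frame_matrix(x, 100)
    expect_equal(aggregate_frames(fm, "sum"),
                 nrow(x) * aggregate_frames(fm, "mean"),
                 tolerance = 1e-9)
    perm <- frame_matrix(x[sample(nrow(x)), ], 100)
    for (s in c("mean", "std", "sum")) {
      expect_equal(aggregate_frames(perm, s), aggregate_frames(fm, s),
                   tolerance = 1e-12)
    }
  }
})

test_that("MFCC means satisfy the output contract", {
  set.seed(3)
  w <- waveform(sin(2 * pi * 440 * (0:15999) / 16000) + 0.01 * rnorm(16000),
                16000)
  m <- extract_mfcc_mean(w)
  expect_length(m, 50)
  expect_true(all(is.finite(m)))
  expect_identical(m, extract_mfcc_mean(w))
  expect_error(extract_mfcc_mean(waveform(w$samples, 44100)),
               "resample_to_16k")

  # averaging invariance: with non-overlapping frames that tile the signal,
  # doubling the signal by concatenation leaves the time average unchanged
  x <- w$samples[1:4096]
  m1 <- extract_mfcc_mean(waveform(x, 16000), n_fft = 1024, hop = 1024)
  m2 <- extract_mfcc_mean(waveform(c(x, x), 16000), n_fft = 1024, hop = 1024)
  expect_equal(m1, m2, tolerance = 1e-6)
})

test_that("resampling preserves duration and spectral content", {
  w16 <- waveform(rnorm(1600), 16000)
  expect_identical(resample_to_16k(w16), w16)

  w48 <- waveform(rnorm(48000), 48000)
  expect_length(resample_to_16k(w48)$samples, 16000)

  t <- (0:44099) / 44100
  tone <- waveform(sin(2 * pi * 100 * t), 44100)
  y <- resample_to_16k(tone)
  expect_equal(y$rate, 16000)
  sp <- Mod(stats::fft(y$samples))
  freqs <- (seq_along(sp) - 1) * y$rate / length(sp)
  half <- freqs <= y$rate / 2
  expect_lt(abs(freqs[half][which.max(sp[half])] - 100), 1)
})

test_that("WAV files round-trip and stereo input is rejected", {
  set.seed(9)
  w <- waveform(round(runif(800, -0.5, 0.5) * 32768) / 32768, 8000)
  p16 <- tempfile(fileext = ".wav")
  write_wav(w, p16, "pcm16")
  r16 <- read_wav(p16)
  expect_equal(r16$rate, 8000)
  expect_equal(r16$samples, w$samples, tolerance = 1 / 32768)
  pf <- tempfile(fileext = ".wav")
  write_wav(w, pf, "float32")
  expect_equal(read_wav(pf)$samples, w$samples, tolerance = 1e-7)

  # hand-build a 2-channel WAV header
  ps <- tempfile(fileext = ".wav")
  con <- file(ps, "wb")
  writeChar("RIFF", con, eos = NULL); writeBin(44L, con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little"); writeBin(2L, con, 2, endian = "little")
  writeBin(8000L, con, 4, endian = "little"); writeBin(32000L, con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little"); writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL); writeBin(8L, con, 4, endian = "little")
  writeBin(rep(0L, 4), con, 2, endian = "little")
  close(con)
  expect_error(read_wav(ps), "mono")
})

test_that("PCA combo vector has the right width and variance accounting", {
  set.seed(21)
  n <- 30
  meta <- data.frame(subject_id = sprintf("s%d", 1:n), dataset = "d",
                     class = rep(c("HC", "PD"), 15))
  # block A: exactly 10 independent variance directions replicated into 12
  # columns (rank 10)
  basis <- matrix(rnorm(10 * 12), 10, 12)
  a_mat <- matrix(rnorm(n * 10), n, 10) %*% basis
  a <- feature_table(meta, a_mat, sprintf("a%02d", 1:12))
  b <- feature_table(meta, matrix(rnorm(n * 15), n, 15), sprintf("b%02d", 1:15))

  combo <- suppressWarnings(pca_combo(a, b, c = 10))
  expect_length(feature_names(combo), 20)
  ev <- attr(combo, "explained_variance")
  expect_equal(unname(ev["A"]), 1, tolerance = 1e-8)
  expect_warning(pca_combo(a, b, c = 10), "block B")
  expect_error(suppressWarnings(pca_combo(a, b, c = 11)), "rank")
})

test_that("PCA combo is invariant to affine rescaling of one input feature", {
  set.seed(22)
  n <- 25
  meta <- data.frame(subject_id = sprintf("s%d", 1:n), dataset = "d",
                     class = rep_len(c("HC", "PD"), n))
  a_mat <- matrix(rnorm(n * 8), n, 8)
  b_mat <- matrix(rnorm(n * 8), n, 8)
  a1 <- feature_table(meta, a_mat, sprintf("a%d", 1:8))
  a_mat2 <- a_mat
  a_mat2[, 3] <- 5.5 * a_mat2[, 3] - 2
  a2 <- feature_table(meta, a_mat2, sprintf("a%d", 1:8))
  b <- feature_table(meta, b_mat, sprintf("b%d", 1:8))
  c1 <- suppressWarnings(pca_combo(a1, b, c = 3))
  c2 <- suppressWarnings(pca_combo(a2, b, c = 3))
  # principal axes are sign-ambiguous; compare up to column sign
  m1 <- feature_matrix(c1)
  m2 <- feature_matrix(c2)
  for (j in seq_len(ncol(m1))) {
    expect_true(max(abs(m1[, j] - m2[, j])) < 1e-8 ||
                max(abs(m1[, j] + m2[, j])) < 1e-8)
  }
})
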