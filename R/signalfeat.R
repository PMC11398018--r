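#' Frame-level embedding matrix
#'
#' A `frame_matrix` holds the T x D frame-level representation of one
#' recording (rows are time frames, columns are embedding channels),
#' together with the nominal frame rate in frames per second.
#'
#' @param values Numeric T x D matrix with finite entries, T >= 1.
#' @param frame_rate Nominal frames per second.
#' @return An object of class `frame_matrix`.
#' @export
frame_matrix <- function(values, frame_rate) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop2("frame matrix needs at least one frame")
  if (!all(is.finite(values))) stop2("frame matrix entries must be finite")
  if (frame_rate <= 0) stop2("frame rate must be positive")
  structure(list(values = values, frame_rate = frame_rate),
            class = "frame_matrix")
}

#' @export
print.frame_matrix <- function(x, ...) {
  cat(sprintf("<frame_matrix: %d frames x %d channels @ %g fps>\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

#' Binary loud-region encoding of a waveform
#'
#' Encodes each sample as 1 when its absolute value strictly exceeds the
#' mean absolute value of the whole signal, else 0. Samples exactly at the
#' mean (including an all-zero signal, whose mean absolute value is 0) are
#' encoded 0.
#'
#' @param w A [waveform()].
#' @return Integer vector of 0/1, same length as the input.
#' @examples
#' binarize_loud(waveform(c(2, -2, 0, 0), 4))  # 1 1 0 0
#' @export
binarize_loud <- function(w) {
  stopifnot(inherits(w, "waveform"))
  a <- abs(w$samples)
  as.integer(a > mean(a))
}

#' Loud-region duration of a recording
#'
#' The loud-region proxy for reading duration: the 0/1 loud encoding from
#' [binarize_loud()] is smoothed with a rolling average over `window`
#' samples and summed; the sum is divided by the sampling rate so the
#' result is reported in seconds. The raw (sample-unit) sum is attached as
#' attribute `"raw_sum"`.
#'
#' @param w A [waveform()].
#' @param window Rolling-average window in samples (default 10000).
#' @param edge `"trailing"` (default): only full trailing windows, giving
#'   `n - window + 1` smoothed values; `"same"`: centered window with
#'   partial windows at the edges, giving `n` values.
#' @return Loud-region duration in seconds (numeric scalar with attribute
#'   `raw_sum`).
#' @examples
#' w <- waveform(c(2, -2, 0, 0), 4)
#' loud_region_duration(w, window = 1)  # 0.5 s
#' loud_region_duration(w, window = 2)  # 0.375 s
#' @export
loud_region_duration <- function(w, window = 10000, edge = c("trailing", "same")) {
  stopifnot(inherits(w, "waveform"))
  edge <- match.arg(edge)
  window <- as.integer(window)
  if (window < 1L) stop2("window must be >= 1 sample")
  n <- length(w$samples)
  if (window > n) {
    stop2("rolling-average window (", window,
          " samples) exceeds signal length (", n, " samples)")
  }
  b <- binarize_loud(w)
  sm <- if (edge == "trailing") {
    zoo::rollmean(b, window, align = "right")
  } else {
    zoo::rollapply(b, window, mean, partial = TRUE, align = "center")
  }
  raw <- sum(sm)
  structure(raw / w$rate, raw_sum = raw)
}

#' Pool a frame matrix into a fixed-length vector
#'
#' Collapses the time axis of a T x D frame matrix with one per-channel
#' statistic, producing the fixed D-vector used as the subject-level
#' feature set. `std` uses the population divisor (divide by T), so a
#' single frame pools to a zero vector.
#'
#' @param fm A [frame_matrix()].
#' @param stat One of `"mean"`, `"std"`, `"sum"`.
#' @return Numeric vector of length D.
#' @examples
#' fm <- frame_matrix(rbind(c(1, 2), c(3, 6)), 100)
#' aggregate_frames(fm, "sum")   # 4 8
#' aggregate_frames(fm, "mean")  # 2 4
#' @export
aggregate_frames <- function(fm, stat = c("mean", "std", "sum")) {
  stopifnot(inherits(fm, "frame_matrix"))
  stat <- match.arg(stat)
  x <- fm$values
  switch(stat,
    mean = colMeans(x),
    sum = colSums(x),
    std = {
      mu <- colMeans(x)
      sqrt(colMeans(sweep(x, 2, mu)^2))
    }
  )
}

# ---- Internal STFT / mel machinery (shared by MFCC and the synthetic
# embedding provider) ---------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_mels x (n_fft/2 + 1).
mel_filterbank <- function(n_mels, n_fft, rate, fmin = 0, fmax = rate / 2) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- seq(0, rate / 2, length.out = n_bins)
  mpts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  fpts <- mel_to_hz(mpts)
  fb <- matrix(0, n_mels, n_bins)
  for (i in seq_len(n_mels)) {
    lo <- fpts[i]; ctr <- fpts[i + 1]; hi <- fpts[i + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Power spectrogram over trailing full frames: (n_fft/2+1) x T.
power_spectrogram <- function(x, n_fft, hop, window = NULL) {
  n <- length(x)
  if (n < n_fft) x <- c(x, rep(0, n_fft - n))
  n <- length(x)
  starts <- seq(1L, n - n_fft + 1L, by = hop)
  if (is.null(window)) {
    window <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_fft - 1) / n_fft)  # periodic Hann
  }
  frames <- vapply(starts, function(s) x[s:(s + n_fft - 1L)] * window,
                   numeric(n_fft))
  sp <- stats::mvfft(frames)
  Mod(sp[seq_len(n_fft %/% 2L + 1L), , drop = FALSE])^2
}

# Orthonormal DCT-II basis, k x n.
dct_basis <- function(k, n) {
  b <- outer(seq_len(k) - 1L, seq_len(n) - 0.5,
             function(i, j) cos(pi * i * j / n))
  b <- b * sqrt(2 / n)
  b[1, ] <- b[1, ] / sqrt(2)
  b
}

#' Time-averaged MFCC vector
#'
#' Computes mel-frequency cepstral coefficients frame by frame (STFT with a
#' Hann window, triangular mel filterbank, log energies, orthonormal
#' DCT-II) and averages each coefficient over time, yielding the fixed
#' `n_mfcc`-length spectral baseline feature vector.
#'
#' The input must already be at 16 kHz; call [resample_to_16k()] first.
#'
#' @param w A [waveform()] at 16 kHz.
#' @param n_mfcc Number of coefficients (default 50).
#' @param n_fft Frame length in samples (default 2048).
#' @param hop Hop between frame starts in samples (default 512). With
#'   `hop = n_fft` frames tile the signal without overlap.
#' @param n_mels Number of mel bands (default 128; must be >= `n_mfcc`).
#' @return Numeric vector of length `n_mfcc`.
#' @export
extract_mfcc_mean <- function(w, n_mfcc = 50, n_fft = 2048, hop = 512,
                              n_mels = 128) {
  stopifnot(inherits(w, "waveform"))
  if (w$rate != 16000) {
    stop2("MFCC extraction expects 16 kHz input; use resample_to_16k() first")
  }
  if (n_mels < n_mfcc) stop2("n_mels must be >= n_mfcc")
  ps <- power_spectrogram(w$samples, n_fft, hop)
  fb <- mel_filterbank(n_mels, n_fft, w$rate)
  loge <- log(fb %*% ps + 1e-10)
  mfcc <- dct_basis(n_mfcc, n_mels) %*% loge
  rowMeans(mfcc)
}

#' Combined PCA feature vector from two feature blocks
#'
#' Projects feature block A and feature block B (same subjects, same row
#' order) onto their leading `c` principal components each and concatenates
#' the scores into a single 2c-length vector per subject — the compact
#' "combo" representation joining an embedding block with a spectral
#' block. Features are standardized (mean 0, variance 1, statistics from
#' the fit rows) before PCA.
#'
#' The cumulative explained variance of each block's `c` components is
#' attached as attribute `"explained_variance"`; a warning is raised when a
#' block captures less than `min_variance` of its total variance.
#'
#' @param a,b [feature_table()]s over the same subjects in the same order.
#' @param c Components per block (default 10).
#' @param fit_rows Integer rows used to fit centering/scaling and the PCA
#'   rotation (default all rows). Pass the training rows of a CV split to
#'   avoid leakage; all rows are then projected with the fitted rotation.
#' @param min_variance Warn when a block's cumulative explained variance
#'   falls below this fraction (default 0.9).
#' @param standardize Standardize each feature before PCA (default TRUE).
#' @return A [feature_table()] with `2c` features named `pcA1..pcAc,
#'   pcB1..pcBc`, metadata taken from `a`.
#' @export
pca_combo <- function(a, b, c = 10, fit_rows = NULL, min_variance = 0.9,
                      standardize = TRUE) {
  xa <- feature_matrix(a)
  xb <- feature_matrix(b)
  if (nrow(xa) != nrow(xb)) stop2("blocks must cover the same subjects")
  if (!is.null(a$subject_id) && !is.null(b$subject_id) &&
      !identical(as.character(a$subject_id), as.character(b$subject_id))) {
    stop2("blocks must list the same subjects in the same order")
  }
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(xa))

  project <- function(x, label) {
    if (standardize) {
      fit <- standardize_fit(x[fit_rows, , drop = FALSE])
      x <- standardize_apply(x, fit)
    }
    pc <- stats::prcomp(x[fit_rows, , drop = FALSE], center = TRUE, scale. = FALSE)
    rank_x <- sum(pc$sdev > max(pc$sdev) * 1e-8)
    if (c > rank_x) {
      stop2("block ", label, " has rank ", rank_x, " < c = ", c)
    }
    ev <- sum(pc$sdev[seq_len(c)]^2) / sum(pc$sdev^2)
    if (ev < min_variance) {
      warning(sprintf(
        "block %s: %d components capture %.1f%% of variance (< %.0f%%)",
        label, c, 100 * ev, 100 * min_variance), call. = FALSE)
    }
    scores <- sweep(x, 2, pc$center) %*% pc$rotation[, seq_len(c), drop = FALSE]
    list(scores = scores, explained = ev)
  }

  pa <- project(xa, "A")
  pb <- project(xb, "B")
  out <- set_features(a, cbind(pa$scores, pb$scores),
                      c(sprintf("pcA%d", seq_len(c)), sprintf("pcB%d", seq_len(c))))
  attr(out, "explained_variance") <- c(A = pa$explained, B = pb$explained)
  out
}
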