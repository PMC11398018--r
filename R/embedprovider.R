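#' Embedding providers: waveform to frame matrix
#'
#' An embedding provider is a uniform contract turning a 16 kHz mono
#' waveform into a T x D [frame_matrix()]. The shipped `"synthetic"`
#' provider computes short-time log-mel filterbank energies (25 ms
#' windows, 10 ms hop) and projects them to `output_dim` channels through
#' a fixed, seeded random matrix followed by a tanh squashing — fully
#' deterministic, dependency-free, and loudness/duration-preserving so
#' that downstream regression targets remain learnable. A `"pretrained"`
#' adapter slot accepts a user-supplied function wrapping a real speech
#' model behind the same contract; none is bundled.
#'
#' @param name `"synthetic"` or `"pretrained"`.
#' @param output_dim Embedding dimension (default 512).
#' @param seed Seed fixing the synthetic projection (default 42).
#' @param n_bands Mel bands feeding the projection (default 40).
#' @param embed_fn For `"pretrained"`: a function `(waveform) ->
#'   frame_matrix` wrapping the external model.
#' @return An object of class `embedding_provider`.
#' @export
embedding_provider <- function(name = c("synthetic", "pretrained"),
                               output_dim = 512, seed = 42, n_bands = 40,
                               embed_fn = NULL) {
  name <- match.arg(name)
  if (name == "pretrained" && !is.function(embed_fn)) {
    stop2("the pretrained adapter needs an embed_fn function")
  }
  proj <- NULL
  if (name == "synthetic") {
    proj <- with_seed(seed, {
      matrix(stats::rnorm(n_bands * output_dim), n_bands, output_dim) /
        sqrt(n_bands)
    })
  }
  structure(list(name = name, output_dim = as.integer(output_dim),
                 frame_rate = 100, n_bands = as.integer(n_bands),
                 seed = as.integer(seed), proj = proj, embed_fn = embed_fn),
            class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat(sprintf("<embedding_provider '%s': %d channels @ %g fps>\n",
              x$name, x$output_dim, x$frame_rate))
  invisible(x)
}

#' Embed a waveform into a frame matrix
#'
#' @param provider An [embedding_provider()].
#' @param w A [waveform()] at 16 kHz (use [resample_to_16k()] otherwise).
#' @return A [frame_matrix()] with `D = output_dim`; the frame count grows
#'   monotonically with duration. Output dimension is checked on every
#'   call.
#' @export
embed <- function(provider, w) {
  stopifnot(inherits(provider, "embedding_provider"), inherits(w, "waveform"))
  if (w$rate != 16000) {
    stop2("provider expects 16 kHz input (got ", w$rate,
          " Hz); call resample_to_16k() first")
  }
  fm <- if (provider$name == "synthetic") {
    win <- 400L  # 25 ms at 16 kHz
    hop <- 160L  # 10 ms
    ps <- power_spectrogram(w$samples, win, hop)
    fb <- mel_filterbank(provider$n_bands, win, w$rate)
    loge <- log(fb %*% ps + 1e-8)  # n_bands x T
    frame_matrix(tanh(crossprod(loge, provider$proj) / 4),
                 frame_rate = provider$frame_rate)
  } else {
    provider$embed_fn(w)
  }
  if (!inherits(fm, "frame_matrix") || ncol(fm$values) != provider$output_dim) {
    stop2("provider returned wrong dimension: expected ", provider$output_dim)
  }
  fm
}
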