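#' Specification of a synthetic test waveform
#'
#' Describes a mono noise recording with designated "loud" segments:
#' Gaussian background noise at RMS `background_amplitude`, with each loud
#' segment replaced by constant-envelope random-sign noise at its own RMS
#' amplitude. Used to exercise the loud-region segmentation with a known
#' ground truth.
#'
#' @param duration_s Duration in seconds.
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @param loud_segments List of numeric triples `c(start_s, end_s,
#'   amplitude)`; segments must lie within the recording and must not
#'   overlap.
#' @param background_amplitude RMS of the background noise.
#' @param seed Integer seed; the generated waveform is a pure function of
#'   the spec.
#' @return An object of class `audio_spec`.
#' @export
audio_spec <- function(duration_s, sample_rate = 16000, loud_segments = list(),
                       background_amplitude = 0.05, seed = 1) {
  if (duration_s <= 0) stop2("duration must be positive")
  if (sample_rate <= 0) stop2("sample_rate must be positive")
  if (background_amplitude < 0) stop2("amplitudes must be non-negative")
  segs <- lapply(loud_segments, function(s) {
    s <- as.numeric(s)
    if (length(s) != 3L) stop2("each loud segment is c(start_s, end_s, amplitude)")
    if (s[1] < 0 || s[2] > duration_s || s[1] >= s[2]) {
      stop2("loud segment [", s[1], ", ", s[2], "] outside [0, ", duration_s, "]")
    }
    if (s[3] < 0) stop2("amplitudes must be non-negative")
    s
  })
  if (length(segs) > 1L) {
    ord <- order(vapply(segs, `[`, numeric(1), 1L))
    segs <- segs[ord]
    for (i in seq_len(length(segs) - 1L)) {
      if (segs[[i]][2] > segs[[i + 1L]][1]) stop2("loud segments overlap")
    }
  }
  structure(list(duration_s = duration_s, sample_rate = sample_rate,
                 loud_segments = segs,
                 background_amplitude = background_amplitude,
                 seed = as.integer(seed)),
            class = "audio_spec")
}

#' Generate a synthetic waveform from an [audio_spec()]
#'
#' @param spec An [audio_spec()].
#' @return A [waveform()]; deterministic for a given spec (seed included).
#' @export
generate_waveform <- function(spec) {
  stopifnot(inherits(spec, "audio_spec"))
  n <- round(spec$duration_s * spec$sample_rate)
  with_seed(spec$seed, {
    x <- stats::rnorm(n, 0, spec$background_amplitude)
    for (s in spec$loud_segments) {
      i0 <- floor(s[1] * spec$sample_rate) + 1L
      i1 <- min(n, ceiling(s[2] * spec$sample_rate))
      # constant-envelope random-sign noise: RMS equals the requested
      # amplitude and every loud sample clears the mean-absolute threshold,
      # so the planted duration is recoverable by the segmentation
      x[i0:i1] <- s[3] * sample(c(-1, 1), i1 - i0 + 1L, replace = TRUE)
    }
    waveform(x, spec$sample_rate)
  })
}

#' Specification of a synthetic embedding cohort
#'
#' Describes one cohort of subjects with frame-level embedding matrices in
#' which the class signal and any quantitative targets are planted on known
#' channels. Per subject, a latent channel-mean vector is drawn as
#' N(0, `noise_sd`^2) per channel; PD subjects are shifted by
#' `effect_size * noise_sd` on the `planted_class_channels`; frames are
#' i.i.d. Gaussian around the subject mean with per-channel standard
#' deviation `noise_sd` and optional AR(1) correlation across channels.
#' Quantitative targets are linear in the subject means of their planted
#' channels plus Gaussian noise.
#'
#' @param name Dataset label.
#' @param n_per_group Named vector `c(HC = , PD = )` of subjects per class
#'   (each >= 2).
#' @param n_channels Embedding dimension (default 512).
#' @param frames_per_subject Integer range `c(lo, hi)` from which each
#'   subject's frame count T is drawn uniformly.
#' @param planted_class_channels Integer channel indices carrying the class
#'   signal.
#' @param planted_targets Named list of target definitions, each a list
#'   with `channels`, `weights` (same length), `intercept`, `noise_sd`.
#'   Target value = intercept + sum(weights * subject_mean[channels]) +
#'   N(0, noise_sd^2).
#' @param effect_size Standardized mean shift on class channels (>= 0).
#' @param noise_sd Per-channel standard deviation (> 0) of both the
#'   between-subject means and the within-subject frame noise.
#' @param channel_correlation AR(1) correlation across adjacent channels,
#'   in `[0, 1)`.
#' @param n_young Number of additional young-HC subjects (default 0); they
#'   are flagged `in_classification = FALSE` and shifted by `young_shift`
#'   on the channels of the `age` target, producing the bimodal age
#'   structure of a mixed young/elderly regression cohort.
#' @param young_shift Additive shift on the `age`-target channels for
#'   young subjects.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_per_group, n_channels = 512,
                        frames_per_subject = c(60, 120),
                        planted_class_channels = integer(),
                        planted_targets = list(),
                        effect_size = 1, noise_sd = 1,
                        channel_correlation = 0,
                        n_young = 0, young_shift = 0, seed = 1) {
  if (length(n_per_group) == 1L) n_per_group <- c(HC = n_per_group, PD = n_per_group)
  if (is.null(names(n_per_group))) names(n_per_group) <- c("HC", "PD")
  if (any(n_per_group < 2L)) stop2("need at least 2 subjects per group to cross-validate")
  chk_idx <- function(idx) {
    idx <- as.integer(idx)
    if (length(idx) && (min(idx) < 1L || max(idx) > n_channels)) {
      stop2("planted channel indices must lie in [1, n_channels]")
    }
    idx
  }
  planted_class_channels <- chk_idx(planted_class_channels)
  for (t in names(planted_targets)) {
    planted_targets[[t]]$channels <- chk_idx(planted_targets[[t]]$channels)
    if (length(planted_targets[[t]]$weights) !=
        length(planted_targets[[t]]$channels)) {
      stop2("target '", t, "': weights and channels lengths differ")
    }
  }
  if (effect_size < 0) stop2("effect_size must be >= 0")
  if (noise_sd <= 0) stop2("noise_sd must be > 0")
  if (channel_correlation < 0 || channel_correlation >= 1) {
    stop2("channel_correlation must be in [0, 1)")
  }
  if (length(frames_per_subject) == 1L) {
    frames_per_subject <- rep(frames_per_subject, 2L)
  }
  if (frames_per_subject[1] < 1L) stop2("frame counts must be >= 1")
  structure(list(name = name, n_per_group = n_per_group,
                 n_channels = as.integer(n_channels),
                 frames_per_subject = as.integer(frames_per_subject),
                 planted_class_channels = planted_class_channels,
                 planted_targets = planted_targets,
                 effect_size = effect_size, noise_sd = noise_sd,
                 channel_correlation = channel_correlation,
                 n_young = as.integer(n_young), young_shift = young_shift,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic embedding cohort
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `embedding_cohort`: a list with `spec`, the
#'   per-subject list `frames` of [frame_matrix()] objects, and `meta`, a
#'   data.frame with `subject_id`, `dataset`, `class`, `group`,
#'   `in_classification` and one column per planted target.
#' @export
generate_embedding_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_hc <- spec$n_per_group[["HC"]]
  n_pd <- spec$n_per_group[["PD"]]
  n <- n_hc + n_pd + spec$n_young
  D <- spec$n_channels
  cls <- c(rep("HC", n_hc), rep("PD", n_pd), rep("HC", spec$n_young))
  grp <- c(rep("HC", n_hc), rep("PD", n_pd), rep("yHC", spec$n_young))

  with_seed(spec$seed, {
    mu <- matrix(stats::rnorm(n * D, 0, spec$noise_sd), n, D)
    if (length(spec$planted_class_channels)) {
      pd_rows <- which(cls == "PD")
      mu[pd_rows, spec$planted_class_channels] <-
        mu[pd_rows, spec$planted_class_channels] +
        spec$effect_size * spec$noise_sd
    }
    if (spec$n_young > 0 && !is.null(spec$planted_targets$age)) {
      yrows <- which(grp == "yHC")
      ach <- spec$planted_targets$age$channels
      mu[yrows, ach] <- mu[yrows, ach] + spec$young_shift
    }

    meta <- data.frame(
      subject_id = sprintf("%s_%03d", spec$name, seq_len(n)),
      dataset = spec$name, class = cls, group = grp,
      in_classification = grp != "yHC",
      stringsAsFactors = FALSE
    )
    for (t in names(spec$planted_targets)) {
      tt <- spec$planted_targets[[t]]
      lin <- as.numeric(mu[, tt$channels, drop = FALSE] %*% tt$weights)
      meta[[t]] <- tt$intercept + lin + stats::rnorm(n, 0, tt$noise_sd)
    }

    t_count <- sample(seq(spec$frames_per_subject[1], spec$frames_per_subject[2]),
                      n, replace = TRUE)
    rho <- spec$channel_correlation
    frames <- lapply(seq_len(n), function(i) {
      z <- matrix(stats::rnorm(t_count[i] * D, 0, spec$noise_sd), t_count[i], D)
      if (rho > 0) {
        # AR(1) across the channel axis, stationary unit-variance scaling
        for (c_idx in 2:D) {
          z[, c_idx] <- rho * z[, c_idx - 1L] + sqrt(1 - rho^2) * z[, c_idx]
        }
      }
      frame_matrix(sweep(z, 2, mu[i, ], "+"), frame_rate = 100)
    })
    structure(list(spec = spec, frames = frames, meta = meta),
              class = "embedding_cohort")
  })
}

#' @export
print.embedding_cohort <- function(x, ...) {
  cat(sprintf("<embedding_cohort '%s': %d subjects (%s), %d channels>\n",
              x$spec$name, nrow(x$meta),
              paste(sprintf("%s=%d", names(table(x$meta$group)),
                            as.integer(table(x$meta$group))), collapse = ", "),
              x$spec$n_channels))
  invisible(x)
}

#' Pool a cohort's frame matrices into a subject-level feature table
#'
#' @param cohort An [generate_embedding_cohort()] result.
#' @param stat Pooling statistic passed to [aggregate_frames()].
#' @param prefix Feature-name prefix (default `"emb"`); features are named
#'   `<prefix>_<stat>_001` and so on.
#' @param classification_only Drop subjects flagged out of classification
#'   (the young-HC group) when TRUE.
#' @return A [feature_table()].
#' @export
pooled_feature_table <- function(cohort, stat = "mean", prefix = "emb",
                                 classification_only = FALSE) {
  stopifnot(inherits(cohort, "embedding_cohort"))
  x <- t(vapply(cohort$frames, aggregate_frames, stat = stat,
                numeric(cohort$spec$n_channels)))
  nm <- sprintf("%s_%s_%03d", prefix, stat, seq_len(ncol(x)))
  tbl <- feature_table(cohort$meta, x, nm)
  if (classification_only) {
    keep <- tbl$in_classification
    tbl <- tbl[keep, , drop = FALSE]
    class(tbl) <- c("feature_table", "data.frame")
    attr(tbl, "features") <- nm
  }
  tbl
}

#' Three-cohort synthetic study suite
#'
#' Builds the three cohorts of the study design: a syllable-repetition
#' cohort (30 HC / 30 PD), a mixed-age read-text cohort (22 elderly HC /
#' 28 PD, plus 15 young HC used only for regression, 65 subjects in all)
#' with quantitative targets `age` (years, bimodal young/elderly), `chps`
#' (characters per second) and `lrd` (loud-region duration, seconds), and
#' a second read-text cohort (21 HC / 16 PD, no age/gender metadata). The
#' read-text cohorts share their planted class channels, emulating
#' cross-lingual transfer between them, while the syllable cohort's class
#' channels are disjoint.
#'
#' @param seed Master seed; the whole suite is a pure function of it.
#' @param n_channels Embedding dimension (default 512).
#' @param effect_size Standardized class shift on planted channels
#'   (default 3).
#' @param noise_sd Channel noise standard deviation (default 1).
#' @param n_planted Planted class channels per cohort (default 30).
#' @param channel_correlation AR(1) channel correlation (default 0).
#' @return A named list of three [generate_embedding_cohort()] cohorts
#'   (`pa`, `italian`, `english`), class `cohort_suite`.
#' @export
make_three_dataset_suite <- function(seed = 1, n_channels = 512,
                                     effect_size = 3, noise_sd = 1,
                                     n_planted = 30,
                                     channel_correlation = 0) {
  sets <- with_seed(derive_seed(seed, 0), {
    shared <- sort(sample(n_channels, n_planted))
    rest <- setdiff(seq_len(n_channels), shared)
    pa <- sort(sample(rest, n_planted))
    rest <- setdiff(rest, pa)
    age <- sort(sample(rest, 8))
    rest <- setdiff(rest, age)
    chps <- sort(sample(rest, 8))
    # lrd shares 5 of its 8 driver channels with chps: both proxy
    # articulation rate, so their importance sets should overlap
    lrd <- sort(c(sample(chps, 5), sample(setdiff(rest, chps), 3)))
    list(shared = shared, pa = pa, age = age, chps = chps, lrd = lrd)
  })

  targets <- list(
    age = list(channels = sets$age, weights = rep(1.5, 8),
               intercept = 70, noise_sd = 2),
    chps = list(channels = sets$chps, weights = rep(0.5, 8),
                intercept = 12, noise_sd = 0.5),
    lrd = list(channels = sets$lrd, weights = rep(1.5, 8),
               intercept = 25, noise_sd = 2)
  )

  suite <- list(
    pa = generate_embedding_cohort(cohort_spec(
      "pa", c(HC = 30, PD = 30), n_channels = n_channels,
      planted_class_channels = sets$pa, effect_size = effect_size,
      noise_sd = noise_sd, channel_correlation = channel_correlation,
      seed = derive_seed(seed, 1))),
    italian = generate_embedding_cohort(cohort_spec(
      "italian", c(HC = 22, PD = 28), n_channels = n_channels,
      planted_class_channels = sets$shared, planted_targets = targets,
      effect_size = effect_size, noise_sd = noise_sd,
      channel_correlation = channel_correlation,
      n_young = 15, young_shift = -46 / (1.5 * 8),
      seed = derive_seed(seed, 2))),
    english = generate_embedding_cohort(cohort_spec(
      "english", c(HC = 21, PD = 16), n_channels = n_channels,
      planted_class_channels = sets$shared, effect_size = effect_size,
      noise_sd = noise_sd, channel_correlation = channel_correlation,
      seed = derive_seed(seed, 3)))
  )
  attr(suite, "planted") <- sets
  attr(suite, "seed") <- seed
  class(suite) <- "cohort_suite"
  suite
}

#' @export
print.cohort_suite <- function(x, ...) {
  cat("<cohort_suite>\n")
  for (nm in names(x)) {
    cat(" ", nm, ": ", nrow(x[[nm]]$meta), " subjects\n", sep = "")
  }
  invisible(x)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Writes the pooled feature table as tab-delimited text and a JSON
#' manifest recording the spec (name, sizes, seed, planted channels).
#'
#' @param cohort An `embedding_cohort`.
#' @param dir Output directory (created if needed).
#' @param stat Pooling statistic for the written table.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, stat = "mean") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- pooled_feature_table(cohort, stat)
  write_feature_table(tbl, file.path(dir, paste0(cohort$spec$name, "_features.tsv")))
  manifest <- cohort$spec
  manifest$planted_targets <- lapply(manifest$planted_targets, function(t) {
    t[c("channels", "weights", "intercept", "noise_sd")]
  })
  path <- file.path(dir, paste0(cohort$spec$name, "_manifest.json"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
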