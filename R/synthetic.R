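# Seeded synthetic accelerometer signals: gravity offset + activity-specific
# periodic content (fundamental + harmonics with random phases) + optional
# impulsive bursts + Gaussian noise.  The generator emulates the gross
# structure of body-worn accelerometer data — it is a test harness, not a
# biomechanical gait model.

# Local RNG scoping: functions that take a seed leave the caller's RNG
# stream untouched.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Parametric model of one activity's acceleration signal
#'
#' @param name Activity label.
#' @param fundamental_hz Fundamental movement frequency in Hz (0 for a
#'   static activity); must stay below the Nyquist rate at simulation.
#' @param harmonic_amplitudes `3 x H` matrix of per-axis amplitudes for
#'   harmonics `1..H` of the fundamental, in signal units.
#' @param gravity_vector Constant gravity projection on the three axes.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param burst_rate_hz Mean rate of impulsive bursts (Poisson-timed,
#'   exponentially decaying); 0 disables bursts.
#' @param burst_amplitude Peak amplitude of a burst.
#' @param amplitude_jitter Relative per-harmonic amplitude jitter in
#'   `[0, 1)`.
#' @return Object of class `"activity_model"`.
#' @export
activity_model <- function(name, fundamental_hz = 0,
                           harmonic_amplitudes = matrix(0, 3, 1),
                           gravity_vector = c(0, 9.80665, 0),
                           noise_sd = 0.1, burst_rate_hz = 0,
                           burst_amplitude = 0, amplitude_jitter = 0.1) {
  harmonic_amplitudes <- as.matrix(harmonic_amplitudes)
  if (nrow(harmonic_amplitudes) != 3L) {
    stop("`harmonic_amplitudes` must have one row per axis")
  }
  if (fundamental_hz < 0 || noise_sd < 0 || burst_rate_hz < 0 ||
      burst_amplitude < 0) {
    stop("rates, amplitudes and noise_sd must be non-negative")
  }
  if (amplitude_jitter < 0 || amplitude_jitter >= 1) {
    stop("`amplitude_jitter` must be in [0, 1)")
  }
  structure(
    list(name = as.character(name), fundamental_hz = fundamental_hz,
         harmonic_amplitudes = harmonic_amplitudes,
         gravity_vector = as.numeric(gravity_vector), noise_sd = noise_sd,
         burst_rate_hz = burst_rate_hz, burst_amplitude = burst_amplitude,
         amplitude_jitter = amplitude_jitter),
    class = "activity_model"
  )
}

# Harmonic series with per-axis first-harmonic amplitudes and a power-law
# decay, as in measured gait spectra where impact transients sustain
# harmonics well beyond the fundamental.
.harmonic_series <- function(a1, n_harm = 7L, decay = 1.2) {
  outer(a1, seq_len(n_harm)^(-decay))
}

#' Default activity models for the synthetic benchmark
#'
#' Six activities spanning the static-to-dynamic range typical of daily
#' living protocols: sitting and standing (static, gravity plus sensor
#' noise), walking (fundamental near 2 Hz), jogging (near 2.8 Hz, larger
#' amplitudes), stair climbing (near 1.6 Hz with axis asymmetry) and
#' jumping (impulsive bursts).  Dynamic activities carry a seven-harmonic
#' series with power-law amplitude decay — mimicking the extended
#' harmonic content that step impacts produce in real gait spectra — and
#' broadband residual noise of the order of 1 m/s^2, standing in for the
#' soft-tissue and placement variability real recordings exhibit.
#' Amplitudes are in m/s^2 by default; in `"g"` units everything is
#' divided by 9.80665, which exercises the unit-dependence of the
#' energy-to-entropy ratio.
#'
#' @param units Signal units for the models.
#' @return Named list of `"activity_model"` objects.
#' @export
default_activity_models <- function(units = c("m_per_s2", "g")) {
  units <- match.arg(units)
  g1 <- 9.80665
  models <- list(
    sitting = activity_model(
      "sitting", fundamental_hz = 0,
      gravity_vector = c(0.4, 9.3, 2.8), noise_sd = 0.06
    ),
    standing = activity_model(
      "standing", fundamental_hz = 0,
      gravity_vector = c(0.1, 9.8, 0.3), noise_sd = 0.09
    ),
    walking = activity_model(
      "walking", fundamental_hz = 2.0,
      harmonic_amplitudes = .harmonic_series(c(1.0, 1.8, 0.8)),
      gravity_vector = c(0.2, 9.7, 0.8), noise_sd = 1.0
    ),
    jogging = activity_model(
      "jogging", fundamental_hz = 2.8,
      harmonic_amplitudes = .harmonic_series(c(2.6, 4.5, 2.1)),
      gravity_vector = c(0.3, 9.6, 0.9), noise_sd = 1.5
    ),
    stairs = activity_model(
      "stairs", fundamental_hz = 1.6,
      harmonic_amplitudes = .harmonic_series(c(1.6, 1.2, 0.4)),
      gravity_vector = c(0.6, 9.5, 1.2), noise_sd = 1.0
    ),
    jumping = activity_model(
      "jumping", fundamental_hz = 1.1,
      harmonic_amplitudes = .harmonic_series(c(0.9, 1.5, 0.7), n_harm = 3L),
      gravity_vector = c(0.2, 9.7, 0.5), noise_sd = 1.2,
      burst_rate_hz = 1.1, burst_amplitude = 12
    )
  )
  if (units == "g") {
    models <- lapply(models, function(m) {
      m$harmonic_amplitudes <- m$harmonic_amplitudes / g1
      m$gravity_vector <- m$gravity_vector / g1
      m$noise_sd <- m$noise_sd / g1
      m$burst_amplitude <- m$burst_amplitude / g1
      m
    })
  }
  models
}

#' Simulate one labelled recording of an activity
#'
#' Per axis: gravity offset, plus each harmonic `h` of the fundamental as
#' a sinusoid with seeded random phase and amplitude jitter, plus seeded
#' Gaussian noise, plus (if configured) Poisson-timed exponentially
#' decaying bursts shared across axes.  Labels are constant.  The output
#' is a deterministic function of the seed.
#'
#' @param model An `"activity_model"`.
#' @param duration_s Duration in seconds.
#' @param rate Sampling rate in Hz (default 50).
#' @param seed Integer seed.
#' @param units Units tag recorded on the output (the model's amplitudes
#'   are taken as given).
#' @return A `"sensor_recording"`.
#' @export
simulate_activity <- function(model, duration_s, rate = 50, seed = 1L,
                              units = c("m_per_s2", "g")) {
  units <- match.arg(units)
  if (!inherits(model, "activity_model")) stop("`model` must be an activity_model")
  if (duration_s <= 0) stop("`duration_s` must be positive")
  n_harm <- ncol(model$harmonic_amplitudes)
  if (model$fundamental_hz > 0 && model$fundamental_hz >= rate / 2) {
    stop("fundamental frequency at or above the Nyquist rate")
  }

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  n <- as.integer(round(duration_s * rate))
  t <- (seq_len(n) - 1L) / rate
  samples <- matrix(0, n, 3L)

  for (a in 1:3) {
    x <- rep(model$gravity_vector[a], n)
    if (model$fundamental_hz > 0) {
      for (h in seq_len(n_harm)) {
        amp <- model$harmonic_amplitudes[a, h]
        if (amp == 0) next
        jit <- 1 + stats::runif(1, -model$amplitude_jitter,
                                model$amplitude_jitter)
        phase <- stats::runif(1, 0, 2 * pi)
        x <- x + amp * jit * sin(2 * pi * h * model$fundamental_hz * t + phase)
      }
    }
    if (model$noise_sd > 0) x <- x + stats::rnorm(n, 0, model$noise_sd)
    samples[, a] <- x
  }

  if (model$burst_rate_hz > 0 && model$burst_amplitude > 0) {
    n_bursts <- stats::rpois(1, model$burst_rate_hz * duration_s)
    if (n_bursts > 0) {
      times <- sort(stats::runif(n_bursts, 0, duration_s))
      axis_scale <- c(0.6, 1.0, 0.5)
      tau <- 0.05  # burst decay constant, seconds
      for (tb in times) {
        sgn <- sample(c(-1, 1), 1)
        env <- ifelse(t >= tb, exp(-(t - tb) / tau), 0)
        for (a in 1:3) {
          samples[, a] <- samples[, a] +
            sgn * axis_scale[a] * model$burst_amplitude * env
        }
      }
    }
  }

  sensor_recording(samples, labels = rep(model$name, n), sampling_rate = rate,
                   units = units, subject_id = "synthetic",
                   placement = "synthetic")
}

# Draw a subject-specific variant of an activity model: cadence scaled by
# +/-12%, overall movement amplitude by +/-30% (inter-subject variability).
.subject_variant <- function(model) {
  if (model$fundamental_hz > 0) {
    model$fundamental_hz <- model$fundamental_hz * stats::runif(1, 0.88, 1.12)
  }
  model$harmonic_amplitudes <- model$harmonic_amplitudes * stats::runif(1, 0.7, 1.3)
  model
}

#' Generate the default synthetic benchmark
#'
#' Simulates `n_subjects` synthetic subjects per activity — each subject
#' a seeded variant of the activity model with cadence and amplitude
#' drawn from inter-subject variability distributions — and segments the
#' recordings into fixed windows, producing a class-balanced labelled
#' segment collection at 50 Hz with 2.5 s windows (125 samples) by
#' default.  The between-subject variability is what keeps the benchmark
#' from being trivially separable.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param segments_per_class Windows per activity (default 120, split
#'   evenly across subjects).
#' @param n_subjects Simulated subjects per activity (default 12).
#' @param rate Sampling rate in Hz (default 50).
#' @param window_seconds Window duration (default 2.5).
#' @param units `"m_per_s2"` (default) or `"g"`.
#' @return List of labelled `"har_segment"` objects.
#' @export
make_benchmark <- function(seed = 1L, segments_per_class = 120L,
                           n_subjects = 12L, rate = 50,
                           window_seconds = 2.5,
                           units = c("m_per_s2", "g")) {
  units <- match.arg(units)
  models <- default_activity_models(units)
  per_subject <- ceiling(segments_per_class / n_subjects)
  duration <- (per_subject + 1L) * window_seconds

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  out <- list()
  for (i in seq_along(models)) {
    class_segs <- list()
    for (s in seq_len(n_subjects)) {
      variant <- .subject_variant(models[[i]])
      rec <- simulate_activity(variant, duration_s = duration, rate = rate,
                               seed = sample.int(2147483646L, 1L),
                               units = units)
      rec$subject_id <- sprintf("S%02d", s)
      class_segs <- c(class_segs,
                      segment_recording(rec, window_seconds = window_seconds))
    }
    out <- c(out, class_segs[seq_len(min(segments_per_class,
                                         length(class_segs)))])
  }
  out
}

#' Signals matched to a given mother wavelet
#'
#' Builds segments whose energy is, by construction, concentrated in a
#' handful of packet coefficients under the generating wavelet: each axis
#' is the inverse packet transform of a level-3 coefficient set with
#' `sparsity` seeded nonzero entries, plus Gaussian noise.  Under the
#' generating wavelet such signals have near-minimal entropy and hence a
#' near-maximal energy-to-entropy ratio — the matched-wavelet premise the
#' selection procedure rests on.
#'
#' @param wavelet Generating wavelet (name or spec).
#' @param n_signals Number of segments.
#' @param sparsity Number of nonzero coefficients per axis (>= 1; use 2
#'   or more to keep the entropy strictly positive).
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer seed.
#' @param window_length Samples per segment (default 125, padded to 128
#'   inside the transform).
#' @param level Decomposition level of the generating packet (default 3).
#' @return List of `"har_segment"` objects labelled `"matched"`.
#' @export
matched_wavelet_signals <- function(wavelet, n_signals = 20L, sparsity = 2L,
                                    noise_sd = 0.02, seed = 1L,
                                    window_length = 125L, level = 3L) {
  w <- wavelet_filters(wavelet)
  sparsity <- as.integer(sparsity)
  if (sparsity < 1L) stop("`sparsity` must be at least 1")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  block <- as.integer(2^level)
  padded <- block * ((window_length + block - 1L) %/% block)
  node_len <- padded %/% block

  lapply(seq_len(n_signals), function(i) {
    samples <- vapply(1:3, function(a) {
      coefs <- numeric(padded)
      pos <- sample.int(padded, sparsity)
      coefs[pos] <- stats::rnorm(sparsity, 0, 1) + sign(stats::rnorm(sparsity))
      pk <- structure(
        list(wavelet_name = w$name, level = level,
             nodes = split(coefs, rep(seq_len(block), each = node_len)),
             original_length = window_length, padded_length = padded),
        class = "wpt_packet"
      )
      x <- wpt_reconstruct(pk, w)[seq_len(window_length)]
      x + stats::rnorm(window_length, 0, noise_sd)
    }, numeric(window_length))
    har_segment(samples, label = "matched", subject_id = "synthetic",
                placement = "synthetic")
  })
}

#' Write a synthetic benchmark as per-subject recording files
#'
#' Simulates the default activities for `n_subjects` synthetic subjects
#' each and writes one CSV per (activity, subject) pair (columns
#' `t, x, y, z, label`) plus a `manifest.csv` with file, subject,
#' placement, units and sampling rate — the same delimited layout
#' [read_recording()] consumes, so the full file-based pipeline can be
#' exercised end to end.
#'
#' @inheritParams make_benchmark
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_benchmark <- function(dir, seed = 1L, segments_per_class = 120L,
                            n_subjects = 12L, rate = 50,
                            window_seconds = 2.5,
                            units = c("m_per_s2", "g")) {
  units <- match.arg(units)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  models <- default_activity_models(units)
  per_subject <- ceiling(segments_per_class / n_subjects)
  duration <- (per_subject + 1L) * window_seconds

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  rows <- list()
  for (i in seq_along(models)) {
    for (s in seq_len(n_subjects)) {
      variant <- .subject_variant(models[[i]])
      rec <- simulate_activity(variant, duration_s = duration, rate = rate,
                               seed = sample.int(2147483646L, 1L),
                               units = units)
      fn <- sprintf("%s_S%02d.csv", models[[i]]$name, s)
      df <- data.frame(
        t = (seq_len(nrow(rec$samples)) - 1L) / rate,
        x = rec$samples[, 1L], y = rec$samples[, 2L], z = rec$samples[, 3L],
        label = rec$labels
      )
      utils::write.csv(df, file.path(dir, fn), row.names = FALSE,
                       quote = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        file = fn, subject_id = sprintf("S%02d", s),
        placement = rec$placement, units = units,
        sampling_rate = rate, stringsAsFactors = FALSE
      )
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  invisible(manifest)
}
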