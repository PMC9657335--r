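#' Motor unit description
#'
#' A motor unit (MU) is one motor neuron plus the muscle fibres it
#' innervates; it is the elementary source of the intramuscular EMG.
#' Each MU contributes a motor unit potential train (MUPT): a stereotyped
#' biphasic waveform repeated at its firing times.
#'
#' @param template_amplitude Peak absolute amplitude of the motor unit
#'   potential, in signal units. Must be >= 0.
#' @param template_duration Duration of the potential waveform in
#'   milliseconds. Must be > 0.
#' @param mean_firing_rate Mean discharge rate in Hz. Must be >= 0.
#' @param firing_jitter_cv Coefficient of variation of the inter-pulse
#'   intervals, dimensionless, in `[0, 1)`.
#' @return An object of class `motor_unit`.
#' @export
#' @examples
#' motor_unit(1, 8, 12, 0.15)
motor_unit <- function(template_amplitude, template_duration,
                       mean_firing_rate, firing_jitter_cv = 0.15) {
  check_scalar_number(template_amplitude, "template_amplitude", lower = 0)
  check_scalar_number(template_duration, "template_duration", lower = 0, strict_lower = TRUE)
  check_scalar_number(mean_firing_rate, "mean_firing_rate", lower = 0)
  check_scalar_number(firing_jitter_cv, "firing_jitter_cv", lower = 0, upper = 1,
                      strict_upper = TRUE)
  structure(
    list(template_amplitude = template_amplitude,
         template_duration = template_duration,
         mean_firing_rate = mean_firing_rate,
         firing_jitter_cv = firing_jitter_cv),
    class = "motor_unit"
  )
}

#' Lesion regime
#'
#' Parameterizes the post-lesion contrast the classifiers must detect:
#' after a spinal cord lesion fewer motor units are recruited, survivors
#' fire more slowly, and their potentials are attenuated. The identity
#' regime `(1, 1, 1)` reproduces pre-lesion statistics exactly.
#'
#' @param recruitment_fraction Fraction of motor units still active, in `[0, 1]`.
#' @param rate_scale Multiplier on mean firing rates, in `(0, 1]`.
#' @param amplitude_scale Multiplier on template amplitudes, in `(0, 1]`.
#' @return An object of class `lesion_regime`.
#' @export
#' @examples
#' lesion_regime()              # package default post-lesion contrast
#' lesion_regime(1, 1, 1)       # identity: indistinguishable from pre-lesion
lesion_regime <- function(recruitment_fraction = 0.5, rate_scale = 0.8,
                          amplitude_scale = 0.6) {
  check_scalar_number(recruitment_fraction, "recruitment_fraction", lower = 0, upper = 1)
  check_scalar_number(rate_scale, "rate_scale", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar_number(amplitude_scale, "amplitude_scale", lower = 0, upper = 1,
                      strict_lower = TRUE)
  structure(
    list(recruitment_fraction = recruitment_fraction,
         rate_scale = rate_scale,
         amplitude_scale = amplitude_scale),
    class = "lesion_regime"
  )
}

#' Simulation configuration
#'
#' Settings for one synthetic intramuscular EMG recording. The default
#' sampling rate of 1000 Hz gives one sample per millisecond, so a
#' 1000 ms analysis window is exactly 1000 samples; it also leaves the
#' 450 Hz conditioning cutoff below Nyquist. The sampling rate must
#' exceed 900 Hz so that cutoff stays realizable.
#'
#' When `motor_units` is `NULL` a motor unit pool is drawn at random
#' (seeded) from broad physiological ranges: peak amplitudes 0.5-1.5
#' signal units, waveform durations 4-12 ms, mean firing rates 8-20 Hz,
#' inter-pulse jitter CV 0.15.
#'
#' @param sampling_rate Sampling rate in Hz; must be > 900.
#' @param duration Recording duration in seconds; must be > 0.
#' @param n_motor_units Number of motor units in the pool; >= 0.
#' @param noise_sigma Standard deviation of additive zero-mean Gaussian
#'   background noise, in signal units; >= 0.
#' @param lesion A [lesion_regime()] or `NULL` for a pre-lesion recording.
#' @param seed Integer seed; the recording is a pure function of the
#'   configuration including this seed.
#' @param motor_units Optional list of [motor_unit()] objects overriding
#'   the random pool (its length then overrides `n_motor_units`).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 1000, duration = 2,
                              n_motor_units = 20, noise_sigma = 0.05,
                              lesion = NULL, seed = 1, motor_units = NULL) {
  check_scalar_number(sampling_rate, "sampling_rate", lower = 2 * 450,
                      strict_lower = TRUE)
  check_scalar_number(duration, "duration", lower = 0, strict_lower = TRUE)
  n_motor_units <- check_count(n_motor_units, "n_motor_units")
  check_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  if (!is.null(lesion) && !inherits(lesion, "lesion_regime")) {
    stop_invalid("lesion must be a lesion_regime or NULL")
  }
  if (!is.null(motor_units)) {
    if (!all(vapply(motor_units, inherits, logical(1), "motor_unit"))) {
      stop_invalid("motor_units must be a list of motor_unit objects")
    }
    n_motor_units <- length(motor_units)
  }
  structure(
    list(sampling_rate = sampling_rate, duration = duration,
         n_motor_units = n_motor_units, noise_sigma = noise_sigma,
         lesion = lesion, seed = seed, motor_units = motor_units),
    class = "simulation_config"
  )
}

#' Biphasic motor unit potential template
#'
#' Generates the per-discharge waveform as the first derivative of a
#' Gaussian: a smooth, band-limited, biphasic shape that is the standard
#' minimal surrogate for an intramuscular motor unit potential. The
#' waveform is mean-subtracted and then peak-normalized so its maximum
#' absolute value equals `amplitude` and its sample mean is zero.
#'
#' @param amplitude Peak absolute value of the returned waveform (>= 0).
#' @param duration_ms Waveform duration in milliseconds (> 0).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @return Numeric vector of length `round(duration_ms * sampling_rate / 1000)`.
#' @export
#' @examples
#' w <- generate_mup_template(1, 8, 1000)
#' max(abs(w))   # exactly 1
#' mean(w)       # ~ 0
generate_mup_template <- function(amplitude, duration_ms, sampling_rate) {
  check_scalar_number(amplitude, "amplitude", lower = 0)
  check_scalar_number(duration_ms, "duration_ms", lower = 0, strict_lower = TRUE)
  check_scalar_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  n <- round(duration_ms * sampling_rate / 1000)
  if (n < 1) {
    return(numeric(0))
  }
  # time axis centred on 0, in units of the Gaussian width; the support
  # spans +/- 3 sigma so the waveform decays essentially to zero at the ends
  t <- seq(-3, 3, length.out = n)
  w <- -t * exp(-t^2 / 2)
  w <- w - mean(w)
  peak <- max(abs(w))
  if (peak == 0) {
    return(rep(0, n))
  }
  amplitude * w / peak
}

#' Simulate the discharge times of one motor unit
#'
#' Motor units fire repeatedly; this draws one spike train as
#' Gaussian-perturbed regular inter-pulse intervals. Interval mean is
#' `1 / rate_hz`, interval standard deviation is `jitter_cv / rate_hz`,
#' and intervals are truncated below at 1 ms so the train stays strictly
#' increasing. The train phase is randomized by drawing the first
#' discharge uniformly inside the first mean interval.
#'
#' @param rate_hz Mean firing rate in Hz (>= 0). A silent unit (`0`) yields
#'   an empty train.
#' @param duration_s Duration in seconds (>= 0).
#' @param jitter_cv Coefficient of variation of inter-pulse intervals,
#'   in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical trains.
#' @return Strictly increasing numeric vector of discharge times in
#'   `[0, duration_s)`, seconds.
#' @export
#' @examples
#' generate_firing_train(10, 1, 0.1, seed = 7)
generate_firing_train <- function(rate_hz, duration_s, jitter_cv = 0.15, seed = 1) {
  check_scalar_number(rate_hz, "rate_hz", lower = 0)
  check_scalar_number(duration_s, "duration_s", lower = 0)
  check_scalar_number(jitter_cv, "jitter_cv", lower = 0, upper = 1, strict_upper = TRUE)
  if (rate_hz == 0 || duration_s == 0) {
    return(numeric(0))
  }
  mean_ipi <- 1 / rate_hz
  sd_ipi <- jitter_cv * mean_ipi
  with_seed(seed, {
    # generous upper bound on the number of intervals needed
    n_max <- ceiling(duration_s / mean_ipi * (1 + 4 * jitter_cv)) + 10L
    ipis <- pmax(stats::rnorm(n_max, mean_ipi, sd_ipi), 1e-3)
    t0 <- stats::runif(1, 0, mean_ipi)
    times <- t0 + cumsum(c(0, ipis))
    while (times[length(times)] < duration_s) {
      extra <- pmax(stats::rnorm(n_max, mean_ipi, sd_ipi), 1e-3)
      times <- c(times, times[length(times)] + cumsum(extra))
    }
    times[times < duration_s]
  })
}

draw_motor_unit_pool <- function(n, seed) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      motor_unit(
        template_amplitude = stats::runif(1, 0.5, 1.5),
        template_duration = stats::runif(1, 4, 12),
        mean_firing_rate = stats::runif(1, 8, 20),
        firing_jitter_cv = 0.15
      )
    })
  })
}

#' Synthesize one labelled EMG recording
#'
#' The recording is the linear superposition of the motor unit potential
#' trains of all active units plus additive zero-mean Gaussian background
#' noise. If the configuration carries a [lesion_regime()], only
#' `round(recruitment_fraction * n_motor_units)` units remain active,
#' with firing rates scaled by `rate_scale` and amplitudes by
#' `amplitude_scale`, and the recording is labelled post-lesion (class 1);
#' otherwise it is labelled pre-lesion (class 0).
#'
#' @param config A [simulation_config()].
#' @param meta Named list of provenance tags (subject, side, day, ...).
#' @return An `emg_recording`: list with `samples`, `sampling_rate`,
#'   `label` (0 = pre-lesion, 1 = post-lesion) and `meta`.
#' @export
#' @examples
#' rec <- synthesize_recording(simulation_config(duration = 1, seed = 3))
#' rec$label
#' length(rec$samples)
synthesize_recording <- function(config, meta = list()) {
  if (!inherits(config, "simulation_config")) {
    stop_invalid("config must be a simulation_config")
  }
  fs <- config$sampling_rate
  n_samples <- round(config$duration * fs)
  pool <- config$motor_units
  if (is.null(pool)) {
    pool <- draw_motor_unit_pool(config$n_motor_units, derive_seed(config$seed, "mu_pool"))
  }
  lesioned <- !is.null(config$lesion)
  if (lesioned) {
    n_active <- round(config$lesion$recruitment_fraction * length(pool))
    pool <- pool[seq_len(n_active)]
  }
  samples <- numeric(n_samples)
  for (i in seq_along(pool)) {
    mu <- pool[[i]]
    rate <- mu$mean_firing_rate
    amp <- mu$template_amplitude
    if (lesioned) {
      rate <- rate * config$lesion$rate_scale
      amp <- amp * config$lesion$amplitude_scale
    }
    template <- generate_mup_template(amp, mu$template_duration, fs)
    if (length(template) == 0) next
    times <- generate_firing_train(rate, config$duration, mu$firing_jitter_cv,
                                   seed = derive_seed(config$seed, paste0("mu_train_", i)))
    for (t0 in times) {
      start <- round(t0 * fs) + 1L
      stop_at <- min(start + length(template) - 1L, n_samples)
      if (start > n_samples) next
      k <- stop_at - start + 1L
      samples[start:stop_at] <- samples[start:stop_at] + template[seq_len(k)]
    }
  }
  if (config$noise_sigma > 0) {
    noise <- with_seed(derive_seed(config$seed, "noise"),
                       stats::rnorm(n_samples, 0, config$noise_sigma))
    samples <- samples + noise
  }
  structure(
    list(samples = samples, sampling_rate = fs,
         label = if (lesioned) 1L else 0L, meta = meta),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples @ %g Hz, label = %d (%s)\n",
              length(x$samples), x$sampling_rate, x$label,
              if (x$label == 1L) "post-lesion" else "pre-lesion"))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate a labelled dataset of synthetic recordings
#'
#' Produces `n_pre` pre-lesion and `n_post` post-lesion recordings.
#' Every recording gets its own seed derived from the master seed, so the
#' whole dataset is reproducible from `seed` alone while recordings stay
#' statistically independent. Provenance tags (`subject`, `side`, `day`)
#' are assigned cyclically over five subjects and two sides.
#'
#' @param n_pre Number of pre-lesion recordings (>= 0).
#' @param n_post Number of post-lesion recordings (>= 0).
#' @param base_config A [simulation_config()] giving the shared settings.
#' @param lesion The [lesion_regime()] applied to post-lesion recordings.
#' @param seed Master integer seed.
#' @return List of `emg_recording` objects, pre-lesion first.
#' @export
#' @examples
#' ds <- generate_dataset(2, 3, simulation_config(duration = 1), lesion_regime(), seed = 1)
#' table(vapply(ds, `[[`, integer(1), "label"))
generate_dataset <- function(n_pre, n_post, base_config = simulation_config(),
                             lesion = lesion_regime(), seed = 1) {
  n_pre <- check_count(n_pre, "n_pre")
  n_post <- check_count(n_post, "n_post")
  if (!inherits(base_config, "simulation_config")) {
    stop_invalid("base_config must be a simulation_config")
  }
  make_one <- function(i, lesioned) {
    tag <- paste0(if (lesioned) "post" else "pre", "_", i)
    cfg <- base_config
    cfg$seed <- derive_seed(seed, tag)
    cfg$lesion <- if (lesioned) lesion else NULL
    meta <- list(subject = ((i - 1L) %% 5L) + 1L,
                 side = if (i %% 2L == 0L) "left" else "right",
                 day = i)
    synthesize_recording(cfg, meta = meta)
  }
  c(lapply(seq_len(n_pre), make_one, lesioned = FALSE),
    lapply(seq_len(n_post), make_one, lesioned = TRUE))
}

#' Write / read one recording as delimited text
#'
#' One file per recording: header comment lines (`# fs=`, `# label=`,
#' `# meta ...`), then one sample per line at full double precision, so a
#' round trip is lossless to better than 1e-12 relative.
#'
#' @param recording An `emg_recording`.
#' @param path Output file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `emg_recording`.
#' @export
write_recording <- function(recording, path) {
  if (!inherits(recording, "emg_recording")) {
    stop_invalid("recording must be an emg_recording")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", recording$sampling_rate), con)
  writeLines(sprintf("# label=%d", recording$label), con)
  for (nm in names(recording$meta)) {
    writeLines(sprintf("# meta %s=%s", nm, as.character(recording$meta[[nm]])), con)
  }
  writeLines(sprintf("%.17g", recording$samples), con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  fs_line <- sub("^# fs=", "", header[startsWith(header, "# fs=")])
  label_line <- sub("^# label=", "", header[startsWith(header, "# label=")])
  meta_lines <- header[startsWith(header, "# meta ")]
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^# meta ", "", ml), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  structure(
    list(samples = as.numeric(lines[!is_header]),
         sampling_rate = as.numeric(fs_line),
         label = as.integer(label_line),
         meta = meta),
    class = "emg_recording"
  )
}

#' Write / read a whole dataset directory
#'
#' Persists each recording with [write_recording()] plus a `manifest.csv`
#' listing file names and labels.
#'
#' @param recordings List of `emg_recording` objects.
#' @param dir Output directory (created if absent).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns
#'   the list of recordings in manifest order.
#' @export
write_dataset <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("recording_%04d.txt", seq_along(recordings))
  for (i in seq_along(recordings)) {
    write_recording(recordings[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(
    file = files,
    label = vapply(recordings, `[[`, integer(1), "label")
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(manifest$file, function(f) read_recording(file.path(dir, f)))
}
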