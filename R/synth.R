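# Seeded synthetic multi-patient EEG cohort generator: patient-specific
# baseline statistics, autocorrelated background noise, and rare seizure
# episodes carrying a shared band-limited oscillatory signature.

#' Synthetic cohort configuration
#'
#' Describes a multi-patient scalp EEG cohort: each patient's background
#' is a per-channel constant offset plus autocorrelated (AR(1), low-pass
#' like) noise with a patient-specific amplitude scale; seizure episodes
#' arrive as a Poisson process with gamma-distributed durations and add a
#' sinusoidal signature in a low-frequency band with fixed per-channel
#' gains shared by all patients (the cross-patient "common epilepsy
#' feature"), while the offsets/scales are the patient-specific
#' nuisance.
#'
#' @param n_patients Number of patients.
#' @param channels Electrode channels per recording.
#' @param sampling_rate Hz.
#' @param duration_s Record length per patient (seconds).
#' @param seizure_rate_per_hour Mean seizure episodes per hour.
#' @param seizure_duration_mean Mean episode duration (seconds).
#' @param seizure_duration_shape Gamma shape of the duration law.
#' @param signature_freq_band Frequency band (Hz) the seizure
#'   oscillation is drawn from; the low-frequency range of rhythmic
#'   ictal discharges.
#' @param signature_amplitude Oscillation amplitude in units of the
#'   background noise standard deviation (0 disables the signature while
#'   keeping the annotations, for null calibration).
#' @param channel_gain_range Per-channel signature gain range (drawn
#'   once per cohort).
#' @param baseline_offset_sd Standard deviation of per-patient
#'   per-channel constant offsets.
#' @param baseline_scale_range Range of per-patient noise amplitude
#'   scales.
#' @param noise_sd Background noise standard deviation.
#' @param ar_coef AR(1) coefficient of the background noise.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10, channels = 4,
                          sampling_rate = 32, duration_s = 360,
                          seizure_rate_per_hour = 30,
                          seizure_duration_mean = 10,
                          seizure_duration_shape = 4,
                          signature_freq_band = c(3, 6),
                          signature_amplitude = 3,
                          channel_gain_range = c(0.5, 1),
                          baseline_offset_sd = 1,
                          baseline_scale_range = c(0.8, 1.25),
                          noise_sd = 1, ar_coef = 0.9, seed = 1L) {
  stopifnot(n_patients >= 1, channels >= 1, sampling_rate > 0,
            duration_s > 0, seizure_rate_per_hour > 0,
            seizure_duration_mean > 0, seizure_duration_shape > 0,
            signature_amplitude >= 0, noise_sd > 0,
            ar_coef >= 0, ar_coef < 1)
  if (seizure_duration_mean >= duration_s) {
    stop("mean episode duration must be shorter than the record.",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic multi-patient EEG cohort
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per patient: `patient_id`,
#'   `sampling_rate`, `data` (channels x samples matrix), and
#'   `annotations` (tibble of half-open seizure intervals `start_s`,
#'   `end_s`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n_s <- as.integer(round(config$duration_s * config$sampling_rate))
  gains <- stats::runif(config$channels, config$channel_gain_range[1],
                        config$channel_gain_range[2])
  e_sd <- config$noise_sd * sqrt(1 - config$ar_coef^2)
  rows <- lapply(seq_len(config$n_patients), function(p) {
    offset <- stats::rnorm(config$channels, 0, config$baseline_offset_sd)
    sc <- stats::runif(1, config$baseline_scale_range[1],
                       config$baseline_scale_range[2])
    data <- t(vapply(seq_len(config$channels), function(ch) {
      noise <- as.numeric(stats::filter(stats::rnorm(n_s, 0, e_sd),
                                        config$ar_coef,
                                        method = "recursive"))
      offset[ch] + sc * noise
    }, numeric(n_s)))
    # Poisson episode starts with gamma durations, rejecting overlaps
    n_ep <- stats::rpois(1, config$seizure_rate_per_hour *
                           config$duration_s / 3600)
    iv <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(iv) < n_ep && tries < 200L) {
      tries <- tries + 1L
      d <- stats::rgamma(1, shape = config$seizure_duration_shape,
                         rate = config$seizure_duration_shape /
                           config$seizure_duration_mean)
      if (d >= config$duration_s) {
        stop("seizure episode longer than the record; adjust the ",
             "duration distribution.", call. = FALSE)
      }
      st <- stats::runif(1, 0, config$duration_s - d)
      if (nrow(iv) == 0 ||
          all(st + d <= iv[, 1] | st >= iv[, 2])) {
        iv <- rbind(iv, c(st, st + d))
      }
    }
    if (nrow(iv) > 0) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      for (k in seq_len(nrow(iv))) {
        i0 <- floor(iv[k, 1] * config$sampling_rate) + 1L
        i1 <- min(n_s, ceiling(iv[k, 2] * config$sampling_rate))
        tt <- (seq(i0, i1) - i0) / config$sampling_rate
        f <- stats::runif(1, config$signature_freq_band[1],
                          config$signature_freq_band[2])
        phase <- stats::runif(1, 0, 2 * pi)
        osc <- config$signature_amplitude * config$noise_sd *
          sin(2 * pi * f * tt + phase)
        data[, i0:i1] <- data[, i0:i1] +
          outer(gains, osc)
      }
    }
    tibble::tibble(patient_id = sprintf("P%02d", p),
                   sampling_rate = config$sampling_rate,
                   data = list(data),
                   annotations = list(tibble::tibble(
                     start_s = iv[, 1], end_s = iv[, 2])))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  out
}

#' Window a whole cohort into labeled segments
#'
#' Applies [segment_recording()] to every patient of a generated (or
#' assembled) cohort tibble.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param window_seconds Window length in seconds.
#' @param overlap_threshold Passed to [segment_recording()].
#' @return A segments tibble over all patients.
#' @export
segment_cohort <- function(cohort, window_seconds,
                           overlap_threshold = 0.5) {
  dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
    rec <- new_recording(cohort$data[[i]], cohort$sampling_rate[i],
                         sprintf("ch%02d", seq_len(nrow(cohort$data[[i]]))),
                         cohort$patient_id[i])
    segment_recording(rec, cohort$annotations[[i]], window_seconds,
                      overlap_threshold)
  }))
}
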