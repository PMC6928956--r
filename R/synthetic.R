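# Synthetic multi-subject cohort generator. Emulates triaxial accelerometer
# streams where every subject performs every activity for the same duration,
# and where each subject deviates systematically (gain, offset, frequency)
# from the class's base pattern, so user-independent models are imperfect and
# personalization has something real to learn.

#' Default per-class signal parameters
#'
#' Builds a class parameter table with amplitudes and fundamental frequencies
#' spread over ranges typical of wrist/pocket accelerometry (fractions of g,
#' sub-3 Hz gait-band frequencies) and per-axis mean offsets placed on a circle
#' so neighbouring classes overlap once subject-level deviations are added.
#'
#' @param class_names character vector of class labels.
#' @return A data.frame with columns `class`, `amplitude`, `frequency_hz`,
#'   `offset_x`, `offset_y`, `offset_z`.
#' @export
default_class_params <- function(class_names) {
  k <- length(class_names)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  data.frame(
    class = class_names,
    amplitude = seq(0.25, 1.6, length.out = k),
    frequency_hz = seq(0.4, 2.0, length.out = k),
    offset_x = 0.4 * cos(ang),
    offset_y = 0.4 * sin(ang),
    offset_z = 0.25 * cos(2 * ang),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Each subject records one contiguous block per activity class of
#' `seconds_per_class` seconds at `sampling_rate_hz`. The class base pattern on
#' axis a is `amplitude * sin(2*pi*frequency_hz*t + phase_a) + offset_a` with
#' axis phases fixed at (0, 2*pi/3, 4*pi/3). Per subject *and* class the
#' generator draws once a gain ~ N(1, `subject_gain_sd`), a per-axis offset
#' ~ N(0, `subject_offset_sd`) and a frequency factor ~ N(1, `subject_freq_sd`),
#' then adds iid N(0, `noise_sd`) noise per sample. Drawing the deviations per
#' subject-and-class guarantees the user-independent model is imperfect for
#' every class, not just globally.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param class_names activity class labels (>= 2).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param seconds_per_class seconds of data per subject per class.
#' @param class_params per-class table as in [default_class_params()];
#'   `NULL` uses the defaults for `class_names`.
#' @param subject_gain_sd sd of the multiplicative subject gain (unitless).
#' @param subject_offset_sd sd of the additive per-axis subject offset
#'   (signal units).
#' @param subject_freq_sd sd of the multiplicative frequency factor (unitless).
#' @param noise_sd sd of the per-sample white noise (signal units).
#' @param seed integer seed; identical config + seed gives bit-identical output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 8,
                             class_names = c("idle", "walk", "stairs", "jog", "bike"),
                             sampling_rate_hz = 50,
                             seconds_per_class = 120,
                             class_params = NULL,
                             subject_gain_sd = 0.15,
                             subject_offset_sd = 0.3,
                             subject_freq_sd = 0.05,
                             noise_sd = 0.2,
                             seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2)
  if (!is.character(class_names) || length(class_names) < 2L ||
      anyDuplicated(class_names)) {
    stop_invalid("class_names", "must be >= 2 unique class labels")
  }
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", min = 0, strict = TRUE)
  check_scalar_number(seconds_per_class, "seconds_per_class", min = 0, strict = TRUE)
  check_scalar_number(subject_gain_sd, "subject_gain_sd", min = 0)
  check_scalar_number(subject_offset_sd, "subject_offset_sd", min = 0)
  check_scalar_number(subject_freq_sd, "subject_freq_sd", min = 0)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  seed <- check_count(seed, "seed")

  class_params <- class_params %||% default_class_params(class_names)
  needed <- c("class", "amplitude", "frequency_hz", "offset_x", "offset_y", "offset_z")
  if (!is.data.frame(class_params) || !all(needed %in% names(class_params))) {
    stop_invalid("class_params",
                 paste("must be a data.frame with columns", paste(needed, collapse = ", ")))
  }
  if (!setequal(class_params$class, class_names)) {
    stop_invalid("class_params", "rows must match class_names exactly")
  }
  class_params <- class_params[match(class_names, class_params$class), , drop = FALSE]

  structure(
    list(
      n_subjects = n_subjects, class_names = class_names,
      sampling_rate_hz = sampling_rate_hz, seconds_per_class = seconds_per_class,
      class_params = class_params, subject_gain_sd = subject_gain_sd,
      subject_offset_sd = subject_offset_sd, subject_freq_sd = subject_freq_sd,
      noise_sd = noise_sd, seed = seed
    ),
    class = "synthetic_config"
  )
}

axis_phases <- c(0, 2 * pi / 3, 4 * pi / 3)

generate_subject <- function(config, subject_index) {
  set.seed(derive_seed(config$seed, subject_index))
  n_per <- round(config$seconds_per_class * config$sampling_rate_hz)
  tt <- (seq_len(n_per) - 1) / config$sampling_rate_hz
  chans <- list(acc_x = list(), acc_y = list(), acc_z = list())
  for (ci in seq_along(config$class_names)) {
    p <- config$class_params[ci, ]
    gain <- rnorm(1, 1, config$subject_gain_sd)
    freq_fac <- rnorm(1, 1, config$subject_freq_sd)
    offs <- rnorm(3, 0, config$subject_offset_sd)
    phase_arg <- 2 * pi * p$frequency_hz * freq_fac * tt
    class_offs <- c(p$offset_x, p$offset_y, p$offset_z)
    for (a in 1:3) {
      chans[[a]][[ci]] <- p$amplitude * gain * sin(phase_arg + axis_phases[a]) +
        class_offs[a] + offs[a] + rnorm(n_per, 0, config$noise_sd)
    }
  }
  raw_recording(
    subject_id = sprintf("S%02d", subject_index),
    sampling_rate_hz = config$sampling_rate_hz,
    channels = lapply(chans, function(x) unlist(x, use.names = FALSE)),
    labels = rep(config$class_names, each = n_per)
  )
}

#' Generate a synthetic multi-subject cohort
#'
#' Produces one [raw_recording()] per subject with three channels
#' (`acc_x`, `acc_y`, `acc_z`) and one contiguous labeled block per class.
#' Each subject's pseudo-random stream is derived from `(seed, subject index)`
#' via [derive_seed()], so cohorts are reproducible and a subject's data does
#' not depend on how many subjects are generated before it.
#'
#' @param config a [synthetic_config()].
#' @return A list of `raw_recording` objects, one per subject.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects = 2, seconds_per_class = 10))
#' table(cohort[[1]]$labels)
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_invalid("config", "must be a synthetic_config object")
  }
  lapply(seq_len(config$n_subjects), function(i) generate_subject(config, i))
}

#' Write a cohort as one CSV recording per subject
#'
#' @param cohort list of `raw_recording` objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cohort, function(rec) {
    path <- file.path(dir, paste0(rec$subject_id, ".csv"))
    write_recording(rec, path)
    path
  }, character(1))
  invisible(paths)
}
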