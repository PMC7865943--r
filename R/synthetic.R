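#' Default activity templates
#'
#' Loads the frozen per-activity signal templates shipped with the
#' package.  Static postures (SIT, STAND, LIE) are constant channel
#' offsets distinguished mainly by the Euler angles and the airbag
#' pressure baseline; gait activities are harmonic oscillations
#' (walking ~1.2 Hz, running ~2.5 Hz, stair climbing ~1 Hz with
#' asymmetric harmonics), with stair ascent and descent separated by
#' the Euler-pitch offset and the harmonic phase.  All fundamentals sit
#' well below the 10 Hz Nyquist frequency of the 20 Hz node.
#'
#' @return named list of 7 activity templates.
#' @export
default_templates <- function() {
  path <- system.file("extdata", "activity_templates.json",
                      package = "ipljpda")
  tpl <- jsonlite::read_json(path, simplifyVector = TRUE)
  tpl$comment <- NULL
  tpl[har_activities()]
}

#' Draw a subject-specific domain shift
#'
#' Inter-subject variation is modeled as an affine distortion plus a
#' frequency warp, shared across that subject's activities: a per-channel
#' gain `~ Normal(1, (0.10 difficulty)^2)` (resampled while <= 0.1), a
#' per-channel additive offset `~ Normal(0, (1.8 difficulty s_ch)^2)`
#' scaled by a characteristic channel scale `s_ch`, and one frequency
#' scale `~ Normal(1, (0.05 difficulty)^2)` clipped to `[0.5, 1.6]`.
#' At difficulty 0 every parameter collapses to its identity value.
#' The composition is deliberately translation-dominant: for body-worn
#' nodes the largest between-user differences come from mounting
#' position and strap tightness (baseline offsets), with milder
#' amplitude scaling and cadence (frequency) differences.
#'
#' @param difficulty non-negative shift magnitude (0 = identical
#'   subjects; 1 = default realistic cross-subject shift).
#' @param rng seeded RNG from the caller (internal use); when `NULL` the
#'   global RNG stream is used.
#' @param profile per-unit-difficulty standard deviations of the three
#'   shift components (`gain_sd`, `offset_sd`, `freq_sd`).  The defaults
#'   are the package's frozen calibration; override only for studying
#'   the generator itself.
#' @return object of class `subject_shift`: list with `gain` and
#'   `offset` (length-10, named by channel) and scalar `freq_scale`.
#' @export
subject_shift <- function(difficulty = 1, rng = NULL,
                          profile = list(gain_sd = 0.10, offset_sd = 1.8,
                                         freq_sd = 0.05)) {
  stopifnot(difficulty >= 0)
  rnorm_ <- if (is.null(rng)) stats::rnorm else rng$rnorm
  channel_scale <- c(pressure = 2.5,
                     acc_x = 0.15, acc_y = 0.15, acc_z = 0.15,
                     gyro_x = 25, gyro_y = 25, gyro_z = 25,
                     euler_roll = 8, euler_pitch = 8, euler_yaw = 8)
  gain <- rnorm_(10, 1, profile$gain_sd * difficulty)
  for (i in which(gain <= 0.1)) {
    while (gain[i] <= 0.1) gain[i] <- rnorm_(1, 1,
                                             profile$gain_sd * difficulty)
  }
  offset <- rnorm_(10, 0, 1) * profile$offset_sd * difficulty *
    channel_scale
  freq <- min(max(rnorm_(1, 1, profile$freq_sd * difficulty), 0.5), 1.6)
  structure(list(gain = stats::setNames(gain, har_channels()),
                 offset = stats::setNames(offset, har_channels()),
                 freq_scale = freq),
            class = "subject_shift")
}

# identity shift (difficulty 0)
.zero_shift <- function() subject_shift(difficulty = 0)

#' Generate one subject's labeled recording
#'
#' Concatenates one bout per activity, each long enough to yield
#' `segments_per_class` pure 2 s / 50%-overlap windows (bout length
#' `20 * (segments_per_class + 1)` samples at 20 Hz), applies the
#' subject's gain/offset/frequency shift, clamps the pressure channel at
#' 0 kPa, and labels every sample.  Fully determined by `seed`.
#'
#' @param templates activity templates from [default_templates()].
#' @param shift a [subject_shift()].
#' @param segments_per_class pure windows wanted per activity
#'   (default 68).
#' @param seed integer seed.
#' @param subject_id subject identifier.
#' @param sample_rate sampling rate in Hz (default 20).
#' @return a [sensor_recording()].
#' @export
generate_subject <- function(templates = default_templates(),
                             shift = .zero_shift(),
                             segments_per_class = 68L, seed = 1L,
                             subject_id = "S1", sample_rate = 20) {
  stopifnot(segments_per_class >= 1L)
  rng <- .local_rng(seed)
  w <- 2 * sample_rate
  step <- w %/% 2L
  bout_len <- step * (segments_per_class + 1L)
  channels <- har_channels()
  values <- NULL
  labels <- character(0)
  for (act in names(templates)) {
    tpl <- templates[[act]]
    t <- (seq_len(bout_len) - 1) / sample_rate
    f0 <- tpl$f0 * shift$freq_scale
    M <- matrix(0, bout_len, 10L)
    for (j in seq_along(channels)) {
      ch <- tpl$channels[[channels[j]]]
      base_wave <- 0
      if (tpl$f0 > 0 && ch$amp > 0) {
        # fixed per-channel phase offsets decorrelate channels; the bout
        # phase origin itself is deterministic -- inter-subject phase
        # variation enters only through the frequency warp of the shift
        # model, not as an extra hidden nuisance factor
        phj <- j * 0.9
        base_wave <- sin(2 * pi * f0 * t + phj) +
          tpl$h2 * sin(2 * pi * 2 * f0 * t + phj + tpl$phase2) +
          tpl$h3 * sin(2 * pi * 3 * f0 * t + phj + 2 * tpl$phase2)
      }
      sig <- ch$base + ch$amp * base_wave + rng$rnorm(bout_len) * ch$noise
      M[, j] <- sig * shift$gain[j] + shift$offset[j]
    }
    M[, 1L] <- pmax(M[, 1L], 0)
    values <- rbind(values, M)
    labels <- c(labels, rep(act, bout_len))
  }
  sensor_recording(values, labels, subject_id = subject_id,
                   sample_rate = sample_rate)
}

#' Generate a multi-subject cohort with inter-subject domain shift
#'
#' Draws an independent [subject_shift()] per subject and generates one
#' recording each; the returned manifest records every shift parameter
#' so tests can assert against the ground truth.
#'
#' @param n_subjects number of subjects (default 7).
#' @param difficulty shift magnitude, see [subject_shift()] (default 1).
#' @param seed master seed; every stream below derives from it.
#' @param segments_per_class pure windows per activity per subject
#'   (default 68).
#' @param templates activity templates.
#' @param profile shift profile, see [subject_shift()].
#' @return list with `recordings` (list of [sensor_recording()]),
#'   `manifest` (list: `subjects`, `gains` and `offsets`
#'   (`n_subjects x 10` data frames), `freq_scale`, `difficulty`,
#'   `seed`, `segments_per_class`).
#' @export
generate_cohort <- function(n_subjects = 7L, difficulty = 1, seed = 1L,
                            segments_per_class = 68L,
                            templates = default_templates(),
                            profile = formals(subject_shift)$profile) {
  stopifnot(n_subjects >= 2L)
  profile <- eval(profile)
  rng <- .local_rng(seed)
  ids <- sprintf("S%d", seq_len(n_subjects))
  shifts <- lapply(seq_len(n_subjects), function(i)
    subject_shift(difficulty, rng, profile))
  seeds <- rng$integer(n_subjects, 1e6)
  recordings <- lapply(seq_len(n_subjects), function(i)
    generate_subject(templates, shifts[[i]], segments_per_class,
                     seed = seeds[i], subject_id = ids[i]))
  gains <- do.call(rbind, lapply(shifts, function(s) s$gain))
  offsets <- do.call(rbind, lapply(shifts, function(s) s$offset))
  manifest <- list(subjects = ids,
                   gains = data.frame(subject = ids, gains),
                   offsets = data.frame(subject = ids, offsets),
                   freq_scale = vapply(shifts, function(s) s$freq_scale,
                                       numeric(1)),
                   difficulty = difficulty, seed = seed,
                   segments_per_class = segments_per_class)
  list(recordings = recordings, manifest = manifest)
}
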