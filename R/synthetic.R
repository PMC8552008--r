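#' Movement-class templates for the synthetic gait generator
#'
#' A class template fixes the population-level structure of one movement
#' class; individual subjects are drawn around it by [make_profile()].
#' Three templates are provided:
#'
#' * `"flat"` — steady cyclic walking: large sagittal-plane oscillations,
#'   small frontal/transverse motion, constant positive pelvic speed.
#' * `"stair"` — staircase navigation alternating between an ascent-like
#'   and a descent-like sub-mode every ~13 stride cycles (a staircase
#'   descended, turned around on, and re-ascended), with a short linear
#'   blend between sub-modes. Sub-modes differ from flat walking in both
#'   joint-angle offsets (more flexed hips/knees) and amplitudes.
#' * `"natural"` — an undirected stream mixing cyclic walking bouts,
#'   smooth non-cyclic movement, and idle periods. Idle periods have a
#'   pelvic speed of exactly zero, so any positive pelvic-velocity
#'   threshold removes them.
#'
#' Angles are Euler ZXY joint angles in degrees over the full 18-channel
#' schema of [channel_schema()]. Each channel's cyclic waveform is a sum of
#' three harmonics of the stride frequency with unequal harmonic phases,
#' which makes the waveform time-asymmetric: a reversed recording is not a
#' phase-shifted copy of a forward one. This matters for testing which
#' reducers can tell forward from backward walking.
#'
#' @param name one of `"flat"`, `"stair"`, `"natural"`.
#' @return a `class_template` object (a list of template parameters).
#' @export
#' @examples
#' tpl <- class_template("flat")
#' tpl$name
class_template <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("flat", "stair", "natural")) {
    gl_stop(sprintf("unknown movement-class template: %s",
                    paste(format(name), collapse = ", ")),
            "gaitlatent_error_template")
  }
  ch <- channel_schema()
  n_ch <- nrow(ch)

  # Base per-channel fundamental phases encode inter-joint coordination:
  # distal joints lag proximal ones within the stride.
  joint_lag <- c(hip = 0, knee = 0.7, ankle = 1.3)
  plane_lag <- c(sagittal = 0, frontal = 0.45, transverse = 0.9)
  base_phase <- joint_lag[ch$joint] + plane_lag[ch$plane]
  names(base_phase) <- ch$channel

  amp_of <- function(hip_s, knee_s, ankle_s, hip_f = 4, hip_t = 3,
                     knee_ft = 1.5, ankle_f = 3, ankle_t = 3.5) {
    a <- numeric(n_ch)
    names(a) <- ch$channel
    a[ch$joint == "hip" & ch$plane == "sagittal"] <- hip_s
    a[ch$joint == "hip" & ch$plane == "frontal"] <- hip_f
    a[ch$joint == "hip" & ch$plane == "transverse"] <- hip_t
    a[ch$joint == "knee" & ch$plane == "sagittal"] <- knee_s
    a[ch$joint == "knee" & ch$plane != "sagittal"] <- knee_ft
    a[ch$joint == "ankle" & ch$plane == "sagittal"] <- ankle_s
    a[ch$joint == "ankle" & ch$plane == "frontal"] <- ankle_f
    a[ch$joint == "ankle" & ch$plane == "transverse"] <- ankle_t
    a
  }
  off_of <- function(hip_s, knee_s, ankle_s, hip_f = 3, hip_t = -2,
                     knee_ft = 1, ankle_f = -2, ankle_t = 6) {
    o <- numeric(n_ch)
    names(o) <- ch$channel
    o[ch$joint == "hip" & ch$plane == "sagittal"] <- hip_s
    o[ch$joint == "hip" & ch$plane == "frontal"] <- hip_f
    o[ch$joint == "hip" & ch$plane == "transverse"] <- hip_t
    o[ch$joint == "knee" & ch$plane == "sagittal"] <- knee_s
    o[ch$joint == "knee" & ch$plane != "sagittal"] <- knee_ft
    o[ch$joint == "ankle" & ch$plane == "sagittal"] <- ankle_s
    o[ch$joint == "ankle" & ch$plane == "frontal"] <- ankle_f
    o[ch$joint == "ankle" & ch$plane == "transverse"] <- ankle_t
    o
  }

  flat_mode <- list(amp = amp_of(20, 30, 12), offset = off_of(10, 25, 0))

  tpl <- list(
    name = name,
    channels = ch$channel,
    base_phase = base_phase,
    # unequal harmonic phases => time-asymmetric waveforms
    harm_phases = c(0, 0.9, 2.1),
    harm_weights = c(1, 0.45, 0.22),
    lr_lag = pi,          # half-cycle left-right alternation
    noise_sd = 2,         # degrees of additive sensor noise
    period_range = c(50L, 75L),  # stride period in frames at 60 Hz
    pelvic = list(base = 1.2, ripple = 0.2)
  )
  tpl$modes <- switch(
    name,
    flat = list(level = flat_mode),
    stair = list(
      ascent  = list(amp = amp_of(28, 40, 16, hip_f = 5, ankle_f = 4),
                     offset = off_of(22, 45, 8, hip_f = 5, ankle_t = 9)),
      descent = list(amp = amp_of(16, 42, 20, hip_f = 4, ankle_t = 5),
                     offset = off_of(8, 38, -4, hip_t = -5, ankle_f = -5))
    ),
    natural = list(level = flat_mode)
  )
  if (name == "stair") {
    tpl$cycles_per_mode <- 13L   # strides per ascent/descent bout
    tpl$transition_s <- 1        # linear blend between sub-modes
    tpl$pelvic <- list(base = 0.6, ripple = 0.1)
  }
  if (name == "natural") {
    tpl$mix_weights <- c(cyclic = 0.4, noncyclic = 0.3, idle = 0.3)
    tpl$segment_s <- c(3, 8)     # segment duration range, seconds
    tpl$pelvic <- list(base = 1.1, ripple = 0.15)
  }
  class(tpl) <- "class_template"
  tpl
}

#' Draw a subject-specific gait profile around a class template
#'
#' Individuality is emulated by per-subject deviations from the template:
#' a stride cadence drawn from 0.8–1.2 strides/s (rounded so the stride
#' period is a whole number of frames at 60 Hz), per-channel amplitude
#' scaling factors, additive joint-angle offsets, per-channel-and-harmonic
#' phase jitter, and subject-specific harmonic weights. Two profiles drawn
#' with different `subject_index` therefore differ in their mean pose and
#' waveform shape, which is what the individual-identification task relies
#' on.
#'
#' @param template a [class_template()], or its name.
#' @param subject_index non-negative integer distinguishing subjects.
#' @param seed master integer seed; draws use the child stream
#'   `profile/<class>/<subject_index>`.
#' @param noise_sd additive angle noise SD in degrees (default from the
#'   template).
#' @return a `gait_profile` object.
#' @export
#' @examples
#' p <- make_profile("flat", 0, seed = 42)
#' p$cadence
make_profile <- function(template, subject_index, seed, noise_sd = NULL) {
  if (is.character(template)) template <- class_template(template)
  stopifnot(inherits(template, "class_template"))
  if (!is.numeric(subject_index) || length(subject_index) != 1L || subject_index < 0) {
    gl_stop("subject_index must be a single non-negative integer",
            "gaitlatent_error_argument")
  }
  ch <- template$channels
  n_ch <- length(ch)
  n_h <- length(template$harm_weights)
  with_child_seed(seed, sprintf("profile/%s/%d", template$name, as.integer(subject_index)), {
    period <- sample(seq(template$period_range[1], template$period_range[2]), 1L)
    amp_factor <- stats::runif(n_ch, 0.8, 1.2)
    off_shift <- stats::rnorm(n_ch, 0, 2)
    phase_jitter <- matrix(stats::rnorm(n_ch * n_h, 0, 0.1), n_ch, n_h)
    w <- c(1, stats::runif(1, 0.35, 0.55), stats::runif(1, 0.15, 0.30))
    modes <- lapply(template$modes, function(m) {
      list(amp = m$amp * amp_factor, offset = m$offset + off_shift)
    })
    phases <- outer(template$base_phase, rep(1, n_h)) +
      matrix(template$harm_phases, n_ch, n_h, byrow = TRUE) + phase_jitter
    rownames(phases) <- ch
    p <- list(
      subject_id = sprintf("%s%02d", template$name, as.integer(subject_index)),
      class = template$name,
      period_frames = period,
      cadence = 60 / period,
      modes = modes,
      phases = phases,
      harm_weights = w,
      lr_lag = template$lr_lag,
      noise_sd = if (is.null(noise_sd)) template$noise_sd else noise_sd,
      channels = ch
    )
    class(p) <- "gait_profile"
    p
  })
}

# Cyclic waveform for one parameter mode, evaluated at integer frame
# indices. Using `frame %% period` keeps noise-free trajectories exactly
# (bitwise) periodic.
mode_waveform <- function(profile, mode, frames, rate) {
  P <- profile$period_frames * rate / 60  # period in frames at this rate
  u <- (frames %% P) / P                  # cycle fraction in [0, 1)
  ch <- profile$channels
  right <- grepl("_right_", ch)
  w <- profile$harm_weights / sum(profile$harm_weights)
  n <- length(frames)
  x <- matrix(0, n, length(ch))
  for (h in seq_along(w)) {
    ph <- profile$phases[, h] + ifelse(right, h * profile$lr_lag, 0)
    # outer over channels: sin(2*pi*h*u + phase_c)
    x <- x + w[h] * sin(outer(2 * pi * h * u, ph, `+`))
  }
  sweep(sweep(x, 2, mode$amp, `*`), 2, mode$offset, `+`)
}

# Alternation weight for the stair template: 1 during ascent bouts, 0
# during descent bouts, linear ramps of `ramp` frames in between.
stair_mode_weight <- function(frames, block, ramp) {
  L <- 2 * block
  pos <- frames %% L
  a <- numeric(length(frames))
  a[pos < block] <- 1
  # descending ramp at the end of the ascent block, ascending at the end
  # of the descent block
  down <- pos >= (block - ramp) & pos < block
  a[down] <- (block - pos[down]) / ramp
  up <- pos >= (L - ramp)
  a[up] <- (pos[up] - (L - ramp)) / ramp
  a
}

# Smooth non-cyclic movement: moving-average-filtered white noise per
# channel, rescaled to a fraction of the cyclic amplitude.
noncyclic_segment <- function(profile, mode, n, rate) {
  k <- max(5L, as.integer(rate / 2))
  ch <- profile$channels
  x <- matrix(0, n, length(ch))
  for (j in seq_along(ch)) {
    z <- stats::rnorm(n + 2L * k)
    sm <- stats::filter(z, rep(1 / k, k), sides = 2L)
    sm <- sm[(k + 1L):(k + n)]
    s <- stats::sd(sm)
    if (s > 0) sm <- sm / s
    x[, j] <- mode$offset[j] + 0.7 * mode$amp[j] * sm
  }
  x
}

#' Generate one synthetic kinematic recording
#'
#' Produces a 60 Hz (by default) multichannel joint-angle time series for
#' one subject and one movement class, together with an auxiliary
#' pelvic-speed trace and, where defined, the true stride-cycle phase of
#' each frame (used by latent-structure diagnostics; `NA` during
#' non-cyclic and idle segments).
#'
#' With `noise_sd = 0` the flat-ground trajectory is an exact harmonic sum
#' and exactly periodic with period `profile$period_frames`.
#'
#' @param profile a [make_profile()] result.
#' @param template the matching [class_template()]; defaults to the
#'   template of the profile's class.
#' @param duration length in seconds (> 0).
#' @param rate sampling rate in Hz (> 0, default 60).
#' @param seed master integer seed; the noise stream is
#'   `recording/<subject_id>`.
#' @param noise_sd override of the profile's additive noise SD.
#' @return a `kinematic_recording`: list with `angles` (frames x 18 matrix,
#'   degrees), `pelvic_speed`, `cycle_phase`, `subject_id`, `activity`,
#'   `rate`, `channels`.
#' @export
generate_recording <- function(profile, template = NULL, duration, rate = 60,
                               seed = 1L, noise_sd = NULL) {
  stopifnot(inherits(profile, "gait_profile"))
  if (is.null(template)) template <- class_template(profile$class)
  if (is.character(template)) template <- class_template(template)
  if (!is.numeric(duration) || duration <= 0) {
    gl_stop("duration must be positive", "gaitlatent_error_argument")
  }
  if (!is.numeric(rate) || rate <= 0) {
    gl_stop("rate must be positive", "gaitlatent_error_argument")
  }
  n <- as.integer(round(duration * rate))
  frames <- seq_len(n) - 1L
  if (is.null(noise_sd)) noise_sd <- profile$noise_sd

  with_child_seed(seed, sprintf("recording/%s", profile$subject_id), {
    pel <- template$pelvic
    if (template$name == "flat") {
      P <- profile$period_frames * rate / 60
      u <- (frames %% P) / P
      x <- mode_waveform(profile, profile$modes$level, frames, rate)
      speed <- pel$base + pel$ripple * sin(2 * pi * u)
      phase <- u
    } else if (template$name == "stair") {
      P <- profile$period_frames * rate / 60
      u <- (frames %% P) / P
      block <- template$cycles_per_mode * profile$period_frames * rate / 60
      ramp <- template$transition_s * rate
      a <- stair_mode_weight(frames, block, ramp)
      xa <- mode_waveform(profile, profile$modes$ascent, frames, rate)
      xd <- mode_waveform(profile, profile$modes$descent, frames, rate)
      x <- a * xa + (1 - a) * xd
      speed <- pel$base + pel$ripple * sin(2 * pi * u)
      phase <- u
    } else {  # natural
      x <- matrix(NA_real_, n, length(profile$channels))
      speed <- numeric(n)
      phase <- rep(NA_real_, n)
      P <- profile$period_frames * rate / 60
      pos <- 0L
      types <- names(template$mix_weights)
      while (pos < n) {
        type <- sample(types, 1L, prob = template$mix_weights)
        seg_n <- min(n - pos,
                     as.integer(round(stats::runif(1, template$segment_s[1],
                                                   template$segment_s[2]) * rate)))
        idx <- (pos + 1L):(pos + seg_n)
        segf <- frames[idx]
        if (type == "cyclic") {
          u <- (segf %% P) / P
          x[idx, ] <- mode_waveform(profile, profile$modes$level, segf, rate)
          speed[idx] <- pel$base + pel$ripple * sin(2 * pi * u)
          phase[idx] <- u
        } else if (type == "noncyclic") {
          x[idx, ] <- noncyclic_segment(profile, profile$modes$level, seg_n, rate)
          speed[idx] <- 0.5 + 0.3 * abs(sin(2 * pi * segf / (4 * rate)))
        } else {  # idle: constant offset pose, pelvic speed exactly zero
          x[idx, ] <- matrix(profile$modes$level$offset, seg_n,
                             length(profile$channels), byrow = TRUE)
          speed[idx] <- 0
        }
        pos <- pos + seg_n
      }
    }
    if (noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
    }
    colnames(x) <- profile$channels
    new_recording(x, pelvic_speed = speed, cycle_phase = phase,
                  subject_id = profile$subject_id, activity = profile$class,
                  rate = rate)
  })
}

# Constructor + validator for the recording container shared by the
# generator and the readers.
new_recording <- function(angles, pelvic_speed = NULL, cycle_phase = NULL,
                          subject_id, activity, rate) {
  stopifnot(is.matrix(angles), !is.null(colnames(angles)))
  if (!all(is.finite(angles))) {
    gl_stop("recording contains non-finite angle values",
            "gaitlatent_error_recording")
  }
  if (!is.null(pelvic_speed)) stopifnot(length(pelvic_speed) == nrow(angles))
  rec <- list(angles = angles, pelvic_speed = pelvic_speed,
              cycle_phase = cycle_phase, subject_id = subject_id,
              activity = activity, rate = rate,
              channels = colnames(angles))
  class(rec) <- "kinematic_recording"
  rec
}

#' @export
print.kinematic_recording <- function(x, ...) {
  cat(sprintf("<kinematic_recording> %s [%s] %d frames x %d channels @ %g Hz\n",
              x$subject_id, x$activity, nrow(x$angles), ncol(x$angles), x$rate))
  invisible(x)
}

#' Generate a full synthetic study
#'
#' One recording per subject, with subject identifiers unique across the
#' three movement classes. The default class sizes used throughout the
#' analyses are 8 flat-ground, 11 stair and 13 natural-movement subjects.
#'
#' @param n_flat,n_stair,n_natural subject counts per class (>= 0).
#' @param duration recording length in seconds per subject.
#' @param seed master integer seed; every profile and recording derives a
#'   child stream from it.
#' @param rate sampling rate in Hz.
#' @param noise_sd optional additive noise SD override (degrees).
#' @return a `synthetic_study`: list with `recordings` (list of
#'   [generate_recording()] results), `profiles`, `seed`, `params`.
#' @export
#' @examples
#' study <- generate_study(2, 2, 0, duration = 10, seed = 7)
#' length(study$recordings)
generate_study <- function(n_flat, n_stair, n_natural, duration, seed,
                           rate = 60, noise_sd = NULL) {
  counts <- c(flat = n_flat, stair = n_stair, natural = n_natural)
  if (any(counts < 0)) gl_stop("subject counts must be >= 0",
                               "gaitlatent_error_argument")
  recordings <- list()
  profiles <- list()
  for (cls in names(counts)) {
    if (counts[[cls]] == 0) next
    tpl <- class_template(cls)
    for (i in seq_len(counts[[cls]]) - 1L) {
      p <- make_profile(tpl, i, seed, noise_sd = noise_sd)
      r <- generate_recording(p, tpl, duration = duration, rate = rate, seed = seed)
      profiles[[p$subject_id]] <- p
      recordings[[p$subject_id]] <- r
    }
  }
  structure(list(recordings = recordings, profiles = profiles, seed = seed,
                 params = list(counts = counts, duration = duration, rate = rate)),
            class = "synthetic_study")
}

#' Write / read a recording as CSV with a JSON sidecar
#'
#' The CSV has one header row naming the angle channels plus a
#' `pelvic_speed` column (and a `cycle_phase` column when available), one
#' row per frame. The sidecar `<path>.json` carries subject id, class
#' label and rate. Any conforming CSV of real kinematics can be read the
#' same way.
#'
#' @param recording a `kinematic_recording`.
#' @param path CSV file path (sidecar written next to it).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `kinematic_recording`.
#' @export
write_recording <- function(recording, path) {
  df <- as.data.frame(recording$angles)
  if (!is.null(recording$pelvic_speed)) df$pelvic_speed <- recording$pelvic_speed
  if (!is.null(recording$cycle_phase)) df$cycle_phase <- recording$cycle_phase
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = recording$subject_id, activity = recording$activity,
               rate = recording$rate, channels = recording$channels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ang <- as.matrix(df[, meta$channels, drop = FALSE])
  new_recording(ang,
                pelvic_speed = if ("pelvic_speed" %in% names(df)) df$pelvic_speed,
                cycle_phase = if ("cycle_phase" %in% names(df)) df$cycle_phase,
                subject_id = meta$subject_id, activity = meta$activity,
                rate = meta$rate)
}
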