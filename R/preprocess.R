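#' Drop the knee frontal/transverse channels
#'
#' Reduces the full 18-channel schema to the 14 analysis channels: all
#' three planes for hips and ankles, sagittal plane only for the knees
#' (knee frontal/transverse motion mostly reflects sensor noise). The
#' operation is idempotent: a recording already on the 14-channel schema
#' is returned unchanged.
#'
#' @param recording a `kinematic_recording`.
#' @return the recording restricted to the 14 analysis channels, in the
#'   fixed order of `channel_schema(reduced = TRUE)`.
#' @export
select_channels <- function(recording) {
  stopifnot(inherits(recording, "kinematic_recording"))
  keep <- analysis_channels()
  missing <- setdiff(keep, recording$channels)
  if (length(missing) > 0) {
    gl_stop(paste("recording lacks required channels:",
                  paste(missing, collapse = ", ")),
            "gaitlatent_error_channels")
  }
  recording$angles <- recording$angles[, keep, drop = FALSE]
  recording$channels <- keep
  recording
}

#' Fit pooled per-channel standardization statistics
#'
#' Per-channel mean and standard deviation computed over the concatenated
#' frames of all supplied recordings — all movement classes pooled, so a
#' single standardization applies to every dataset. Population (divide by
#' n) moments are used so that standardized channels have variance exactly
#' one, which makes a standardized RMSE of 1 correspond exactly to
#' reconstructing the pooled mean pose.
#'
#' @param recordings list of channel-compatible `kinematic_recording`s.
#' @return a `standardizer` with fields `mean`, `sd`, `channels`.
#' @export
fit_standardizer <- function(recordings) {
  if (inherits(recordings, "kinematic_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1)
  ch <- recordings[[1]]$channels
  for (r in recordings) {
    if (!identical(r$channels, ch)) {
      gl_stop("recordings have differing channel schemas",
              "gaitlatent_error_channels")
    }
  }
  n_tot <- sum(vapply(recordings, function(r) nrow(r$angles), numeric(1)))
  if (n_tot < 2) gl_stop("need at least 2 pooled frames", "gaitlatent_error_argument")
  s1 <- Reduce(`+`, lapply(recordings, function(r) colSums(r$angles)))
  s2 <- Reduce(`+`, lapply(recordings, function(r) colSums(r$angles^2)))
  mu <- s1 / n_tot
  v <- s2 / n_tot - mu^2
  v <- pmax(v, 0)
  if (any(v <= 0)) {
    gl_stop(paste("zero pooled variance in channel(s):",
                  paste(ch[v <= 0], collapse = ", ")),
            "gaitlatent_error_degenerate")
  }
  structure(list(mean = mu, sd = sqrt(v), channels = ch),
            class = "standardizer")
}

#' Apply / invert a standardizer
#'
#' @param standardizer a [fit_standardizer()] result.
#' @param x frames x channels matrix in degrees (or standardized units for
#'   `unstandardize`), columns in standardizer channel order.
#' @return matrix of the same shape.
#' @export
standardize <- function(standardizer, x) {
  stopifnot(inherits(standardizer, "standardizer"), ncol(x) == length(standardizer$mean))
  sweep(sweep(x, 2, standardizer$mean, `-`), 2, standardizer$sd, `/`)
}

#' @rdname standardize
#' @export
unstandardize <- function(standardizer, x) {
  stopifnot(inherits(standardizer, "standardizer"), ncol(x) == length(standardizer$mean))
  sweep(sweep(x, 2, standardizer$sd, `*`), 2, standardizer$mean, `+`)
}

#' Keep only segments where the pelvis is moving
#'
#' Splits a recording into the maximal contiguous runs of frames whose
#' pelvic speed is at or above `threshold`, discarding runs shorter than
#' `min_segment` frames. Used on the natural-movement stream, which
#' contains long idle periods (sitting, standing) that would otherwise
#' dominate the data; cyclic datasets are left unfiltered.
#'
#' @param recording a `kinematic_recording` with a pelvic-speed trace.
#' @param threshold speed threshold (same units as the trace). `NULL`
#'   (default) uses 10% of the median speed over frames with positive
#'   speed — the filter's scale is not observable from idle frames.
#' @param min_segment minimum run length in frames (default 60 = 1 s).
#' @return list of sub-recordings (possibly empty).
#' @export
filter_by_pelvic_velocity <- function(recording, threshold = NULL,
                                      min_segment = 60L) {
  stopifnot(inherits(recording, "kinematic_recording"))
  sp <- recording$pelvic_speed
  if (is.null(sp)) {
    gl_stop("recording has no pelvic-speed trace", "gaitlatent_error_pelvic")
  }
  if (is.null(threshold)) {
    pos <- sp[sp > 0]
    threshold <- if (length(pos) > 0) 0.1 * stats::median(pos) else Inf
  }
  act <- sp >= threshold
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_segment)
  lapply(seq_along(keep), function(i) {
    k <- keep[i]
    idx <- starts[k]:ends[k]
    seg <- recording
    seg$angles <- recording$angles[idx, , drop = FALSE]
    seg$pelvic_speed <- sp[idx]
    if (!is.null(recording$cycle_phase)) seg$cycle_phase <- recording$cycle_phase[idx]
    seg$segment <- i
    seg
  })
}

#' Sample standardized poses from a recording
#'
#' Takes the frame at 0, `stride`, `2*stride`, ... and standardizes it,
#' yielding 14-dimensional pose samples. The default stride of 10 frames
#' at 60 Hz corresponds to sampling every 0.166 s.
#'
#' @param recording a channel-selected `kinematic_recording`.
#' @param standardizer a [fit_standardizer()] result on the same schema.
#' @param stride sampling stride in frames (>= 1, default 10).
#' @return a `pose_set`: list with `x` (n x 14 standardized matrix) and a
#'   provenance data.frame `info` (subject, activity, frame, cycle_phase).
#' @export
sample_poses <- function(recording, standardizer, stride = 10L) {
  stopifnot(stride >= 1)
  check_analysis_schema(recording)
  idx <- seq(1L, nrow(recording$angles), by = as.integer(stride))
  x <- standardize(standardizer, recording$angles[idx, , drop = FALSE])
  info <- data.frame(subject = recording$subject_id,
                     activity = recording$activity,
                     frame = idx - 1L,
                     cycle_phase = if (is.null(recording$cycle_phase))
                       NA_real_ else recording$cycle_phase[idx])
  structure(list(x = x, info = info), class = "pose_set")
}

#' Sample standardized one-second movement windows
#'
#' Extracts overlapping windows of `window` consecutive frames starting at
#' 0, `stride`, ...; the last window must fit entirely inside the
#' recording, so a recording shorter than `window` yields no windows.
#' Windows never cross recording (hence subject or segment) boundaries.
#' Row `r` of a window equals the pose that [sample_poses()] would produce
#' at the same frame, so pose-level and movement-level reducers consume
#' consistent views of the data.
#'
#' @inheritParams sample_poses
#' @param window window length in frames (default 60 = 1 s at 60 Hz).
#' @return a `window_set`: list with `x` (n x window x 14 standardized
#'   array) and provenance `info` (subject, activity, start_frame,
#'   cycle_phase of the window's first frame).
#' @export
sample_windows <- function(recording, standardizer, window = 60L, stride = 10L) {
  stopifnot(stride >= 1, window >= 2)
  check_analysis_schema(recording)
  n <- nrow(recording$angles)
  xs <- standardize(standardizer, recording$angles)
  starts <- seq(1L, by = as.integer(stride),
                length.out = max(0L, (n - window) %/% stride + 1L))
  if (n < window) starts <- integer(0)
  k <- ncol(xs)
  arr <- array(0, dim = c(length(starts), window, k))
  for (i in seq_along(starts)) {
    arr[i, , ] <- xs[starts[i]:(starts[i] + window - 1L), ]
  }
  info <- data.frame(subject = rep(recording$subject_id, length(starts)),
                     activity = rep(recording$activity, length(starts)),
                     start_frame = starts - 1L,
                     cycle_phase = if (is.null(recording$cycle_phase))
                       rep(NA_real_, length(starts)) else recording$cycle_phase[starts])
  structure(list(x = arr, info = info), class = "window_set")
}

check_analysis_schema <- function(recording) {
  if (!identical(recording$channels, analysis_channels())) {
    gl_stop("recording is not on the 14-channel analysis schema; apply select_channels() first",
            "gaitlatent_error_channels")
  }
  invisible(recording)
}

# Concatenate pose_sets / window_sets.
bind_pose_sets <- function(sets) {
  sets <- Filter(function(s) nrow(s$x) > 0, sets)
  structure(list(x = do.call(rbind, lapply(sets, `[[`, "x")),
                 info = do.call(rbind, lapply(sets, `[[`, "info"))),
            class = "pose_set")
}

bind_window_sets <- function(sets) {
  sets <- Filter(function(s) dim(s$x)[1] > 0, sets)
  xs <- lapply(sets, `[[`, "x")
  n <- sum(vapply(xs, function(a) dim(a)[1], numeric(1)))
  d <- dim(xs[[1]])
  arr <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (a in xs) {
    if (dim(a)[1] == 0) next
    arr[(at + 1L):(at + dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  structure(list(x = arr, info = do.call(rbind, lapply(sets, `[[`, "info"))),
            class = "window_set")
}

#' Preprocess a study end to end
#'
#' Applies the full preprocessing chain: channel selection on every
#' recording; pelvic-velocity filtering of natural-class recordings only;
#' a single standardizer fit on the pooled frames of all (filtered)
#' recordings of all classes; pose and window sampling per recording.
#'
#' @param study a [generate_study()] result (or any list of
#'   `kinematic_recording`s under `$recordings`).
#' @param stride sampling stride in frames.
#' @param window window length in frames.
#' @param pelvic_threshold,min_segment see [filter_by_pelvic_velocity()].
#' @return a list with `poses` (pose_set over all recordings), `windows`
#'   (window_set), `standardizer`, and `recordings` (the channel-selected,
#'   filtered segments).
#' @export
preprocess_study <- function(study, stride = 10L, window = 60L,
                             pelvic_threshold = NULL, min_segment = 60L) {
  recs <- lapply(study$recordings, select_channels)
  out <- list()
  for (r in recs) {
    if (identical(r$activity, "natural")) {
      out <- c(out, filter_by_pelvic_velocity(r, threshold = pelvic_threshold,
                                              min_segment = min_segment))
    } else {
      out <- c(out, list(r))
    }
  }
  std <- fit_standardizer(out)
  poses <- bind_pose_sets(lapply(out, sample_poses, standardizer = std,
                                 stride = stride))
  windows <- bind_window_sets(lapply(out, sample_windows, standardizer = std,
                                     window = window, stride = stride))
  list(poses = poses, windows = windows, standardizer = std, recordings = out)
}
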