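#' Circular rank correlation between two angular variables
#'
#' Both variables are converted to circular ranks (uniform angles in rank
#' order) and the Fisher-Lee rank correlation is computed:
#' `(R2(a - b) - R2(a + b)) / n^2`, where `R(x)` is the resultant length
#' of the angles `x`. Moment-based circular correlations are undefined for
#' uniform marginals — and circular ranks are uniform by construction —
#' whereas this statistic is exactly +1 when one angle traverses the
#' circle in lockstep with the other, -1 for the reversed orientation,
#' and near 0 when the angular orders are unrelated.
#'
#' @param theta,phi numeric vectors of angles in radians (equal length).
#' @return correlation in `[-1, 1]`.
#' @export
circular_rank_cor <- function(theta, phi) {
  stopifnot(length(theta) == length(phi), length(theta) >= 3)
  n <- length(theta)
  a <- 2 * pi * rank(theta, ties.method = "average") / n
  b <- 2 * pi * rank(phi, ties.method = "average") / n
  r2 <- function(x) sum(cos(x))^2 + sum(sin(x))^2
  (r2(a - b) - r2(a + b)) / n^2
}

#' Phase alignment of a latent embedding of cyclic gait
#'
#' Steady cyclic gait should be embedded as a closed loop ordered by gait
#' phase. This diagnostic estimates the mean latent trajectory over the
#' stride cycle — the average latent position within each of `n_bins`
#' phase bins — converts each bin mean to an angle about the trajectory's
#' centroid, and reports the absolute circular rank correlation between
#' bin angle and bin phase. Values near 1 mean the latent loop is
#' traversed in phase order (in either orientation); values near 0 mean
#' the loop, if any, is not phase-organized.
#'
#' Averaging within phase bins measures the trajectory rather than the
#' individual points: per-sample sensor noise scatters points about the
#' loop and would otherwise dominate the angular ranks wherever the loop
#' passes near its own centroid, for linear and nonlinear reducers alike.
#'
#' @param latent n x 2 latent coordinate matrix.
#' @param phase stride-cycle phase per point, as a fraction in `[0, 1)`
#'   (e.g. the `cycle_phase` provenance of a pose or window set); entries
#'   with non-finite phase are ignored.
#' @param n_bins number of phase bins (default 24); every bin must be
#'   occupied.
#' @return absolute circular rank correlation in `[0, 1]`.
#' @export
latent_phase_alignment <- function(latent, phase, n_bins = 24L) {
  latent <- as.matrix(latent)
  stopifnot(ncol(latent) == 2)
  ok <- is.finite(phase)
  latent <- latent[ok, , drop = FALSE]
  phase <- phase[ok] %% 1
  bin <- pmin(floor(phase * n_bins), n_bins - 1L)
  if (length(unique(bin)) < n_bins) {
    gl_stop("every phase bin must contain at least one sample",
            "gaitlatent_error_argument")
  }
  bm <- cbind(tapply(latent[, 1], bin, mean), tapply(latent[, 2], bin, mean))
  bm <- sweep(bm, 2, colMeans(bm))
  # whiten: a reducer's latent axes are arbitrary affine coordinates, so
  # angular order must not depend on the loop's eccentricity
  ev <- eigen(crossprod(bm) / nrow(bm), symmetric = TRUE)
  bm <- bm %*% ev$vectors %*% diag(1 / sqrt(pmax(ev$values, 1e-12))) %*% t(ev$vectors)
  theta <- atan2(bm[, 2], bm[, 1])
  centers <- 2 * pi * (as.numeric(rownames(bm)) + 0.5) / n_bins
  abs(circular_rank_cor(theta, centers))
}

#' Time-reverse movement windows
#'
#' Reverses the frame order of every window in an n x time x channels
#' array. Because the synthetic waveforms are time-asymmetric, reversed
#' windows are genuinely different movements (walking "backward"), while
#' the multiset of individual poses they contain is unchanged — which is
#' exactly why pose-level reducers cannot tell the two apart.
#'
#' @param x n x time x channels array (or `window_set`).
#' @return array of the same shape with time running backward.
#' @export
reverse_windows <- function(x) {
  x <- window_array(x)
  x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
}

#' Shuffle frames within each window
#'
#' Independently permutes the frame order of every window, destroying
#' temporal structure while keeping each window's multiset of poses. Used
#' as a control: a temporal property that survives frame shuffling was
#' never temporal to begin with.
#'
#' @param x n x time x channels array (or `window_set`).
#' @param seed integer seed for the permutations.
#' @return array of the same shape.
#' @export
shuffle_window_frames <- function(x, seed = 1L) {
  x <- window_array(x)
  with_child_seed(seed, "shuffle_frames", {
    for (i in seq_len(dim(x)[1])) {
      x[i, , ] <- x[i, sample.int(dim(x)[2]), ]
    }
    x
  })
}

#' Poses contained in a set of windows
#'
#' Flattens an n x time x channels window array into an (n*time) x
#' channels pose matrix, with an accompanying window index. The pose-level
#' view of the same data that a window-level reducer sees.
#'
#' @param x n x time x channels array (or `window_set`).
#' @param stride keep every `stride`-th frame of each window (default 10,
#'   matching the pose sampling stride).
#' @return list with `x` (pose matrix) and `window` (source window index).
#' @export
windows_as_poses <- function(x, stride = 10L) {
  x <- window_array(x)
  tkeep <- seq(1L, dim(x)[2], by = as.integer(stride))
  n <- dim(x)[1]
  out <- matrix(0, n * length(tkeep), dim(x)[3])
  win <- integer(n * length(tkeep))
  at <- 0L
  for (t in tkeep) {
    out[(at + 1L):(at + n), ] <- x[, t, ]
    win[(at + 1L):(at + n)] <- seq_len(n)
    at <- at + n
  }
  list(x = out, window = win)
}
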