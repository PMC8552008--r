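#' Variance accounted for (VAF) by a reconstruction
#'
#' `VAF(%) = (1 - var(y - yhat) / var(y)) * 100`. A VAF of 100% means the
#' reconstruction is identical to the input; 0% means it is no better than
#' reconstructing the per-channel mean; negative values mean worse than
#' the mean. For multichannel data the variances are pooled over channels:
#' `VAF = 100 * (1 - sum_c var(y_c - yhat_c) / sum_c var(y_c))`, which
#' reduces to the scalar definition for one channel and makes the VAF of a
#' rank-k PCA reconstruction exactly the cumulative explained-variance
#' ratio of its top k eigenvalues. Population (divide by n) variances are
#' used throughout for the same reason.
#'
#' @param y,y_hat numeric matrices (samples x channels) of equal shape;
#'   vectors are treated as single-channel. For window sets, 3-d arrays
#'   (n x time x channels) are accepted and flattened over time.
#' @param per_channel logical; if `TRUE` return the vector of per-channel
#'   VAFs instead of the pooled value.
#' @return VAF in percent (scalar, or per-channel vector).
#' @export
#' @examples
#' y <- matrix(rnorm(60), 20, 3)
#' vaf(y, y)  # 100
vaf <- function(y, y_hat, per_channel = FALSE) {
  y <- as_sample_matrix(y)
  y_hat <- as_sample_matrix(y_hat)
  if (!identical(dim(y), dim(y_hat))) {
    gl_stop("y and y_hat must have identical shapes", "gaitlatent_error_shape")
  }
  vy <- col_pop_var(y)
  vr <- col_pop_var(y - y_hat)
  if (per_channel) {
    if (any(vy == 0)) gl_stop("zero variance in an input channel",
                              "gaitlatent_error_degenerate")
    return(100 * (1 - vr / vy))
  }
  if (sum(vy) == 0) gl_stop("input has zero variance", "gaitlatent_error_degenerate")
  100 * (1 - sum(vr) / sum(vy))
}

#' Root-mean-square reconstruction error
#'
#' The root of the mean squared entrywise difference over all samples and
#' channels. On data standardized to unit variance per channel, an RMSE of
#' 1 is achieved by reconstructing the pooled mean pose, so values above 1
#' indicate a reconstruction worse than the mean.
#'
#' @inheritParams vaf
#' @return RMSE (standardized units if the inputs are standardized).
#' @export
rmse <- function(y, y_hat) {
  y <- as_sample_matrix(y)
  y_hat <- as_sample_matrix(y_hat)
  if (!identical(dim(y), dim(y_hat))) {
    gl_stop("y and y_hat must have identical shapes", "gaitlatent_error_shape")
  }
  sqrt(mean((y - y_hat)^2))
}

#' Normalized per-dimension latent variance
#'
#' The variance of the latent coordinates along each bottleneck dimension,
#' normalized to sum to one. For PCA latent scores this equals the
#' eigenvalue distribution over the retained components. Used to compare
#' how evenly reducers spread information across latent dimensions.
#'
#' @param latent n x k matrix of latent coordinates (n >= 2).
#' @return numeric vector of k non-negative ratios summing to 1.
#' @export
dimensional_variance <- function(latent) {
  latent <- as.matrix(latent)
  if (nrow(latent) < 2) gl_stop("need >= 2 latent samples", "gaitlatent_error_argument")
  v <- col_pop_var(latent)
  if (sum(v) == 0) gl_stop("latent has zero total variance",
                           "gaitlatent_error_degenerate")
  v / sum(v)
}

#' Shannon entropy of a variance-ratio distribution
#'
#' In nats; maximal (`log(k)`) when variance is spread uniformly over the
#' k latent dimensions, 0 when concentrated in one. Quantifies how evenly
#' a reducer distributes variance across its bottleneck.
#'
#' @param ratios non-negative ratios summing to 1 (e.g.
#'   [dimensional_variance()] output).
#' @return entropy in nats.
#' @export
variance_entropy <- function(ratios) {
  stopifnot(all(ratios >= -1e-12), abs(sum(ratios) - 1) < 1e-6)
  p <- ratios[ratios > 0]
  -sum(p * log(p))
}

# ---- shared helpers ----

# Population (divide-by-n) column variances.
col_pop_var <- function(x) {
  mu <- colMeans(x)
  colMeans(x^2) - mu^2
}

# Coerce vectors / window arrays to a samples x channels matrix.
as_sample_matrix <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    return(matrix(x, d[1] * d[2], d[3]))
  }
  if (is.null(dim(x))) return(matrix(x, ncol = 1)) else as.matrix(x)
}
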