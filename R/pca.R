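#' Principal component analysis of pose samples
#'
#' Eigendecomposition of the population covariance matrix of the training
#' poses. Components are returned in descending eigenvalue order with a
#' fixed sign convention (the largest-magnitude loading of each component
#' is positive), so repeated fits on identical data are identical.
#'
#' @param poses a `pose_set` or an n x d numeric matrix of standardized
#'   poses, with n > d.
#' @return a `pca_model` with fields `mean` (length d), `components`
#'   (d x d orthonormal matrix, one component per column), `eigenvalues`
#'   (length d, descending).
#' @export
fit_pca <- function(poses) {
  x <- pose_matrix(poses)
  n <- nrow(x)
  d <- ncol(x)
  if (n <= d) {
    gl_stop(sprintf("need more samples (%d) than dimensions (%d)", n, d),
            "gaitlatent_error_argument")
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, `-`)
  covm <- crossprod(xc) / n            # population covariance
  e <- eigen(covm, symmetric = TRUE)   # descending eigenvalues
  comp <- e$vectors
  for (j in seq_len(d)) {              # sign convention
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean = mu, components = comp,
                 eigenvalues = pmax(e$values, 0)),
            class = c("pca_model", "reducer"))
}

#' Encode / decode with a fitted reducer
#'
#' The common contract satisfied by every dimensionality-reduction method
#' in the package: `encode()` maps inputs to latent coordinates, `decode()`
#' maps latent coordinates back to input space, and
#' `reconstruct()` is `decode(encode(x))`.
#'
#' @param reducer a fitted reducer (`pca_model`, `pose_ae_model`,
#'   `move_ae_model`).
#' @param x inputs in the reducer's native shape (poses: n x d matrix or
#'   `pose_set`; windows: n x time x channels array or `window_set`).
#' @param latent an n x k latent coordinate matrix.
#' @param ... method-specific arguments (`k` for `encode.pca_model`).
#' @return `encode()`: n x k latent matrix; `decode()`: inputs in native
#'   shape; `reconstruct()`: same shape as `x`.
#' @export
encode <- function(reducer, x, ...) UseMethod("encode")

#' @rdname encode
#' @export
decode <- function(reducer, latent, ...) UseMethod("decode")

#' @rdname encode
#' @export
reconstruct <- function(reducer, x, ...) decode(reducer, encode(reducer, x, ...))

#' @rdname encode
#' @param k number of retained components (1..d, default 2).
#' @export
encode.pca_model <- function(reducer, x, k = 2L, ...) {
  x <- pose_matrix(x)
  d <- ncol(reducer$components)
  if (k < 1 || k > d) {
    gl_stop(sprintf("k must be in 1..%d", d), "gaitlatent_error_argument")
  }
  sweep(x, 2, reducer$mean, `-`) %*% reducer$components[, seq_len(k), drop = FALSE]
}

#' @rdname encode
#' @export
decode.pca_model <- function(reducer, latent, ...) {
  latent <- as.matrix(latent)
  k <- ncol(latent)
  if (k > ncol(reducer$components)) {
    gl_stop("latent width exceeds component count", "gaitlatent_error_argument")
  }
  sweep(latent %*% t(reducer$components[, seq_len(k), drop = FALSE]),
        2, reducer$mean, `+`)
}

#' Cumulative explained-variance ratio of a PCA model
#'
#' `100 * sum(eigenvalues[1:k]) / sum(eigenvalues)` — equal to the VAF of
#' the rank-k PCA reconstruction of the training data.
#'
#' @param model a `pca_model`.
#' @param k number of leading components.
#' @return percentage in `[0, 100]`.
#' @export
pca_explained <- function(model, k) {
  100 * sum(model$eigenvalues[seq_len(k)]) / sum(model$eigenvalues)
}

# Accept pose_set or plain matrix.
pose_matrix <- function(x) {
  if (inherits(x, "pose_set")) x$x else as.matrix(x)
}
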