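#' Plot helpers for reconstruction and latent-space summaries
#'
#' Small ggplot2 wrappers for the three standard views of the analysis:
#' VAF as a function of latent width per reducer, stacked normalized
#' dimensional-variance bars per bottleneck width, and a 2-D latent
#' scatter colored by class or subject. ggplot2 is only suggested; these
#' helpers error informatively when it is unavailable.
#'
#' @param df for `plot_vaf_curve`: data.frame with columns `reducer`, `k`,
#'   `vaf`; for `plot_dimensional_variance`: columns `reducer`, `width`,
#'   `dim`, `ratio`.
#' @param latent n x 2 latent matrix.
#' @param labels class or subject label per latent point.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_vaf_curve <- function(df, title = "Variance accounted for") {
  need_ggplot2()
  ggplot2::ggplot(df, ggplot2::aes(x = k, y = vaf, colour = reducer)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "latent dimensions", y = "VAF (%)", title = title) +
    ggplot2::theme_minimal()
}

#' @rdname plot_vaf_curve
#' @export
plot_dimensional_variance <- function(df, title = "Dimensional variance") {
  need_ggplot2()
  ggplot2::ggplot(df, ggplot2::aes(x = factor(width), y = ratio,
                                   fill = factor(dim))) +
    ggplot2::geom_col(position = "stack", show.legend = FALSE) +
    ggplot2::facet_wrap(~reducer) +
    ggplot2::labs(x = "bottleneck width", y = "variance ratio", title = title) +
    ggplot2::theme_minimal()
}

#' @rdname plot_vaf_curve
#' @export
plot_latent <- function(latent, labels, title = "Latent space") {
  need_ggplot2()
  df <- data.frame(x = latent[, 1], y = latent[, 2], label = labels)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = label)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "latent 1", y = "latent 2", title = title) +
    ggplot2::theme_minimal()
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    gl_stop("ggplot2 is required for plotting helpers", "gaitlatent_error_suggests")
  }
}
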