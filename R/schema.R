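#' Joint-angle channel schemas
#'
#' Lower-limb kinematics are described by three joints (hip, knee, ankle)
#' on each side of the body, each decomposed into three anatomical planes
#' (sagittal, frontal, transverse) of an Euler ZXY joint-angle vector in
#' degrees. The full schema therefore has 18 channels. The analysis schema
#' drops the frontal and transverse planes of the knees, which in wearable
#' motion capture mostly reflect sensor noise rather than physiological
#' movement, leaving the 14 channels every reducer consumes.
#'
#' Channel order is fixed: joints in the order hip, knee, ankle; within a
#' joint, left side before right; within a side, sagittal, frontal,
#' transverse. Channel names are `"<joint>_<side>_<plane>"`.
#'
#' @param reduced logical; if `TRUE` return the 14-channel analysis schema,
#'   otherwise the full 18-channel schema.
#' @return a data.frame with columns `channel`, `joint`, `side`, `plane`.
#' @export
#' @examples
#' nrow(channel_schema())          # 18
#' nrow(channel_schema(reduced = TRUE))  # 14
channel_schema <- function(reduced = FALSE) {
  joints <- c("hip", "knee", "ankle")
  sides  <- c("left", "right")
  planes <- c("sagittal", "frontal", "transverse")
  g <- expand.grid(plane = planes, side = sides, joint = joints,
                   stringsAsFactors = FALSE)[, c("joint", "side", "plane")]
  g$channel <- paste(g$joint, g$side, g$plane, sep = "_")
  g <- g[, c("channel", "joint", "side", "plane")]
  rownames(g) <- NULL
  if (reduced) {
    g <- g[!(g$joint == "knee" & g$plane %in% c("frontal", "transverse")), ]
    rownames(g) <- NULL
  }
  g
}

# Names of the channels kept for analysis, in fixed order.
analysis_channels <- function() channel_schema(reduced = TRUE)$channel

full_channels <- function() channel_schema()$channel
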