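#' Landmark template: index ranges of the 85-point hip outline
#'
#' The outline convention places 85 points around the left proximal femur and
#' acetabulum. The measurements only rely on a handful of published index
#' ranges: points 15--28 define the femoral-head circle of best fit, the
#' superior minimum joint-space width is taken between points 78--84
#' (acetabulum) and 22--31 (femoral head), and point 78 marks the lateral
#' acetabular edge used for the centre-edge angle. The femoral-neck ranges are
#' not part of the published template and default to the layout used by the
#' synthetic generator; override them for outlines with a different ordering.
#'
#' All indices are 1-based and ranges are inclusive on both ends.
#'
#' @param head_circle_range integer length-2, first/last index of the points
#'   fitted by the head circle. Default \code{c(15, 28)}.
#' @param mjsw_acetabulum_range integer length-2, acetabular polyline for mJSW.
#'   Default \code{c(78, 84)}.
#' @param mjsw_femoral_range integer length-2, femoral polyline for mJSW.
#'   Default \code{c(22, 31)}.
#' @param lateral_edge_index index of the lateral acetabular edge point used by
#'   the lateral centre-edge angle. Default 78.
#' @param neck_superior_range integer length-2, superior (superolateral) neck
#'   boundary sub-polyline.
#' @param neck_inferior_range integer length-2, inferior (inferomedial) neck
#'   boundary sub-polyline.
#' @param scan_end_index last outline index scanned for the alpha-angle
#'   departure point; the scan runs from the end of \code{head_circle_range}
#'   toward the neck. Defaults to the index just before
#'   \code{neck_superior_range}.
#' @param n_points total number of outline points (85).
#' @return an object of class \code{hip_template}.
#' @export
#' @examples
#' tpl <- hip_template()
#' tpl$head_circle_range
hip_template <- function(head_circle_range = c(15L, 28L),
                         mjsw_acetabulum_range = c(78L, 84L),
                         mjsw_femoral_range = c(22L, 31L),
                         lateral_edge_index = 78L,
                         neck_superior_range = c(47L, 60L),
                         neck_inferior_range = c(1L, 10L),
                         scan_end_index = NULL,
                         n_points = 85L) {
  tpl <- list(
    head_circle_range = as.integer(head_circle_range),
    mjsw_acetabulum_range = as.integer(mjsw_acetabulum_range),
    mjsw_femoral_range = as.integer(mjsw_femoral_range),
    lateral_edge_index = as.integer(lateral_edge_index),
    neck_superior_range = as.integer(neck_superior_range),
    neck_inferior_range = as.integer(neck_inferior_range),
    scan_end_index = as.integer(scan_end_index %||%
                                  (min(neck_superior_range) - 1L)),
    n_points = as.integer(n_points)
  )
  class(tpl) <- "hip_template"
  validate_template(tpl)
  tpl
}

validate_template <- function(tpl) {
  rng_fields <- c("head_circle_range", "mjsw_acetabulum_range",
                  "mjsw_femoral_range", "neck_superior_range",
                  "neck_inferior_range")
  for (f in rng_fields) {
    r <- tpl[[f]]
    if (length(r) != 2L || any(!is.finite(r)))
      stopf("template %s must be two finite indices", f)
    if (r[1] > r[2]) stopf("template %s is empty (start > end)", f)
    if (r[1] < 1L || r[2] > tpl$n_points)
      stopf("template %s outside [1, %d]", f, tpl$n_points)
  }
  i <- tpl$lateral_edge_index
  if (length(i) != 1L || i < 1L || i > tpl$n_points)
    stopf("lateral_edge_index outside [1, %d]", tpl$n_points)
  invisible(tpl)
}

range_idx <- function(r) seq.int(r[1], r[2])

#' @export
print.hip_template <- function(x, ...) {
  cat("Hip landmark template (", x$n_points, " points)\n", sep = "")
  cat("  head circle fit : points ", x$head_circle_range[1], "-",
      x$head_circle_range[2], "\n", sep = "")
  cat("  mJSW acetabulum : points ", x$mjsw_acetabulum_range[1], "-",
      x$mjsw_acetabulum_range[2], "\n", sep = "")
  cat("  mJSW femoral    : points ", x$mjsw_femoral_range[1], "-",
      x$mjsw_femoral_range[2], "\n", sep = "")
  cat("  lateral edge    : point ", x$lateral_edge_index, "\n", sep = "")
  cat("  neck superior   : points ", x$neck_superior_range[1], "-",
      x$neck_superior_range[2], "; inferior ", x$neck_inferior_range[1], "-",
      x$neck_inferior_range[2], "\n", sep = "")
  invisible(x)
}
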