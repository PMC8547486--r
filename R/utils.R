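# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Round half away from zero
#'
#' Base \code{round()} rounds halves to even; descriptive tables here use
#' commercial rounding (half away from zero) instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage display rounding used by the descriptive tables: two-stage
# (2 dp then 1 dp, each half away from zero). Stage one absorbs floating-point
# representation of ratios such as 519/3382 so that e.g. 15.3459...% -> 15.35
# -> 15.4, the convention the reported tables follow.
format_pct <- function(count, total) {
  if (total <= 0) return(NA_real_)
  round_half_away(round_half_away(100 * count / total, 2), 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == floor(x)

# angle of vector (x, y) in degrees, in [0, 360)
polar_deg <- function(x, y) {
  a <- rad2deg(atan2(y, x))
  ifelse(a < 0, a + 360, a)
}

# unsigned angle in degrees between two 2-D vectors, in [0, 180]
angle_between_deg <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu == 0 || cv == 0) stopf("angle undefined for zero-length vector")
  rad2deg(acos(max(-1, min(1, sum(u * v) / (cu * cv)))))
}
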