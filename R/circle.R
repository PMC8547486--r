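#' Least-squares circle of best fit
#'
#' Fits the circle minimising the sum of squared radial (geometric) residuals
#' \eqn{\sum_i (\lVert p_i - c \rVert - r)^2}. An algebraic (Kasa) fit gives
#' the starting values; Gauss--Newton iteration on the geometric residuals
#' refines them until the parameter step falls below 1e-10 mm or 100
#' iterations. The result is independent of point order and equivariant under
#' rigid motions of the input.
#'
#' @param points numeric matrix (n x 2) of planar coordinates, n >= 3, not all
#'   collinear.
#' @return object of class \code{circle_fit}: \code{centre} (length-2),
#'   \code{radius}, \code{rms_radial_residual}, \code{n_points},
#'   \code{converged}.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' fit_circle(cbind(3 + 5 * cos(th), -2 + 5 * sin(th)))
fit_circle <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stopf("points must be an n x 2 matrix")
  n <- nrow(points)
  if (n < 3L) stopf("degenerate geometry: circle fit needs >= 3 points")
  if (any(!is.finite(points))) stopf("non-finite coordinates in circle fit")

  x <- points[, 1]; y <- points[, 2]
  # collinearity check on centred coordinates
  cx <- x - mean(x); cy <- y - mean(y)
  M <- cbind(cx, cy)
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[2] <= max(sv[1], 1) * 1e-10)
    stopf("degenerate geometry: points are collinear")

  # Kasa algebraic fit: x^2 + y^2 + D x + E y + F = 0
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coefs <- qr.coef(qr(A), b)
  a0 <- -coefs[1] / 2; b0 <- -coefs[2] / 2
  r0 <- sqrt(max(a0^2 + b0^2 - coefs[3], .Machine$double.eps))

  # Gauss-Newton on geometric residuals
  par <- c(a0, b0, r0)
  converged <- FALSE
  for (it in seq_len(100L)) {
    dx <- x - par[1]; dy <- y - par[2]
    di <- sqrt(dx^2 + dy^2)
    di[di == 0] <- .Machine$double.eps
    resid <- di - par[3]
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.coef(qr(J), -resid), error = function(e) rep(0, 3))
    step[!is.finite(step)] <- 0
    par <- par + step
    if (sqrt(sum(step^2)) < 1e-10) { converged <- TRUE; break }
  }
  dx <- x - par[1]; dy <- y - par[2]
  di <- sqrt(dx^2 + dy^2)
  if (par[3] <= 0) stopf("degenerate geometry: non-positive fitted radius")
  structure(list(centre = c(x = unname(par[1]), y = unname(par[2])),
                 radius = unname(par[3]),
                 rms_radial_residual = sqrt(mean((di - par[3])^2)),
                 n_points = n, converged = converged),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Circle fit (%d points): centre (%.*f, %.*f) mm, radius %.*f mm, RMS residual %.*g mm\n",
              x$n_points, digits, x$centre[1], digits, x$centre[2],
              digits, x$radius, digits, x$rms_radial_residual))
  invisible(x)
}
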