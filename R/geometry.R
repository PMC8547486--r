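# Geometric measurements on a landmark outline: neck axis, alpha angle,
# lateral centre-edge angle and minimum joint-space width.

# distance from point p to segment [a, b]; returns list(dist, closest)
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  q <- a + t * ab
  list(dist = sqrt(sum((p - q)^2)), closest = q)
}

# minimum over vertices of P (m x 2) to segments of polyline Q (k x 2);
# returns list(dist, p, q) with achieving points
vertices_to_polyline <- function(P, Q) {
  best <- list(dist = Inf, p = NULL, q = NULL)
  nq <- nrow(Q)
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    if (nq == 1L) {
      d <- sqrt(sum((p - Q[1, ])^2))
      if (d < best$dist) best <- list(dist = d, p = p, q = Q[1, ])
      next
    }
    for (j in seq_len(nq - 1L)) {
      r <- point_segment_dist(p, Q[j, ], Q[j + 1L, ])
      if (r$dist < best$dist) best <- list(dist = r$dist, p = p, q = r$closest)
    }
  }
  best
}

# symmetric polyline-to-polyline minimum distance (vertex-to-segment both ways)
polyline_min_dist <- function(P, Q) {
  a <- vertices_to_polyline(P, Q)
  b <- vertices_to_polyline(Q, P)
  if (b$dist < a$dist) list(dist = b$dist, p = b$q, q = b$p) else a
}

#' Estimate the femoral neck axis
#'
#' The neck axis is the line through the fitted femoral-head centre and the
#' neck centre, taken as the midpoint of the minimum-width cross-section
#' between the superior and inferior neck boundary sub-polylines of the
#' outline (the published measurement protocol states only "centre of the
#' femoral head and neck"; this construction is the package's documented
#' stand-in and is configurable through the template's neck ranges).
#'
#' @param landmarks a \code{landmark_set}.
#' @param template a \code{hip_template} with non-degenerate neck ranges.
#' @param circle a \code{circle_fit} of the femoral head.
#' @return object of class \code{neck_axis}: \code{head_centre},
#'   \code{neck_centre}, \code{direction} (unit vector head -> neck),
#'   \code{neck_width_mm}.
#' @export
estimate_neck_axis <- function(landmarks, template, circle) {
  sup_r <- template$neck_superior_range
  inf_r <- template$neck_inferior_range
  if (identical(sup_r, inf_r))
    stopf("configuration error: superior and inferior neck ranges coincide")
  if (max(min(sup_r), min(inf_r)) <= min(max(sup_r), max(inf_r)) &&
      length(intersect(range_idx(sup_r), range_idx(inf_r))) > 0)
    stopf("configuration error: neck ranges overlap")
  hc <- range_idx(template$head_circle_range)
  if (length(intersect(range_idx(sup_r), hc)) > 0 ||
      length(intersect(range_idx(inf_r), hc)) > 0)
    stopf("configuration error: neck ranges overlap the head-circle range")
  P <- landmarks$points[range_idx(sup_r), , drop = FALSE]
  Q <- landmarks$points[range_idx(inf_r), , drop = FALSE]
  hit <- polyline_min_dist(P, Q)
  if (!is.finite(hit$dist) || hit$dist == 0)
    stopf("configuration error: zero-width neck cross-section")
  neck_centre <- (hit$p + hit$q) / 2
  head_centre <- unname(circle$centre)
  d <- neck_centre - head_centre
  nd <- sqrt(sum(d^2))
  if (nd == 0) stopf("degenerate geometry: neck centre equals head centre")
  structure(list(head_centre = head_centre, neck_centre = unname(neck_centre),
                 direction = unname(d / nd), neck_width_mm = hit$dist),
            class = "neck_axis")
}

#' Alpha angle from outline, head circle and neck axis
#'
#' Walks the outline from the last head-circle index toward the neck
#' (increasing outline index, up to the template's \code{scan_end_index}) and
#' finds the first location where the radial distance from the fitted head
#' centre exceeds \code{radius * (1 + departure_tolerance_frac)}. The crossing
#' is linearly interpolated between the last interior and first exterior
#' outline points. The alpha angle is the angle at the head centre between the
#' neck-axis direction and the direction to this departure point, in degrees.
#'
#' @param landmarks a \code{landmark_set}.
#' @param template a \code{hip_template}.
#' @param circle a \code{circle_fit}.
#' @param axis a \code{neck_axis}.
#' @param departure_tolerance_frac radial tolerance as a fraction of the
#'   fitted radius, in (0, 0.2); default 0.02.
#' @param min_run number of consecutive scanned points that must exceed the
#'   tolerance for a departure to count (runs truncated by the scan end are
#'   accepted). Default 3, which leaves noiseless outlines untouched (a true
#'   bump keeps growing) while suppressing isolated noise spikes.
#' @return list with \code{alpha_angle_deg} and \code{departure_point}.
#'   If no scanned point leaves the tolerance band a condition of class
#'   \code{hip_no_departure} is signalled (spherical head: alpha undefined).
#' @export
compute_alpha_angle <- function(landmarks, template, circle, axis,
                                departure_tolerance_frac = 0.02,
                                min_run = 3L) {
  if (!is.finite(departure_tolerance_frac) ||
      departure_tolerance_frac <= 0 || departure_tolerance_frac >= 0.2)
    stopf("departure_tolerance_frac must lie in (0, 0.2)")
  start <- max(template$head_circle_range)
  end <- template$scan_end_index
  if (end <= start) stopf("configuration error: empty departure scan range")
  idx <- seq.int(start, end)
  pts <- landmarks$points[idx, , drop = FALSE]
  ctr <- circle$centre
  di <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  thr <- circle$radius * (1 + departure_tolerance_frac)
  above <- di > thr
  sustained <- function(k) {
    run <- seq.int(k, min(length(above), k + min_run - 1L))
    all(above[run])
  }
  out <- Filter(sustained, which(above))
  if (!length(out)) {
    cond <- structure(class = c("hip_no_departure", "error", "condition"),
                      list(message = sprintf(
                        "no departure: outline of '%s' stays within %.1f%% of the head circle",
                        landmarks$participant_id,
                        100 * departure_tolerance_frac), call = NULL))
    stop(cond)
  }
  k <- out[1]
  if (k == 1L) {
    cond <- structure(class = c("hip_no_departure", "error", "condition"),
                      list(message = sprintf(
                        "departure undefined: outline of '%s' already outside tolerance at scan start",
                        landmarks$participant_id), call = NULL))
    stop(cond)
  }
  t <- (thr - di[k - 1L]) / (di[k] - di[k - 1L])
  dep <- pts[k - 1L, ] + t * (pts[k, ] - pts[k - 1L, ])
  aa <- angle_between_deg(axis$direction, dep - ctr)
  list(alpha_angle_deg = unname(aa), departure_point = unname(dep))
}

#' Lateral centre-edge angle
#'
#' Angle at the fitted femoral-head centre between the vertical (the line
#' perpendicular to the image x-axis through the centre) and the segment to
#' the lateral acetabular edge point (template index, default 78). Signed:
#' positive when the edge lies lateral of the vertical (canonical frame,
#' lateral = -x), negative when medial.
#'
#' @inheritParams compute_alpha_angle
#' @return list with \code{lcea_deg}.
#' @export
compute_lcea <- function(landmarks, template, circle) {
  edge <- landmarks$points[template$lateral_edge_index, ]
  d <- edge - circle$centre
  if (sqrt(sum(d^2)) == 0)
    stopf("degenerate geometry: lateral edge point coincides with head centre")
  # lateral = -x, superior = +y: positive angle when dx < 0
  list(lcea_deg = unname(rad2deg(atan2(-d[1], d[2]))))
}

#' Minimum joint-space width
#'
#' Minimum Euclidean distance between the acetabular polyline (template
#' points 78--84) and the femoral-head polyline (points 22--31), computed as
#' the minimum over all vertex-to-segment distances in both directions
#' (symmetric in its arguments).
#'
#' @inheritParams compute_alpha_angle
#' @return list with \code{mjsw_mm} and the achieving points
#'   \code{acetabular_point}, \code{femoral_point}.
#' @export
compute_mjsw <- function(landmarks, template) {
  ar <- template$mjsw_acetabulum_range
  fr <- template$mjsw_femoral_range
  ai <- range_idx(ar); fi <- range_idx(fr)
  if (length(intersect(ai, fi)) > 0)
    stopf("configuration error: mJSW ranges overlap")
  if (length(ai) < 2L || length(fi) < 2L)
    stopf("configuration error: mJSW polylines need >= 2 points")
  A <- landmarks$points[ai, , drop = FALSE]
  B <- landmarks$points[fi, , drop = FALSE]
  hit <- polyline_min_dist(A, B)
  list(mjsw_mm = hit$dist, acetabular_point = unname(hit$p),
       femoral_point = unname(hit$q))
}

#' Measure one hip outline
#'
#' Runs the full geometric chain: head-circle fit on the template's
#' head-circle range, neck-axis estimation, alpha angle (with no-departure
#' flagging), lateral centre-edge angle and minimum joint-space width.
#'
#' @param landmarks a \code{landmark_set}.
#' @param template a \code{hip_template} (default \code{hip_template()}).
#' @param departure_tolerance_frac see \code{\link{compute_alpha_angle}}.
#' @return object of class \code{hip_measures}: \code{participant_id},
#'   \code{alpha_angle_deg} (NA when no departure), \code{lcea_deg},
#'   \code{mjsw_mm}, \code{departure_flag} (TRUE when a departure point was
#'   found), \code{departure_point}, \code{circle}, \code{axis}.
#' @export
#' @examples
#' tpl <- hip_template()
#' hip <- generate_hip_outline(shape_params(cam_present = TRUE,
#'                                          cam_departure_deg = 72.5), tpl)
#' measure_hip(hip$landmarks, tpl)
measure_hip <- function(landmarks, template = hip_template(),
                        departure_tolerance_frac = 0.02) {
  circ <- fit_circle(landmarks$points[range_idx(template$head_circle_range), ,
                                      drop = FALSE])
  axis <- estimate_neck_axis(landmarks, template, circ)
  aa <- tryCatch(
    compute_alpha_angle(landmarks, template, circ, axis,
                        departure_tolerance_frac),
    hip_no_departure = function(e) list(alpha_angle_deg = NA_real_,
                                        departure_point = NULL))
  lc <- compute_lcea(landmarks, template, circ)
  mj <- compute_mjsw(landmarks, template)
  structure(list(participant_id = landmarks$participant_id,
                 alpha_angle_deg = aa$alpha_angle_deg,
                 lcea_deg = lc$lcea_deg,
                 mjsw_mm = mj$mjsw_mm,
                 departure_flag = !is.na(aa$alpha_angle_deg),
                 departure_point = aa$departure_point,
                 circle = circ, axis = axis),
            class = "hip_measures")
}

#' @export
print.hip_measures <- function(x, ...) {
  cat("Hip measures, participant ", x$participant_id, ":\n", sep = "")
  cat(sprintf("  alpha angle : %s\n",
              if (is.na(x$alpha_angle_deg)) "undefined (no departure)"
              else sprintf("%.1f deg", x$alpha_angle_deg)))
  cat(sprintf("  LCEA        : %.1f deg\n", x$lcea_deg))
  cat(sprintf("  mJSW        : %.2f mm\n", x$mjsw_mm))
  invisible(x)
}

#' Measure a cohort of landmark outlines
#'
#' @param landmarks named list of \code{landmark_set} objects.
#' @param template a \code{hip_template}.
#' @param departure_tolerance_frac radial departure tolerance fraction.
#' @return data.frame with one row per outline:
#'   \code{participant_id, alpha_angle_deg, lcea_deg, mjsw_mm, departure_flag}.
#' @export
measure_cohort <- function(landmarks, template = hip_template(),
                           departure_tolerance_frac = 0.02) {
  rows <- lapply(landmarks, function(ls) {
    m <- measure_hip(ls, template, departure_tolerance_frac)
    data.frame(participant_id = m$participant_id,
               alpha_angle_deg = m$alpha_angle_deg,
               lcea_deg = m$lcea_deg, mjsw_mm = m$mjsw_mm,
               departure_flag = m$departure_flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
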