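#' Construct a landmark set for one hip
#'
#' An ordered outline of planar landmark coordinates in millimetres, in the
#' canonical left-hip frame: superior = +y, lateral = -x. Readers of imaging
#' exports with a different axis convention should normalise before
#' construction (e.g. flip y for image-row coordinates).
#'
#' @param participant_id identifier (coerced to character).
#' @param points numeric matrix with \code{n_points} rows and 2 columns (x, y)
#'   in mm.
#' @param n_points expected number of points (default 85).
#' @return object of class \code{landmark_set} with fields
#'   \code{participant_id}, \code{points}, \code{side}, \code{orientation}.
#' @export
landmark_set <- function(participant_id, points, n_points = 85L) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stopf("points must be a two-column (x, y) matrix")
  if (nrow(points) != n_points)
    stopf("landmark set for '%s' has %d points, expected %d [point_count]",
          participant_id, nrow(points), n_points)
  if (any(!is.finite(points)))
    stopf("landmark set for '%s' has non-finite coordinates [nonfinite]",
          participant_id)
  d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(d == 0))
    stopf("landmark set for '%s' has coincident consecutive points [coincident]",
          participant_id)
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(participant_id = as.character(participant_id),
                 points = points, side = "left", orientation = "canonical"),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmark set: participant ", x$participant_id, ", ",
      nrow(x$points), " points (", x$side, " hip, ", x$orientation,
      " frame)\n", sep = "")
  invisible(x)
}

#' Read a landmark cohort from CSV
#'
#' Expects columns \code{participant_id,point_index,x_mm,y_mm}; one row per
#' outline point, points 1..85 per participant. Invalid records (wrong point
#' count, non-finite coordinates, coincident consecutive points) are dropped
#' with a reason code rather than aborting the cohort.
#'
#' @param path CSV file path.
#' @param n_points expected points per outline (default 85).
#' @return list with \code{landmarks} (named list of \code{landmark_set}) and
#'   \code{rejected} (data.frame participant_id, reason).
#' @export
read_landmarks <- function(path, n_points = 85L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "point_index", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stopf("landmark CSV must have columns %s", paste(need, collapse = ", "))
  ids <- unique(as.character(df$participant_id))
  out <- vector("list", length(ids)); names(out) <- ids
  rej <- list()
  for (id in ids) {
    sub <- df[as.character(df$participant_id) == id, , drop = FALSE]
    sub <- sub[order(sub$point_index), , drop = FALSE]
    ls <- tryCatch(
      landmark_set(id, cbind(sub$x_mm, sub$y_mm), n_points = n_points),
      error = function(e) e)
    if (inherits(ls, "error")) {
      reason <- regmatches(conditionMessage(ls),
                           regexpr("\\[[a-z_]+\\]", conditionMessage(ls)))
      rej[[length(rej) + 1L]] <- data.frame(
        participant_id = id,
        reason = if (length(reason)) gsub("[][]", "", reason) else "invalid",
        stringsAsFactors = FALSE)
      out[[id]] <- NULL
    } else out[[id]] <- ls
  }
  list(landmarks = Filter(Negate(is.null), out),
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(participant_id = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

#' Write a landmark cohort to CSV
#'
#' @param landmarks list of \code{landmark_set} objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- lapply(landmarks, function(ls) {
    data.frame(participant_id = ls$participant_id,
               point_index = seq_len(nrow(ls$points)),
               x_mm = ls$points[, 1], y_mm = ls$points[, 2],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
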