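# Ordinal grading: ROC-calibrated thresholds for osteophyte areas and
# height-adjusted mJSW, morphology classification, and the composite
# radiographic hip OA (rHOA) definitions.

#' Calibrate a grade threshold by ROC analysis
#'
#' Finds the cutpoint on a continuous measure that best predicts a reference
#' grade of at least \code{boundary}, by maximising Youden's J
#' (sensitivity + specificity - 1) over all midpoints between consecutive
#' sorted unique values — the classical ROC operating-point calibration used
#' to turn shaded osteophyte areas (or adjusted mJSW) into semi-quantitative
#' grades. An alternative closest-to-(0,1) criterion is available.
#'
#' @param values numeric vector of the continuous measure (finite).
#' @param reference_grades integer vector of reference ordinal grades.
#' @param boundary grade boundary being calibrated (positive class is
#'   \code{reference_grades >= boundary}). Default 1.
#' @param direction \code{"greater"} if larger values indicate higher grade
#'   (osteophyte area), \code{"less"} if smaller values do (adjusted mJSW).
#' @param criterion \code{"youden"} (default) or \code{"closest_topleft"}.
#' @return the threshold (numeric scalar) with attributes \code{youden},
#'   \code{sensitivity}, \code{specificity}. Among tied optimal candidates the
#'   midpoint of the first contiguous optimal interval is returned.
#' @export
#' @examples
#' area <- c(0, 0.2, 0.5, 3, 4, 9)
#' grade <- c(0, 0, 0, 1, 1, 2)
#' calibrate_threshold_roc(area, grade, boundary = 1)
calibrate_threshold_roc <- function(values, reference_grades, boundary = 1L,
                                    direction = c("greater", "less"),
                                    criterion = c("youden", "closest_topleft")) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  if (length(values) != length(reference_grades))
    stopf("values and reference_grades must have equal length")
  if (any(!is.finite(values))) stopf("non-finite values in calibration")
  pos <- reference_grades >= boundary
  if (!any(pos) || all(pos))
    stopf("calibration error: only one grade class present at boundary %d",
          boundary)
  v <- if (direction == "greater") values else -values
  u <- sort(unique(v))
  if (length(u) < 2L)
    stopf("calibration error: all values identical")
  cand <- (u[-1] + u[-length(u)]) / 2
  npos <- sum(pos); nneg <- sum(!pos)
  stat <- vapply(cand, function(cc) {
    pred <- v >= cc
    sens <- sum(pred & pos) / npos
    spec <- sum(!pred & !pos) / nneg
    c(sens = sens, spec = spec,
      score = if (criterion == "youden") sens + spec - 1
      else -sqrt((1 - sens)^2 + (1 - spec)^2))
  }, numeric(3))
  best <- which(stat["score", ] == max(stat["score", ]))
  # first contiguous run of optimal candidates; threshold at its midpoint
  run_end <- best[1]
  while (run_end + 1 <= length(cand) && (run_end + 1) %in% best)
    run_end <- run_end + 1
  thr <- (cand[best[1]] + cand[run_end]) / 2
  pred <- v >= thr
  out <- if (direction == "greater") thr else -thr
  structure(out,
            youden = sum(pred & pos) / npos + sum(!pred & !pos) / nneg - 1,
            sensitivity = sum(pred & pos) / npos,
            specificity = sum(!pred & !pos) / nneg)
}

#' Grade thresholds for one site
#'
#' @param site one of \code{"acetabular"}, \code{"superior_femoral"},
#'   \code{"inferior_femoral"}, \code{"jsn"}.
#' @param cutpoints strictly increasing numeric vector of 1--3 cutpoints on
#'   the measure's scale (grade boundaries 1, 2, 3).
#' @param direction \code{"greater"} (higher measure, higher grade; the
#'   osteophyte sites) or \code{"less"} (lower measure, higher grade; JSN).
#'   Defaults to \code{"less"} for site \code{"jsn"}.
#' @return object of class \code{grade_thresholds}.
#' @export
grade_thresholds <- function(site, cutpoints,
                             direction = if (site == "jsn") "less" else "greater") {
  site <- match.arg(site, c("acetabular", "superior_femoral",
                            "inferior_femoral", "jsn"))
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 1L || length(cutpoints) > 3L)
    stopf("1 to 3 cutpoints required")
  if (any(!is.finite(cutpoints)) || any(diff(cutpoints) <= 0))
    stopf("cutpoints must be finite and strictly increasing")
  structure(list(site = site, cutpoints = cutpoints, direction = direction),
            class = "grade_thresholds")
}

#' Ordinal grade from a continuous measure
#'
#' For an increasing direction the grade is the number of cutpoints less than
#' or equal to the value (so a value exactly on a cutpoint receives the higher
#' grade). For JSN the comparison is mirrored: the grade is the number of
#' cutpoints greater than or equal to the value (smaller adjusted mJSW, higher
#' grade).
#'
#' @param value numeric vector of measures (finite).
#' @param thresholds a \code{\link{grade_thresholds}} object.
#' @return integer vector of grades 0..length(cutpoints).
#' @export
#' @examples
#' th <- grade_thresholds("acetabular", c(1, 4, 9))
#' grade_from_thresholds(c(0, 4, 20), th)   # 0, 2, 3
grade_from_thresholds <- function(value, thresholds) {
  stopifnot(inherits(thresholds, "grade_thresholds"))
  if (any(!is.finite(value))) stopf("non-finite measure in grading")
  cp <- thresholds$cutpoints
  g <- if (thresholds$direction == "greater")
    rowSums(outer(value, cp, `>=`))
  else
    rowSums(outer(value, cp, `<=`))
  as.integer(g)
}

#' Fit a sex-specific linear height adjustment for mJSW
#'
#' Regresses mJSW on height separately by sex on a calibration cohort,
#' returning per-sex slope and mean height for use by
#' \code{\link{height_adjust_mjsw}}.
#'
#' @param mjsw_mm,height_cm numeric vectors.
#' @param sex character vector ("male"/"female").
#' @return list with \code{male} and \code{female} components, each
#'   \code{list(slope, mean_height)}.
#' @export
fit_height_adjustment <- function(mjsw_mm, height_cm, sex) {
  out <- list()
  for (s in c("male", "female")) {
    i <- sex == s & is.finite(mjsw_mm) & is.finite(height_cm)
    if (sum(i) < 3L) {
      out[[s]] <- list(slope = 0, mean_height = NA_real_)
      next
    }
    fit <- stats::lm.fit(cbind(1, height_cm[i]), mjsw_mm[i])
    out[[s]] <- list(slope = unname(fit$coefficients[2]),
                     mean_height = mean(height_cm[i]))
  }
  out
}

#' Height-adjusted mJSW
#'
#' Removes the linear height trend from mJSW before JSN grading:
#' \code{adjusted = mjsw - slope_sex * (height - mean_height_sex)}. With a
#' zero slope this is the identity. Missing heights yield NA (such records
#' are excluded from JSN grading, complete-case).
#'
#' @param mjsw_mm,height_cm numeric vectors.
#' @param sex character vector ("male"/"female").
#' @param reference adjustment model as returned by
#'   \code{\link{fit_height_adjustment}}.
#' @return numeric vector of adjusted mJSW (mm).
#' @export
height_adjust_mjsw <- function(mjsw_mm, height_cm, sex, reference) {
  slope <- vapply(sex, function(s) reference[[s]]$slope %||% 0, numeric(1))
  mh <- vapply(sex, function(s) reference[[s]]$mean_height %||% NA_real_,
               numeric(1))
  adj <- mjsw_mm - slope * (height_cm - mh)
  unname(ifelse(is.finite(height_cm), adj, NA_real_))
}

#' Classify cam, pincer and acetabular dysplasia
#'
#' Cam morphology: alpha angle >= 60 degrees. Pincer morphology: LCEA >= 45
#' degrees. Acetabular dysplasia (AD): LCEA < 25 degrees. Boundary
#' inclusivity exactly as stated. Records with undefined alpha angle (no
#' departure) are classified on LCEA only, with cam absent.
#'
#' @param alpha_angle_deg numeric vector (NA allowed: no-departure records).
#' @param lcea_deg numeric vector.
#' @param cam_cut_deg,pincer_cut_deg,ad_cut_deg classification cutoffs
#'   (defaults 60, 45, 25).
#' @return data.frame with logical columns \code{cam}, \code{pincer},
#'   \code{acetabular_dysplasia}; attribute \code{n_no_departure} counts
#'   records with undefined alpha angle.
#' @export
classify_morphology <- function(alpha_angle_deg, lcea_deg, cam_cut_deg = 60,
                                pincer_cut_deg = 45, ad_cut_deg = 25) {
  cam <- !is.na(alpha_angle_deg) & alpha_angle_deg >= cam_cut_deg
  structure(data.frame(cam = cam,
                       pincer = lcea_deg >= pincer_cut_deg,
                       acetabular_dysplasia = lcea_deg < ad_cut_deg),
            n_no_departure = sum(is.na(alpha_angle_deg)))
}

#' Radiographic hip OA from constituent grades
#'
#' rHOA requires both grade >= 1 JSN and a grade >= 1 osteophyte at any of
#' the three sites; the stricter rHOA grade >= 2 requires grade >= 2 of each.
#'
#' @param jsn_grade integer vector.
#' @param op_acetabular,op_superior_femoral,op_inferior_femoral integer
#'   vectors of per-site osteophyte grades.
#' @return data.frame with logical columns \code{rhoa}, \code{rhoa_grade2}.
#' @export
classify_rhoa <- function(jsn_grade, op_acetabular, op_superior_femoral,
                          op_inferior_femoral) {
  op_max <- pmax(op_acetabular, op_superior_femoral, op_inferior_femoral)
  data.frame(rhoa = jsn_grade >= 1 & op_max >= 1,
             rhoa_grade2 = jsn_grade >= 2 & op_max >= 2)
}

#' Default (synthetic) grading configuration
#'
#' Cutpoints on this scale are study-specific and ROC-calibrated in practice;
#' these defaults are synthetic values aligned with the synthetic cohort
#' generator's area and mJSW distributions, for use when no calibration
#' subset is supplied.
#'
#' @return list with \code{osteophyte_cutpoints} (per site),
#'   \code{jsn_cutpoints}, \code{morphology} cutoffs.
#' @export
default_grading_config <- function() {
  list(osteophyte_cutpoints = list(acetabular = c(0.5, 4.5, 14),
                                   superior_femoral = c(0.5, 4.5, 14),
                                   inferior_femoral = c(0.5, 4.5, 14)),
       jsn_cutpoints = c(2.05, 2.75, 3.75),
       morphology = c(cam_deg = 60, pincer_deg = 45, ad_deg = 25))
}

#' Grade a measured cohort
#'
#' Joins geometric measures with per-participant osteophyte areas and
#' covariates, applies (or calibrates) grade thresholds and produces one
#' grading record per participant: per-site osteophyte grades, JSN grade from
#' height-adjusted mJSW, rHOA flags and morphology flags.
#'
#' @param measures data.frame from \code{\link{measure_cohort}} (or columns
#'   \code{participant_id, alpha_angle_deg, lcea_deg, mjsw_mm}).
#' @param participants data.frame with \code{participant_id}, per-site
#'   \code{area_*_mm2} columns, \code{height_cm} and \code{sex}.
#' @param config grading configuration (see
#'   \code{\link{default_grading_config}}).
#' @param height_adjust optional pre-fitted adjustment model
#'   (\code{\link{fit_height_adjustment}}); fitted on this cohort when NULL.
#' @return data.frame of grading records joined to the inputs, one row per
#'   participant present in both inputs.
#' @export
grade_cohort <- function(measures, participants,
                         config = default_grading_config(),
                         height_adjust = NULL) {
  df <- merge(measures, participants, by = "participant_id", sort = TRUE)
  if (nrow(df) == 0) stopf("no overlapping participant ids to grade")
  if (is.null(height_adjust))
    height_adjust <- fit_height_adjustment(df$mjsw_mm, df$height_cm, df$sex)
  sites <- c(acetabular = "area_acetabular_mm2",
             superior_femoral = "area_superior_femoral_mm2",
             inferior_femoral = "area_inferior_femoral_mm2")
  for (s in names(sites)) {
    th <- grade_thresholds(s, config$osteophyte_cutpoints[[s]])
    df[[paste0("op_grade_", s)]] <- grade_from_thresholds(df[[sites[s]]], th)
  }
  df$adjusted_mjsw_mm <- height_adjust_mjsw(df$mjsw_mm, df$height_cm, df$sex,
                                            height_adjust)
  th_jsn <- grade_thresholds("jsn", config$jsn_cutpoints)
  ok <- is.finite(df$adjusted_mjsw_mm)
  df$jsn_grade <- NA_integer_
  df$jsn_grade[ok] <- grade_from_thresholds(df$adjusted_mjsw_mm[ok], th_jsn)
  mo <- classify_morphology(df$alpha_angle_deg, df$lcea_deg,
                            config$morphology["cam_deg"],
                            config$morphology["pincer_deg"],
                            config$morphology["ad_deg"])
  df$cam <- mo$cam; df$pincer <- mo$pincer
  df$acetabular_dysplasia <- mo$acetabular_dysplasia
  rh <- classify_rhoa(ifelse(is.na(df$jsn_grade), 0L, df$jsn_grade),
                      df$op_grade_acetabular, df$op_grade_superior_femoral,
                      df$op_grade_inferior_femoral)
  df$rhoa <- rh$rhoa; df$rhoa_grade2 <- rh$rhoa_grade2
  attr(df, "n_no_departure") <- attr(mo, "n_no_departure")
  df
}
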