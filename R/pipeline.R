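# End-to-end pipeline: simulate -> measure -> grade -> associate, with
# structured logging, deterministic outputs and a repeatability report.

#' Default pipeline configuration
#'
#' @param n_participants cohort size when simulating.
#' @param seed integer seed controlling all randomness in the run.
#' @return nested list understood by \code{\link{run_pipeline}}: template
#'   index ranges, departure tolerance, grading thresholds, morphology
#'   cutoffs, analysis strata and the simulate block.
#' @export
default_pipeline_config <- function(n_participants = 500, seed = 1) {
  list(
    seed = seed,
    simulate = list(n = n_participants, with_landmarks = TRUE),
    template = list(head_circle_range = c(15, 28),
                    mjsw_acetabulum_range = c(78, 84),
                    mjsw_femoral_range = c(22, 31),
                    lateral_edge_index = 78,
                    neck_superior_range = c(47, 60),
                    neck_inferior_range = c(1, 10)),
    alpha = list(departure_tolerance_frac = 0.02),
    grading = default_grading_config(),
    analysis = list(strata = c("male", "female", "combined"),
                    sensitivity_restricted_reference = TRUE,
                    pain_attenuation_stratum = "male"))
}

pipeline_template <- function(config) {
  tc <- config$template
  hip_template(head_circle_range = tc$head_circle_range,
               mjsw_acetabulum_range = tc$mjsw_acetabulum_range,
               mjsw_femoral_range = tc$mjsw_femoral_range,
               lateral_edge_index = tc$lateral_edge_index,
               neck_superior_range = tc$neck_superior_range,
               neck_inferior_range = tc$neck_inferior_range)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> measure -> grade -> associate and writes
#' all stage outputs, descriptive and association tables, a structured log
#' and the resolved configuration to a run directory. Given identical
#' configuration and seed, outputs are byte-identical.
#'
#' @param config configuration list (see
#'   \code{\link{default_pipeline_config}}) or path to a YAML file.
#' @param out_dir run directory (created if needed).
#' @param landmarks_csv optional path to an existing landmark cohort CSV
#'   (schema \code{participant_id,point_index,x_mm,y_mm}); when given, the
#'   simulate stage only draws participant covariates/outcomes if
#'   \code{participants_csv} is not also supplied.
#' @param participants_csv optional path to a participant covariate/area CSV.
#' @return invisibly, a list with the stage outputs (\code{measures},
#'   \code{grades}, \code{table1}, \code{associations}, \code{sensitivity},
#'   \code{pain_attenuation}, \code{log}).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("hipmorph_run_"),
                         landmarks_csv = NULL, participants_csv = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  logf <- function(stage, action, ...) {
    line <- sprintf("[%s] %s %s", stage, action, sprintf(...))
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  template <- pipeline_template(config)
  tol <- config$alpha$departure_tolerance_frac %||% 0.02
  seed <- config$seed %||% 1

  # stage: simulate / load ---------------------------------------------------
  if (is.null(landmarks_csv)) {
    sim <- generate_cohort(config$simulate$n, seed = seed,
                           with_landmarks = isTRUE(config$simulate$with_landmarks))
    participants <- sim$participants
    landmarks <- sim$landmarks
    logf("simulate", "generated", "%d participants (seed %d)",
         nrow(participants), seed)
    write_landmarks(landmarks, file.path(out_dir, "landmarks.csv"))
    utils::write.csv(participants, file.path(out_dir, "participants.csv"),
                     row.names = FALSE)
  } else {
    rl <- read_landmarks(landmarks_csv)
    landmarks <- rl$landmarks
    for (i in seq_len(nrow(rl$rejected)))
      logf("load", "rejected", "%s reason=%s", rl$rejected$participant_id[i],
           rl$rejected$reason[i])
    logf("load", "loaded", "%d records, %d rejected", length(landmarks),
         nrow(rl$rejected))
    if (!length(landmarks)) stopf("no valid landmark records in %s",
                                  landmarks_csv)
    participants <- if (!is.null(participants_csv))
      utils::read.csv(participants_csv, stringsAsFactors = FALSE)
    else generate_cohort(length(landmarks), seed = seed)$participants
  }

  # stage: measure ------------------------------------------------------------
  measures <- measure_cohort(landmarks, template, tol)
  logf("measure", "measured", "%d/%d records; %d without departure point",
       nrow(measures), length(landmarks), sum(!measures$departure_flag))
  utils::write.csv(measures, file.path(out_dir, "measures.csv"),
                   row.names = FALSE)

  # stage: grade ---------------------------------------------------------------
  grades <- grade_cohort(measures, participants, config$grading)
  logf("grade", "graded", "%d records; %d no-departure kept for LCEA analyses",
       nrow(grades), attr(grades, "n_no_departure") %||% 0L)
  utils::write.csv(grades, file.path(out_dir, "grades.csv"), row.names = FALSE)

  # stage: descriptive + associations -----------------------------------------
  tab1 <- prevalence_table(grades)
  utils::write.csv(tab1, file.path(out_dir, "table1.csv"), row.names = FALSE)
  strata <- config$analysis$strata %||% c("male", "female", "combined")
  assoc <- run_association_suite(grades, strata = strata)
  logf("associate", "fitted", "%d cells (%d skipped/flagged)", nrow(assoc),
       sum(assoc$status != "ok"))
  utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                   row.names = FALSE)
  sens <- NULL
  if (isTRUE(config$analysis$sensitivity_restricted_reference)) {
    sens <- run_sensitivity_restricted_reference(grades, strata = strata)
    utils::write.csv(sens, file.path(out_dir, "sensitivity_restricted.csv"),
                     row.names = FALSE)
  }
  pain <- run_pain_attenuation(grades,
                               config$analysis$pain_attenuation_stratum %||%
                                 "male")
  utils::write.csv(pain, file.path(out_dir, "pain_attenuation.csv"),
                   row.names = FALSE)

  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(measures = measures, grades = grades, table1 = tab1,
                 associations = assoc, sensitivity = sens,
                 pain_attenuation = pain, log = log_lines,
                 out_dir = out_dir))
}

#' Repeatability report for re-measured cohorts
#'
#' Compares two measurement passes over the same participants (matched by
#' id): Lin's concordance correlation coefficient for alpha angle and LCEA,
#' and Cohen's kappa with percent agreement for the derived cam, pincer and
#' dysplasia classifications.
#'
#' @param measures_a,measures_b data.frames as from
#'   \code{\link{measure_cohort}}.
#' @param cam_cut_deg,pincer_cut_deg,ad_cut_deg classification cutoffs.
#' @return data.frame: one row per measure with \code{ccc} or \code{kappa}
#'   and \code{percent_agreement}, plus \code{n}.
#' @export
repeatability_report <- function(measures_a, measures_b, cam_cut_deg = 60,
                                 pincer_cut_deg = 45, ad_cut_deg = 25) {
  m <- merge(measures_a, measures_b, by = "participant_id",
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stopf("no overlapping participant ids between passes")
  ok_aa <- is.finite(m$alpha_angle_deg_a) & is.finite(m$alpha_angle_deg_b)
  rows <- list()
  add <- function(measure, ccc = NA_real_, kappa = NA_real_,
                  agree = NA_real_, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, ccc = ccc, kappa = kappa,
      percent_agreement = agree, n = n, stringsAsFactors = FALSE)
  }
  add("alpha_angle", ccc = lin_ccc(m$alpha_angle_deg_a[ok_aa],
                                   m$alpha_angle_deg_b[ok_aa])$ccc,
      n = sum(ok_aa))
  add("lcea", ccc = lin_ccc(m$lcea_deg_a, m$lcea_deg_b)$ccc, n = nrow(m))
  ka <- cohens_kappa(m$alpha_angle_deg_a[ok_aa] >= cam_cut_deg,
                     m$alpha_angle_deg_b[ok_aa] >= cam_cut_deg)
  add("cam", kappa = ka$kappa, agree = ka$percent_agreement, n = sum(ok_aa))
  kp <- cohens_kappa(m$lcea_deg_a >= pincer_cut_deg,
                     m$lcea_deg_b >= pincer_cut_deg)
  add("pincer", kappa = kp$kappa, agree = kp$percent_agreement, n = nrow(m))
  kd <- cohens_kappa(m$lcea_deg_a < ad_cut_deg, m$lcea_deg_b < ad_cut_deg)
  add("acetabular_dysplasia", kappa = kd$kappa,
      agree = kd$percent_agreement, n = nrow(m))
  do.call(rbind, rows)
}
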