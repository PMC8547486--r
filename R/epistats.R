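# Logistic association suite: odds ratios with Wald intervals, sensitivity
# analyses, and the descriptive prevalence table.

#' Fit one logistic exposure-outcome model
#'
#' Maximum-likelihood logistic regression (IRLS via \code{stats::glm.fit},
#' relative deviance tolerance 1e-8, at most 50 iterations) of a binary
#' outcome on a binary exposure plus optional covariates. Reports the odds
#' ratio for the exposure with a Wald 95\% confidence interval
#' \code{exp(beta +/- 1.96 SE)} and two-sided Wald p-value. Complete-case:
#' rows with any missing value are dropped. Single-class outcomes or
#' exposures give a skipped row; apparent separation (|beta| > 15 or
#' SE > 10) is flagged, not silently reported.
#'
#' @param outcome logical/binary vector.
#' @param exposure logical/binary vector.
#' @param covariates optional numeric design matrix (no intercept column) or
#'   data.frame passed through \code{stats::model.matrix}.
#' @param exposure_name,outcome_name,stratum labels copied to the result.
#' @param adjusted logical label copied to the result.
#' @return one-row data.frame of class \code{hip_assoc}: \code{exposure},
#'   \code{outcome}, \code{stratum}, \code{adjusted}, \code{or},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{n_used}, \code{status}
#'   ("ok", "skipped_single_class", "separation", "not_converged").
#' @export
#' @examples
#' # 2x2 table: exposed 30/100 cases, unexposed 10/100 cases
#' y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
#' x <- rep(c(1, 0), each = 100)
#' fit_logistic(y, x)   # OR = (30*90)/(70*10) = 3.857
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         exposure_name = "exposure", outcome_name = "outcome",
                         stratum = "combined", adjusted = !is.null(covariates)) {
  row <- function(or = NA_real_, lo = NA_real_, hi = NA_real_, p = NA_real_,
                  n = 0L, status = "ok") {
    out <- data.frame(exposure = exposure_name, outcome = outcome_name,
                      stratum = stratum, adjusted = adjusted, or = or,
                      ci_low = lo, ci_high = hi, p = p, n_used = n,
                      status = status, stringsAsFactors = FALSE)
    class(out) <- c("hip_assoc", "data.frame")
    out
  }
  y <- as.numeric(outcome); x <- as.numeric(exposure)
  if (!is.null(covariates)) {
    if (is.data.frame(covariates))
      covariates <- stats::model.matrix(~ ., data = covariates)[, -1,
                                                                drop = FALSE]
    covariates <- as.matrix(covariates)
    keep <- is.finite(y) & is.finite(x) &
      apply(is.finite(covariates), 1, all)
  } else {
    keep <- is.finite(y) & is.finite(x)
  }
  y <- y[keep]; x <- x[keep]
  Z <- if (!is.null(covariates)) covariates[keep, , drop = FALSE] else NULL
  n <- length(y)
  if (n == 0L || length(unique(y)) < 2L || length(unique(x)) < 2L)
    return(row(n = n, status = "skipped_single_class"))
  if (!is.null(Z)) {
    # drop constant covariate columns (degenerate strata)
    keepc <- apply(Z, 2, function(col) stats::var(col) > 0)
    Z <- Z[, keepc, drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, exposure = x, Z)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 50L)))
  p1 <- seq_len(fit$rank)
  piv <- fit$qr$pivot[p1]
  covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se_all <- rep(NA_real_, ncol(X))
  se_all[piv] <- sqrt(diag(covmat))
  beta <- fit$coefficients["exposure"]
  se <- se_all[2L]
  if (is.na(beta) || is.na(se))
    return(row(n = n, status = "skipped_single_class"))
  status <- if (!fit$converged) "not_converged"
  else if (abs(beta) > 15 || se > 10) "separation" else "ok"
  z <- beta / se
  row(or = unname(exp(beta)),
      lo = unname(exp(beta - stats::qnorm(0.975) * se)),
      hi = unname(exp(beta + stats::qnorm(0.975) * se)),
      p = unname(2 * stats::pnorm(-abs(z))), n = n, status = status)
}

#' @export
print.hip_assoc <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  fmt <- function(v) formatC(round_half_away(v, digits), format = "f",
                             digits = digits)
  df$`OR [95% CI]` <- ifelse(df$status %in% c("ok", "separation"),
                             sprintf("%s [%s-%s]%s", fmt(df$or),
                                     fmt(df$ci_low), fmt(df$ci_high),
                                     ifelse(df$status == "separation", "*", "")),
                             paste0("(", df$status, ")"))
  df$P <- signif(df$p, 3)
  print(df[, c("exposure", "outcome", "stratum", "adjusted",
               "OR [95% CI]", "P", "n_used")], row.names = FALSE)
  if (any(x$status == "separation"))
    cat("* flagged: apparent separation; estimate unreliable\n")
  invisible(x)
}

# covariate design for the adjusted models: age, height, weight, ethnicity
# (one-hot, White reference), plus sex for combined-sex models
adjustment_design <- function(df, with_sex) {
  eth <- factor(df$ethnicity, levels = c("White", "Asian", "Black", "Chinese",
                                         "Mixed", "Unknown"))
  eth[is.na(eth)] <- "Unknown"
  dd <- data.frame(age = df$age_years, height = df$height_cm,
                   weight = df$weight_kg, ethnicity = droplevels(eth))
  if (with_sex) dd$sex <- as.numeric(df$sex == "female")
  if (nlevels(dd$ethnicity) < 2L) dd$ethnicity <- NULL
  stats::model.matrix(~ ., data = dd)[, -1, drop = FALSE]
}

suite_outcomes <- function() c(rhoa = "rhoa",
                               op_acetabular = "op_grade_acetabular",
                               op_superior_femoral = "op_grade_superior_femoral",
                               op_inferior_femoral = "op_grade_inferior_femoral",
                               jsn = "jsn_grade",
                               hip_pain = "hip_pain")

outcome_binary <- function(df, col, grade2 = FALSE) {
  v <- df[[col]]
  if (col == "rhoa" && grade2) v <- df$rhoa_grade2
  if (is.logical(v)) as.numeric(v)
  else if (col %in% c("hip_pain")) as.numeric(v)
  else as.numeric(v >= if (grade2) 2 else 1)
}

#' Run the full morphology-outcome association suite
#'
#' For each exposure (cam, pincer, acetabular dysplasia) x outcome (rHOA,
#' per-site osteophytes, JSN, hip pain) x stratum (male, female, combined) x
#' adjustment (none; age, height, weight, ethnicity, plus sex in combined
#' models), fits one logistic model and returns one row per cell. Cells that
#' cannot be fitted (degenerate stratum, single-class outcome) are emitted as
#' flagged skipped rows, never silently dropped.
#'
#' @param cohort graded cohort data.frame (output of
#'   \code{\link{grade_cohort}} or equivalent columns).
#' @param exposures character subset of
#'   \code{c("cam", "pincer", "acetabular_dysplasia")}.
#' @param strata character subset of \code{c("male", "female", "combined")}.
#' @param grade2 use the stricter rHOA/osteophyte/JSN grade >= 2 outcome
#'   definitions (sensitivity analysis).
#' @return \code{hip_assoc} data.frame, one row per cell.
#' @export
run_association_suite <- function(cohort,
                                  exposures = c("cam", "pincer",
                                                "acetabular_dysplasia"),
                                  strata = c("male", "female", "combined"),
                                  grade2 = FALSE) {
  outs <- suite_outcomes()
  rows <- list()
  for (st in strata) {
    df <- if (st == "combined") cohort else cohort[cohort$sex == st, ,
                                                   drop = FALSE]
    for (adj in c(FALSE, TRUE)) {
      Z <- if (adj && nrow(df)) adjustment_design(df, st == "combined")
      for (ex in exposures) for (on in names(outs)) {
        rows[[length(rows) + 1L]] <- fit_logistic(
          outcome_binary(df, outs[[on]], grade2 && on != "hip_pain"),
          df[[ex]],
          covariates = if (adj) Z,
          exposure_name = ex, outcome_name = on, stratum = st,
          adjusted = adj)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hip_assoc", "data.frame")
  out
}

#' Pincer/dysplasia suite against a restricted normal-coverage reference
#'
#' Sensitivity analysis: pincer morphology and acetabular dysplasia are each
#' compared against a reference of hips with LCEA in [25, 45) degrees (rows
#' carrying the other morphology are dropped from each model), since both
#' ends of the LCEA spectrum have been linked to radiographic hip OA.
#'
#' @inheritParams run_association_suite
#' @param lcea_col column holding LCEA in degrees.
#' @return \code{hip_assoc} data.frame.
#' @export
run_sensitivity_restricted_reference <- function(cohort,
                                                 strata = c("male", "female",
                                                            "combined"),
                                                 lcea_col = "lcea_deg") {
  rows <- list()
  ref <- cohort[[lcea_col]] >= 25 & cohort[[lcea_col]] < 45
  for (ex in c("pincer", "acetabular_dysplasia")) {
    sub <- cohort[cohort[[ex]] | ref, , drop = FALSE]
    rows[[length(rows) + 1L]] <- run_association_suite(sub, exposures = ex,
                                                       strata = strata)
  }
  out <- do.call(rbind, rows)
  out$reference <- "lcea_25_45"
  class(out) <- c("hip_assoc", "data.frame")
  out
}

#' Cam-to-hip-pain models with osteophyte adjustment (attenuation analysis)
#'
#' Fits the cam-exposure hip-pain model with demographic covariates, then
#' with additional adjustment for each osteophyte-presence indicator in turn
#' and for all three together, returning all five odds ratios for
#' comparison. Attenuation of the cam odds ratio toward 1 under osteophyte
#' adjustment is the signature of osteophyte-mediated pain.
#'
#' @param cohort graded cohort data.frame.
#' @param stratum "male", "female" or "combined".
#' @return \code{hip_assoc} data.frame with an \code{adjustment_set} column
#'   ("demographic", "+acetabular", "+superior_femoral", "+inferior_femoral",
#'   "+all_osteophytes").
#' @export
run_pain_attenuation <- function(cohort, stratum = "male") {
  df <- if (stratum == "combined") cohort
  else cohort[cohort$sex == stratum, , drop = FALSE]
  base <- adjustment_design(df, stratum == "combined")
  ops <- cbind(op_acetabular = as.numeric(df$op_grade_acetabular >= 1),
               op_superior_femoral = as.numeric(df$op_grade_superior_femoral >= 1),
               op_inferior_femoral = as.numeric(df$op_grade_inferior_femoral >= 1))
  sets <- list(demographic = NULL, `+acetabular` = "op_acetabular",
               `+superior_femoral` = "op_superior_femoral",
               `+inferior_femoral` = "op_inferior_femoral",
               `+all_osteophytes` = colnames(ops))
  rows <- lapply(names(sets), function(nm) {
    Z <- cbind(base, ops[, sets[[nm]], drop = FALSE])
    r <- fit_logistic(as.numeric(df$hip_pain), df$cam, covariates = Z,
                      exposure_name = "cam", outcome_name = "hip_pain",
                      stratum = stratum, adjusted = TRUE)
    r$adjustment_set <- nm
    r
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hip_assoc", "data.frame")
  out
}

#' Cohen's kappa and percent agreement
#'
#' Chance-corrected categorical agreement: \code{kappa = (p_o - p_e)/(1 -
#' p_e)} with expected agreement \code{p_e} from the product of marginal
#' proportions. Undefined (flagged NA) when both raters are constant and
#' identical (\code{p_e = 1}).
#'
#' @param labels_a,labels_b equal-length categorical vectors.
#' @return list with \code{kappa}, \code{percent_agreement}, \code{n}.
#' @export
#' @examples
#' a <- rep(c(0, 0, 1, 1), c(40, 10, 20, 30))
#' b <- rep(c(0, 1, 0, 1), c(40, 10, 20, 30))
#' cohens_kappa(a, b)   # kappa 0.4, agreement 70%
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("label vectors must have equal length")
  if (!length(labels_a)) stopf("empty label vectors")
  lv <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lv); b <- factor(labels_b, levels = lv)
  tab <- table(a, b) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  kap <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_
  else (po - pe) / (1 - pe)
  list(kappa = kap, percent_agreement = 100 * po, n = length(a))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement for continuous re-measurements: \code{CCC = 2 cov(x, y) /
#' (var(x) + var(y) + (mean(x) - mean(y))^2)} with population (1/n) moments.
#' Combines precision (correlation) and accuracy (location/scale shift);
#' equals 1 only for perfect agreement.
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return list with \code{ccc} and \code{n}; \code{ccc} is NA (flagged) when
#'   both vectors are constant.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors must have equal length")
  n <- length(x)
  if (n < 2L) stopf("need at least two paired measurements")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  list(ccc = if (den == 0) NA_real_ else 2 * cxy / den, n = n)
}

#' Descriptive prevalence table
#'
#' Counts and percentages per stratum (male, female, combined) for the
#' morphology and rHOA indicator variables, and mean [range] summaries for
#' the continuous demographics and angles. Percentages are display-rounded to
#' one decimal (via two-stage half-away-from-zero rounding, see
#' \code{\link{round_half_away}}).
#'
#' @param cohort graded cohort data.frame; indicator columns among
#'   \code{cam, pincer, acetabular_dysplasia, rhoa, rhoa_grade2, hip_pain}
#'   plus grade columns are summarised when present.
#' @return data.frame of class \code{hip_prevalence}: one row per variable x
#'   stratum with \code{n}, \code{count}, \code{pct} (indicators) or
#'   \code{mean}, \code{min}, \code{max} (continuous).
#' @export
prevalence_table <- function(cohort) {
  strata <- list(male = cohort[cohort$sex == "male", , drop = FALSE],
                 female = cohort[cohort$sex == "female", , drop = FALSE],
                 combined = cohort)
  bin_vars <- list(cam = "cam", pincer = "pincer",
                   acetabular_dysplasia = "acetabular_dysplasia",
                   rhoa = "rhoa",
                   op_acetabular = "op_grade_acetabular",
                   op_superior_femoral = "op_grade_superior_femoral",
                   op_inferior_femoral = "op_grade_inferior_femoral",
                   jsn = "jsn_grade",
                   rhoa_grade2 = "rhoa_grade2",
                   hip_pain = "hip_pain")
  cont_vars <- c(age = "age_years", height = "height_cm",
                 weight = "weight_kg", alpha_angle = "alpha_angle_deg",
                 lcea = "lcea_deg")
  rows <- list()
  for (st in names(strata)) {
    df <- strata[[st]]
    n <- nrow(df)
    for (v in names(bin_vars)) {
      col <- bin_vars[[v]]
      if (!col %in% names(cohort)) next
      x <- df[[col]]
      cnt <- if (is.logical(x)) sum(x, na.rm = TRUE)
      else sum(x >= 1, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stratum = st, n = n, count = cnt,
        pct = format_pct(cnt, n), mean = NA_real_, min = NA_real_,
        max = NA_real_, stringsAsFactors = FALSE)
    }
    for (v in names(cont_vars)) {
      col <- cont_vars[[v]]
      if (!col %in% names(cohort)) next
      x <- df[[col]]
      x <- x[is.finite(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stratum = st, n = n, count = NA_integer_,
        pct = NA_real_,
        mean = if (length(x)) mean(x) else NA_real_,
        min = if (length(x)) min(x) else NA_real_,
        max = if (length(x)) max(x) else NA_real_, stringsAsFactors = FALSE)
    }
    if ("ethnicity" %in% names(cohort) && n) {
      for (e in sort(unique(cohort$ethnicity))) {
        cnt <- sum(df$ethnicity == e, na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = paste0("ethnicity_", e), stratum = st, n = n,
          count = cnt, pct = format_pct(cnt, n), mean = NA_real_,
          min = NA_real_, max = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  class(out) <- c("hip_prevalence", "data.frame")
  out
}
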