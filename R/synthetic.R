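# Synthetic hip generator: landmark outlines with exact geometric ground
# truth, and outcome cohorts drawn from configurable logistic models.

#' Shape parameters for one synthetic hip outline
#'
#' Describes a left hip in the canonical frame (superior = +y, lateral = -x):
#' a circular femoral head, a symmetric neck at a configurable axis angle, an
#' optional cam bump whose first tolerance crossing is placed analytically at
#' the requested departure angle (so ground-truth alpha angle is exact by
#' construction), an acetabular edge at a configurable centre-edge angle and a
#' configurable joint-space gap.
#'
#' @param head_radius_mm femoral-head radius (mm), default 25 (a typical adult
#'   femoral head).
#' @param head_centre length-2 centre of the head (mm).
#' @param neck_axis_angle_deg angle of the neck axis below the image x-axis;
#'   the axis direction from head centre into the neck is infero-lateral.
#'   Default 40.
#' @param cam_present logical; add a cam bump?
#' @param cam_departure_deg ground-truth alpha angle: the angle from the neck
#'   axis at which the contour first exceeds the departure tolerance.
#' @param cam_amplitude_frac full bump height as a fraction of the radius
#'   (default 0.15, i.e. 3.75 mm on a 25 mm head — a pronounced but realistic
#'   cam). Must exceed \code{departure_tolerance_frac}.
#' @param cam_width_deg angular width of the smoothstep rise (default 20).
#' @param edge_angle_deg ground-truth lateral centre-edge angle (deg).
#' @param joint_space_mm ground-truth minimum joint-space width (mm).
#' @param landmark_noise_sd_mm isotropic Gaussian noise SD added to every
#'   landmark (default 0, noiseless).
#' @param departure_tolerance_frac tolerance used to anchor the bump's
#'   crossing; keep equal to the measurement tolerance (default 0.02).
#' @param neck_halfwidth_frac neck half-width as fraction of head radius.
#' @param neck_length_frac neck length (from head centre) as fraction of head
#'   radius.
#' @return object of class \code{shape_params}.
#' @export
shape_params <- function(head_radius_mm = 25, head_centre = c(0, 0),
                         neck_axis_angle_deg = 40,
                         cam_present = FALSE, cam_departure_deg = 72.5,
                         cam_amplitude_frac = 0.15, cam_width_deg = 20,
                         edge_angle_deg = 35, joint_space_mm = 4,
                         landmark_noise_sd_mm = 0,
                         departure_tolerance_frac = 0.02,
                         neck_halfwidth_frac = 0.55,
                         neck_length_frac = 1.8) {
  p <- list(head_radius_mm = head_radius_mm, head_centre = head_centre,
            neck_axis_angle_deg = neck_axis_angle_deg,
            cam_present = isTRUE(cam_present),
            cam_departure_deg = cam_departure_deg,
            cam_amplitude_frac = cam_amplitude_frac,
            cam_width_deg = cam_width_deg,
            edge_angle_deg = edge_angle_deg,
            joint_space_mm = joint_space_mm,
            landmark_noise_sd_mm = landmark_noise_sd_mm,
            departure_tolerance_frac = departure_tolerance_frac,
            neck_halfwidth_frac = neck_halfwidth_frac,
            neck_length_frac = neck_length_frac)
  if (p$head_radius_mm <= 0) stopf("head_radius_mm must be > 0")
  if (p$joint_space_mm <= 0) stopf("joint_space_mm must be > 0")
  if (p$landmark_noise_sd_mm < 0) stopf("landmark noise SD must be >= 0")
  if (p$cam_present &&
      (p$cam_departure_deg <= 0 || p$cam_departure_deg >= 180))
    stopf("cam_departure_deg must lie in (0, 180)")
  if (p$cam_present && p$cam_amplitude_frac <= p$departure_tolerance_frac)
    stopf("cam_amplitude_frac must exceed departure_tolerance_frac")
  if (p$edge_angle_deg <= -90 || p$edge_angle_deg >= 90)
    stopf("edge_angle_deg must lie in (-90, 90)")
  class(p) <- "shape_params"
  p
}

# smoothstep and the offset s* at which it equals `frac` of full amplitude
smoothstep <- function(s) {
  s <- pmin(1, pmax(0, s))
  3 * s^2 - 2 * s^3
}
smoothstep_inv <- function(frac) {
  stats::uniroot(function(s) smoothstep(s) - frac, c(0, 1),
                 tol = 1e-12)$root
}

# Fixed layout of the generator's 85-point template, expressed in angles
# relative to the neck axis (phi = counter-clockwise angle from the axis
# direction; the superolateral head-neck junction lies at phi > 180).
# The head-circle fit range (15-28) is placed adjacent to the departure scan
# region and the junction arc (29-46) is sampled densely: both choices limit
# the leverage of landmark noise on the extrapolated fitted circle at the
# departure crossing.
gen_layout <- list(
  inferior_neck = 1:10,
  head_arc = 11:46,
  head_phi = c(seq(44, 47, length.out = 4),      # inferomedial head
               seq(48, 240, length.out = 14),    # circle-fit arc (15-28)
               seq(245.6, 324, length.out = 18)),# junction scan arc (29-46)
  superior_neck = 47:60,
  acetab_filler = 61:77,
  acetab_edge = 78L,
  acetab_arc = 79:84,
  acetab_last = 85L
)

#' Generate one synthetic hip outline with known ground truth
#'
#' Produces an 85-point landmark outline laid out to match the default
#' \code{\link{hip_template}}: head-circle points (15--28) exactly on the head
#' circle, an optional cam bump on the superolateral head--neck junction whose
#' first crossing of \code{radius * (1 + tolerance)} sits exactly at
#' \code{cam_departure_deg} from the neck axis, a symmetric neck about the
#' configured axis, and an acetabular polyline whose closest approach to the
#' femoral mJSW polyline equals \code{joint_space_mm} exactly, with the
#' lateral edge (point 78) at \code{edge_angle_deg} from the vertical.
#'
#' @param params a \code{\link{shape_params}} object.
#' @param template a \code{hip_template}; must keep the default published
#'   index ranges, which the generator's layout realises.
#' @param participant_id identifier for the emitted landmark set.
#' @param seed optional integer seed for the landmark noise.
#' @return list with \code{landmarks} (a \code{landmark_set}) and
#'   \code{truth} (list \code{alpha_angle_deg} — NA when no cam bump —,
#'   \code{lcea_deg}, \code{mjsw_mm}, \code{neck_axis_angle_deg}).
#' @export
generate_hip_outline <- function(params = shape_params(),
                                 template = hip_template(),
                                 participant_id = "sim", seed = NULL) {
  stopifnot(inherits(params, "shape_params"))
  if (!identical(template$head_circle_range, c(15L, 28L)) ||
      !identical(template$mjsw_acetabulum_range, c(78L, 84L)) ||
      !identical(template$mjsw_femoral_range, c(22L, 31L)) ||
      template$lateral_edge_index != 78L)
    stopf("generator layout requires the default published template ranges")
  if (!is.null(seed)) set.seed(seed)

  r <- params$head_radius_mm
  hc <- params$head_centre
  th <- params$neck_axis_angle_deg
  lay <- gen_layout
  pts <- matrix(NA_real_, 85, 2)

  # cam bump: radial excess as a function of the angle psi from the neck axis
  tol <- params$departure_tolerance_frac
  if (params$cam_present) {
    psi_dep <- params$cam_departure_deg
    W <- params$cam_width_deg
    A <- params$cam_amplitude_frac
    s_star <- smoothstep_inv(tol / A)
    psi0 <- psi_dep + s_star * W    # excess reaches tol*r exactly at psi_dep
    phi_grid <- lay$head_phi
    psi_min_arc <- 360 - max(phi_grid)    # smallest axis angle on the arc
    psi_fit_end <- 360 - 240              # axis angle at the end of the fit arc
    if (psi_dep <= psi_min_arc + 1 || psi0 >= psi_fit_end - 1)
      stopf("cam_departure_deg %.1f outside the generated arc", psi_dep)
    excess <- function(psi) A * r * smoothstep((psi0 - psi) / W)
  } else {
    excess <- function(psi) 0 * psi
  }

  # femoral head arc (indices 11-46); absolute polar angle = 180 + th + phi
  phi <- lay$head_phi
  if (params$cam_present) {
    # landmark placement concentrates on the head-neck junction, as anatomical
    # templates do: a coarse backbone over the junction arc plus a dense band
    # around the departure region
    phi_dep <- 360 - params$cam_departure_deg
    backbone <- seq(245.6, 324, length.out = 8)
    dense <- pmax(246.2, pmin(323.5,
      seq(phi_dep - 7, phi_dep + params$cam_width_deg + 5, length.out = 10)))
    junct <- sort(c(backbone, dense))
    for (i in 2:length(junct))
      if (junct[i] <= junct[i - 1] + 0.3) junct[i] <- junct[i - 1] + 0.3
    phi[lay$head_arc >= 29] <- junct
  }
  psi <- pmin(phi, 360 - phi)                 # unsigned angle from axis
  rho <- r + ifelse(phi > 180, excess(psi), 0)
  ang <- deg2rad(180 + th + phi)
  pts[lay$head_arc, ] <- cbind(hc[1] + rho * cos(ang), hc[2] + rho * sin(ang))

  # neck: symmetric parallel boundaries about the axis
  d_ax <- c(-cos(deg2rad(th)), -sin(deg2rad(th)))        # head -> neck
  n_sup <- c(-sin(deg2rad(th)), cos(deg2rad(th)))        # superolateral
  n_inf <- -n_sup
  w <- params$neck_halfwidth_frac * r
  t0 <- sqrt(r^2 - w^2)
  L <- params$neck_length_frac * r
  t_sup <- seq(t0 + 1, L, length.out = length(lay$superior_neck))
  t_inf <- seq(L, t0 + 1, length.out = length(lay$inferior_neck))
  pts[lay$superior_neck, ] <- cbind(hc[1] + t_sup * d_ax[1] + w * n_sup[1],
                                    hc[2] + t_sup * d_ax[2] + w * n_sup[2])
  pts[lay$inferior_neck, ] <- cbind(hc[1] + t_inf * d_ax[1] + w * n_inf[1],
                                    hc[2] + t_inf * d_ax[2] + w * n_inf[2])

  # acetabulum: lateral edge at edge_angle_deg from vertical (lateral = -x)
  gap <- params$joint_space_mm
  edge_polar <- 90 + params$edge_angle_deg
  # non-closest acetabular points are padded outward so that chords incident
  # to the designated closest vertex cannot dip inside the gap (sagitta bound
  # over at most 1.5 point spacings, plus margin)
  spacing <- (edge_polar - 50) / length(gen_layout$acetab_arc)
  pad <- (r + gap) * (1 - cos(deg2rad(1.5 * spacing + 2))) + 0.5
  filler_polar <- seq(170, edge_polar + 4,
                      length.out = length(lay$acetab_filler))
  put_polar <- function(idx, polar_deg_v, radius) {
    a <- deg2rad(polar_deg_v)
    pts[idx, ] <<- cbind(hc[1] + radius * cos(a), hc[2] + radius * sin(a))
  }
  put_polar(lay$acetab_filler, filler_polar, r + gap + 6)
  put_polar(lay$acetab_edge, edge_polar, r + gap + pad)
  arc_polar <- seq(edge_polar, 50, length.out = length(lay$acetab_arc) + 1)[-1]
  put_polar(lay$acetab_arc, arc_polar, r + gap + pad)
  put_polar(lay$acetab_last, 46, r + gap + 2)

  # designated closest acetabular vertex: exactly `gap` above the midpoint of
  # a femoral mJSW chord facing the acetabular arc, so the polyline-to-
  # polyline minimum equals joint_space_mm to machine precision
  fem_idx <- range_idx(template$mjsw_femoral_range)
  mids <- (pts[fem_idx[-length(fem_idx)], , drop = FALSE] +
             pts[fem_idx[-1], , drop = FALSE]) / 2
  mid_polar <- polar_deg(mids[, 1] - hc[1], mids[, 2] - hc[2])
  target <- (50 + edge_polar) / 2
  ok <- mid_polar > 52 & mid_polar < edge_polar - 2
  if (!any(ok)) stopf("no femoral chord faces the acetabular arc")
  kchord <- which(ok)[which.min(abs(mid_polar[ok] - target))]
  chord_mid <- mids[kchord, ]
  n_hat <- (chord_mid - hc) / sqrt(sum((chord_mid - hc)^2))
  closest_pt <- chord_mid + gap * n_hat
  closest_polar <- polar_deg(closest_pt[1] - hc[1], closest_pt[2] - hc[2])
  repl <- lay$acetab_arc[which.min(abs(arc_polar - closest_polar))]
  pts[repl, ] <- closest_pt

  if (params$landmark_noise_sd_mm > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0,
                                     params$landmark_noise_sd_mm),
                        nrow(pts), 2)

  list(landmarks = landmark_set(participant_id, pts),
       truth = list(
         alpha_angle_deg = if (params$cam_present)
           params$cam_departure_deg else NA_real_,
         lcea_deg = params$edge_angle_deg,
         mjsw_mm = params$joint_space_mm,
         neck_axis_angle_deg = th))
}

#' Outcome-model parameters for synthetic cohorts
#'
#' Defaults echo the source study's descriptive statistics and adjusted male
#' effect sizes (e.g. cam to inferior femoral osteophyte odds ratio 4.75);
#' they are simulator configuration, not estimates from data. All effects are
#' log odds ratios in the logistic models that generate osteophyte presence,
#' joint-space narrowing and hip pain, in that causal order (morphology ->
#' osteophytes/JSN -> pain), which supports mediation-structured tests of the
#' pain-attenuation analysis.
#'
#' @param ... named overrides of any default component (see the function
#'   body / methods vignette for the full structure).
#' @return object of class \code{outcome_model_params} (a nested list).
#' @export
outcome_model_params <- function(...) {
  p <- list(
    prevalence = list(
      cam = c(male = 0.154, female = 0.018),
      pincer = c(male = 0.089, female = 0.081),
      ad = c(male = 0.056, female = 0.070)),
    covariates = list(
      age = list(male = c(mean = 63.4, sd = 7.5, lo = 45, hi = 80),
                 female = c(mean = 62.1, sd = 7.5, lo = 46, hi = 79)),
      height = list(male = c(mean = 177.0, sd = 6.8, lo = 153, hi = 203),
                    female = c(mean = 163.3, sd = 6.2, lo = 137, hi = 195)),
      weight = list(male = c(mean = 83.8, sd = 13.0, lo = 50, hi = 160),
                    female = c(mean = 68.7, sd = 12.5, lo = 36, hi = 155)),
      ethnicity = c(White = 0.970, Asian = 0.011, Black = 0.006,
                    Mixed = 0.005, Chinese = 0.002, Unknown = 0.006)),
    angle_dist = list(
      aa_cam = list(shift = 60.5, sd = 9, hi = 110),
      aa_nocam = list(male = c(mean = 51, sd = 5), female = c(mean = 44, sd = 4.5),
                      lo = 40, hi = 59.4),
      lcea_pincer = list(shift = 45.5, sd = 4.5, hi = 60),
      lcea_ad = list(shift = 24.5, sd = 4.5, lo = 5.5),
      lcea_normal = c(mean = 35.4, sd = 4.3, lo = 25.3, hi = 44.7)),
    osteophyte = list(
      intercept = c(acetabular = -2.0, superior_femoral = -2.5,
                    inferior_femoral = -3.2),
      female = c(acetabular = log(0.67), superior_femoral = log(0.45),
                 inferior_femoral = log(0.29)),
      cam = c(acetabular = log(1.87), superior_femoral = log(1.94),
              inferior_femoral = log(4.75)),
      pincer = c(acetabular = log(0.86), superior_femoral = log(0.63),
                 inferior_femoral = log(0.81)),
      ad = c(acetabular = log(1.41), superior_femoral = log(1.07),
             inferior_femoral = log(1.95)),
      age_per_year = 0.03,
      grade_probs = c(0.70, 0.22, 0.08),            # grade 1..3 given present
      area_gamma = list(shape = c(2, 4, 6), scale = c(1, 2, 4))),
    jsn = list(
      intercept = -1.55, female = log(0.60), cam = log(1.53),
      pincer = log(4.15), ad = log(0.28), age_per_year = 0.03,
      grade_probs = c(0.75, 0.20, 0.05),
      mjsw_by_grade = c(4.4, 3.1, 2.4, 1.8), mjsw_sd = 0.25,
      mjsw_height_slope = 0.012, mjsw_floor = 0.3),
    pain = list(
      intercept = -2.95, female = log(1.8), cam_direct = log(1.15),
      op = c(acetabular = log(1.3), superior_femoral = log(1.3),
             inferior_femoral = log(1.6))),
    age_centre = 62.7)
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- utils::modifyList(p[[nm]], dots[[nm]])
  class(p) <- "outcome_model_params"
  p
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(hi, pmax(lo, x))
}

#' Generate a synthetic participant cohort with known effect sizes
#'
#' Draws sex (equal numbers by default), covariates, hip morphology from
#' sex-specific prevalences, true hip angles and joint-space width conditional
#' on morphology, latent semi-quantitative osteophyte/JSN grades and areas,
#' and hip pain — in the causal order morphology -> osteophytes/JSN -> pain.
#' Optionally also renders the landmark outline of every hip from the drawn
#' shape truths, for end-to-end pipeline tests.
#'
#' @param n number of participants.
#' @param params an \code{\link{outcome_model_params}}.
#' @param shape_defaults a \code{\link{shape_params}} giving the non-varying
#'   geometry (head radius, neck axis, noise SD, ...).
#' @param seed integer seed; identical seed and parameters give identical
#'   output.
#' @param sex "both" (50/50), "male" or "female".
#' @param with_landmarks logical; render landmark outlines (slower)?
#' @return list with \code{participants} (data.frame of covariates, outcomes,
#'   areas and latent \code{true_*} columns) and \code{landmarks} (named list
#'   of \code{landmark_set}, or NULL).
#' @export
generate_cohort <- function(n, params = outcome_model_params(),
                            shape_defaults = shape_params(), seed = 1,
                            sex = c("both", "male", "female"),
                            with_landmarks = FALSE) {
  sex <- match.arg(sex)
  if (!is_count(n)) stopf("n must be a non-negative integer")
  set.seed(seed)
  if (n == 0) {
    return(list(participants = data.frame(participant_id = character()),
                landmarks = if (with_landmarks) list() else NULL))
  }
  sx <- switch(sex,
               both = sample(rep(c("male", "female"), length.out = n)),
               male = rep("male", n), female = rep("female", n))
  id <- sprintf("P%05d", seq_len(n))
  cv <- params$covariates
  draw_cov <- function(spec) {
    out <- numeric(n)
    for (s in c("male", "female")) {
      i <- sx == s
      if (any(i)) out[i] <- rtruncnorm1(sum(i), spec[[s]]["mean"],
                                        spec[[s]]["sd"], spec[[s]]["lo"],
                                        spec[[s]]["hi"])
    }
    out
  }
  age <- draw_cov(cv$age); height <- draw_cov(cv$height)
  weight <- draw_cov(cv$weight)
  ethnicity <- sample(names(cv$ethnicity), n, replace = TRUE,
                      prob = cv$ethnicity)

  prev <- params$prevalence
  p_of <- function(v) unname(v[ifelse(sx == "male", "male", "female")])
  cam <- stats::runif(n) < p_of(prev$cam)
  # pincer and AD are LCEA classes, mutually exclusive
  u <- stats::runif(n)
  pincer <- u < p_of(prev$pincer)
  ad <- !pincer & u < p_of(prev$pincer) + p_of(prev$ad)

  an <- params$angle_dist
  aa <- numeric(n)
  aa[cam] <- pmin(an$aa_cam$hi,
                  an$aa_cam$shift + abs(stats::rnorm(sum(cam), 0, an$aa_cam$sd)))
  nc <- !cam
  for (s in c("male", "female")) {
    i <- nc & sx == s
    if (any(i)) aa[i] <- rtruncnorm1(sum(i), an$aa_nocam[[s]]["mean"],
                                     an$aa_nocam[[s]]["sd"],
                                     an$aa_nocam$lo, an$aa_nocam$hi)
  }
  lcea <- numeric(n)
  lcea[pincer] <- pmin(an$lcea_pincer$hi, an$lcea_pincer$shift +
                         abs(stats::rnorm(sum(pincer), 0, an$lcea_pincer$sd)))
  lcea[ad] <- pmax(an$lcea_ad$lo, an$lcea_ad$shift -
                     abs(stats::rnorm(sum(ad), 0, an$lcea_ad$sd)))
  nrm <- !pincer & !ad
  lcea[nrm] <- rtruncnorm1(sum(nrm), an$lcea_normal["mean"],
                           an$lcea_normal["sd"], an$lcea_normal["lo"],
                           an$lcea_normal["hi"])

  # osteophytes: presence (logistic), latent grade, shaded area
  op <- params$osteophyte
  fem <- as.numeric(sx == "female")
  agec <- age - params$age_centre
  sites <- c("acetabular", "superior_femoral", "inferior_femoral")
  op_grade <- matrix(0L, n, 3, dimnames = list(NULL, sites))
  op_area <- matrix(0, n, 3, dimnames = list(NULL, sites))
  for (s in sites) {
    lp <- op$intercept[s] + op$female[s] * fem + op$cam[s] * cam +
      op$pincer[s] * pincer + op$ad[s] * ad + op$age_per_year * agec
    present <- stats::runif(n) < stats::plogis(lp)
    k <- sum(present)
    if (k) {
      g <- sample(1:3, k, replace = TRUE, prob = op$grade_probs)
      op_grade[present, s] <- g
      op_area[present, s] <- stats::rgamma(k, shape = op$area_gamma$shape[g],
                                           scale = op$area_gamma$scale[g])
    }
  }

  # JSN: presence (logistic), latent grade, then the mJSW that realises it
  js <- params$jsn
  lp <- js$intercept + js$female * fem + js$cam * cam + js$pincer * pincer +
    js$ad * ad + js$age_per_year * agec
  jsn_present <- stats::runif(n) < stats::plogis(lp)
  jsn_grade <- integer(n)
  jsn_grade[jsn_present] <- sample(1:3, sum(jsn_present), replace = TRUE,
                                   prob = js$grade_probs)
  hmean <- ifelse(sx == "male", cv$height$male["mean"],
                  cv$height$female["mean"])
  mjsw <- js$mjsw_by_grade[jsn_grade + 1L] +
    js$mjsw_height_slope * (height - hmean) +
    stats::rnorm(n, 0, js$mjsw_sd)
  mjsw <- pmax(js$mjsw_floor, mjsw)

  # hip pain: direct morphology effect plus osteophyte effects (mediation)
  pn <- params$pain
  lp <- pn$intercept + pn$female * fem + pn$cam_direct * cam +
    pn$op["acetabular"] * (op_grade[, "acetabular"] >= 1) +
    pn$op["superior_femoral"] * (op_grade[, "superior_femoral"] >= 1) +
    pn$op["inferior_femoral"] * (op_grade[, "inferior_femoral"] >= 1)
  hip_pain <- stats::runif(n) < stats::plogis(lp)

  participants <- data.frame(
    participant_id = id, age_years = age, height_cm = height,
    weight_kg = weight, sex = sx, ethnicity = ethnicity,
    hip_pain = hip_pain,
    area_acetabular_mm2 = op_area[, 1],
    area_superior_femoral_mm2 = op_area[, 2],
    area_inferior_femoral_mm2 = op_area[, 3],
    true_aa_deg = aa, true_lcea_deg = lcea, true_mjsw_mm = mjsw,
    true_cam = cam, true_pincer = pincer, true_ad = ad,
    true_op_grade_acetabular = op_grade[, 1],
    true_op_grade_superior_femoral = op_grade[, 2],
    true_op_grade_inferior_femoral = op_grade[, 3],
    true_jsn_grade = jsn_grade,
    stringsAsFactors = FALSE)

  landmarks <- NULL
  if (with_landmarks) {
    landmarks <- vector("list", n); names(landmarks) <- id
    for (i in seq_len(n)) {
      sp <- shape_defaults
      sp$cam_present <- TRUE
      sp$cam_departure_deg <- aa[i]
      sp$edge_angle_deg <- lcea[i]
      sp$joint_space_mm <- mjsw[i]
      landmarks[[i]] <- generate_hip_outline(sp, participant_id = id[i])$landmarks
    }
  }
  list(participants = participants, landmarks = landmarks)
}
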