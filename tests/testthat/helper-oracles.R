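# Independent oracles used to check the package's geometric and statistical
# primitives, deliberately implemented by different routes than the package.

# Brute-force geometric least-squares circle: derivative-free Nelder-Mead on
# sum((|p - c| - r)^2) from several starts (no algebraic initialisation, no
# Gauss-Newton).
oracle_circle <- function(points) {
  obj <- function(par) {
    d <- sqrt((points[, 1] - par[1])^2 + (points[, 2] - par[2])^2)
    sum((d - par[3])^2)
  }
  ctr <- colMeans(points)
  r0 <- mean(sqrt((points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2))
  starts <- list(c(ctr, r0), c(ctr + c(r0 / 4, 0), r0),
                 c(ctr + c(0, -r0 / 4), 1.5 * r0))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(centre = best$par[1:2], radius = best$par[3])
}

# Dense-sampling minimum distance between two polylines: sample many points
# along every segment of each polyline and take the minimum cross pairwise
# distance (no point-to-segment projection formula).
oracle_polyline_dist <- function(P, Q, samples_per_segment = 400) {
  densify <- function(M) {
    out <- list()
    for (j in seq_len(nrow(M) - 1)) {
      t <- seq(0, 1, length.out = samples_per_segment)
      out[[j]] <- cbind(M[j, 1] + t * (M[j + 1, 1] - M[j, 1]),
                        M[j, 2] + t * (M[j + 1, 2] - M[j, 2]))
    }
    do.call(rbind, out)
  }
  A <- densify(P); B <- densify(Q)
  d2 <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
  sqrt(min(d2))
}

# Exhaustive Youden scan over all midpoints between sorted unique values,
# written as a plain double loop over candidates and observations.
oracle_youden <- function(values, grades, boundary = 1) {
  u <- sort(unique(values))
  cand <- (u[-1] + u[-length(u)]) / 2
  pos <- grades >= boundary
  best_j <- -Inf
  for (cc in cand) {
    sens <- mean(values[pos] >= cc)
    spec <- mean(values[!pos] < cc)
    best_j <- max(best_j, sens + spec - 1)
  }
  best_j
}

# Hand-built 85-point outline whose radial profile ramps linearly with the
# angle from the neck axis, crossing radius*(1+tol) exactly at `cross_deg`;
# independent of the package's generator.
ramp_hip <- function(cross_deg, r = 25, tol = 0.02, axis_deg = 40) {
  pts <- matrix(0, 85, 2)
  phi <- c(seq(44, 47, length.out = 4), seq(48, 240, length.out = 14),
           seq(245, 324, length.out = 18))
  psi <- pmin(phi, 360 - phi)
  psi0 <- cross_deg + tol / 0.001          # excess = 0.001*(psi0 - psi)
  exc <- ifelse(phi > 180 & psi < psi0, 0.001 * (psi0 - psi), 0)
  rho <- r * (1 + exc)
  ang <- pi / 180 * (180 + axis_deg + phi)
  pts[11:46, ] <- cbind(rho * cos(ang), rho * sin(ang))
  d <- c(-cos(pi / 180 * axis_deg), -sin(pi / 180 * axis_deg))
  nsup <- c(-sin(pi / 180 * axis_deg), cos(pi / 180 * axis_deg))
  w <- 0.55 * r
  t_sup <- seq(sqrt(r^2 - w^2) + 1, 1.8 * r, length.out = 14)
  pts[47:60, ] <- cbind(t_sup * d[1] + w * nsup[1], t_sup * d[2] + w * nsup[2])
  t_inf <- rev(t_sup)[1:10]
  pts[1:10, ] <- cbind(t_inf * d[1] - w * nsup[1], t_inf * d[2] - w * nsup[2])
  a <- pi / 180 * seq(170, 50, length.out = 25)
  pts[61:85, ] <- cbind((r + 5) * cos(a), (r + 5) * sin(a))
  landmark_set("ramp", pts)
}

# synthetic cohort parameter sets for the statistical simulations
null_outcome_params <- function() {
  zero3 <- c(acetabular = 0, superior_femoral = 0, inferior_femoral = 0)
  outcome_model_params(
    osteophyte = list(cam = zero3, pincer = zero3, ad = zero3,
                      age_per_year = 0),
    jsn = list(cam = 0, pincer = 0, ad = 0, age_per_year = 0),
    pain = list(cam_direct = 0, op = zero3))
}

mediation_outcome_params <- function() {
  # cam affects pain only through inferior osteophytes; the mediator is made
  # common (baseline ~18%) and strongly painful so the indirect path carries
  # a clearly detectable signal at cohort scale
  outcome_model_params(
    pain = list(cam_direct = 0,
                op = c(acetabular = 0, superior_femoral = 0,
                       inferior_femoral = log(5))),
    osteophyte = list(intercept = c(acetabular = -2.0,
                                    superior_femoral = -2.5,
                                    inferior_femoral = -1.5)))
}

# graded cohort straight from latent truths (geometry skipped)
graded_from_truth <- function(participants) {
  df <- participants
  df$alpha_angle_deg <- df$true_aa_deg
  df$lcea_deg <- df$true_lcea_deg
  df$cam <- df$true_cam
  df$pincer <- df$true_pincer
  df$acetabular_dysplasia <- df$true_ad
  df$op_grade_acetabular <- df$true_op_grade_acetabular
  df$op_grade_superior_femoral <- df$true_op_grade_superior_femoral
  df$op_grade_inferior_femoral <- df$true_op_grade_inferior_femoral
  df$jsn_grade <- df$true_jsn_grade
  rh <- classify_rhoa(df$jsn_grade, df$op_grade_acetabular,
                      df$op_grade_superior_femoral,
                      df$op_grade_inferior_femoral)
  df$rhoa <- rh$rhoa
  df$rhoa_grade2 <- rh$rhoa_grade2
  df
}
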