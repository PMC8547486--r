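tpl <- hip_template()

test_that("identical seeds give byte-identical cohorts", {
  a <- generate_cohort(60, seed = 7, with_landmarks = TRUE)
  b <- generate_cohort(60, seed = 7, with_landmarks = TRUE)
  expect_identical(a$participants, b$participants)
  expect_identical(a$landmarks, b$landmarks)
  c <- generate_cohort(60, seed = 8)
  expect_false(identical(a$participants$true_aa_deg,
                         c$participants$true_aa_deg))
})

test_that("noiseless round trip recovers ground truth across the sweeps", {
  for (a in seq(40, 110, by = 10)) {
    g <- generate_hip_outline(shape_params(cam_present = TRUE,
                                           cam_departure_deg = a))
    m <- measure_hip(g$landmarks, tpl)
    expect_lt(abs(m$alpha_angle_deg - a), 1.5)
  }
  for (e in seq(5, 60, by = 5)) {
    g <- generate_hip_outline(shape_params(edge_angle_deg = e))
    expect_lt(abs(measure_hip(g$landmarks, tpl)$lcea_deg - e), 0.5)
  }
  for (j in c(2, 3.5, 5)) {
    g <- generate_hip_outline(shape_params(joint_space_mm = j))
    expect_lt(abs(measure_hip(g$landmarks, tpl)$mjsw_mm - j), 1e-3)
  }
})

test_that("head-circle-range points lie exactly on the head circle", {
  g <- generate_hip_outline(shape_params(cam_present = TRUE,
                                         cam_departure_deg = 108))
  d <- sqrt(rowSums(g$landmarks$points[15:28, ]^2))
  expect_lt(max(abs(d - 25)), 1e-9)
})

test_that("cam departure outside the generated arc is rejected", {
  expect_error(generate_hip_outline(shape_params(cam_present = TRUE,
                                                 cam_departure_deg = 178)),
               "outside the generated arc")
  expect_error(generate_hip_outline(shape_params(cam_present = TRUE,
                                                 cam_departure_deg = 20)),
               "outside the generated arc")
})

test_that("measurement stays accurate under landmark noise", {
  set.seed(77)
  errs <- vapply(seq_len(500), function(i) {
    a <- runif(1, 42, 100)
    g <- generate_hip_outline(shape_params(cam_present = TRUE,
                                           cam_departure_deg = a,
                                           landmark_noise_sd_mm = 0.3))
    m <- measure_hip(g$landmarks, tpl)
    c(m$alpha_angle_deg - a, m$lcea_deg - 35)
  }, numeric(2))
  expect_lt(mean(abs(errs[1, ]), na.rm = TRUE), 3)
  expect_lt(abs(mean(errs[2, ])), 1)
})

test_that("cohort prevalences match their binomial targets", {
  cht <- generate_cohort(3000, seed = 29, sex = "male")
  p <- mean(cht$participants$true_cam)
  expect_lt(abs(p - 0.154), 3 * sqrt(0.154 * 0.846 / 3000))
  expect_true(all(cht$participants$sex == "male"))

  both <- generate_cohort(2001, seed = 30)
  expect_equal(abs(diff(table(both$participants$sex))), 1,
               ignore_attr = TRUE)
  expect_identical(nrow(generate_cohort(0, seed = 1)$participants), 0L)
})

test_that("empirical conditional odds ratios converge to configured truths", {
  cht <- generate_cohort(100000, seed = 31)
  gr <- graded_from_truth(cht$participants)
  covs <- cbind(age = gr$age_years, female = as.numeric(gr$sex == "female"))
  # inferior femoral osteophytes: configured conditional OR 4.75
  f <- fit_logistic(gr$op_grade_inferior_femoral >= 1, gr$cam,
                    covariates = covs)
  expect_lt(abs(f$or - 4.75) / 4.75, 0.05)
  # JSN: configured conditional OR 1.53
  fj <- fit_logistic(gr$jsn_grade >= 1, gr$cam, covariates = covs)
  expect_lt(abs(fj$or - 1.53) / 1.53, 0.05)
})

test_that("full pipeline recovers configured effect sizes within CI", {
  cht <- generate_cohort(3400, seed = 33, sex = "male", with_landmarks = TRUE)
  meas <- measure_cohort(cht$landmarks, tpl)
  gr <- grade_cohort(meas, cht$participants)
  a <- run_association_suite(gr, exposures = "cam", strata = "male")
  cell <- a[a$outcome == "op_inferior_femoral" & !a$adjusted, ]
  expect_identical(cell$status, "ok")
  half_width <- (log(cell$ci_high) - log(cell$ci_low)) / 2
  expect_lt(abs(log(cell$or) - log(4.75)), half_width)
  jcell <- a[a$outcome == "jsn" & !a$adjusted, ]
  expect_lt(abs(log(jcell$or) - log(1.53)),
            (log(jcell$ci_high) - log(jcell$ci_low)) / 2)
})
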