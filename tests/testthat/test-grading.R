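test_that("ROC calibration separates separable classes perfectly", {
  area <- c(0.1, 0.4, 0.9, 3.0, 4.5, 9.0)
  grade <- c(0, 0, 0, 1, 1, 2)
  th <- calibrate_threshold_roc(area, grade, boundary = 1)
  expect_gt(as.numeric(th), 0.9)
  expect_lt(as.numeric(th), 3.0)
  expect_equal(attr(th, "sensitivity"), 1)
  expect_equal(attr(th, "specificity"), 1)
  expect_equal(attr(th, "youden"), 1)
})

test_that("ROC calibration matches the exhaustive Youden scan", {
  set.seed(41)
  for (rep in 1:6) {
    v <- c(rgamma(60, 2, 1), rgamma(40, 5, 1))
    g <- rep(c(0, 1), c(60, 40))
    th <- calibrate_threshold_roc(v, g, boundary = 1)
    expect_equal(attr(th, "youden"), oracle_youden(v, g), tolerance = 1e-12)
  }
  # cross-check against pROC when available
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(42)
    v <- c(rnorm(80, 1), rnorm(50, 2.2))
    g <- rep(c(0, 1), c(80, 50))
    th <- calibrate_threshold_roc(v, g, boundary = 1)
    roc <- pROC::roc(g, v, quiet = TRUE, direction = "<")
    best_j <- max(roc$sensitivities + roc$specificities - 1)
    expect_equal(attr(th, "youden"), best_j, tolerance = 1e-12)
  }
})

test_that("degenerate references and reversed direction are handled", {
  expect_error(calibrate_threshold_roc(1:10, rep(0, 10), 1), "calibration")
  # reversed direction: small values predict high grade
  v <- c(4.5, 4.0, 3.9, 2.2, 2.0, 1.5)
  g <- c(0, 0, 0, 1, 1, 2)
  th <- calibrate_threshold_roc(v, g, 1, direction = "less")
  expect_gt(as.numeric(th), 2.2)
  expect_lt(as.numeric(th), 3.9)
  expect_equal(attr(th, "youden"), 1)
})

test_that("grades follow inclusive cutpoints and are monotone", {
  th <- grade_thresholds("acetabular", c(1, 4, 9))
  expect_identical(grade_from_thresholds(c(0, 0.99, 1, 4, 8.9, 9, 50), th),
                   c(0L, 0L, 1L, 2L, 2L, 3L, 3L))
  sweep <- grade_from_thresholds(seq(0, 20, by = 0.05), th)
  expect_true(all(diff(sweep) >= 0))

  thj <- grade_thresholds("jsn", c(1.5, 2.5, 3.5))
  expect_identical(grade_from_thresholds(c(4, 3.5, 3, 2.5, 1.6, 1.5, 0.5), thj),
                   c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
  sweepj <- grade_from_thresholds(seq(5, 0, by = -0.05), thj)
  expect_true(all(diff(sweepj) >= 0))

  expect_error(grade_thresholds("jsn", c(2, 2)), "increasing")
  expect_error(grade_from_thresholds(NA_real_, th), "non-finite")
})

test_that("height adjustment removes the height trend", {
  # slope 0 is the identity
  ref0 <- list(male = list(slope = 0, mean_height = 177),
               female = list(slope = 0, mean_height = 163))
  expect_equal(height_adjust_mjsw(c(3, 4), c(150, 190),
                                  c("male", "female"), ref0), c(3, 4))

  # equal mJSW, heights +/- 10 cm of the mean, slope 0.01 mm/cm
  ref <- list(male = list(slope = 0.01, mean_height = 177),
              female = list(slope = 0.01, mean_height = 163))
  adj <- height_adjust_mjsw(c(3.5, 3.5), c(187, 167), c("male", "male"), ref)
  expect_equal(adj[2] - adj[1], 0.2, tolerance = 1e-12)

  # exact linear mJSW-height relation: the adjustment removes it entirely
  set.seed(5)
  h <- rnorm(200, 177, 7)
  mj <- 1.5 + 0.015 * h
  fitted <- fit_height_adjustment(mj, h, rep("male", 200))
  a <- height_adjust_mjsw(mj, h, rep("male", 200), fitted)
  expect_lt(max(abs(a - mean(a))), 1e-9)
  # with measurement noise on top, residual correlation with height is zero
  mj2 <- mj + rnorm(200, 0, 0.2)
  fitted2 <- fit_height_adjustment(mj2, h, rep("male", 200))
  a2 <- height_adjust_mjsw(mj2, h, rep("male", 200), fitted2)
  expect_lt(abs(cor(a2, h)), 1e-6)
})

test_that("morphology boundaries are inclusive exactly as defined", {
  m <- classify_morphology(c(60, 59.9, NA), c(30, 30, 30))
  expect_identical(m$cam, c(TRUE, FALSE, FALSE))
  expect_identical(attr(m, "n_no_departure"), 1L)
  m2 <- classify_morphology(c(50, 50, 50, 50), c(45, 44.9, 25, 24.99))
  expect_identical(m2$pincer, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(m2$acetabular_dysplasia, c(FALSE, FALSE, FALSE, TRUE))
  # pincer and dysplasia can never both hold
  expect_false(any(m2$pincer & m2$acetabular_dysplasia))
})

test_that("rHOA needs both JSN and an osteophyte at any site", {
  r <- classify_rhoa(jsn_grade = c(1, 1, 2, 2, 0),
                     op_acetabular = c(1, 0, 0, 2, 3),
                     op_superior_femoral = c(0, 0, 0, 0, 0),
                     op_inferior_femoral = c(0, 2, 0, 0, 0))
  expect_identical(r$rhoa, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(r$rhoa_grade2, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_true(all(!r$rhoa_grade2 | r$rhoa))   # grade2 implies rhoa
})

test_that("graded cohorts satisfy the prevalence identities", {
  cht <- generate_cohort(800, seed = 9)
  gr <- graded_from_truth(cht$participants)
  t1 <- prevalence_table(gr)
  cnt <- function(v, st) t1$count[t1$variable == v & t1$stratum == st]
  expect_lte(cnt("rhoa_grade2", "combined"), cnt("rhoa", "combined"))
  expect_lte(cnt("pincer", "combined") + cnt("acetabular_dysplasia", "combined"),
             nrow(gr))
  expect_equal(cnt("cam", "male") + cnt("cam", "female"),
               cnt("cam", "combined"))
})
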