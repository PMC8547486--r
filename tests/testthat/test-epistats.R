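test_that("unadjusted logistic OR equals the 2x2 cross-product ratio", {
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  x <- rep(c(1, 0), each = 100)
  r <- fit_logistic(y, x)
  expect_equal(r$or, 27 / 7, tolerance = 1e-6)
  expect_true(r$ci_low < r$or && r$or < r$ci_high)

  # equal case fractions: no association
  y2 <- c(rep(1, 20), rep(0, 80), rep(1, 20), rep(0, 80))
  expect_equal(fit_logistic(y2, x)$or, 1, tolerance = 1e-6)

  # random 2x2 tables against the closed form
  set.seed(51)
  for (rep in 1:8) {
    tab <- matrix(rpois(4, 40) + 5, 2)
    yy <- rep(c(1, 0, 1, 0), tab)
    xx <- rep(c(1, 1, 0, 0), tab)
    expect_equal(fit_logistic(yy, xx)$or,
                 (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2]),
                 tolerance = 1e-6)
  }
})

test_that("degenerate and separated models are flagged, not reported silently", {
  expect_identical(fit_logistic(rep(0, 50), rep(c(0, 1), 25))$status,
                   "skipped_single_class")
  expect_identical(fit_logistic(rep(c(0, 1), 25), rep(1, 50))$status,
                   "skipped_single_class")
  # perfect separation
  y <- rep(c(0, 1), each = 30)
  x <- rep(c(0, 1), each = 30)
  expect_identical(fit_logistic(y, x)$status, "separation")
})

test_that("Wald CI excludes 1 exactly when Wald p < 0.05", {
  cht <- generate_cohort(3000, seed = 13)
  gr <- graded_from_truth(cht$participants)
  a <- run_association_suite(gr)
  ok <- a$status == "ok"
  excl <- a$ci_low[ok] > 1 | a$ci_high[ok] < 1
  expect_identical(excl, a$p[ok] < 0.05)
})

test_that("the suite emits exactly one row per cell and flags skips", {
  cht <- generate_cohort(4000, seed = 17)
  gr <- graded_from_truth(cht$participants)
  gr$cam[gr$sex == "female"] <- FALSE            # degenerate female stratum
  a <- run_association_suite(gr)
  expect_equal(nrow(a), 3 * 6 * 3 * 2)
  key <- with(a, paste(exposure, outcome, stratum, adjusted))
  expect_false(any(duplicated(key)))
  fem_cam <- a[a$exposure == "cam" & a$stratum == "female", ]
  expect_true(all(fem_cam$status == "skipped_single_class"))
  other <- a[!(a$exposure == "cam" & a$stratum == "female"), ]
  expect_true(mean(other$status == "ok") > 0.85)
})

test_that("restricted-reference sensitivity handles absent morphologies", {
  cht <- generate_cohort(400, seed = 19)
  gr <- graded_from_truth(cht$participants)
  gr$pincer[] <- FALSE
  gr$acetabular_dysplasia[] <- FALSE
  s <- run_sensitivity_restricted_reference(gr)
  expect_true(all(s$status == "skipped_single_class"))
})

test_that("restricted and full reference agree when reference dominates", {
  cht <- generate_cohort(6000, seed = 23)
  gr <- graded_from_truth(cht$participants)
  full <- run_association_suite(gr, exposures = "acetabular_dysplasia",
                                strata = "combined")
  restr <- run_sensitivity_restricted_reference(gr, strata = "combined")
  f <- full[full$outcome == "jsn" & !full$adjusted, ]
  r <- restr[restr$exposure == "acetabular_dysplasia" &
               restr$outcome == "jsn" & !restr$adjusted, ]
  # one Monte-Carlo SE on the log OR
  se <- (log(f$ci_high) - log(f$ci_low)) / (2 * 1.96)
  expect_lt(abs(log(f$or) - log(r$or)), se)
})

test_that("kappa follows its closed form and sampling behaviour", {
  # identical vectors, two categories
  a <- c(0, 1, 1, 0, 1)
  expect_equal(cohens_kappa(a, a)$kappa, 1)
  expect_equal(cohens_kappa(a, a)$percent_agreement, 100)

  # hand-computed confusion matrix [[40,10],[20,30]]
  x <- rep(c(0, 0, 1, 1), c(40, 10, 20, 30))
  y <- rep(c(0, 1, 0, 1), c(40, 10, 20, 30))
  k <- cohens_kappa(x, y)
  expect_equal(k$kappa, 0.4, tolerance = 1e-12)
  expect_equal(k$percent_agreement, 70)

  # independent labels: kappa near zero
  set.seed(61)
  kk <- cohens_kappa(rbinom(20000, 1, 0.3), rbinom(20000, 1, 0.6))
  expect_lt(abs(kk$kappa), 0.02)

  # constant identical raters: undefined
  expect_true(is.na(cohens_kappa(rep(1, 5), rep(1, 5))$kappa))
})

test_that("Lin's CCC follows its closed form", {
  x <- rnorm(50)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  xm <- x - mean(x)
  expect_equal(lin_ccc(xm, -xm)$ccc, -1)

  # pure mean shift on population-standardised x: CCC = 2 / (2 + c^2)
  xs <- xm / sqrt(mean(xm^2))
  for (c_shift in c(0.5, 1, 2))
    expect_equal(lin_ccc(xs, xs + c_shift)$ccc, 2 / (2 + c_shift^2),
                 tolerance = 1e-12)

  # |CCC| <= |Pearson r|
  set.seed(71)
  u <- rnorm(200); v <- 2 * u + rnorm(200)
  expect_lte(abs(lin_ccc(u, v)$ccc), abs(cor(u, v)) + 1e-12)
})

test_that("prevalence percentages use half-away display rounding", {
  sex <- rep(c("male", "female"), c(3382, 3425))
  cam <- c(rep(TRUE, 519), rep(FALSE, 3382 - 519),
           rep(TRUE, 63), rep(FALSE, 3425 - 63))
  t1 <- prevalence_table(data.frame(sex = sex, cam = cam,
                                    stringsAsFactors = FALSE))
  pct <- function(st) t1$pct[t1$variable == "cam" & t1$stratum == st]
  expect_equal(pct("male"), 15.4)
  expect_equal(pct("female"), 1.8)
  expect_equal(pct("combined"), 8.6)
  # empty class
  t0 <- prevalence_table(data.frame(sex = rep("male", 10), cam = rep(FALSE, 10)))
  expect_equal(t0$pct[t0$variable == "cam" & t0$stratum == "male"], 0)
  # empty cohort gives an empty table
  te <- prevalence_table(data.frame(sex = character(), cam = logical()))
  expect_true(all(te$n == 0))
})
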