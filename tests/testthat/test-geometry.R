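tpl <- hip_template()

test_that("neck axis recovers the midline of a symmetric neck", {
  g <- generate_hip_outline(shape_params(neck_axis_angle_deg = 40))
  circ <- fit_circle(g$landmarks$points[15:28, ])
  ax <- estimate_neck_axis(g$landmarks, tpl, circ)
  # symmetric parallel boundaries force the midpoint onto the axis
  expect_equal(ax$head_centre, c(0, 0), tolerance = 1e-6)
  off_axis <- abs(-sin(-40 * pi / 180) * ax$neck_centre[1] -
                    cos(-40 * pi / 180) * ax$neck_centre[2])
  expect_lt(off_axis, 1e-6)
  ang <- atan2(-ax$direction[2], -ax$direction[1]) * 180 / pi
  expect_equal(ang, 40, tolerance = 1)

  # ground-truth axis angles are recovered across a sweep
  for (th in c(30, 45, 50)) {
    gg <- generate_hip_outline(shape_params(neck_axis_angle_deg = th))
    cc <- fit_circle(gg$landmarks$points[15:28, ])
    aa <- estimate_neck_axis(gg$landmarks, tpl, cc)
    expect_equal(atan2(-aa$direction[2], -aa$direction[1]) * 180 / pi, th,
                 tolerance = 1)
  }
})

test_that("degenerate neck configuration is rejected", {
  g <- generate_hip_outline(shape_params())
  circ <- fit_circle(g$landmarks$points[15:28, ])
  bad <- tpl
  bad$neck_inferior_range <- bad$neck_superior_range
  expect_error(estimate_neck_axis(g$landmarks, bad, circ), "configuration")
})

test_that("alpha angle finds a linearly interpolated crossing", {
  # hand-built ramp contour crossing radius*(1+tol) exactly at 45 deg
  ls <- ramp_hip(45)
  circ <- fit_circle(ls$points[15:28, ])
  ax <- estimate_neck_axis(ls, tpl, circ)
  aa <- compute_alpha_angle(ls, tpl, circ, ax)
  expect_equal(aa$alpha_angle_deg, 45, tolerance = 0.5)

  ls2 <- ramp_hip(80)
  aa2 <- compute_alpha_angle(ls2, tpl, fit_circle(ls2$points[15:28, ]),
                             estimate_neck_axis(ls2, tpl,
                                                fit_circle(ls2$points[15:28, ])))
  expect_equal(aa2$alpha_angle_deg, 80, tolerance = 0.5)
})

test_that("a spherical head raises a no-departure condition", {
  g <- generate_hip_outline(shape_params(cam_present = FALSE))
  circ <- fit_circle(g$landmarks$points[15:28, ])
  ax <- estimate_neck_axis(g$landmarks, tpl, circ)
  expect_error(compute_alpha_angle(g$landmarks, tpl, circ, ax),
               class = "hip_no_departure")
  m <- measure_hip(g$landmarks, tpl)
  expect_true(is.na(m$alpha_angle_deg))
  expect_false(m$departure_flag)
})

test_that("LCEA is the signed angle from the vertical to the lateral edge", {
  g <- generate_hip_outline(shape_params(edge_angle_deg = 33.7))
  circ <- fit_circle(g$landmarks$points[15:28, ])
  fake_circ <- circ

  # edge directly superior to the head centre
  ls <- g$landmarks
  ls$points[78, ] <- c(0, 31)
  expect_equal(compute_lcea(ls, tpl, fake_circ)$lcea_deg, 0, tolerance = 1e-6)
  # equal lateral and superior offsets force 45 deg (lateral = -x)
  ls$points[78, ] <- c(-5, 5)
  expect_equal(compute_lcea(ls, tpl, fake_circ)$lcea_deg, 45, tolerance = 1e-6)
  # medial edge gives a negative angle
  ls$points[78, ] <- c(5, 5)
  expect_equal(compute_lcea(ls, tpl, fake_circ)$lcea_deg, -45, tolerance = 1e-6)

  expect_equal(compute_lcea(g$landmarks, tpl, circ)$lcea_deg, 33.7,
               tolerance = 0.5)
})

test_that("mJSW equals the gap between parallel polylines and is symmetric", {
  pts <- generate_hip_outline(shape_params())$landmarks$points
  pts[22:31, ] <- cbind(seq(0, 9, length.out = 10), 0)
  pts[78:84, ] <- cbind(seq(1, 8, length.out = 7), 4)
  ls <- landmark_set("par", pts)
  expect_equal(compute_mjsw(ls, tpl)$mjsw_mm, 4, tolerance = 1e-12)

  # swapped template ranges give the same distance (symmetry)
  tpl_sw <- tpl
  tpl_sw$mjsw_acetabulum_range <- tpl$mjsw_femoral_range
  tpl_sw$mjsw_femoral_range <- tpl$mjsw_acetabulum_range
  expect_equal(compute_mjsw(ls, tpl_sw)$mjsw_mm, 4, tolerance = 1e-12)

  # touching polylines
  pts[78, ] <- pts[25, ]
  ls0 <- landmark_set("touch", pts)
  expect_equal(compute_mjsw(ls0, tpl)$mjsw_mm, 0)
})

test_that("mJSW matches the dense-sampling oracle on random polylines", {
  set.seed(31)
  base <- generate_hip_outline(shape_params())$landmarks$points
  for (rep in 1:5) {
    pts <- base
    pts[22:31, ] <- cbind(sort(runif(10, 0, 10)), runif(10, 0, 2))
    pts[78:84, ] <- cbind(sort(runif(7, 0, 10)), runif(7, 3.5, 6))
    ls <- landmark_set("rand", pts)
    d <- compute_mjsw(ls, tpl)$mjsw_mm
    expect_equal(d, oracle_polyline_dist(pts[78:84, ], pts[22:31, ]),
                 tolerance = 1e-4)
  }
})

test_that("mJSW rejects overlapping ranges", {
  g <- generate_hip_outline(shape_params())
  bad <- tpl
  bad$mjsw_femoral_range <- c(70L, 80L)
  expect_error(compute_mjsw(g$landmarks, bad), "overlap")
})

test_that("angles are scale invariant and mJSW scales linearly", {
  g <- generate_hip_outline(shape_params(cam_present = TRUE,
                                         cam_departure_deg = 72.5,
                                         edge_angle_deg = 28))
  m <- measure_hip(g$landmarks, tpl)
  for (s in c(0.5, 3.7)) {
    ls <- g$landmarks
    ls$points <- ls$points * s
    ms <- measure_hip(ls, tpl)
    expect_equal(ms$alpha_angle_deg, m$alpha_angle_deg, tolerance = 1e-6)
    expect_equal(ms$lcea_deg, m$lcea_deg, tolerance = 1e-6)
    expect_equal(ms$mjsw_mm, s * m$mjsw_mm, tolerance = 1e-9)
  }
})
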