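test_that("resampling preserves arc length and spacing", {
  ml <- midline_series(c(0, 1),
                       list(straight_vertical_points(10, 0.5),
                            straight_vertical_points(10.2, 0.5)),
                       validate = FALSE)
  rs <- resample_midline(ml, 0.5)
  expect_equal(nrow(rs$points[[1]]), 21)
  expect_equal(diff(coleokin:::frame_arclength(rs$points[[1]])),
               rep(0.5, 20), tolerance = 1e-10)

  # quarter circle of radius 10: arc length 5*pi
  arc <- circle_arc_points(10, pi / 2, step = 0.01)
  ml2 <- midline_series(c(0, 1), list(arc, arc), validate = FALSE)
  rs2 <- resample_midline(ml2, 0.1)
  # total length = arc-length parameter of the last sample
  L_tot <- (nrow(rs2$points[[1]]) - 1) * 0.1
  expect_lt(abs(L_tot - 5 * pi), 0.1)
})

test_that("degenerate midline inputs are rejected", {
  expect_error(resample_midline(
    midline_series(0, list(matrix(c(1, 2), 1, 2)), validate = FALSE)),
    "fewer than 2 points")
  shrink <- list(straight_vertical_points(10), straight_vertical_points(5))
  expect_error(midline_series(c(0, 1), shrink), "decreases")
  dup <- rbind(c(0, 10), c(0, 10), c(0, 10))
  expect_error(
    orientation_profile(midline_series(0, list(dup), validate = FALSE),
                        step = 1),
    "duplicate|degenerate")
})

test_that("orientation follows the zenith-angle convention", {
  vert <- midline_series(0, list(straight_vertical_points(10, 0.1)),
                         validate = FALSE)
  a <- orientation_profile(vert, 0.1)
  expect_lt(max(abs(a$values), na.rm = TRUE), 1e-9)

  # horizontal organ, apex pointing along +x -> A = pi/2 everywhere
  x <- seq(0, 10, by = 0.1)
  horiz <- midline_series(0, list(cbind(rev(x), 0)), validate = FALSE)
  ah <- orientation_profile(horiz, 0.1)
  expect_equal(max(abs(ah$values - pi / 2), na.rm = TRUE), 0,
               tolerance = 1e-9)

  # quarter arc, vertical at base and horizontal at apex: A rises
  # linearly from 0 at the apex to pi/2 at the base with slope 1/R
  R <- 20
  arc <- midline_series(0, list(circle_arc_points(R, pi / 2, 0.1)),
                        validate = FALSE)
  aa <- orientation_profile(arc, 0.1)
  sup <- aa$mask[1, ]
  expect_equal(aa$values[1, 1], pi / 2, tolerance = 1e-2)
  expect_equal(aa$values[1, sum(sup)], 0, tolerance = 1e-2)
  slope <- diff(aa$values[1, sup]) / 0.1
  expect_lt(max(abs(slope + 1 / R)), 0.01 / R)
})

test_that("curvature recovers 1/R on circular arcs within 2%", {
  for (R in c(5, 20, 100)) {
    arc <- midline_series(0, list(circle_arc_points(R, pi / 2, 0.1)),
                          validate = FALSE)
    cv <- curvature_profile(orientation_profile(arc, 0.1))
    err <- max(abs(abs(cv$values[1, ]) - 1 / R), na.rm = TRUE)
    expect_lt(err, 0.02 / R)
  }
})

test_that("arc-length integral of curvature recovers the orientation", {
  R <- 20
  arc <- midline_series(0, list(circle_arc_points(R, pi / 2, 0.1)),
                        validate = FALSE)
  a <- orientation_profile(arc, 0.1)
  # trapezoid-integrate the centred-difference field back up; on exact
  # inputs the discrete operations invert each other almost exactly at
  # interior points
  cv <- curvature_profile(a)
  sup <- which(a$mask[1, ])
  av <- a$values[1, sup]; cvv <- cv$values[1, sup]
  recon <- av[1] + c(0, cumsum((cvv[-1] + cvv[-length(cvv)]) / 2) * 0.1)
  expect_lt(max(abs(recon - av)[2:(length(av) - 1)]), 1e-3)
  # and the discrete sum telescopes to the end-to-end angle change
  expect_equal(sum(diff(av)), av[length(av)] - av[1], tolerance = 1e-6)
})

test_that("curvature errors on too-small support", {
  a <- kinematic_field(c(0, 0.1), 0:2, matrix(0, 3, 2),
                       quantity = "orientation")
  expect_error(curvature_profile(a), "at least 3")
})

test_that("temporal averages use magnitudes and honour the split", {
  f <- kinematic_field(seq(0, 1, 0.5), seq(0, 24, 0.5),
                       matrix(2, 49, 3), quantity = "regr")
  expect_equal(temporal_field_average(f), 2)
  signed <- kinematic_field(seq(0, 1, 0.5), seq(0, 24, 0.5),
                            matrix(rep(ifelse(seq(0, 24, 0.5) <= 12, 1, -1),
                                       3), 49, 3),
                            quantity = "curvature_rate")
  avg <- temporal_field_average(signed, t_split = 12)
  expect_equal(avg$early, 1)
  expect_equal(avg$late, 1)

  chk <- matrix(c(3, -3), 4, 2)  # checkerboard +-3
  fc <- kinematic_field(c(0, 1), 1:4, chk)
  expect_equal(temporal_field_average(fc), 3)

  empty <- kinematic_field(c(0, 1), 1:3, matrix(NA_real_, 3, 2))
  expect_error(temporal_field_average(empty), "empty")
})
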