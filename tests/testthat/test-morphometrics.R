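step_regr_field <- function(zone = 10, L = 25, e0 = 0.04, ds = 0.5,
                            nt = 10) {
  s <- seq(0, L, by = ds)
  row <- ifelse(s < zone, e0, 0)
  kinematic_field(s, seq(0, by = 0.25, length.out = nt),
                  matrix(row, nt, length(s), byrow = TRUE),
                  quantity = "regr")
}

test_that("effective length is the apical above-threshold extent, capped
           by the initial organ length", {
  f <- step_regr_field(zone = 10, L = 25)
  eff <- effective_length(f, regr_threshold = 0.01)
  expect_equal(eff$L_eff, 10)
  short <- step_regr_field(zone = 10, L = 8)
  eff2 <- effective_length(short, regr_threshold = 0.01)
  expect_equal(eff2$L_eff, 8)
  expect_error(effective_length(f, regr_threshold = 1), "threshold")
})

test_that("curved-zone length measures the final above-threshold extent
           once curvature variation has ceased", {
  s <- seq(0, 25, by = 0.5); nt <- 12
  t <- seq(0, by = 0.25, length.out = nt)
  prof <- ifelse(s >= 12 & s < 17, 0.2, 0.001)
  Cf <- kinematic_field(s, t, matrix(prof, nt, length(s), byrow = TRUE),
                        quantity = "curvature")
  quiet <- kinematic_field(s, t, matrix(1e-6, nt, length(s)),
                           quantity = "curvature_rate")
  cz <- curved_zone_length(Cf, quiet, eps_rate = 1e-3, eps_curv = 0.05)
  expect_equal(cz$L_c, 5)

  # still varying -> error with diagnostic
  loud <- kinematic_field(s, t, matrix(0.5, nt, length(s)),
                          quantity = "curvature_rate")
  expect_error(curved_zone_length(Cf, loud, eps_rate = 1e-3,
                                  eps_curv = 0.05), "still varying")
  # straight organ -> error
  flat <- kinematic_field(s, t, matrix(0, nt, length(s)),
                          quantity = "curvature")
  expect_error(curved_zone_length(flat, quiet, eps_rate = 1e-3,
                                  eps_curv = 0.05), "straight")
})

test_that("classification arithmetic, threshold and the straight-group
           refusal", {
  s <- seq(0, 25, by = 0.5); nt <- 12
  t <- seq(0, by = 0.25, length.out = nt)
  mk <- function(zone, curved_lo, curved_hi) {
    regr <- kinematic_field(s, t, matrix(ifelse(s < zone, 0.04, 0),
                                         nt, length(s), byrow = TRUE),
                            quantity = "regr")
    curv <- kinematic_field(s, t,
                            matrix(ifelse(s >= curved_lo & s < curved_hi,
                                          0.2, 0.0001),
                                   nt, length(s), byrow = TRUE),
                            quantity = "curvature")
    rate <- kinematic_field(s, t, matrix(1e-6, nt, length(s)),
                            quantity = "curvature_rate")
    list(regr = regr, curvature = curv, curvature_rate = rate,
         tip_angle = c(1.5, 0.4, 0.1))
  }
  # L_eff 10, L_c 5 -> B = 2, no predicted overshoot
  r1 <- classify_plant(mk(10, 2, 7), "tilted", regr_threshold = 0.01,
                       eps_rate = 1e-3, eps_curv = 0.05)
  expect_equal(r1$B, 2, tolerance = 1e-9)
  expect_false(r1$predicted_overshoot)
  expect_false(r1$observed_overshoot)
  # L_eff 15, L_c 5 -> B = 3, predicted
  r2 <- classify_plant(mk(15, 2, 7), "tilted", regr_threshold = 0.01,
                       eps_rate = 1e-3, eps_curv = 0.05)
  expect_equal(r2$B, 3, tolerance = 1e-9)
  expect_true(r2$predicted_overshoot)
  # monotone: the larger measured B can never flip TRUE -> FALSE
  expect_true(r2$B > r1$B && (r2$predicted_overshoot >=
                                r1$predicted_overshoot))
  # straight plants: B refused, observed still reported
  r3 <- classify_plant(mk(10, 2, 7), "straight")
  expect_true(is.na(r3$B))
  expect_false(r3$observed_overshoot)
  r4 <- classify_plant(list(tip_angle = c(0.1, -0.3)), "straight")
  expect_true(r4$observed_overshoot)
})

test_that("the balance number is invariant under uniform spatial
           rescaling", {
  s <- seq(0, 25, by = 0.5); nt <- 8
  t <- seq(0, by = 0.25, length.out = nt)
  build <- function(scale) {
    ss <- s * scale
    regr <- kinematic_field(ss, t, matrix(ifelse(ss < 10 * scale, 0.04, 0),
                                          nt, length(ss), byrow = TRUE),
                            quantity = "regr")
    curv <- kinematic_field(ss, t,
                            matrix(ifelse(ss >= 2 * scale & ss < 7 * scale,
                                          0.2, 1e-4),
                                   nt, length(ss), byrow = TRUE),
                            quantity = "curvature")
    rate <- kinematic_field(ss, t, matrix(1e-6, nt, length(ss)),
                            quantity = "curvature_rate")
    classify_plant(list(regr = regr, curvature = curv,
                        curvature_rate = rate, tip_angle = c(1, 0.2)),
                   "tilted", regr_threshold = 0.01, eps_rate = 1e-3,
                   eps_curv = 0.05)$B
  }
  expect_equal(build(1), build(2.5), tolerance = 1e-9)
})

test_that("morphometric B agrees with the dynamic balance number on
           simulated organs", {
  # wave-free elongating organs under the linear graviceptive response:
  # the morphometric ratio should track beta*L_eff/gamma within 20%
  for (B_true in c(2.2, 3.4)) {
    g <- quick_plant(seed = 300 + round(10 * B_true), B = B_true,
                     regr_amp = 0, diff_amp = 0,
                     angular_response = "linear")
    pl <- generate_coleoptile_series(g)
    res <- suppressWarnings(
      analyze_plant(pl$midline, pl$markers, group = "tilted"))
    expect_false(is.null(res$morpho))
    expect_lt(abs(res$morpho$B - B_true) / B_true, 0.2)
    expect_equal(res$morpho$predicted_overshoot, B_true > 2.8)
    expect_equal(res$morpho$observed_overshoot, pl$truth$overshoot)
  }
})
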