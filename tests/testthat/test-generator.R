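test_that("a fixed seed reproduces the generated plant exactly", {
  g <- quick_plant(seed = 77)
  a <- generate_coleoptile_series(g)
  b <- generate_coleoptile_series(g)
  expect_identical(a$midline$points, b$midline$points)
  expect_identical(a$markers$intensity, b$markers$intensity)
  expect_identical(a$truth$state$regr$values, b$truth$state$regr$values)
})

test_that("zero wave amplitudes and no tilt give a straight elongating
           organ with a constant-in-zone REGR kymograph", {
  g <- quick_plant(seed = 5, tilt = 0, regr_amp = 0, diff_amp = 0)
  g$noise_sd_xy <- 0
  pl <- generate_coleoptile_series(g)
  # straight and vertical: x extent negligible
  xs <- vapply(pl$midline$points, function(p) diff(range(p[, 1])),
               numeric(1))
  expect_lt(max(xs), 1e-6)
  # organ grows
  expect_gt(pl$midline$lengths[length(pl$midline$lengths)],
            pl$midline$lengths[1] + 3)
  # truth REGR time-invariant and equal to the tapered baseline profile
  tr <- pl$truth$state$regr
  zone <- which(tr$s < g$ac$Lgz - 2)
  for (j in zone[c(1, length(zone) %/% 2, length(zone))]) {
    col <- tr$values[, j]
    expect_lt(diff(range(col, na.rm = TRUE)), 1e-5)
  }
  expected <- g$ac$regr0 * plogis((g$ac$Lgz - tr$s[zone]) / g$zone_taper)
  expect_lt(max(abs(t(tr$values[, zone]) - expected), na.rm = TRUE), 1e-5)
})

test_that("degenerate generator configurations are rejected", {
  g <- quick_plant(seed = 1)
  g$ac$regr0 <- 0
  expect_error(generate_coleoptile_series(g), "regr0 > 0")
  g2 <- quick_plant(seed = 1)
  g2$regr_wave$amplitude <- 1.2
  expect_error(generate_coleoptile_series(g2), "amplitude")
})

test_that("anti-phase differential growth gives negatively correlated
           ground-truth kymographs over the growth zone", {
  pl <- generate_coleoptile_series(quick_plant(seed = 7, delta_phase = pi))
  tr <- pl$truth$state
  r <- kymograph_correlation(tr$regr, tr$curvature_rate, gz_length = 12)
  expect_lt(r$r, 0)
  pl0 <- generate_coleoptile_series(quick_plant(seed = 7, delta_phase = 0))
  tr0 <- pl0$truth$state
  r0 <- kymograph_correlation(tr0$regr, tr0$curvature_rate, gz_length = 12)
  expect_gt(r0$r, 0)
})

test_that("cohort generation writes a reproducible two-group dataset", {
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_cohort(1, 1, d1, seed = 4)
  m2 <- generate_cohort(1, 1, d2, seed = 4)
  expect_equal(as.vector(table(m1$group)), c(1, 1))
  for (f in c("plant_01/midline.csv", "plant_01/truth.json",
              "plant_02/markers.csv", "manifest.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("every high-B tilted plant carries a ground-truth overshoot flag", {
  d <- file.path(tempdir(), "cohHighB")
  unlink(d, recursive = TRUE)
  cfg <- gen_config()
  cfg$ac$angular_response <- "linear"
  generate_cohort(1, 4, d, seed = 6, B_range = c(3.6, 4.5),
                  config_base = cfg)
  flags <- vapply(sprintf("plant_%02d", 2:5), function(p)
    jsonlite::read_json(file.path(d, p, "truth.json"))$overshoot,
    logical(1))
  expect_true(all(flags))
})

test_that("the analysis pipeline recovers the generated fields to the
           documented closure levels", {
  pl <- generate_coleoptile_series(quick_plant(seed = 11))
  res <- suppressWarnings(
    analyze_plant(pl$midline, pl$markers, group = "tilted"))
  expect_lt(closure_rel_rms(res$regr, pl$truth$state$regr), 0.25)
  expect_lt(closure_rel_rms(res$curvature_rate,
                            pl$truth$state$curvature_rate), 0.32)
})
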