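test_that("an upright organ is a fixed point", {
  p <- ac_params(beta = 0.2, gamma = 1, L0 = 10, tilt = 0, duration = 5,
                 dt = 0.002, ds = 0.1)
  st <- simulate_ac(p)
  expect_lt(max(abs(st$tip_angle$angle)), 1e-9)
  expect_lt(max(abs(st$curvature$values), na.rm = TRUE), 1e-9)
})

test_that("a subcritical tilted organ straightens without overshoot and
           concentrates curvature near the base", {
  p <- ac_params(beta = 0.15, gamma = 1, L0 = 10, tilt = pi / 2,
                 duration = 25, dt = 0.002, ds = 0.1)
  st <- simulate_ac(p)           # B = 1.5
  tip <- st$tip_angle$angle
  # decreases toward its fixed point; tiny numerical rebounds allowed
  expect_lt(tip[length(tip)], 0.5 * tip[1])
  expect_lt(max(diff(tip)), 1e-3)
  expect_gt(min(tip), 0)                  # never crosses vertical
  expect_false(overshoot_predicate(tip))
  # final |C| maximal in the basal third of the organ (s near L)
  cf <- st$curvature
  last <- abs(cf$values[nrow(cf$values), ])
  sup <- which(cf$mask[nrow(cf$values), ] & !is.na(last))
  s_peak <- cf$s[sup[which.max(last[sup])]]
  expect_gt(s_peak, 2 / 3 * max(cf$s[sup]))
})

test_that("a strongly graviceptive organ overshoots the vertical", {
  p <- ac_params(beta = 0.5, gamma = 1, L0 = 10, tilt = pi / 2,
                 duration = 25, dt = 0.002, ds = 0.1)
  st <- simulate_ac(p)           # B = 5
  expect_lt(min(st$tip_angle$angle), 0)
  expect_true(st$overshoot)
})

test_that("the steady state satisfies the graviception-proprioception
           balance inside the growth zone", {
  p <- ac_params(beta = 0.2, gamma = 1, L0 = 10, tilt = pi / 2,
                 duration = 15, dt = 0.002, ds = 0.1)
  st <- simulate_ac(p)
  i <- nrow(st$orientation$values)
  sup <- st$orientation$mask[i, ] & st$curvature$mask[i, ]
  A <- st$orientation$values[i, sup]
  C <- st$curvature$values[i, sup]
  # apex-convention curvature: the balance reads gamma*C = beta*sin(A)
  resid <- max(abs(p$gamma * C - p$beta * sin(A)), na.rm = TRUE)
  expect_lt(resid, 0.01 * p$beta)
})

test_that("dynamics are invariant under joint rescaling of both gains", {
  run <- function(beta, gamma, duration)
    simulate_ac(ac_params(beta = beta, gamma = gamma, L0 = 10,
                          tilt = pi / 2, duration = duration,
                          dt = 0.002 / gamma, ds = 0.1,
                          record_interval = duration / 20))
  a <- run(0.2, 1, 20)
  b <- run(0.4, 2, 10)     # c = 2: same shapes at halved times
  expect_equal(a$balance_number, b$balance_number)
  expect_lt(max(abs(a$tip_angle$angle - b$tip_angle$angle)), 1e-3)
})

test_that("overshoot depends on the parameters only through B", {
  pairs <- list(c(0.35, 1), c(0.7, 2), c(0.175, 0.5))  # all B = 3.5
  flags <- vapply(pairs, function(bg) {
    st <- simulate_ac(ac_params(beta = bg[1], gamma = bg[2], L0 = 10,
                                tilt = pi / 2, duration = 40 / bg[2],
                                dt = 0.002 / bg[2], ds = 0.1,
                                record_interval = 1 / bg[2]))
    st$overshoot
  }, logical(1))
  expect_true(all(flags == flags[1]))
})

test_that("overshoot predicate applies a strict dead band", {
  expect_false(overshoot_predicate(c(1, 0.5, 0.1)))
  expect_true(overshoot_predicate(c(1, -0.2), delta = 0.05))
  expect_false(overshoot_predicate(c(1, -0.05), delta = 0.05))
  expect_error(overshoot_predicate(numeric(0)), "empty")
})

test_that("critical_balance_number validates its bracket and is monotone", {
  expect_error(critical_balance_number(5, 2), "bracket")
  expect_error(critical_balance_number(5, 10, Tmax = 20), "bracket")
  # overshoot indicator non-decreasing on a coarse grid
  grid <- seq(1, 8, length.out = 10)
  flags <- vapply(grid, function(B)
    coleokin:::ac_min_tip(B, Tmax = 30) < -0.02, logical(1))
  expect_false(is.unsorted(flags))
})

test_that("bisection agrees with a fine grid scan of the transition", {
  Bc <- critical_balance_number(2, 4, tol = 0.02)
  grid <- seq(2.6, 3.2, by = 0.02)
  flags <- vapply(grid, function(B)
    coleokin:::ac_min_tip(B, Tmax = 40) < -0.02, logical(1))
  B_scan <- grid[which(flags)[1]]
  expect_lt(abs(Bc - B_scan), 0.03)
})
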