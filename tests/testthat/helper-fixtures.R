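# Fixture builders shared across the suite.  All geometry is generated in
# code; no data files.

# Circular arc of radius R sampled exactly on the circle at uniform arc
# length, vertical at the base and bending clockwise toward the apex.
# Returned apex-first.
circle_arc_points <- function(R, arc_angle = pi / 2, step = 0.1) {
  L <- R * arc_angle
  sg <- seq(0, L, length.out = max(2, round(L / step)) + 1)
  A <- sg / R
  pts <- cbind(R * (1 - cos(A)), R * sin(A))
  pts[rev(seq_len(nrow(pts))), ]
}

straight_vertical_points <- function(L = 10, step = 0.5) {
  y <- seq(0, L, by = step)
  cbind(0, rev(y))
}

# Marker intensity profile: Gaussian bumps at given positions.
render_profile <- function(pos, amp, L, step = 0.05, sigma = 0.15) {
  g <- seq(0, L, by = step)
  v <- numeric(length(g))
  for (j in seq_along(pos))
    v <- v + amp[j] * exp(-(g - pos[j])^2 / (2 * sigma^2))
  list(s = g, intensity = v)
}

# Two-frame marker series under the displacement map s -> s + u(s).
stretched_marker_series <- function(u_fun, dt = 0.25, L = 20, seed = 1,
                                    density = 8, step = 0.05) {
  set.seed(seed)
  pos <- sort(runif(round(density * L), 0, L))
  amp <- runif(length(pos), 0.5, 1)
  p1 <- render_profile(pos, amp, L, step)
  pos2 <- pos + u_fun(pos)
  p2 <- render_profile(pos2, amp, L + u_fun(L), step)
  marker_profile_series(c(0, dt), list(p1$s, p2$s),
                        list(p1$intensity, p2$intensity))
}

# Analytic kinematic fields on shared grids.
analytic_field <- function(f, s = seq(0, 20, by = 0.1),
                           t = seq(0, 10, by = 0.1), quantity = "curvature") {
  kinematic_field(s, t, outer(t, s, f), quantity = quantity)
}

# Small generated plant (defaults unless overridden); config tweaks as a
# named list reaching into gen_config fields.
quick_plant <- function(seed = 1, tilt = pi / 2, delta_phase = pi,
                        Tp = 3, vp = 12, B = 2, L0 = 15,
                        regr_amp = 0.4, diff_amp = 0.4,
                        angular_response = "sin") {
  g <- gen_config(seed = seed)
  g$ac$tilt <- tilt
  g$delta_phase <- delta_phase
  g$regr_wave$Tp <- Tp; g$regr_wave$vp <- vp
  g$regr_wave$amplitude <- regr_amp
  g$diff_growth_wave$Tp <- Tp; g$diff_growth_wave$vp <- vp
  g$diff_growth_wave$amplitude <- diff_amp
  g$ac$L0 <- L0
  g$ac$Lgz <- min(12, L0 + 5)
  g$ac$beta <- B * g$ac$gamma / min(g$ac$L0, g$ac$Lgz)
  g$ac$angular_response <- angular_response
  g
}

# Interpolate a truth field onto a measured field's grid (time-linear,
# s-linear) and return the relative RMS difference over the joint support.
closure_rel_rms <- function(meas, tru) {
  vals <- matrix(NA_real_, length(meas$t), length(meas$s))
  for (k in seq_along(meas$t)) {
    i1 <- max(1, findInterval(meas$t[k], tru$t))
    i2 <- min(length(tru$t), i1 + 1)
    w <- if (i2 == i1) 0 else (meas$t[k] - tru$t[i1]) / (tru$t[i2] - tru$t[i1])
    ok <- tru$mask[i1, ] & tru$mask[i2, ]
    row <- (1 - w) * tru$values[i1, ] + w * tru$values[i2, ]
    vals[k, ] <- approx(tru$s[ok], row[ok], xout = meas$s, rule = 1)$y
  }
  joint <- meas$mask & !is.na(vals) & !is.na(meas$values)
  sqrt(mean((meas$values[joint] - vals[joint])^2)) /
    sqrt(mean(vals[joint]^2))
}
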