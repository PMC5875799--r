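#' Parameters for the graviceptive-proprioceptive posture model
#'
#' The model evolves the curvature of an elongating organ under two
#' opposing drives: graviception (gain `beta`, pushing the local
#' orientation toward the vertical) and proprioception (gain `gamma`,
#' relaxing curvature toward straightness).  Inside the growth zone the
#' curvature obeys `DC/Dt = -beta * g(A) - gamma * C` with `g = sin` or the
#' small-deflection linearization `g(A) = A`; outside it curvature is
#' frozen and only advected.  The base is clamped at the tilt angle and the
#' orientation follows by integrating curvature from the base.
#'
#' The behaviour is governed by the dimensionless balance number
#' `B = beta * L_eff / gamma`, with `L_eff = min(L0, Lgz)`.
#'
#' @param beta graviceptive gain (mm^-1 h^-1 per unit deflection), > 0.
#' @param gamma proprioceptive gain (h^-1), > 0.
#' @param L0 initial organ length (mm).
#' @param Lgz growth-zone length measured from the apex (mm); may exceed
#'   `L0`, in which case the whole organ curves.
#' @param regr0 baseline relative elongation rate inside the growth zone
#'   (h^-1); 0 turns growth off (fixed length).
#' @param tilt clamped base angle (rad); pi/2 is the horizontal tilt
#'   treatment, 0 the upright control.
#' @param duration simulated time (h).
#' @param dt Euler time step (h); default `0.002 / gamma`, and
#'   `dt * gamma < 0.5` is required for stability.
#' @param ds spatial step (mm).
#' @param angular_response `"sin"` for the full graviceptive response,
#'   `"linear"` for the small-deflection form.
#' @param record_interval interval between recorded frames (h).
#' @return A validated list of class `ac_params`.
#' @export
ac_params <- function(beta = 0.28, gamma = 1, L0 = 10, Lgz = L0,
                      regr0 = 0, tilt = pi / 2, duration = 24,
                      dt = 0.002 / gamma, ds = 0.1,
                      angular_response = c("sin", "linear"),
                      record_interval = 0.25) {
  angular_response <- match.arg(angular_response)
  if (beta <= 0 || gamma <= 0) stop("beta and gamma must be positive")
  if (L0 <= 0 || Lgz <= 0 || ds <= 0 || dt <= 0 || duration <= 0)
    stop("lengths, steps and duration must be positive")
  if (dt * gamma >= 0.5)
    stop("unstable time step: dt * gamma must be < 0.5")
  if (regr0 < 0) stop("regr0 must be non-negative")
  structure(list(beta = beta, gamma = gamma, L0 = L0, Lgz = Lgz,
                 regr0 = regr0, tilt = tilt, duration = duration,
                 dt = dt, ds = ds, angular_response = angular_response,
                 record_interval = record_interval),
            class = "ac_params")
}

#' Balance number of a parameter set
#' @param params an [ac_params].
#' @return `beta * min(L0, Lgz) / gamma`.
#' @export
balance_number <- function(params) {
  params$beta * min(params$L0, params$Lgz) / params$gamma
}

ac_gfun <- function(angular_response) {
  if (angular_response == "sin") sin else identity
}

# Upper bound on the final organ length for grid allocation.
ac_length_bound <- function(params, regr_cap) {
  L <- params$L0; Tt <- params$duration
  if (params$regr0 == 0) return(L)
  if (L < params$Lgz) {
    t_exp <- min(Tt, log(params$Lgz / L) / regr_cap)
    L <- L * exp(regr_cap * t_exp)
    Tt <- Tt - t_exp
  }
  L + regr_cap * min(L, params$Lgz) * Tt * 1.05 + params$ds
}

#' Simulate the graviceptive-proprioceptive posture dynamics
#'
#' Explicit Euler integration of the curvature law on a base-anchored
#' grid, with first-order upwind advection of material when growth is on.
#' Orientation is recovered each step by trapezoid integration of
#' curvature from the clamped base.  Recorded kymographs are re-expressed
#' in the apex-origin convention used everywhere else in the package
#' (`s = 0` at the tip), so the emitted curvature field is the arc-length
#' derivative of the emitted orientation field.
#'
#' @param params an [ac_params].
#' @param forcing optional function `(s_apex, t, L)` returning a list with
#'   elements `regr` (imposed REGR profile, h^-1, apex coordinates) and
#'   `curv_force` (additional curvature production DC/Dt, mm^-1 h^-1,
#'   apex-convention sign); both are applied inside the growth zone only.
#'   When `NULL`, REGR is uniform at `regr0` in the zone and there is no
#'   extra forcing.
#' @param forcing_amp_bound amplitude bound of the forcing's relative REGR
#'   modulation, used only to size the spatial grid.
#' @return An object of class `ac_state`: kymographs `orientation`,
#'   `curvature`, `regr`, `curvature_rate` (the model's own DC/Dt,
#'   production only), `tip_angle` (data.frame `t`, `angle`),
#'   `velocity_base` (material speed at each recorded frame, base frame),
#'   `length` (L(t)), `balance_number`, `overshoot`, and `params`.
#' @export
simulate_ac <- function(params, forcing = NULL, forcing_amp_bound = 1) {
  g <- ac_gfun(params$angular_response)
  ds <- params$ds; dt <- params$dt
  growth <- params$regr0 > 0
  regr_cap <- params$regr0 * (1 + abs(forcing_amp_bound))
  Lmax <- ac_length_bound(params, regr_cap)
  sigma <- seq(0, Lmax, by = ds)          # distance from the clamped base
  n <- length(sigma)
  K <- numeric(n)                         # dA/dsigma, base-frame curvature
  L <- params$L0
  rec_t <- seq(0, params$duration, by = params$record_interval)
  n_rec <- length(rec_t)
  A_rec <- matrix(NA_real_, n_rec, n)
  K_rec <- matrix(NA_real_, n_rec, n)
  E_rec <- matrix(NA_real_, n_rec, n)
  F_rec <- matrix(NA_real_, n_rec, n)     # total DC/Dt production, apex sign
  W_rec <- matrix(NA_real_, n_rec, n)
  L_rec <- numeric(n_rec)
  tip <- numeric(n_rec)
  nsteps <- round(params$duration / dt)
  rec_next <- 1L
  t_cur <- 0
  for (step_i in 0:nsteps) {
    na <- min(n, floor(L / ds + 1e-9) + 1L)
    idx <- seq_len(na)
    Ka <- K[idx]
    A <- params$tilt +
      c(0, cumsum((Ka[-1] + Ka[-na]) / 2) * ds)
    zone <- sigma[idx] > L - min(params$Lgz, L) - 1e-12
    if (is.null(forcing)) {
      regr <- ifelse(zone, params$regr0, 0)
      curv_force <- numeric(na)
    } else {
      # a forcing supplies its own (possibly tapered) growth-zone profile
      f <- forcing(L - sigma[idx], t_cur, L)
      regr <- pmax(f$regr, 0)
      curv_force <- f$curv_force
    }
    w <- c(0, cumsum((regr[-1] + regr[-na]) / 2) * ds)
    # production in base-frame sign: C_apex = -K
    rhsK <- ifelse(zone, -params$beta * g(A) - params$gamma * Ka, 0) -
      curv_force
    if (growth) {
      dK_up <- c(0, (Ka[-1] - Ka[-na]) / ds)   # upwind (w >= 0)
      rhsK <- rhsK - w * dK_up
    }
    # record before stepping so frame 0 is the initial condition
    if (rec_next <= n_rec && t_cur >= rec_t[rec_next] - dt / 2) {
      A_rec[rec_next, idx] <- A
      K_rec[rec_next, idx] <- Ka
      E_rec[rec_next, idx] <- regr
      F_rec[rec_next, idx] <- -(rhsK + if (growth) w * dK_up else 0)
      W_rec[rec_next, idx] <- w
      L_rec[rec_next] <- L
      tip[rec_next] <- A[na]
      rec_next <- rec_next + 1L
    }
    K[idx] <- Ka + dt * rhsK
    if (growth) {
      L <- min(L + dt * w[na], Lmax - ds)
      na2 <- min(n, floor(L / ds + 1e-9) + 1L)
      if (na2 > na) K[(na + 1):na2] <- K[na]
    }
    if (max(abs(K[idx])) * min(params$L0, params$Lgz) > 1e3)
      stop("curvature diverging; reduce dt (instability)")
    t_cur <- t_cur + dt
  }
  keep <- seq_len(rec_next - 1L)
  ac_state_fields(params, sigma, rec_t[keep], A_rec[keep, , drop = FALSE],
                  K_rec[keep, , drop = FALSE], E_rec[keep, , drop = FALSE],
                  F_rec[keep, , drop = FALSE], W_rec[keep, , drop = FALSE],
                  L_rec[keep], tip[keep])
}

# Flip base-frame records into apex-origin kymographs.
ac_state_fields <- function(params, sigma, rec_t, A_rec, K_rec, E_rec,
                            F_rec, W_rec, L_rec, tip) {
  ds <- params$ds
  s_grid <- sigma                          # same spacing, apex origin
  n <- length(s_grid); n_rec <- length(rec_t)
  flip_row <- function(row, L, negate = FALSE) {
    ok <- !is.na(row)
    if (sum(ok) < 2) return(rep(NA_real_, n))
    out <- stats::approx(L - sigma[ok], row[ok], xout = s_grid, rule = 1)$y
    if (negate) -out else out
  }
  Af <- Cf <- Ef <- Ff <- matrix(NA_real_, n_rec, n)
  for (i in seq_len(n_rec)) {
    Af[i, ] <- flip_row(A_rec[i, ], L_rec[i])
    Cf[i, ] <- flip_row(K_rec[i, ], L_rec[i], negate = TRUE)
    Ef[i, ] <- flip_row(E_rec[i, ], L_rec[i])
    Ff[i, ] <- flip_row(F_rec[i, ], L_rec[i])
  }
  mask <- outer(L_rec, s_grid, function(L, s) s <= L + 1e-9)
  tip_df <- data.frame(t = rec_t, angle = tip)
  structure(list(
    orientation = kinematic_field(s_grid, rec_t, Af, mask & !is.na(Af),
                                  quantity = "orientation"),
    curvature = kinematic_field(s_grid, rec_t, Cf, mask & !is.na(Cf),
                                quantity = "curvature"),
    regr = kinematic_field(s_grid, rec_t, Ef, mask & !is.na(Ef),
                           quantity = "regr"),
    curvature_rate = kinematic_field(s_grid, rec_t, Ff, mask & !is.na(Ff),
                                     quantity = "curvature_rate"),
    velocity_base = list(sigma = sigma, t = rec_t, values = W_rec,
                         length = L_rec),
    tip_angle = tip_df,
    length = data.frame(t = rec_t, L = L_rec),
    balance_number = balance_number(params),
    overshoot = overshoot_predicate(tip, delta = 0.02),
    params = params), class = "ac_state")
}

#' @export
print.ac_state <- function(x, ...) {
  cat(sprintf("<ac_state> B = %.3g, tilt = %.3g rad, %d frames\n",
              x$balance_number, x$params$tilt, nrow(x$orientation$values)))
  cat(sprintf("  tip angle: start %.3g, min %.3g rad; overshoot: %s\n",
              x$tip_angle$angle[1], min(x$tip_angle$angle), x$overshoot))
  invisible(x)
}

#' Did the tip overshoot the vertical?
#'
#' @param tip_angle_series numeric vector of tip zenith angles (rad), or a
#'   data.frame with an `angle` column as returned in an `ac_state`.
#' @param delta dead band (rad): the tip must pass more than `delta`
#'   beyond the vertical (strictly below `-delta`) to count, rejecting
#'   numerical ripple.  Default 0.02 rad.
#' @return logical.
#' @export
overshoot_predicate <- function(tip_angle_series, delta = 0.02) {
  if (is.data.frame(tip_angle_series)) tip_angle_series <- tip_angle_series$angle
  if (length(tip_angle_series) == 0) stop("empty tip-angle series")
  if (delta < 0) stop("delta must be non-negative")
  min(tip_angle_series) < -delta
}

# Fast fixed-length scan: minimum tip angle for a given balance number,
# on the nondimensional problem (gamma = 1, L = 1, beta = B).
ac_min_tip <- function(B, tilt = pi / 2, n = 101, dt = 0.002, Tmax = 40,
                       angular_response = "linear") {
  g <- ac_gfun(angular_response)
  ds <- 1 / (n - 1)
  K <- numeric(n)
  min_tip <- tilt
  for (i in seq_len(ceiling(Tmax / dt))) {
    A <- tilt + c(0, cumsum((K[-1] + K[-n]) / 2) * ds)
    K <- K + dt * (-B * g(A) - K)
    if (A[n] < min_tip) min_tip <- A[n]
  }
  min_tip
}

#' Critical balance number of the overshoot transition
#'
#' Locates the balance number at which a tilted organ of fixed length
#' first overshoots the vertical, by a monotonicity pre-scan followed by
#' bisection on B.  The simulation is the fixed-length (no elongation)
#' posture dynamic in nondimensional form, so the result depends only on
#' B, the tilt, the overshoot dead band and the discretization.
#'
#' The published transition value (B = 2.8) corresponds to the
#' small-deflection graviceptive response, which is therefore the default
#' here; the full `sin` response places the transition somewhat higher
#' (near 3.2) and can be selected for comparison.
#'
#' @param B_low,B_high bracket: no overshoot at `B_low`, overshoot at
#'   `B_high` (checked).
#' @param tol bisection width (default 0.05).
#' @param tilt initial tilt (rad).
#' @param delta overshoot dead band (rad), see [overshoot_predicate()].
#' @param angular_response `"linear"` (default) or `"sin"`.
#' @param prescan_n number of pre-scan points used to assert that the
#'   overshoot indicator is monotone in B.
#' @param n,dt,Tmax discretization of the nondimensional simulation.
#' @return The transition balance number (bracket midpoint).
#' @export
critical_balance_number <- function(B_low = 0.5, B_high = 10, tol = 0.05,
                                    tilt = pi / 2, delta = 0.02,
                                    angular_response = c("linear", "sin"),
                                    prescan_n = 8, n = 101, dt = 0.002,
                                    Tmax = 40) {
  angular_response <- match.arg(angular_response)
  if (B_low >= B_high) stop("invalid bracket: B_low must be < B_high")
  pred <- function(B)
    ac_min_tip(B, tilt, n, dt, Tmax, angular_response) < -delta
  grid <- seq(B_low, B_high, length.out = max(3, prescan_n))
  flags <- vapply(grid, pred, logical(1))
  if (flags[1] || !flags[length(flags)])
    stop("invalid bracket: overshoot must be absent at B_low and present at B_high")
  if (is.unsorted(flags))
    stop("overshoot indicator is not monotone on the pre-scan grid")
  i <- max(which(!flags))
  lo <- grid[i]; hi <- grid[min(i + 1, length(grid))]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pred(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
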