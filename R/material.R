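#' Material derivative of curvature DC/Dt
#'
#' Rate of change of curvature following the moving tissue, computed as
#' `DC/Dt = dC/dt + v(s,t) * dC/ds` with the advection velocity
#' `v(s, t) = integral of the REGR from the apex (s = 0) to s`.  A positive
#' value means the curvature of the co-moving material element is
#' increasing.
#'
#' Both partials use local-quadratic (Savitzky-Golay) derivative filters
#' along the supported runs (reducing to finite differences on short
#' runs), evaluated on the curvature field's frame grid and then
#' interpolated in time to the REGR field's time stamps (which sit between
#' frames when the REGR was estimated over multi-frame intervals).  The
#' two fields must share the same arc-length grid; the result is reported
#' on the REGR field's grid.
#'
#' @param curvature a [kinematic_field] with quantity `"curvature"`.
#' @param regr a [kinematic_field] with quantity `"regr"`.
#' @param t_deriv_frames window (in frames) of the time-derivative filter
#'   (odd; 3 = centered difference).
#' @param s_deriv_window window (mm) of the arc-length derivative filter.
#' @return A [kinematic_field] with `quantity = "curvature_rate"`
#'   (mm^-1 h^-1).
#' @export
material_curvature_derivative <- function(curvature, regr,
                                          t_deriv_frames = 3,
                                          s_deriv_window = 0) {
  if (length(curvature$s) != length(regr$s) ||
      max(abs(curvature$s - regr$s)) > 1e-9)
    stop("grid mismatch: curvature and regr fields differ in s")
  if (length(curvature$t) < 2)
    stop("need at least 2 frames for a time derivative")
  if (min(regr$t) < min(curvature$t) - 1e-6 ||
      max(regr$t) > max(curvature$t) + 1e-6)
    stop("grid mismatch: regr times fall outside the curvature record")
  h <- field_step(curvature)
  nt_c <- length(curvature$t); ns <- length(curvature$s)

  s_wpts <- if (s_deriv_window > 0)
    max(5, 2 * floor(s_deriv_window / h / 2) + 1) else 0
  dc_ds <- t(vapply(seq_len(nt_c), function(i) {
    if (s_wpts >= 5)
      masked_sg_deriv(curvature$values[i, ], curvature$mask[i, ], h, s_wpts)
    else
      masked_gradient(curvature$values[i, ], curvature$mask[i, ], h)
  }, numeric(ns)))

  dt_h <- stats::median(diff(curvature$t))
  t_wpts <- max(3, 2 * floor(t_deriv_frames / 2) + 1)
  dc_dt <- vapply(seq_len(ns), function(j) {
    if (t_wpts >= 5)
      masked_sg_deriv(curvature$values[, j], curvature$mask[, j], dt_h, t_wpts)
    else
      masked_gradient(curvature$values[, j], curvature$mask[, j], dt_h)
  }, numeric(nt_c))
  if (ns == 1) dc_dt <- matrix(dc_dt, ncol = 1)

  out <- matrix(NA_real_, length(regr$t), ns)
  for (k in seq_along(regr$t)) {
    tt <- regr$t[k]
    i1 <- max(1, findInterval(tt + 1e-9, curvature$t))
    i2 <- min(nt_c, i1 + 1)
    wt <- if (i2 == i1) 0 else
      (tt - curvature$t[i1]) / (curvature$t[i2] - curvature$t[i1])
    wt <- min(1, max(0, wt))
    ddt <- (1 - wt) * dc_dt[i1, ] + wt * dc_dt[i2, ]
    dds <- (1 - wt) * dc_ds[i1, ] + wt * dc_ds[i2, ]
    v_adv <- advection_velocity(regr$s, regr$values[k, ], regr$mask[k, ])
    out[k, ] <- ddt + dds * v_adv
  }
  mask <- !is.na(out)
  kinematic_field(regr$s, regr$t, out, mask, quantity = "curvature_rate")
}

match_times <- function(t_sub, t_full) {
  idx <- vapply(t_sub, function(tt) {
    j <- which.min(abs(t_full - tt))
    if (abs(t_full[j] - tt) > 1e-6) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx))
    stop("grid mismatch: times are not a subset of the field's time grid")
  idx
}

# Cumulative integral of the REGR from the apex.  Interior gaps are closed
# by linear interpolation and the leading/trailing unmeasured stretches by
# nearest-value extension, so the integral is defined wherever the REGR
# field has support.
advection_velocity <- function(s, regr_row, mask) {
  out <- rep(NA_real_, length(s))
  if (sum(mask) < 2) return(out)
  filled <- fill_gaps(s, regr_row, mask)
  v <- pracma::cumtrapz(s, filled)[, 1]
  out[mask] <- v[mask]
  out
}

fill_gaps <- function(s, x, mask) {
  if (all(mask)) return(x)
  stats::approx(s[mask], x[mask], xout = s, rule = 2)$y
}

#' Track a material point through a velocity field
#'
#' Advects a material point from an initial arc-length position using the
#' apex-referenced velocity `v(s, t)` implied by a REGR field
#' (`ds/dt = integral of REGR from apex to s`), with midpoint (RK2) time
#' stepping on the field's frame cadence.  Used as an independent check of
#' [material_curvature_derivative()]: the finite difference of curvature
#' sampled along the returned trajectory approximates DC/Dt for that
#' element.
#'
#' @param regr a [kinematic_field] with quantity `"regr"`.
#' @param s0 initial arc-length position (mm) at the field's first frame.
#' @return data.frame with columns `t` and `s`.
#' @export
track_material_point <- function(regr, s0) {
  ts <- regr$t
  s_cur <- s0
  out <- numeric(length(ts))
  out[1] <- s0
  vel <- function(k, s_at) {
    v <- advection_velocity(regr$s, regr$values[k, ], regr$mask[k, ])
    ok <- !is.na(v)
    stats::approx(regr$s[ok], v[ok], xout = s_at, rule = 2)$y
  }
  for (k in seq_len(length(ts) - 1)) {
    dt <- ts[k + 1] - ts[k]
    v1 <- vel(k, s_cur)
    v2 <- vel(k, s_cur + 0.5 * dt * v1)
    s_cur <- s_cur + dt * v2
    out[k + 1] <- s_cur
  }
  data.frame(t = ts, s = out)
}
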