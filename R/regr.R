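#' Marker intensity profiles along the organ
#'
#' Per-frame intensity of growth tracer markers sampled at uniform arc
#' length from the apex, used to estimate the relative elongation growth
#' rate (REGR) by one-dimensional digital image correlation.
#'
#' @param times frame times (h), strictly increasing.
#' @param s list of arc-length sample vectors (mm, from the apex, uniform
#'   spacing shared by all frames).
#' @param intensity list of non-negative intensity vectors matching `s`.
#' @return An object of class `marker_profile_series` with elements
#'   `times`, `s`, `intensity` and `step`.
#' @export
marker_profile_series <- function(times, s, intensity) {
  times <- as.numeric(times)
  if (length(times) != length(s) || length(times) != length(intensity))
    stop("times, s and intensity must have the same length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  steps <- unlist(lapply(s, function(x) diff(x)))
  if (any(steps <= 0)) stop("arc-length samples must be increasing")
  step <- stats::median(steps)
  if (max(abs(steps - step)) > 1e-6 * max(step, 1))
    stop("marker profiles must be uniformly sampled")
  if (any(unlist(intensity) < 0)) stop("intensities must be non-negative")
  structure(list(times = times, s = s, intensity = intensity, step = step),
            class = "marker_profile_series")
}

#' @export
print.marker_profile_series <- function(x, ...) {
  cat(sprintf("<marker_profile_series> %d frames, step %.3g mm\n",
              length(x$times), x$step))
  invisible(x)
}

# Windowed sums of x over [ic - hw, ic + hw] for all centers ic at once.
.win_sums <- function(cs, ic, hw) cs[ic + hw + 1] - cs[ic - hw]

# Normalized cross-correlation displacement between two intensity profiles.
# Returns the displacement (mm) of each window of `i1` in `i2`, with
# sub-sample refinement of the correlation peak, plus flags for flat
# windows and for windows without an acceptable match (peak on the search
# bound or best correlation below `min_corr` -- a false match on
# unrelated texture).
dic_displacement <- function(i1, i2, step, centers_idx, half_w, max_lag,
                             min_corr = 0.6) {
  n1 <- length(i1); n2 <- length(i2)
  m <- 2 * half_w + 1
  nc <- length(centers_idx)
  lags <- -max_lag:max_lag
  cs1 <- cumsum(c(0, i1)); cs11 <- cumsum(c(0, i1^2))
  cs2 <- cumsum(c(0, i2)); cs22 <- cumsum(c(0, i2^2))
  S1 <- .win_sums(cs1, centers_idx, half_w)
  S11 <- .win_sums(cs11, centers_idx, half_w)
  var1 <- S11 - S1^2 / m
  ncc <- matrix(-Inf, nc, length(lags))
  for (li in seq_along(lags)) {
    k <- lags[li]
    ok <- centers_idx - half_w + k >= 1 & centers_idx + half_w + k <= n2
    if (!any(ok)) next
    ic <- centers_idx[ok]
    # cross products I1[j] * I2[j + k] window-summed via cumsum
    jmax <- min(n1, n2 - k); jmin <- max(1, 1 - k)
    prod <- numeric(n1)
    prod[jmin:jmax] <- i1[jmin:jmax] * i2[(jmin + k):(jmax + k)]
    csp <- cumsum(c(0, prod))
    S12 <- .win_sums(csp, ic, half_w)
    S2 <- .win_sums(cs2, ic + k, half_w)
    S22 <- .win_sums(cs22, ic + k, half_w)
    var2 <- S22 - S2^2 / m
    denom <- sqrt(pmax(var1[ok], 0) * pmax(var2, 0))
    r <- ifelse(denom > 1e-12, (S12 - S1[ok] * S2 / m) / denom, -Inf)
    ncc[ok, li] <- r
  }
  best <- max.col(ncc, ties.method = "first")
  # the correlation peak measures the displacement of the window's marker
  # texture, i.e. the displacement at the intensity centroid rather than
  # at the geometric center; report the centroid so the caller can place
  # the estimate correctly (first-order bias removal for strained fields)
  gpos <- (seq_along(i1) - 1) * step
  wsum <- .win_sums(cs11, centers_idx, half_w)
  csg <- cumsum(c(0, i1^2 * gpos))
  centroid <- ifelse(wsum > 1e-9,
                     .win_sums(csg, centers_idx, half_w) / wsum,
                     (centers_idx - 1) * step)
  u <- numeric(nc); flat <- var1 < 1e-10 * m; bound <- logical(nc)
  for (ci in seq_len(nc)) {
    b <- best[ci]
    if (!is.finite(ncc[ci, b])) { bound[ci] <- TRUE; next }
    if (b == 1 || b == length(lags)) { bound[ci] <- TRUE; next }
    y0 <- ncc[ci, b - 1]; y1 <- ncc[ci, b]; y2 <- ncc[ci, b + 1]
    if (!is.finite(y0) || !is.finite(y2)) { bound[ci] <- TRUE; next }
    if (y1 < min_corr) { bound[ci] <- TRUE; next }
    if (y1 >= 1 - 1e-9) {
      # perfect match: the displacement is exactly this integer lag and
      # sub-sample refinement on an asymmetric windowed correlation
      # would only add noise
      u[ci] <- lags[b] * step
      next
    }
    # Gaussian (log-parabola) sub-sample peak estimator where the
    # correlation values allow it; plain parabola otherwise
    if (y0 > 0 && y1 > 0 && y2 > 0) {
      l0 <- log(y0); l1 <- log(y1); l2 <- log(y2)
      denom <- l0 - 2 * l1 + l2
      delta <- if (abs(denom) > 1e-12) 0.5 * (l0 - l2) / denom else 0
    } else {
      denom <- y0 - 2 * y1 + y2
      delta <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
    }
    delta <- max(-0.5, min(0.5, delta))
    u[ci] <- (lags[b] + delta) * step
  }
  list(u = u, flat = flat, bound = bound, centroid = centroid)
}

#' REGR kymograph from marker profiles by 1-D image correlation
#'
#' For every consecutive frame pair the axial displacement of the marker
#' texture is estimated by maximizing the windowed normalized
#' cross-correlation of the two intensity profiles, with 3-point parabolic
#' sub-sample peak interpolation.  The velocity `v(s) = u(s) / dt` relative
#' to the apex is differentiated along arc length to give the relative
#' elongation growth rate, reported at the earlier frame's time.
#'
#' Windows whose texture is flat, whose best match sits on the search
#' bound, or whose peak correlation falls below `min_corr` (a false match
#' on unrelated texture) are masked and counted in a single warning.
#'
#' @param mp a [marker_profile_series].
#' @param window correlation window length (mm, default 2).
#' @param search displacement search range per frame interval (mm,
#'   default 1).
#' @param overlap fractional overlap of neighbouring windows (default
#'   0.75, i.e. centers every `window/4`).
#' @param deriv_window baseline (mm) of the local-quadratic
#'   (Savitzky-Golay) first-derivative filter that turns the velocity
#'   profile into a strain rate; one-sided fits are used at the ends of
#'   each supported run.  Default 3 mm.
#' @param min_corr minimum acceptable peak correlation (default 0.6).
#' @param frame_step correlate frame `i` against frame `i + frame_step`
#'   (sliding).  A larger step increases the measured displacement while
#'   the texture-interference error of the correlation peak stays fixed,
#'   improving the strain-rate signal-to-noise at the cost of averaging
#'   the REGR over a longer interval.  Default 1.
#' @return A [kinematic_field] with `quantity = "regr"` (h^-1) on the grid
#'   of window centers; one time row per correlated frame pair, at the
#'   earlier frame's time.
#' @export
regr_from_markers <- function(mp, window = 2, search = 1, overlap = 0.75,
                              deriv_window = 3, frame_step = 1,
                              min_corr = 0.6) {
  frame_step <- max(1L, as.integer(frame_step))
  if (length(mp$times) < frame_step + 1) stop("need at least 2 frames")
  step <- mp$step
  if (window <= step) stop("window must exceed the sampling step")
  half_w <- max(2, round(window / 2 / step))
  max_lag <- max(1, round(search / step))
  c_step <- max(1, round(2 * half_w * (1 - overlap)))
  lens <- vapply(mp$s, function(x) x[length(x)], numeric(1))
  n_max <- max(vapply(mp$s, length, 1L))
  centers_all <- seq(half_w + 1, n_max - half_w, by = c_step)
  if (length(centers_all) < 2)
    stop("profiles too short for the chosen window")
  # uniform output grid from the apex at the window-center spacing
  s_centers <- seq(0, (max(centers_all) - 1) * step, by = c_step * step)
  nt <- length(mp$times) - frame_step
  vmat <- matrix(NA_real_, nt, length(s_centers))
  n_flat <- 0L; n_bound <- 0L
  for (i in seq_len(nt)) {
    i1 <- mp$intensity[[i]]; i2 <- mp$intensity[[i + frame_step]]
    ok <- centers_all + half_w <= length(i1)
    if (sum(ok) < 2) next
    d <- dic_displacement(i1, i2, step, centers_all[ok], half_w, max_lag,
                          min_corr)
    dt <- mp$times[i + frame_step] - mp$times[i]
    v <- d$u / dt
    keep <- !(d$flat | d$bound)
    n_flat <- n_flat + sum(d$flat); n_bound <- n_bound + sum(d$bound & !d$flat)
    if (sum(keep) >= 2) {
      # velocities live at the windows' intensity centroids; resample onto
      # the regular center grid before differentiating.  The apex itself
      # is a known anchor: arc length is measured from the apex in every
      # frame, so the apex-referenced displacement at s = 0 is exactly 0.
      ctr <- c(0, d$centroid[keep])
      vv <- c(0, v[keep])
      o <- order(ctr)
      vmat[i, ] <- stats::approx(ctr[o], vv[o], xout = s_centers,
                                 rule = 1)$y
    }
  }
  if (n_flat > 0)
    warning(n_flat, " flat (zero-variance) correlation windows masked")
  if (n_bound > 0)
    warning(n_bound,
            " windows without an acceptable correlation match (search",
            " bound or low peak correlation) were masked")
  cdist <- c_step * step
  wpts <- max(5, 2 * floor(deriv_window / cdist / 2) + 1)
  emat <- matrix(NA_real_, nt, length(s_centers))
  for (i in seq_len(nt)) {
    row <- vmat[i, ]
    mask <- !is.na(row)
    if (sum(mask) < 3) next
    emat[i, ] <- masked_sg_deriv(row, mask, cdist, wpts)
  }
  # each row is the average strain rate over its frame pair's interval;
  # label it at the interval midpoint
  t_out <- (mp$times[seq_len(nt)] + mp$times[seq_len(nt) + frame_step]) / 2
  kinematic_field(s_centers, t_out, emat, quantity = "regr")
}
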