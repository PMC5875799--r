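#' Midline time series of a growing organ
#'
#' A `midline_series` holds, for each frame, the planar coordinates of the
#' organ's median line ordered **apex first** (the tip is the first row and
#' carries arc length `s = 0`), plus the frame times in hours.  Coordinates
#' are in mm with `y` pointing vertically up, against gravity.
#'
#' @param times numeric vector of frame times (h), strictly increasing.
#' @param points list of two-column matrices `(x_mm, y_mm)`, one per frame,
#'   apex first.
#' @param validate check frame sizes and that organ length is
#'   non-decreasing over time (a growing organ); a small tolerance absorbs
#'   digitization noise.
#' @return An object of class `midline_series` with elements `times`,
#'   `points`, `lengths` (arc length per frame) and `frame_interval`.
#' @export
midline_series <- function(times, points, validate = TRUE) {
  times <- as.numeric(times)
  if (length(times) != length(points))
    stop("times and points must have the same length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  points <- lapply(points, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2) stop("each frame needs two coordinate columns")
    storage.mode(p) <- "double"
    p
  })
  lens <- vapply(points, function(p) {
    if (nrow(p) < 2) return(NA_real_)
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  if (validate) {
    if (any(vapply(points, nrow, 1L) < 2))
      stop("malformed midline: every frame needs at least 2 points")
    if (length(lens) > 1) {
      shrink <- diff(lens) < -0.05 * lens[-length(lens)] - 0.2
      if (any(shrink))
        stop("organ length decreases between frames ",
             paste(which(shrink), collapse = ", "),
             "; midlines must describe a growing organ")
    }
  }
  structure(list(times = times, points = points, lengths = lens,
                 frame_interval = if (length(times) > 1)
                   stats::median(diff(times)) else NA_real_),
            class = "midline_series")
}

#' @export
print.midline_series <- function(x, ...) {
  cat(sprintf("<midline_series> %d frames, t = %.3g..%.3g h\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  organ length %.2f -> %.2f mm\n",
              x$lengths[1], x$lengths[length(x$lengths)]))
  invisible(x)
}

frame_arclength <- function(p) {
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

#' Resample midlines to uniform arc-length spacing
#'
#' Each frame is re-parameterized to points spaced `target_step` mm apart
#' along the curve, starting at the apex (`s = 0`).  Total length is
#' preserved to within one step (the final partial segment is dropped).
#'
#' @param ml a [midline_series].
#' @param target_step arc-length spacing in mm (default 0.1).
#' @return A [midline_series] whose frames are uniformly spaced.
#' @export
resample_midline <- function(ml, target_step = 0.1) {
  if (target_step <= 0) stop("target_step must be positive")
  if (length(ml$points) == 0) stop("midline series has no frames")
  pts <- lapply(ml$points, function(p) {
    if (nrow(p) < 2) stop("malformed midline: frame with fewer than 2 points")
    s <- frame_arclength(p)
    keep <- c(TRUE, diff(s) > 0)  # drop duplicate consecutive points
    p <- p[keep, , drop = FALSE]
    s <- s[keep]
    if (nrow(p) < 2) stop("malformed midline: degenerate frame")
    s_new <- seq(0, s[length(s)], by = target_step)
    cbind(stats::approx(s, p[, 1], xout = s_new)$y,
          stats::approx(s, p[, 2], xout = s_new)$y)
  })
  midline_series(ml$times, pts, validate = FALSE)
}

# Zenith angle of the base-to-apex tangent: 0 = vertical up, clockwise
# (toward +x) positive.  Points are apex-first so the growth direction is
# the direction of decreasing s.
tangent_zenith_angle <- function(p) {
  n <- nrow(p)
  if (n < 2) stop("need at least 2 points for a tangent")
  dx <- numeric(n); dy <- numeric(n)
  if (n == 2) {
    dx[] <- p[2, 1] - p[1, 1]; dy[] <- p[2, 2] - p[1, 2]
  } else {
    # second-order one-sided stencils at the ends avoid the half-step
    # angle bias of a simple forward/backward difference
    dx[1] <- -3 * p[1, 1] + 4 * p[2, 1] - p[3, 1]
    dy[1] <- -3 * p[1, 2] + 4 * p[2, 2] - p[3, 2]
    dx[n] <- 3 * p[n, 1] - 4 * p[n - 1, 1] + p[n - 2, 1]
    dy[n] <- 3 * p[n, 2] - 4 * p[n - 1, 2] + p[n - 2, 2]
    dx[2:(n - 1)] <- p[3:n, 1] - p[1:(n - 2), 1]
    dy[2:(n - 1)] <- p[3:n, 2] - p[1:(n - 2), 2]
  }
  if (any(dx == 0 & dy == 0))
    stop("malformed midline: duplicate consecutive points")
  # base->apex tangent = -(d/ds), s increasing apex->base
  unwrap_angles(atan2(-dx, -dy))
}

unwrap_angles <- function(a) {
  if (length(a) < 2) return(a)
  d <- diff(a)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  a - 2 * pi * jumps
}

#' Orientation kymograph A(s, t) from a midline series
#'
#' The local orientation is the zenith angle of the organ axis: 0 for a
#' locally vertical, upright element and +pi/2 for an element pointing
#' horizontally to the reader's right (clockwise angles positive).  Angles
#' are unwrapped along arc length so the profile has no +-pi jumps.
#'
#' @param ml a [midline_series], ideally already passed through
#'   [resample_midline()]; frames are resampled to `step` here otherwise.
#' @param step arc-length grid step in mm.
#' @return A [kinematic_field] with `quantity = "orientation"` (rad) on a
#'   common s grid spanning the longest frame; cells beyond a frame's
#'   length are masked.
#' @export
orientation_profile <- function(ml, step = 0.1) {
  ml <- resample_midline(ml, step)
  n_max <- max(vapply(ml$points, nrow, 1L))
  s_grid <- (seq_len(n_max) - 1) * step
  nt <- length(ml$times)
  values <- matrix(NA_real_, nt, n_max)
  for (i in seq_len(nt)) {
    a <- tangent_zenith_angle(ml$points[[i]])
    values[i, seq_along(a)] <- a
  }
  kinematic_field(s_grid, ml$times, values, quantity = "orientation")
}

#' Curvature kymograph C(s, t) = dA/ds
#'
#' Spatial derivative of the orientation field by centered finite
#' differences (one-sided at the support edges), optionally smoothed with a
#' local quadratic filter beforehand.
#'
#' @param orientation a [kinematic_field] with quantity `"orientation"`.
#' @param s_window Savitzky-Golay window along s in mm applied to the
#'   orientation before differentiation; 0 disables smoothing.
#' @param t_window companion window in frames (default 0, disabled).
#' @return A [kinematic_field] with `quantity = "curvature"` (mm^-1).
#' @export
curvature_profile <- function(orientation, s_window = 0, t_window = 0) {
  if (!inherits(orientation, "kinematic_field"))
    stop("orientation must be a kinematic_field")
  if (max(rowSums(orientation$mask)) < 3)
    stop("need at least 3 arc-length samples inside the support")
  f <- orientation
  if (s_window > 0 || t_window >= 3)
    f <- smooth_field(f, s_window, t_window)
  h <- field_step(f)
  v <- t(vapply(seq_along(f$t), function(i)
    masked_gradient(f$values[i, ], f$mask[i, ], h),
    numeric(length(f$s))))
  kinematic_field(f$s, f$t, v, f$mask, quantity = "curvature")
}
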