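#' Detect oscillation maxima on a kymograph
#'
#' Finds, at every arc-length position, the local maxima of the field
#' along time whose value exceeds a per-organ quantile threshold.  Points
#' outside the support mask are excluded.  Minima can be detected by
#' negating the field (`minima = TRUE`).
#'
#' @param field a [kinematic_field] with at least 3 time samples.
#' @param threshold_quantile quantile of the supported values used as the
#'   detection threshold (default 0.7; 1.0 keeps only the global maximum).
#' @param minima detect minima instead of maxima.
#' @param min_separation minimum time between retained maxima at one
#'   arc-length position (h); of any closer pair the larger survives.
#'   Suppresses spurious noise peaks between genuine pulses.  Default 1 h.
#' @return data.frame with columns `t` (h), `s` (mm), `value`.
#' @export
detect_maxima <- function(field, threshold_quantile = 0.7, minima = FALSE,
                          min_separation = 1) {
  if (length(field$t) < 3) stop("need at least 3 time samples")
  if (!any(field$mask)) stop("field has empty support")
  v <- field$values
  if (minima) v <- -v
  thr <- stats::quantile(v[field$mask], threshold_quantile, na.rm = TRUE,
                         names = FALSE)
  nt <- nrow(v)
  res_t <- numeric(0); res_s <- numeric(0); res_v <- numeric(0)
  for (j in seq_len(ncol(v))) {
    col <- v[, j]; m <- field$mask[, j]
    cand_i <- which(vapply(2:(nt - 1), function(i)
      m[i - 1] && m[i] && m[i + 1] &&
        col[i] > col[i - 1] && col[i] >= col[i + 1] && col[i] >= thr,
      logical(1))) + 1L
    if (min_separation > 0 && length(cand_i) > 1) {
      keep <- logical(length(cand_i))
      for (o in order(col[cand_i], decreasing = TRUE)) {
        ti <- field$t[cand_i[o]]
        if (!any(keep & abs(field$t[cand_i] - ti) < min_separation))
          keep[o] <- TRUE
      }
      cand_i <- sort(cand_i[keep])
    }
    # sub-frame peak timing by local quadratic fit (up to 2 frames each
    # side), so crest times are not quantized to the frame cadence
    t_ref <- vapply(cand_i, function(i) {
      lo <- i; hi <- i
      while (lo > 1 && i - lo < 2 && m[lo - 1] && !is.na(col[lo - 1])) lo <- lo - 1
      while (hi < nt && hi - i < 2 && m[hi + 1] && !is.na(col[hi + 1])) hi <- hi + 1
      tt <- field$t[lo:hi] - field$t[i]
      yy <- col[lo:hi]
      if (length(tt) < 3) return(field$t[i])
      cf <- stats::lm.fit(cbind(1, tt, tt^2), yy)$coefficients
      if (!is.finite(cf[3]) || cf[3] >= -1e-12) return(field$t[i])
      dlt <- -cf[2] / (2 * cf[3])
      step_t <- stats::median(diff(field$t[lo:hi]))
      field$t[i] + max(-step_t, min(step_t, dlt))
    }, numeric(1))
    res_t <- c(res_t, t_ref)
    res_s <- c(res_s, rep(field$s[j], length(cand_i)))
    res_v <- c(res_v, col[cand_i])
  }
  data.frame(t = res_t, s = res_s, value = if (minima) -res_v else res_v)
}

#' Link detected maxima into travelling pulse tracks
#'
#' Greedy nearest-neighbour linking in time order: each point joins the
#' track whose most recent point is no older than `max_gap` and no farther
#' than `max_jump` in arc length, preferring the smallest jump and, on
#' ties, the track updated earliest.  Each track with at least 3 points is
#' fitted by least squares to the linear crest locus `s = vp * (t - t0)`,
#' giving the pulse velocity `vp` (slope) and the apex-crossing time `t0`.
#'
#' @param maxima data.frame from [detect_maxima()].
#' @param max_gap maximum time gap within a track (h, default 0.75).
#' @param max_jump maximum arc-length jump between linked points (mm,
#'   default 8).
#' @param min_points minimum points for a fitted track (default 3).
#' @return list of `pulse_track` objects, each with `points`, `vp`
#'   (mm/h), `t0` (h), `fit_residual` (rms, mm) and `n`.
#' @export
link_tracks <- function(maxima, max_gap = 0.75, max_jump = 8,
                        min_points = 3) {
  if (nrow(maxima) == 0) return(list())
  ord <- order(maxima$t, maxima$s)
  pts <- maxima[ord, , drop = FALSE]
  last_t <- numeric(0); last_s <- numeric(0); assign_id <- integer(nrow(pts))
  members <- list()
  for (i in seq_len(nrow(pts))) {
    ti <- pts$t[i]; si <- pts$s[i]
    cand <- which(ti - last_t <= max_gap & ti - last_t >= 0 &
                    abs(si - last_s) <= max_jump)
    if (length(cand) == 0) {
      last_t <- c(last_t, ti); last_s <- c(last_s, si)
      members[[length(members) + 1L]] <- i
    } else {
      jump <- abs(si - last_s[cand])
      best <- cand[order(jump, last_t[cand])][1]
      last_t[best] <- ti; last_s[best] <- si
      members[[best]] <- c(members[[best]], i)
    }
  }
  tracks <- lapply(members, function(idx) {
    p <- pts[idx, , drop = FALSE]
    if (nrow(p) < min_points || length(unique(p$t)) < 2) return(NULL)
    # regress the frame-quantized coordinate (t) on the continuous one (s)
    # so cadence quantization does not attenuate the fitted slope; the
    # crest locus s = vp * (t - t0) is recovered by inversion
    if (stats::var(p$s) < 1e-12) {
      vp <- 0; t0 <- NA_real_
      resid <- p$s - mean(p$s)
    } else {
      fit <- stats::lm.fit(cbind(1, p$s), p$t)
      slope <- unname(fit$coefficients[2])
      if (abs(slope) < 1e-12) {
        vp <- Inf; t0 <- unname(fit$coefficients[1])
        resid <- rep(0, nrow(p))
      } else {
        vp <- 1 / slope
        t0 <- unname(fit$coefficients[1])
        resid <- p$s - vp * (p$t - t0)
      }
    }
    structure(list(points = p[, c("t", "s", "value")],
                   vp = vp, t0 = t0,
                   fit_residual = sqrt(mean(resid^2)),
                   n = nrow(p)),
              class = "pulse_track")
  })
  tracks[!vapply(tracks, is.null, logical(1))]
}

#' @export
print.pulse_track <- function(x, ...) {
  cat(sprintf("<pulse_track> %d points, vp = %.3g mm/h, t0 = %.3g h\n",
              x$n, x$vp, x$t0))
  invisible(x)
}

#' Oscillation period from ordered peak times
#'
#' `Tp = T / n`: the time span `T` covering `n` inter-peak intervals,
#' divided by the number of intervals.
#'
#' @param peak_times numeric vector of at least 2 peak times (h).
#' @return list with `Tp`, `n_intervals`, `T_span`.
#' @export
period_estimate <- function(peak_times) {
  peak_times <- sort(peak_times)
  if (length(peak_times) < 2)
    stop("need at least 2 peak times for a period estimate")
  T_span <- peak_times[length(peak_times)] - peak_times[1]
  n_int <- length(peak_times) - 1L
  list(Tp = T_span / n_int, n_intervals = n_int, T_span = T_span)
}

#' Characterize the oscillations of a kymograph
#'
#' Detects thresholded maxima, estimates the pulse period from the peak
#' trains at the most strongly oscillating arc-length stations (each
#' station gives an independent span / n-intervals estimate; the median
#' over a handful of well-separated stations is reported), and fits
#' linear tracks to the travelling crests to estimate pulse velocities.
#'
#' @param field a [kinematic_field].
#' @param threshold_quantile see [detect_maxima()].
#' @param max_gap,max_jump see [link_tracks()].
#' @param min_points minimum points per fitted track.
#' @param s_min,s_max restrict detection to arc lengths in `[s_min,
#'   s_max]`; stations within a derivative baseline of the apex, or past
#'   the growth zone, carry unreliable pulse phase and bias the velocity
#'   fit.
#' @param n_period_stations number of well-separated high-variance
#'   stations whose per-station period estimates are combined (median).
#' @return An `oscillation_summary`: list with `Tp` (h, station-median
#'   estimate), `Tp_ref` (estimate at the single reference station),
#'   `n_intervals`, `T_span`, `tracks`, `vp_median` (median of per-track
#'   slopes, mm/h), `vp_pooled` (common-slope fit over all tracks),
#'   `s_ref` (reference station, mm) and `peak_times`.
#' @export
characterize_oscillations <- function(field, threshold_quantile = 0.7,
                                      max_gap = 0.75, max_jump = 8,
                                      min_points = 3,
                                      s_min = -Inf, s_max = Inf,
                                      n_period_stations = 5) {
  keep_s <- field$s >= s_min & field$s <= s_max
  if (sum(keep_s) < 2) stop("no arc-length stations inside [s_min, s_max]")
  field <- kinematic_field(field$s[keep_s], field$t,
                           field$values[, keep_s, drop = FALSE],
                           field$mask[, keep_s, drop = FALSE],
                           field$quantity, field$units)
  maxima <- detect_maxima(field, threshold_quantile)
  # period: span-over-intervals estimates at the most strongly
  # oscillating stations; the median over a handful of well-separated
  # stations is robust to one station missing or double-counting a peak
  cover <- colSums(field$mask)
  vs <- apply(field$values, 2, stats::var, na.rm = TRUE)
  vs[is.na(vs)] <- -Inf
  vs[cover < max(3, stats::median(cover) / 2)] <- -Inf
  j_ref <- which.max(vs)
  s_ref <- field$s[j_ref]
  st_sep <- max(1, round(1 / max(field$s[2] - field$s[1], 1e-6)))
  stations <- field$s[order(vs, decreasing = TRUE)]
  picked <- numeric(0)
  for (sv in stations) {
    if (length(picked) >= n_period_stations) break
    if (!is.finite(vs[which(field$s == sv)[1]])) break
    if (all(abs(sv - picked) >= 1)) picked <- c(picked, sv)
  }
  tp_at <- function(sv) {
    pk <- sort(maxima$t[abs(maxima$s - sv) < 1e-9])
    if (length(pk) < 2) return(NA_real_)
    span <- pk[length(pk)] - pk[1]
    # a peak missed mid-train would inflate span/(count-1); infer the
    # number of periods covered from the median inter-peak interval
    n_eff <- max(1, round(span / stats::median(diff(pk))))
    span / n_eff
  }
  tps <- vapply(picked, tp_at, numeric(1))
  pk <- maxima$t[abs(maxima$s - s_ref) < 1e-9]
  per <- if (length(pk) >= 2) period_estimate(pk) else
    list(Tp = NA_real_, n_intervals = 0L, T_span = NA_real_)
  Tp_robust <- if (any(is.finite(tps))) stats::median(tps, na.rm = TRUE) else
    per$Tp
  tracks <- link_tracks(maxima, max_gap, max_jump, min_points)
  vps <- vapply(tracks, function(tr) tr$vp, numeric(1))
  # pooled velocity: all pulses of one organ travel at a common speed, so
  # a shared-slope fit (per-track intercepts) over every tracked point is
  # the low-variance per-organ estimate
  vp_pooled <- NA_real_
  if (length(tracks) > 0) {
    pt <- do.call(rbind, lapply(seq_along(tracks), function(k)
      cbind(tracks[[k]]$points[, c("t", "s")], trk = k)))
    if (stats::var(pt$s) > 1e-12 && length(unique(pt$t)) > 1) {
      X <- cbind(stats::model.matrix(~ factor(pt$trk) - 1), pt$s)
      slope <- stats::lm.fit(X, pt$t)$coefficients[ncol(X)]
      if (is.finite(slope) && abs(slope) > 1e-12) vp_pooled <- 1 / slope
    }
  }
  structure(list(Tp = Tp_robust, Tp_ref = per$Tp,
                 n_intervals = per$n_intervals,
                 T_span = per$T_span, tracks = tracks,
                 vp_median = if (length(vps)) stats::median(vps) else NA_real_,
                 vp_pooled = vp_pooled,
                 s_ref = s_ref, peak_times = sort(pk)),
            class = "oscillation_summary")
}

#' @export
print.oscillation_summary <- function(x, ...) {
  cat(sprintf("<oscillation_summary> Tp = %.3g h (%d intervals), vp median = %.3g mm/h, %d tracks\n",
              x$Tp, x$n_intervals, x$vp_median, length(x$tracks)))
  invisible(x)
}
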