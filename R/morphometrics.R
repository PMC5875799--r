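#' Effective length of the growth zone from a REGR kymograph
#'
#' The growth zone is the apical contiguous stretch where the
#' time-averaged REGR exceeds a threshold; the effective length is the
#' smaller of the growth-zone length and the organ's initial length
#' (if the organ is shorter than its growth zone, the whole organ curves).
#'
#' @param regr a [kinematic_field] with quantity `"regr"`.
#' @param regr_threshold absolute threshold (h^-1); if `NULL`, 20% of the
#'   peak time-averaged REGR is used.
#' @return list with `L_eff`, `L_gz`, `L0` (initial supported length, mm).
#' @export
effective_length <- function(regr, regr_threshold = NULL) {
  avg <- colMeans(ifelse(regr$mask, regr$values, NA), na.rm = TRUE)
  avg[is.nan(avg)] <- NA
  if (all(is.na(avg))) stop("REGR field has empty support")
  if (is.null(regr_threshold)) regr_threshold <- 0.2 * max(avg, na.rm = TRUE)
  above <- !is.na(avg) & avg > regr_threshold
  if (!any(above))
    stop("no position exceeds the REGR threshold; growth zone undefined")
  first_above <- which(above)[1]
  run_end <- first_above
  while (run_end < length(above) && above[run_end + 1]) run_end <- run_end + 1
  ds <- field_step(regr)
  L_gz <- regr$s[run_end] - regr$s[1] + ds  # apical contiguous extent
  m0 <- regr$mask[1, ]
  L0 <- if (any(m0)) max(regr$s[m0]) else max(regr$s)
  list(L_eff = min(L0, L_gz), L_gz = L_gz, L0 = L0)
}

#' Length of the curved zone at the end of the record
#'
#' Over the final time window in which the mean curvature-variation
#' magnitude has died down (|DC/Dt| below `eps_rate` on average), the
#' curved zone is the arc-length measure of the positions whose final
#' curvature magnitude exceeds `eps_curv`.
#'
#' @param curvature a [kinematic_field] with quantity `"curvature"`.
#' @param curvature_rate a [kinematic_field] with quantity
#'   `"curvature_rate"` on the same s grid.
#' @param eps_rate threshold on mean |DC/Dt| in the final window
#'   (mm^-1 h^-1); `NULL` uses 5% of the record's peak |DC/Dt|.
#' @param eps_curv threshold on |C| (mm^-1); `NULL` uses `exp(-1)` (about
#'   37%) of the peak final-profile magnitude.  For a curvature profile
#'   relaxing exponentially from the base -- the fixed-point shape of the
#'   graviception-proprioception balance -- this threshold makes the
#'   curved-zone length equal the profile's decay length, so the
#'   morphometric ratio `L_eff / L_c` estimates the dynamic balance
#'   number directly.
#' @param final_window length of the final window (h, default 2).
#' @param gz_length if non-`NULL`, measure the curved zone within the
#'   apical growth zone only (`s <= gz_length`).  In an elongating organ,
#'   tissue leaving the growth zone freezes with whatever curvature it
#'   carries, so the whole-organ curved extent keeps growing with time
#'   and no longer reflects the graviception-proprioception balance; the
#'   zone-restricted measure does.
#' @return list with `L_c` (mm), `eps_rate`, `eps_curv`.
#' @export
curved_zone_length <- function(curvature, curvature_rate, eps_rate = NULL,
                               eps_curv = NULL, final_window = 2,
                               gz_length = NULL) {
  if (length(curvature$s) != length(curvature_rate$s) ||
      max(abs(curvature$s - curvature_rate$s)) > 1e-9)
    stop("fields are on different s grids")
  t_end <- max(curvature_rate$t)
  late <- curvature_rate$t >= t_end - final_window
  late_vals <- abs(curvature_rate$values[late, , drop = FALSE])
  late_mask <- curvature_rate$mask[late, , drop = FALSE]
  if (is.null(eps_rate)) {
    peak <- max(abs(curvature_rate$values), na.rm = TRUE)
    eps_rate <- 0.05 * peak
    # below the growth zone DC/Dt is structurally zero (frozen tissue),
    # so its late-window magnitude estimates the measurement-noise floor;
    # a quiescence threshold cannot be meaningful below that floor
    if (!is.null(gz_length)) {
      below <- late_mask &
        matrix(curvature_rate$s > gz_length, nrow(late_vals),
               ncol(late_vals), byrow = TRUE)
      if (sum(below) >= 20)
        eps_rate <- max(eps_rate, 1.3 * mean(late_vals[below]))
    }
  }
  if (!any(late_mask)) stop("curvature-rate field has no support in the final window")
  if (mean(late_vals[late_mask]) >= eps_rate)
    stop(sprintf(paste0("curvature is still varying at the end of the record ",
                        "(mean |DC/Dt| = %.3g >= eps_rate = %.3g); ",
                        "the curved-zone length is undefined"),
                 mean(late_vals[late_mask]), eps_rate))
  i_end <- nrow(curvature$values)
  prof <- abs(curvature$values[i_end, ])
  m <- curvature$mask[i_end, ] & !is.na(prof)
  if (!is.null(gz_length)) m <- m & curvature$s <= gz_length
  if (!any(m) || max(prof[m]) <= 0)
    stop("final curvature profile is identically zero; organ is straight")
  if (is.null(eps_curv)) eps_curv <- exp(-1) * max(prof[m])
  curved <- m & prof > eps_curv
  if (!any(curved))
    stop("final curvature profile is below eps_curv everywhere; organ is straight")
  L_c <- sum(curved) * field_step(curvature)
  list(L_c = L_c, eps_rate = eps_rate, eps_curv = eps_curv)
}

#' Morphometric overshoot classification of one plant
#'
#' Computes the morphometric balance number `B = L_eff / L_c` from the
#' plant's kymographs, predicts an overshoot when `B` exceeds the critical
#' threshold, and reads the observed overshoot off the measured tip-angle
#' series.  For plants of the upright (straight) treatment the balance
#' number is a gravitropic quantity and is refused (`B = NA`); the
#' observed flag is still reported.
#'
#' @param kin list with elements `regr`, `curvature`, `curvature_rate`
#'   ([kinematic_field]s on a shared s grid) and `tip_angle` (numeric
#'   vector or data.frame with column `angle`).
#' @param group `"tilted"` or `"straight"`.
#' @param B_threshold critical balance number (default 2.8).
#' @param delta overshoot dead band (rad), see [overshoot_predicate()].
#' @param regr_threshold,eps_rate,eps_curv,final_window passed to
#'   [effective_length()] and [curved_zone_length()].
#' @return A `morphometric_result`: list with `L_eff`, `L_c`, `B`,
#'   `A_max_tip` (rad), `predicted_overshoot`, `observed_overshoot`,
#'   `group`.
#' @export
classify_plant <- function(kin, group = c("tilted", "straight"),
                           B_threshold = 2.8, delta = 0.02,
                           regr_threshold = NULL, eps_rate = NULL,
                           eps_curv = NULL, final_window = 2) {
  group <- match.arg(group)
  tip <- kin$tip_angle
  if (is.data.frame(tip)) tip <- tip$angle
  observed <- overshoot_predicate(tip, delta)
  A_max_tip <- max(tip)
  if (group == "straight") {
    return(structure(list(L_eff = NA_real_, L_c = NA_real_, B = NA_real_,
                          A_max_tip = A_max_tip,
                          predicted_overshoot = NA,
                          observed_overshoot = observed, group = group),
                     class = "morphometric_result"))
  }
  eff <- effective_length(kin$regr, regr_threshold)
  cz <- curved_zone_length(kin$curvature, kin$curvature_rate,
                           eps_rate, eps_curv, final_window,
                           gz_length = eff$L_gz)
  B <- eff$L_eff / cz$L_c
  structure(list(L_eff = eff$L_eff, L_c = cz$L_c, B = B,
                 A_max_tip = A_max_tip,
                 predicted_overshoot = B > B_threshold,
                 observed_overshoot = observed, group = group),
            class = "morphometric_result")
}

#' @export
print.morphometric_result <- function(x, ...) {
  cat(sprintf("<morphometric_result> group %s: B = %.3g (L_eff %.3g / L_c %.3g)\n",
              x$group, x$B, x$L_eff, x$L_c))
  cat(sprintf("  predicted overshoot: %s; observed: %s; max tip angle %.3g rad\n",
              x$predicted_overshoot, x$observed_overshoot, x$A_max_tip))
  invisible(x)
}
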