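#' Full kinematic analysis of one plant
#'
#' From a midline series and marker profiles to the four kymographs and
#' their summaries: orientation A(s,t); curvature C(s,t) (arc-length
#' derivative of the smoothed orientation); REGR by 1-D image correlation
#' of the marker profiles; the material curvature derivative DC/Dt; the
#' oscillation characteristics of the REGR and DC/Dt kymographs; the
#' growth-curvature coupling correlation; temporal averages split at
#' `t_split`; and (for tilted plants) the morphometric balance number and
#' overshoot classification.
#'
#' @param midline a [midline_series].
#' @param markers a [marker_profile_series] along the same organ.
#' @param group `"tilted"` or `"straight"`.
#' @param config a `run_config`, see [default_config()].
#' @return A list of class `plant_kinematics` with elements
#'   `orientation`, `curvature`, `regr`, `curvature_rate` (fields),
#'   `tip_angle`, `osc_regr`, `osc_curvrate`, `coupling_r`,
#'   `avg_regr`, `avg_curvrate`, `morpho`, `summary` (one-row
#'   data.frame of scalar summaries).
#' @export
analyze_plant <- function(midline, markers, group = c("tilted", "straight"),
                          config = default_config()) {
  group <- match.arg(group)
  orient <- orientation_profile(midline, step = config$s_step)
  orient_s <- smooth_field(orient, config$smooth_s_window,
                           config$smooth_t_frames)
  curv <- curvature_profile(orient_s)
  regr_raw <- regr_from_markers(markers, window = config$dic_window,
                                search = config$dic_search,
                                overlap = config$dic_overlap,
                                deriv_window = config$regr_deriv_window,
                                frame_step = config$dic_frame_step)
  regr <- smooth_field(regrid_field(regr_raw, curv), s_window = 0,
                       t_window = config$smooth_t_frames)
  dcdt <- material_curvature_derivative(curv, regr,
                                        t_deriv_frames = config$dcdt_t_frames)
  regr_m <- subset_times(regr, dcdt$t)
  # coupling between the two oscillation kymographs, over the growth zone
  # (below it the REGR is structurally zero and would only dilute r)
  gz <- tryCatch(effective_length(regr)$L_gz, error = function(e) NULL)
  r <- tryCatch(kymograph_correlation(regr_m, dcdt, gz_length = gz)$r,
                error = function(e) NA_real_)
  tip <- data.frame(t = orient$t, angle = orient_s$values[, 1])
  osc_args <- function(f) characterize_oscillations(
    f, threshold_quantile = config$peak_quantile,
    max_gap = config$max_gap, max_jump = config$max_jump,
    min_points = config$min_track_points,
    s_min = config$osc_edge_margin,
    s_max = if (is.null(gz)) Inf else gz)
  osc_regr <- tryCatch(osc_args(regr), error = function(e) NULL)
  osc_curv <- tryCatch(osc_args(dcdt), error = function(e) NULL)
  avg_regr <- temporal_field_average(regr, config$t_split)
  avg_dcdt <- temporal_field_average(dcdt, config$t_split)
  kin <- list(regr = regr, curvature = curv, curvature_rate = dcdt,
              tip_angle = tip)
  morpho <- tryCatch(
    classify_plant(kin, group, B_threshold = config$B_threshold,
                   delta = config$overshoot_delta,
                   regr_threshold = na_null(config$regr_threshold),
                   eps_rate = na_null(config$eps_rate),
                   eps_curv = na_null(config$eps_curv),
                   final_window = config$final_window),
    error = function(e) NULL)
  summary <- data.frame(
    group = group,
    Tp_regr = osc_or_na(osc_regr, "Tp"),
    vp_regr = osc_or_na(osc_regr, "vp_pooled"),
    Tp_curvrate = osc_or_na(osc_curv, "Tp"),
    vp_curvrate = osc_or_na(osc_curv, "vp_pooled"),
    mean_regr = avg_regr$overall,
    mean_regr_early = avg_regr$early,
    mean_regr_late = avg_regr$late,
    mean_curvrate = avg_dcdt$overall,
    mean_curvrate_early = avg_dcdt$early,
    mean_curvrate_late = avg_dcdt$late,
    coupling_r = r,
    B = if (is.null(morpho)) NA_real_ else morpho$B,
    A_max_tip = max(tip$angle),
    predicted_overshoot = if (is.null(morpho)) NA else
      morpho$predicted_overshoot,
    observed_overshoot = overshoot_predicate(tip$angle,
                                             config$overshoot_delta),
    stringsAsFactors = FALSE)
  structure(list(orientation = orient_s, curvature = curv, regr = regr,
                 curvature_rate = dcdt, tip_angle = tip,
                 osc_regr = osc_regr, osc_curvrate = osc_curv,
                 coupling_r = r, avg_regr = avg_regr,
                 avg_curvrate = avg_dcdt, morpho = morpho,
                 summary = summary),
            class = "plant_kinematics")
}

na_null <- function(x) if (length(x) != 1 || is.na(x)) NULL else x
osc_or_na <- function(o, what) if (is.null(o)) NA_real_ else o[[what]]

# Interpolate a field onto the s grid of a reference field (per time row,
# linear, nearest-value extension inside the organ).
regrid_field <- function(field, ref) {
  out <- matrix(NA_real_, length(field$t), length(ref$s))
  for (i in seq_along(field$t)) {
    ok <- field$mask[i, ]
    if (sum(ok) < 2) next
    rng <- range(field$s[ok])
    y <- stats::approx(field$s[ok], field$values[i, ok], xout = ref$s,
                       rule = 2)$y
    # nearest-value extension only up to half a source step beyond support
    pad <- (field$s[2] - field$s[1])
    y[ref$s < rng[1] - pad | ref$s > rng[2] + pad] <- NA
    out[i, ] <- y
  }
  # clip to the reference organ support at the nearest reference frame
  t_idx <- vapply(field$t, function(tt) which.min(abs(ref$t - tt)), 1L)
  for (k in seq_along(field$t)) out[k, !ref$mask[t_idx[k], ]] <- NA
  kinematic_field(ref$s, field$t, out, quantity = field$quantity,
                  units = field$units)
}

subset_times <- function(field, t_sub) {
  idx <- match_times(t_sub, field$t)
  kinematic_field(field$s, field$t[idx],
                  field$values[idx, , drop = FALSE],
                  field$mask[idx, , drop = FALSE],
                  field$quantity, field$units)
}

#' Run the full pipeline over a generated or recorded dataset
#'
#' Reads the cohort manifest, analyses every plant, writes per-plant
#' kymographs and a JSON summary, then the cohort comparison table.  A
#' failing plant is recorded and skipped; the remaining plants complete.
#'
#' @param dataset_dir directory with `manifest.csv` and `plant_*/`
#'   subdirectories (`midline.csv`, `markers.csv`).
#' @param out_dir results directory (created).
#' @param config a `run_config`.
#' @return Invisibly, a list with `summaries` (per-plant data.frame),
#'   `comparisons` (cohort table or `NULL`), `failures` (named character
#'   vector of error messages) and `files` (manifest of written files).
#' @export
run_pipeline <- function(dataset_dir, out_dir, config = default_config()) {
  manifest <- utils::read.csv(file.path(dataset_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", file = log_path,
                                append = TRUE, sep = "")
  cat("pipeline configuration:\n", file = log_path)
  for (k in names(config))
    log_line("  %s = %s", k, paste(format(config[[k]]), collapse = ","))
  summaries <- list(); failures <- character(0); files <- character(0)
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$plant_id[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      ml <- read_midline_csv(file.path(dataset_dir, pid, "midline.csv"))
      mp <- read_markers_csv(file.path(dataset_dir, pid, "markers.csv"))
      analyze_plant(ml, mp, group = manifest$group[i], config = config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[pid] <- conditionMessage(res)
      log_line("plant %s FAILED: %s", pid, conditionMessage(res))
      next
    }
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    for (f in c("orientation", "curvature", "regr", "curvature_rate")) {
      fp <- file.path(pdir, paste0(f, ".csv"))
      write_kymograph(res[[f]], fp)
      files <- c(files, fp, sidecar_path(fp))
    }
    sj <- file.path(pdir, "summary.json")
    jsonlite::write_json(c(list(plant_id = pid), as.list(res$summary)),
                         sj, auto_unbox = TRUE, digits = NA)
    files <- c(files, sj)
    summaries[[pid]] <- cbind(plant_id = pid, res$summary)
    log_line("plant %s ok (%.1f s)", pid,
             proc.time()[["elapsed"]] - t0)
  }
  summary_df <- if (length(summaries)) do.call(rbind, summaries) else NULL
  comparisons <- NULL
  if (!is.null(summary_df) && length(unique(summary_df$group)) == 2 &&
      min(table(summary_df$group)) >= 2) {
    comparisons <- suppressWarnings(cohort_compare(summary_df))
    cp <- file.path(out_dir, "comparisons.csv")
    utils::write.csv(comparisons, cp, row.names = FALSE)
    files <- c(files, cp)
  }
  if (!is.null(summary_df)) {
    sp <- file.path(out_dir, "summaries.csv")
    utils::write.csv(summary_df, sp, row.names = FALSE)
    files <- c(files, sp)
  }
  writeLines(files, file.path(out_dir, "produced_files.txt"))
  invisible(list(summaries = summary_df, comparisons = comparisons,
                 failures = failures, files = files))
}

#' Plot a kymograph to a raster image
#'
#' Colour map of the field over time (x, hours) and arc length (y, mm,
#' apex at 0); masked cells are blank.
#'
#' @param field a [kinematic_field].
#' @param out_image output PNG path.
#' @param width,height image size in pixels.
#' @return `out_image`, invisibly.
#' @export
plot_kymograph <- function(field, out_image, width = 900, height = 500) {
  if (!any(field$mask)) stop("field has empty support")
  grDevices::png(out_image, width = width, height = height)
  on.exit(grDevices::dev.off())
  v <- field$values
  graphics::image(x = field$t, y = field$s, z = v,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time t (h)", ylab = "arc length s (mm)",
                  main = sprintf("%s [%s]", field$quantity, field$units),
                  useRaster = TRUE)
  invisible(out_image)
}
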