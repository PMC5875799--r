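#' Write a midline series to delimited text
#'
#' One row per point with columns `frame_index`, `time_h`, `x_mm`,
#' `y_mm`; points are ordered apex first within each frame.
#'
#' @param ml a [midline_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_midline_csv <- function(ml, path) {
  rows <- lapply(seq_along(ml$times), function(i) {
    p <- ml$points[[i]]
    data.frame(frame_index = i, time_h = ml$times[i],
               x_mm = p[, 1], y_mm = p[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a midline series written by [write_midline_csv()]
#'
#' Validates the expected columns and the apex-first ordering: across
#' frames the apex (first point) of a growing, moving organ displaces more
#' than the anchored base (last point); a file whose points run base-first
#' is rejected.
#'
#' @param path input path.
#' @param check_apex_first disable the ordering heuristic if the organ is
#'   known to be static.
#' @return A [midline_series].
#' @export
read_midline_csv <- function(path, check_apex_first = TRUE) {
  tab <- utils::read.csv(path)
  need <- c("frame_index", "time_h", "x_mm", "y_mm")
  if (!all(need %in% names(tab)))
    stop("midline file must have columns ", paste(need, collapse = ", "))
  idx <- sort(unique(tab$frame_index))
  pts <- lapply(idx, function(i) {
    fr <- tab[tab$frame_index == i, ]
    as.matrix(fr[, c("x_mm", "y_mm")])
  })
  times <- vapply(idx, function(i)
    tab$time_h[tab$frame_index == i][1], numeric(1))
  if (check_apex_first && length(idx) > 2) {
    firsts <- t(vapply(pts, function(p) p[1, ], numeric(2)))
    lasts <- t(vapply(pts, function(p) p[nrow(p), ], numeric(2)))
    disp <- function(m) sum(apply(m, 2, function(v) stats::sd(v)))
    if (disp(firsts) < 0.5 * disp(lasts))
      stop("midline points appear to be ordered base-first; ",
           "apex-first ordering is required")
  }
  midline_series(times, pts)
}

#' Write marker intensity profiles to delimited text
#'
#' Columns `frame_index`, `s_mm`, `intensity`.
#'
#' @param mp a [marker_profile_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_markers_csv <- function(mp, path) {
  rows <- lapply(seq_along(mp$times), function(i)
    data.frame(frame_index = i, time_h = mp$times[i],
               s_mm = mp$s[[i]], intensity = mp$intensity[[i]]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read marker profiles written by [write_markers_csv()]
#' @param path input path.
#' @return A [marker_profile_series].
#' @export
read_markers_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("frame_index", "s_mm", "intensity")
  if (!all(need %in% names(tab)))
    stop("marker file must have columns ", paste(need, collapse = ", "))
  idx <- sort(unique(tab$frame_index))
  times <- if ("time_h" %in% names(tab))
    vapply(idx, function(i) tab$time_h[tab$frame_index == i][1], numeric(1))
  else as.numeric(idx)
  marker_profile_series(
    times,
    lapply(idx, function(i) tab$s_mm[tab$frame_index == i]),
    lapply(idx, function(i) tab$intensity[tab$frame_index == i]))
}

#' Default analysis configuration
#'
#' All tunable parameters of the kinematics pipeline in one list: grid and
#' smoothing settings, image-correlation (DIC) settings, oscillation
#' detection and linking, morphometric thresholds and the early/late split
#' time.  Units: mm, h, rad.
#'
#' @return A named list of class `run_config` (schema version 1).
#' @export
default_config <- function() {
  structure(list(
    schema_version = 1L,
    s_step = 0.25,            # analysis arc-length grid (mm)
    smooth_s_window = 1.5,    # orientation smoothing along s (mm)
    smooth_t_frames = 3,      # smoothing along t (frames)
    dic_window = 2,           # correlation window (mm)
    dic_search = 1,           # displacement search range (mm)
    dic_overlap = 0.75,       # window overlap fraction
    dic_frame_step = 2,       # frames between correlated pairs
    dcdt_t_frames = 5,        # time-derivative filter window (frames)
    regr_deriv_window = 3,    # strain-rate derivative baseline (mm)
    peak_quantile = 0.7,      # oscillation maxima threshold quantile
    max_gap = 0.75,           # track linking gap (h)
    max_jump = 8,             # track linking jump (mm)
    min_track_points = 3,
    osc_edge_margin = 2,      # apical margin excluded from pulse tracking (mm)
    t_split = 12,             # early/late split (h)
    B_threshold = 2.8,        # predicted-overshoot threshold
    overshoot_delta = 0.02,   # tip dead band (rad)
    regr_threshold = NA,      # absolute growth-zone threshold (h^-1)
    eps_rate = NA,            # curved-zone rate threshold (mm^-1 h^-1)
    eps_curv = NA,            # curved-zone curvature threshold (mm^-1)
    final_window = 2          # quiescent final window (h)
  ), class = "run_config")
}

#' Write / read a run configuration (JSON)
#'
#' The configuration round-trips through serialization unchanged; files
#' containing keys unknown to this schema are rejected.
#'
#' @param config a `run_config` list.
#' @param path file path.
#' @return `write_config`: `path` invisibly; `read_config`: the
#'   configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- default_config()
  unknown <- setdiff(names(raw), names(ref))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  out <- ref
  for (k in names(raw)) out[[k]] <- resolve_null(raw[[k]], ref[[k]])
  structure(out, class = "run_config")
}

resolve_null <- function(x, ref) {
  if (is.null(x)) return(NA)
  if (is.integer(ref)) return(as.integer(x))
  x
}
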