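#' Spatiotemporal kinematic fields (kymographs)
#'
#' A `kinematic_field` stores one scalar kinematic quantity of a growing
#' organ on a regular arc-length x time grid, together with a support mask
#' marking the cells that lie inside the organ (`s <= L(t)`).  Arc length is
#' measured **from the apex** (`s = 0` at the tip), times are in hours and
#' lengths in millimetres throughout the package.
#'
#' @param s numeric vector of arc-length grid positions (mm), strictly
#'   increasing and uniformly spaced.
#' @param t numeric vector of frame times (h), strictly increasing.
#' @param values numeric matrix, `length(t)` rows by `length(s)` columns
#'   (time-major storage).  Cells outside the support are set to `NA`.
#' @param mask logical matrix of the same shape; `TRUE` where the cell is
#'   inside the organ.  Defaults to the non-`NA` cells of `values`.
#' @param quantity one of `"orientation"` (rad), `"curvature"` (mm^-1),
#'   `"regr"` (h^-1), `"curvature_rate"` (mm^-1 h^-1), or another
#'   descriptive string.
#' @param units unit string; filled automatically for the standard
#'   quantities.
#'
#' @return An object of class `kinematic_field` with elements `s`, `t`,
#'   `values`, `mask`, `quantity`, `units`.
#' @export
kinematic_field <- function(s, t, values, mask = NULL,
                            quantity = "field", units = NULL) {
  s <- as.numeric(s); t <- as.numeric(t)
  values <- as.matrix(values)
  if (length(s) > 1 && any(diff(s) <= 0))
    stop("s grid must be strictly increasing")
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("t grid must be strictly increasing")
  if (nrow(values) != length(t) || ncol(values) != length(s))
    stop("values must be a length(t) x length(s) matrix")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- matrix(as.logical(mask), nrow(values), ncol(values))
  values[!mask] <- NA_real_
  if (is.null(units)) {
    units <- switch(quantity,
      orientation    = "rad",
      curvature      = "mm^-1",
      regr           = "h^-1",
      curvature_rate = "mm^-1 h^-1",
      "")
  }
  structure(list(s = s, t = t, values = values, mask = mask,
                 quantity = quantity, units = units),
            class = "kinematic_field")
}

#' @export
print.kinematic_field <- function(x, ...) {
  cat(sprintf("<kinematic_field> %s [%s]\n", x$quantity, x$units))
  cat(sprintf("  s: %d points, %.3g..%.3g mm (step %.3g)\n",
              length(x$s), min(x$s), max(x$s),
              if (length(x$s) > 1) x$s[2] - x$s[1] else NA))
  cat(sprintf("  t: %d frames, %.3g..%.3g h\n",
              length(x$t), min(x$t), max(x$t)))
  cat(sprintf("  support: %d / %d cells\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
dim.kinematic_field <- function(x) dim(x$values)

field_step <- function(field) {
  if (length(field$s) < 2) stop("field needs at least 2 s samples")
  field$s[2] - field$s[1]
}

stopifnot_same_grid <- function(a, b) {
  if (length(a$s) != length(b$s) || max(abs(a$s - b$s)) > 1e-9)
    stop("fields are on different s grids")
  if (length(a$t) != length(b$t) || max(abs(a$t - b$t)) > 1e-9)
    stop("fields are on different t grids")
  invisible(TRUE)
}

#' Temporal average of a kinematic field's magnitude
#'
#' Averages `|values|` over all supported cells, optionally split at a time
#' `t_split` into an early and a late phase (as used to contrast the first
#' hours after a gravitropic perturbation against the later quasi-steady
#' regime; 12 h is the conventional split for a 24 h record).
#'
#' @param field a [kinematic_field].
#' @param t_split split time in hours, or `NULL` for a single overall mean.
#' @return If `t_split` is `NULL`, a single number.  Otherwise a named list
#'   with `overall`, `early` (t <= t_split) and `late` (t > t_split).
#' @export
temporal_field_average <- function(field, t_split = NULL) {
  v <- abs(field$values)
  if (!any(field$mask)) stop("field has empty support")
  if (is.null(t_split)) return(mean(v[field$mask]))
  early <- field$t <= t_split
  m_early <- field$mask & matrix(early, nrow(v), ncol(v))
  m_late  <- field$mask & matrix(!early, nrow(v), ncol(v))
  list(overall = mean(v[field$mask]),
       early = if (any(m_early)) mean(v[m_early]) else NA_real_,
       late  = if (any(m_late))  mean(v[m_late])  else NA_real_)
}

# Savitzky-Golay smoothing of one series; shrinks the window on short
# segments and falls through untouched when fewer than 5 samples.
sgolay_smooth_vec <- function(x, window_pts) {
  n <- length(x)
  w <- min(window_pts, if (n %% 2 == 1) n else n - 1)
  if (w %% 2 == 0) w <- w - 1
  if (w < 5 || n < 5) return(x)
  as.numeric(signal::sgolayfilt(x, p = 2, n = w))
}

#' Smooth a kinematic field with a local quadratic (Savitzky-Golay) filter
#'
#' Smoothing is applied along arc length within each frame and then along
#' time within each arc-length column, restricted to contiguous supported
#' runs so that values never bleed across the organ boundary.
#'
#' @param field a [kinematic_field].
#' @param s_window window length along s in mm (default 1.5 mm).
#' @param t_window window length in frames (default 3).
#' @return A smoothed [kinematic_field] with the same grid and mask.
#' @export
smooth_field <- function(field, s_window = 1.5, t_window = 3) {
  v <- field$values
  if (s_window > 0 && length(field$s) > 4) {
    wpts <- max(5, 2 * floor(s_window / field_step(field) / 2) + 1)
    for (i in seq_len(nrow(v)))
      v[i, ] <- smooth_masked_run(v[i, ], field$mask[i, ], wpts)
  }
  if (t_window >= 3 && length(field$t) > 4) {
    wt <- if (t_window %% 2 == 1) t_window else t_window + 1
    for (j in seq_len(ncol(v)))
      v[, j] <- smooth_masked_run(v[, j], field$mask[, j], wt)
  }
  kinematic_field(field$s, field$t, v, field$mask, field$quantity, field$units)
}

smooth_masked_run <- function(x, mask, wpts) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    x[idx] <- sgolay_smooth_vec(x[idx], wpts)
  }
  x
}

# Local-quadratic (Savitzky-Golay) first derivative along each contiguous
# supported run; falls back to finite differences on runs shorter than the
# filter window.
masked_sg_deriv <- function(x, mask, h, wpts) {
  out <- rep(NA_real_, length(x))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    n <- length(idx)
    if (n < 2) next
    if (n < wpts) {
      out[idx] <- masked_gradient(x[idx], rep(TRUE, n), h)
    } else {
      out[idx] <- as.numeric(
        signal::sgolayfilt(x[idx], p = 2, n = wpts, m = 1, ts = h))
    }
  }
  out
}

# Centered first differences with one-sided stencils at the edges of each
# contiguous supported run; NA outside support or for runs shorter than 2.
masked_gradient <- function(x, mask, h) {
  out <- rep(NA_real_, length(x))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    n <- i1 - i0 + 1
    if (n < 2) next
    seg <- x[i0:i1]
    g <- numeric(n)
    if (n == 2) {
      g[] <- (seg[2] - seg[1]) / h
    } else {
      # second-order one-sided stencils at run edges
      g[1] <- (-3 * seg[1] + 4 * seg[2] - seg[3]) / (2 * h)
      g[n] <- (3 * seg[n] - 4 * seg[n - 1] + seg[n - 2]) / (2 * h)
      g[2:(n - 1)] <- (seg[3:n] - seg[1:(n - 2)]) / (2 * h)
    }
    out[i0:i1] <- g
  }
  out
}

# Interpolate a field's row values at arbitrary s positions (NA outside).
field_interp_row <- function(field, row, s_out) {
  ok <- field$mask[row, ]
  if (sum(ok) < 2) return(rep(NA_real_, length(s_out)))
  stats::approx(field$s[ok], field$values[row, ok], xout = s_out,
                rule = 1)$y
}

#' Write a kymograph to delimited text with a JSON sidecar
#'
#' The matrix file has the s grid as its header row and the t grid as its
#' first column; the sidecar records quantity, units and the support mask as
#' per-row run lengths so the mask survives the round trip exactly.
#'
#' @param field a [kinematic_field].
#' @param path output path for the matrix (the sidecar gets `.json`
#'   appended to `path` without its extension).
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(field, path) {
  m <- field$values
  tab <- cbind(t_h = field$t, m)
  colnames(tab) <- c("t_h", formatC(field$s, format = "g", digits = 12))
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  mask_rle <- apply(field$mask, 1, function(r) {
    x <- rle(r); list(lengths = x$lengths, values = x$values)
  })
  sidecar <- list(quantity = field$quantity, units = field$units,
                  s_mm = field$s, t_h = field$t, mask_rle = mask_rle)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[^.]*$", "", path), ".json")

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path path to the matrix file.
#' @return A [kinematic_field].
#' @export
read_kymograph <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  t <- tab[[1]]
  s <- as.numeric(colnames(tab)[-1])
  values <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(values) <- NULL
  side <- sidecar_path(path)
  quantity <- "field"; units <- NULL; mask <- NULL
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side)
    quantity <- sc$quantity; units <- sc$units
    if (!is.null(sc$mask_rle)) {
      mask <- t(vapply(seq_along(t), function(i) {
        r <- sc$mask_rle[[i]]
        inverse.rle(list(lengths = as.integer(unlist(r$lengths)),
                         values = as.logical(unlist(r$values))))
      }, logical(length(s))))
    }
  }
  kinematic_field(s, t, values, mask, quantity, units)
}
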