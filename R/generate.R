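#' Configuration of the synthetic coleoptile generator
#'
#' Bundles everything needed to produce one ground-truthed synthetic
#' plant: the posture-model parameters, the propagating pulse waves
#' superposed on elongation and on differential growth, the phase relation
#' between the two, marker rendering and observation noise.
#'
#' Defaults emulate the experimental conditions of a darkroom tilting
#' assay on wheat coleoptiles: 15-minute frame cadence over 24 h, initial
#' length 10-20 mm with an apical growth zone, baseline REGR 0.036 h^-1
#' (about 1e-5 s^-1), pulses with periods near 3 h travelling apex to base
#' at 8-17 mm/h, and sub-pixel midline digitization noise.
#'
#' @param ac an [ac_params]; must have `regr0 > 0` so the organ elongates.
#' @param regr_wave a [wave_params] for the relative REGR modulation
#'   (`amplitude` in `[0, 1)`).
#' @param diff_growth_wave a [wave_params] for the differential-growth
#'   fraction driving curvature-rate pulses.
#' @param delta_phase phase (rad) of the differential-growth wave relative
#'   to the REGR wave; `pi` yields anti-phase pulses and a negative
#'   correlation between the two kymographs.
#' @param radius_R organ radius (mm) converting differential growth into
#'   curvature production (`DC/Dt = REGR * Delta / R`).
#' @param zone_taper width (mm) of the smooth logistic decay of the REGR
#'   profile at the basal end of the growth zone.
#' @param marker_density fluorescent markers per mm.
#' @param marker_sigma Gaussian footprint of a rendered marker (mm).
#' @param marker_step sampling step of the emitted intensity profiles (mm).
#' @param noise_sd_xy sd of additive coordinate noise on midline points
#'   (mm); emulates sub-pixel digitization error.
#' @param noise_sd_intensity sd of additive intensity noise (profile units).
#' @param frame_interval frame cadence (h).
#' @param seed integer seed; a fixed seed reproduces the dataset exactly.
#' @return A list of class `gen_config`.
#' @export
gen_config <- function(ac = ac_params(beta = 0.2, gamma = 1, L0 = 15,
                                      Lgz = 12, regr0 = 0.036,
                                      tilt = pi / 2, duration = 24,
                                      dt = 0.01, ds = 0.1),
                       regr_wave = wave_params(Tp = 3, vp = 12,
                                               amplitude = 0.4),
                       diff_growth_wave = wave_params(Tp = 3, vp = 12,
                                                      amplitude = 0.4),
                       delta_phase = pi, radius_R = 0.5,
                       zone_taper = 0.75,
                       marker_density = 8, marker_sigma = 0.15,
                       marker_step = 0.05, noise_sd_xy = 0.001,
                       noise_sd_intensity = 0.01,
                       frame_interval = 0.25, seed = 1L) {
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (marker_density <= 0) stop("marker_density must be positive")
  if (regr_wave$amplitude < 0 || regr_wave$amplitude >= 1)
    stop("relative REGR amplitude must lie in [0, 1)")
  ac$record_interval <- frame_interval
  structure(list(ac = ac, regr_wave = regr_wave,
                 diff_growth_wave = diff_growth_wave,
                 delta_phase = delta_phase, radius_R = radius_R,
                 zone_taper = zone_taper,
                 marker_density = marker_density,
                 marker_sigma = marker_sigma, marker_step = marker_step,
                 noise_sd_xy = noise_sd_xy,
                 noise_sd_intensity = noise_sd_intensity,
                 frame_interval = frame_interval,
                 seed = as.integer(seed)),
            class = "gen_config")
}

#' Generate one synthetic coleoptile with ground truth
#'
#' Runs the posture model with growth and superposed propagating pulses:
#' the REGR field is `regr0 * (1 + a * wave)` clipped at zero inside the
#' growth zone, and curvature production receives the extra term
#' `REGR * Delta / R` with the differential-growth wave `Delta` shifted by
#' `delta_phase` relative to the REGR wave.  Midlines are integrated from
#' the clamped base each frame, markers are advected materially and
#' rendered as Gaussian bumps, and coordinate/intensity noise is added.
#' All randomness derives from `config$seed`.
#'
#' @param config a [gen_config].
#' @return A list with elements `midline` (a noisy [midline_series]),
#'   `markers` (a [marker_profile_series]) and `truth` (noise-free ground
#'   truth: the simulated `ac_state` including the true REGR and DC/Dt
#'   kymographs, the wave parameters, balance number, overshoot flag and
#'   noise-free midlines).
#' @export
generate_coleoptile_series <- function(config) {
  if (config$ac$regr0 <= 0)
    stop("generator requires an elongating organ (regr0 > 0)")
  if (config$regr_wave$amplitude >= 1)
    stop("relative REGR amplitude >= 1 would clip the REGR field to zero")
  set.seed(config$seed)
  rw <- config$regr_wave
  dw <- config$diff_growth_wave
  dphase <- config$delta_phase
  regr0 <- config$ac$regr0
  R <- config$radius_R
  Lgz <- config$ac$Lgz
  taper_w <- config$zone_taper
  forcing <- function(s_apex, t, L) {
    # smooth basal decay of the growth zone (real REGR profiles fall off
    # gradually toward the base rather than stepping to zero)
    taper <- stats::plogis((Lgz - s_apex) / taper_w)
    e <- regr0 * (1 + rw$amplitude * wave_value(rw, s_apex, t)) * taper
    e <- pmax(e, 0)
    delta <- dw$amplitude *
      wave_value(wave_params(dw$Tp, dw$vp, phase = rw$phase + dphase),
                 s_apex, t)
    list(regr = e, curv_force = e * delta / R)
  }
  state <- simulate_ac(config$ac, forcing = forcing,
                       forcing_amp_bound = rw$amplitude)
  clean_ml <- ac_state_midlines(state)
  noisy_pts <- lapply(clean_ml$points, function(p)
    p + cbind(correlated_noise(nrow(p), config$noise_sd_xy),
              correlated_noise(nrow(p), config$noise_sd_xy)))
  noisy_ml <- midline_series(clean_ml$times, noisy_pts, validate = FALSE)
  markers <- render_markers(state, config)
  truth <- list(state = state,
                regr_wave = rw, diff_growth_wave = dw,
                delta_phase = dphase,
                Tp = rw$Tp, vp = rw$vp,
                balance_number = state$balance_number,
                overshoot = state$overshoot,
                midline = clean_ml)
  list(midline = noisy_ml, markers = markers, truth = truth)
}

# Noise-free midlines (apex-first) from the recorded base-frame angles.
ac_state_midlines <- function(state) {
  vb <- state$velocity_base
  sigma <- vb$sigma
  pts <- vector("list", length(vb$t))
  orient <- state$orientation
  for (i in seq_along(vb$t)) {
    L <- vb$length[i]
    ok <- orient$mask[i, ]
    s_sup <- orient$s[ok]
    A_apex <- orient$values[i, ok]
    # integrate positions from the base (sigma = L - s)
    ord <- order(L - s_sup)
    sig <- (L - s_sup)[ord]
    A <- A_apex[ord]
    x <- pracma::cumtrapz(sig, sin(A))[, 1]
    y <- pracma::cumtrapz(sig, cos(A))[, 1]
    pts[[i]] <- cbind(rev(x), rev(y))   # apex first
  }
  midline_series(vb$t, pts, validate = FALSE)
}

# Material marker advection and Gaussian rendering into intensity profiles.
render_markers <- function(state, config) {
  vb <- state$velocity_base
  L0 <- vb$length[1]
  n_mark <- max(10L, round(config$marker_density * L0))
  pos <- sort(stats::runif(n_mark, 0, L0))          # base-frame positions
  amp <- stats::runif(n_mark, 0.5, 1)
  times <- vb$t
  s_list <- vector("list", length(times))
  i_list <- vector("list", length(times))
  sig2 <- 2 * config$marker_sigma^2
  for (i in seq_along(times)) {
    L <- vb$length[i]
    s_apex <- L - pos
    grid <- seq(0, L, by = config$marker_step)
    prof <- numeric(length(grid))
    for (j in seq_along(pos)) {
      d2 <- (grid - s_apex[j])^2
      near <- d2 < 9 * sig2
      if (any(near))
        prof[near] <- prof[near] + amp[j] * exp(-d2[near] / sig2)
    }
    if (config$noise_sd_intensity > 0)
      prof <- pmax(0, prof + stats::rnorm(length(prof), 0,
                                          config$noise_sd_intensity))
    s_list[[i]] <- grid
    i_list[[i]] <- prof
    if (i < length(times)) {
      # midpoint advection on the frame cadence with the recorded speeds
      dt <- times[i + 1] - times[i]
      w_i <- function(p) stats::approx(vb$sigma, fill_na(vb$values[i, ]),
                                       xout = p, rule = 2)$y
      p_half <- pos + 0.5 * dt * w_i(pos)
      w_next <- stats::approx(vb$sigma, fill_na(vb$values[i + 1, ]),
                              xout = p_half, rule = 2)$y
      pos <- pos + dt * 0.5 * (w_i(pos) + w_next)
    }
  }
  marker_profile_series(times, s_list, i_list)
}

fill_na <- function(x) { x[is.na(x)] <- 0; x }

# Digitization noise of a contour-derived midline: neighbouring points
# come from overlapping pixel neighbourhoods, so the error is smooth along
# the organ rather than independent per point.  Gaussian noise with a
# correlation length of ~0.5 mm, scaled to marginal sd `sd`.
correlated_noise <- function(n, sd, corr_pts = 5) {
  if (sd <= 0) return(numeric(n))
  half <- 3 * corr_pts
  kern <- stats::dnorm(seq(-half, half), sd = corr_pts)
  e <- stats::rnorm(n + 2 * half)
  sm <- stats::convolve(e, kern, type = "filter")
  sd * sm / sqrt(sum(kern^2))
}

#' Generate a two-treatment synthetic cohort on disk
#'
#' Draws per-plant ground-truth parameters from the configured
#' distributions, simulates each plant, and writes a dataset directory:
#' `plant_<k>/midline.csv`, `plant_<k>/markers.csv`, `plant_<k>/truth.json`
#' (scalar ground truth, kept separate from the observables) and a cohort
#' `manifest.csv` with the treatment labels.  Tilted plants start at pi/2
#' with anti-phase differential growth (`delta_phase = pi`); straight
#' plants are upright with in-phase pulses.
#'
#' @param n_straight,n_tilted plants per group (>= 1).
#' @param dir output directory (created).
#' @param seed master seed; per-plant seeds are derived from it, so a
#'   fixed seed reproduces the whole dataset.
#' @param Tp_range,vp_range,B_range,L0_range uniform ranges for the pulse
#'   period (h), pulse speed (mm/h), balance number and initial length
#'   (mm).
#' @param config_base template [gen_config]; per-plant draws override the
#'   wave parameters, `beta` (via B) and `L0`.
#' @return Invisibly, the manifest data.frame (columns `plant_id`,
#'   `group`).
#' @export
generate_cohort <- function(n_straight, n_tilted, dir, seed = 1L,
                            Tp_range = c(2.5, 3.5), vp_range = c(8, 17),
                            B_range = c(0.5, 4), L0_range = c(10, 20),
                            config_base = gen_config()) {
  if (n_straight < 1 || n_tilted < 1) stop("need at least 1 plant per group")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_straight + n_tilted
  set.seed(as.integer(seed))
  plant_seeds <- sample.int(.Machine$integer.max, n)
  Tp <- stats::runif(n, Tp_range[1], Tp_range[2])
  vp <- stats::runif(n, vp_range[1], vp_range[2])
  B <- stats::runif(n, B_range[1], B_range[2])
  L0 <- stats::runif(n, L0_range[1], L0_range[2])
  group <- c(rep("straight", n_straight), rep("tilted", n_tilted))
  manifest <- data.frame(plant_id = sprintf("plant_%02d", seq_len(n)),
                         group = group, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    cfg <- config_base
    cfg$seed <- plant_seeds[k]
    cfg$regr_wave$Tp <- Tp[k]; cfg$regr_wave$vp <- vp[k]
    cfg$diff_growth_wave$Tp <- Tp[k]; cfg$diff_growth_wave$vp <- vp[k]
    cfg$ac$L0 <- L0[k]
    cfg$ac$Lgz <- min(cfg$ac$Lgz, L0[k] + 5)
    L_eff <- min(cfg$ac$L0, cfg$ac$Lgz)
    cfg$ac$beta <- B[k] * cfg$ac$gamma / L_eff
    if (group[k] == "straight") {
      cfg$ac$tilt <- 0
      cfg$delta_phase <- 0
    } else {
      cfg$ac$tilt <- pi / 2
      cfg$delta_phase <- pi
    }
    plant <- generate_coleoptile_series(cfg)
    pdir <- file.path(dir, manifest$plant_id[k])
    dir.create(pdir, showWarnings = FALSE)
    write_midline_csv(plant$midline, file.path(pdir, "midline.csv"))
    write_markers_csv(plant$markers, file.path(pdir, "markers.csv"))
    truth <- list(plant_id = manifest$plant_id[k], group = group[k],
                  seed = plant_seeds[k], Tp = Tp[k], vp = vp[k],
                  balance_number = plant$truth$balance_number,
                  overshoot = plant$truth$overshoot,
                  delta_phase = cfg$delta_phase, tilt = cfg$ac$tilt,
                  beta = cfg$ac$beta, gamma = cfg$ac$gamma,
                  L0 = cfg$ac$L0, Lgz = cfg$ac$Lgz,
                  regr0 = cfg$ac$regr0)
    jsonlite::write_json(truth, file.path(pdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
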