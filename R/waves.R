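#' Parameters of a propagating pulse wave
#'
#' Describes the idealized oscillation travelling from the apex toward the
#' base of the organ: temporal period `Tp`, propagation speed `vp`, an
#' amplitude (relative for REGR modulation, or the differential-growth
#' fraction for curvature forcing) and a phase.
#'
#' @param Tp pulse period (h), > 0.
#' @param vp pulse speed (mm/h), > 0.
#' @param amplitude wave amplitude; relative REGR amplitudes must lie in
#'   `[0, 1)`.
#' @param phase phase offset (rad).
#' @return A list of class `wave_params`.
#' @export
wave_params <- function(Tp = 3, vp = 12, amplitude = 0.4, phase = 0) {
  if (Tp <= 0 || vp <= 0) stop("Tp and vp must be positive")
  structure(list(Tp = Tp, vp = vp, amplitude = amplitude, phase = phase),
            class = "wave_params")
}

wave_value <- function(wp, s, t, literal_form = FALSE) {
  if (literal_form) {
    # verbatim textbook form; note its temporal period is 2*pi*Tp and its
    # crests travel toward the apex under the apex-origin convention
    sin(s / (wp$Tp * wp$vp) + t / wp$Tp)
  } else {
    sin(2 * pi * (t / wp$Tp - s / (wp$vp * wp$Tp)) + wp$phase)
  }
}

#' Evaluate a propagating wave on a kymograph grid
#'
#' The default waveform is `sin(2*pi*(t/Tp - s/(vp*Tp)) + phase)`: its
#' temporal period is exactly `Tp` and its crests travel from the apex
#' (`s = 0`) toward the base at speed `vp`, matching the linear crest
#' locus `s = vp * (t - t0)`.  The `literal_form` switch instead emits the
#' form `sin(s/(Tp*vp) + t/Tp)`, retained for documentation: that form has
#' temporal period `2*pi*Tp` and apex-ward crest motion.
#'
#' @param wp a [wave_params] (its amplitude is not applied here; the
#'   returned field is the unit waveform).
#' @param s_grid,t_grid grid vectors (mm, h).
#' @param literal_form use the literal alternative form.
#' @return A [kinematic_field] with quantity `"wave"` and full support.
#' @export
wave_field <- function(wp, s_grid, t_grid, literal_form = FALSE) {
  v <- outer(t_grid, s_grid, function(t, s)
    wave_value(wp, s, t, literal_form))
  kinematic_field(s_grid, t_grid, v, quantity = "wave", units = "")
}
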