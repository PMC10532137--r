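#' Parametric flow waveform specification
#'
#' Describes the ground-truth total-flow waveform imposed on a synthetic
#' acquisition plane. Three shapes are available:
#' \describe{
#'   \item{`sinusoid`}{pure sine oscillation.}
#'   \item{`arterial_like`}{fast systolic peak followed by a slow decay
#'     (gamma-variate pulse), the typical carotid/basilar profile.}
#'   \item{`biphasic_csf`}{sharper systolic (craniocaudal) lobe and a
#'     broader diastolic return lobe, the typical cervical CSF profile.}
#' }
#' Every shape is normalised so that the waveform has temporal mean equal
#' to `mean_offset` (exactly, on the 32 samples) and peak-to-trough
#' excursion `2 * amplitude`; for the sinusoid this reduces to
#' `amplitude * sin(2*pi*k/32 + phase) + mean_offset`.
#'
#' @param shape One of `"sinusoid"`, `"arterial_like"`, `"biphasic_csf"`.
#' @param amplitude Oscillation amplitude in mL/s (>= 0); half the
#'   peak-to-trough excursion.
#' @param mean_offset Temporal-mean flow in mL/s (net flow through the
#'   plane; 0 for a pure oscillation).
#' @param period Cardiac cycle duration in seconds (> 0).
#' @param phase_shift Phase of the waveform as a fraction of the cycle in
#'   `[0, 1)`.
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(shape = c("sinusoid", "arterial_like", "biphasic_csf"),
                          amplitude = 1, mean_offset = 0,
                          period = 1, phase_shift = 0) {
  shape <- match.arg(shape)
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("amplitude must be >= 0")
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("period must be a single positive number")
  if (phase_shift < 0 || phase_shift >= 1)
    stop("phase_shift must lie in [0, 1)")
  structure(list(shape = shape, amplitude = amplitude,
                 mean_offset = mean_offset, period = period,
                 phase_shift = phase_shift),
            class = "waveform_spec")
}

# continuous unit shapes on u in [0, 1); un-normalised
.waveform_shape_fun <- function(shape) {
  switch(shape,
    sinusoid      = function(u) sin(2 * pi * u),
    # gamma-variate pulse: rapid systolic upstroke peaking early in the
    # cycle, exponential decay through diastole
    arterial_like = function(u) (u / 0.18)^2.5 * exp(2.5 * (1 - u / 0.18)),
    # asymmetric biphasic oscillation: concentrated systolic lobe,
    # broader counter-directional diastolic lobe
    biphasic_csf  = function(u) sin(2 * pi * u) + 0.35 * sin(4 * pi * u))
}

# zero-mean, max - min = 2 normalisation constants on a fine grid of the
# continuous shape (sample-count independent)
.waveform_norm <- function(shape) {
  f <- .waveform_shape_fun(shape)
  u <- (seq_len(8192L) - 1L) / 8192L
  y <- f(u)
  m <- mean(y)
  list(center = m, halfrange = (max(y) - min(y)) / 2)
}

#' Evaluate a waveform specification at the 32 cardiac phases
#'
#' @param spec A [waveform_spec()].
#' @param compartment,sign_convention Passed through to [flow_curve()].
#' @return A [flow_curve()] with 32 samples whose temporal mean equals
#'   `spec$mean_offset` exactly.
#' @export
make_waveform <- function(spec, compartment = "synthetic",
                          sign_convention = "craniocaudal_positive") {
  if (!inherits(spec, "waveform_spec")) stop("expected a waveform_spec")
  f <- .waveform_shape_fun(spec$shape)
  nrm <- .waveform_norm(spec$shape)
  u <- ((seq_len(32L) - 1L) / 32 + spec$phase_shift) %% 1
  s <- (f(u) - nrm$center) / nrm$halfrange
  # re-centre the discrete samples so the 32-sample mean is the offset
  # exactly (phase sampling of an asymmetric shape has a small mean bias)
  s <- s - mean(s)
  flow_curve(spec$mean_offset + spec$amplitude * s,
             cycle_s = spec$period, compartment = compartment,
             sign_convention = sign_convention)
}

#' Rescale a zero-mean waveform to a prescribed stroke volume
#'
#' Utility for building synthetic acquisitions whose ground-truth stroke
#' volume is an exact, prescribed value: scales the oscillatory part of the
#' curve so that [stroke_volume()] of the result equals `target_ul`.
#'
#' @param curve A [flow_curve()] with non-zero oscillation.
#' @param target_ul Desired stroke volume in microlitres per cardiac cycle.
#' @param detrend Passed to [stroke_volume()] when measuring the curve.
#' @return The rescaled [flow_curve()].
#' @export
calibrate_stroke_volume <- function(curve, target_ul, detrend = FALSE) {
  stopifnot_curve(curve)
  sv0 <- stroke_volume(curve, detrend = detrend)
  if (sv0 <= 0) stop("curve has zero stroke volume; cannot calibrate")
  flow_curve(curve$values * (target_ul / sv0), cycle_s = curve$cycle_s,
             compartment = curve$compartment,
             sign_convention = curve$sign_convention)
}
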