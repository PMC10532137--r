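#' Volumetric flow curve over one cardiac cycle
#'
#' A `flow_curve` holds one volumetric flow waveform sampled at the 32
#' uniformly spaced cardiac phases of a cardiac-gated phase-contrast
#' acquisition, together with the cycle duration and a sign-convention tag.
#'
#' Sign conventions follow the acquisition geometry: positive is
#' craniocaudal for CSF and tonsil motion, inflow for arteries and outflow
#' for venous sinuses.
#'
#' @param values Numeric vector of 32 flow samples, in mL/s.
#' @param cycle_s Cardiac cycle duration in seconds (> 0).
#' @param compartment Character label for the flow compartment (e.g.
#'   `"csf_cervical"`, `"internal_carotid_left"`).
#' @param sign_convention Character tag describing the positive direction.
#' @return An object of class `flow_curve`.
#' @export
flow_curve <- function(values, cycle_s = 1,
                       compartment = "unspecified",
                       sign_convention = "craniocaudal_positive") {
  values <- as.numeric(values)
  if (length(values) != 32L)
    stop("a flow curve must have exactly 32 samples, got ", length(values))
  if (!all(is.finite(values)))
    stop("flow curve contains non-finite values")
  if (!is.numeric(cycle_s) || length(cycle_s) != 1L || cycle_s <= 0)
    stop("cycle_s must be a single positive number")
  structure(
    list(values = values, cycle_s = cycle_s,
         compartment = compartment, sign_convention = sign_convention),
    class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> %s (%s)\n", x$compartment, x$sign_convention))
  cat(sprintf("  32 phases over %.3g s cycle; mean %.3g mL/s, range [%.3g, %.3g]\n",
              x$cycle_s, mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.flow_curve <- function(x, ...) {
  data.frame(phase = seq_len(32L),
             time_s = (seq_len(32L) - 1L) / 32 * x$cycle_s,
             flow_ml_s = x$values)
}

stopifnot_curve <- function(x) {
  if (!inherits(x, "flow_curve")) stop("expected a flow_curve object")
  invisible(x)
}

check_curves_compatible <- function(...) {
  curves <- list(...)
  cyc <- vapply(curves, function(c) c$cycle_s, numeric(1))
  if (any(abs(cyc - cyc[1]) > 1e-9 * cyc[1]))
    stop("flow curves have mismatched cycle durations: ",
         paste(signif(cyc, 6), collapse = ", "))
  invisible(curves)
}

#' Temporal mean of a flow curve
#'
#' @param curve A [flow_curve()].
#' @param units `"ml_s"` (default) or `"ml_min"`.
#' @return Mean flow in the requested units.
#' @export
mean_flow <- function(curve, units = c("ml_s", "ml_min")) {
  stopifnot_curve(curve)
  units <- match.arg(units)
  m <- mean(curve$values)
  if (units == "ml_min") m * 60 else m
}

#' Stroke volume of an oscillatory flow curve
#'
#' The stroke volume is the volume displaced through the region of interest
#' during one cardiac cycle, in both directions. With `V+` the integral of
#' the positive (e.g. craniocaudal) flow and `V-` the integral of the
#' negative flow magnitude over one cycle, SV = (V+ + V-)/2, so that for a
#' pure oscillation SV equals the one-directional displaced volume.
#' Integration uses the trapezoidal rule on the 32 uniform phase samples
#' with periodic closure (phase 32 connects back to phase 1).
#'
#' @param curve A [flow_curve()] in mL/s.
#' @param detrend If `TRUE`, subtract the temporal mean before integrating.
#'   CSF and tissue curves are integrated as measured (their small net flow
#'   is physiological); the arteriovenous curve is detrended.
#' @return Stroke volume in microlitres per cardiac cycle.
#' @export
stroke_volume <- function(curve, detrend = FALSE) {
  stopifnot_curve(curve)
  q <- curve$values
  if (isTRUE(detrend)) q <- q - mean(q)
  dt <- curve$cycle_s / 32
  v_pos <- trapz_periodic(pmax(q, 0), dt)
  v_neg <- trapz_periodic(pmax(-q, 0), dt)
  1000 * (v_pos + v_neg) / 2   # mL -> uL
}

# trapezoid over one full cycle, closing the last segment back to sample 1
trapz_periodic <- function(x, dt) {
  xc <- c(x, x[1L])
  sum((xc[-length(xc)] + xc[-1L]) / 2) * dt
}

#' Peak-to-trough amplitude of a flow curve
#'
#' @param curve A [flow_curve()].
#' @return `max(curve) - min(curve)` in mL/s.
#' @export
peak_amplitude <- function(curve) {
  stopifnot_curve(curve)
  max(curve$values) - min(curve$values)
}

#' Intracranial volume change over the cardiac cycle
#'
#' Cumulative trapezoidal integral of a zero-mean (arteriovenous) flow
#' curve, giving the instantaneous excess intracranial volume at each of
#' the 32 cardiac phases. By periodicity the curve starts and ends at zero;
#' the closure residual is checked and returned as an attribute.
#'
#' @param av_curve A zero-mean [flow_curve()] (typically from
#'   [arteriovenous_curve()]).
#' @param tol Relative tolerance on the temporal mean of the input; a mean
#'   exceeding `tol * max(|flow|)` signals a non-detrended input and raises
#'   an error.
#' @return Numeric vector of 32 volume samples in mL, with attributes
#'   `closure_ml` (signed integral over the full cycle) and `cycle_s`.
#' @export
intracranial_volume_change <- function(av_curve, tol = 1e-8) {
  stopifnot_curve(av_curve)
  q <- av_curve$values
  scale <- max(abs(q), .Machine$double.eps)
  if (abs(mean(q)) > tol * scale)
    stop("input curve has a non-zero temporal mean; detrend first ",
         "(mean = ", signif(mean(q), 4), " mL/s)")
  dt <- av_curve$cycle_s / 32
  seg <- (q[-32L] + q[-1L]) / 2 * dt
  vol <- c(0, cumsum(seg))
  closure <- vol[32L] + (q[32L] + q[1L]) / 2 * dt
  structure(vol, closure_ml = closure, cycle_s = av_curve$cycle_s)
}
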