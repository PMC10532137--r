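#' Volumetric flow curve of a segmented region
#'
#' Multiplies the region's velocities by the pixel area and sums over the
#' region at each of the 32 cardiac phases, giving the volumetric flow
#' waveform in mL/s (velocities in cm/s times area in cm² give cm³/s).
#'
#' @param series A [velocity_series()].
#' @param mask A [roi_mask()] (or logical matrix) aligned to the series.
#' @return A [flow_curve()] in mL/s.
#' @export
compute_flow_curve <- function(series, mask) {
  if (!inherits(series, "velocity_series"))
    stop("expected a velocity_series")
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(dim(m), dim(series$v)[1:2]))
    stop("mask dimensions do not match the series grid")
  if (!any(m)) stop("empty mask")
  V <- .series_matrix(series)
  q <- colSums(V[as.vector(m), , drop = FALSE]) * pixel_area(series, "cm2")
  flow_curve(q, cycle_s = series$cycle_s,
             compartment = series$compartment,
             sign_convention = series$sign_convention)
}

#' Cerebral arterial blood flow
#'
#' Sums the flow curves of the two internal carotid arteries and the
#' basilar artery (inflow-positive) and reports the temporal-mean total
#' arterial flow CBFa in mL/min.
#'
#' @param left_carotid,right_carotid,basilar [flow_curve()] objects with a
#'   common cycle duration.
#' @return A list with `curve` (the summed [flow_curve()]) and
#'   `cbfa_ml_min` (its temporal mean in mL/min).
#' @export
cerebral_arterial_flow <- function(left_carotid, right_carotid, basilar) {
  stopifnot_curve(left_carotid); stopifnot_curve(right_carotid)
  stopifnot_curve(basilar)
  check_curves_compatible(left_carotid, right_carotid, basilar)
  total <- flow_curve(left_carotid$values + right_carotid$values +
                        basilar$values,
                      cycle_s = left_carotid$cycle_s,
                      compartment = "cerebral_arterial",
                      sign_convention = "inflow_positive")
  list(curve = total, cbfa_ml_min = mean_flow(total, "ml_min"))
}

#' Cerebral venous blood flow
#'
#' Sums the straight-sinus and superior-sagittal-sinus flow curves
#' (outflow-positive) and reports the temporal-mean venous flow CBFv in
#' mL/min. CBFv underestimates total drainage because accessory routes
#' (epidural and other peripheral veins) bypass the sinuses; see
#' [alpha_factor()].
#'
#' @param straight_sinus,superior_sagittal [flow_curve()] objects with a
#'   common cycle duration.
#' @return A list with `curve` and `cbfv_ml_min`.
#' @export
cerebral_venous_flow <- function(straight_sinus, superior_sagittal) {
  stopifnot_curve(straight_sinus); stopifnot_curve(superior_sagittal)
  check_curves_compatible(straight_sinus, superior_sagittal)
  total <- flow_curve(straight_sinus$values + superior_sagittal$values,
                      cycle_s = straight_sinus$cycle_s,
                      compartment = "cerebral_venous",
                      sign_convention = "outflow_positive")
  list(curve = total, cbfv_ml_min = mean_flow(total, "ml_min"))
}

#' Venous drainage repartition (alpha) factor
#'
#' The sinuses do not drain all of the cerebral blood flow; the venous
#' correction factor is the ratio of the temporal-mean arterial flow to
#' the temporal-mean sinus venous flow, `alpha = mean(CBFa)/mean(CBFv)`.
#' A value of 1 means exclusive sinus (jugular) drainage; values above 1
#' measure the magnitude of accessory drainage routes. Values below 1 are
#' physically unexpected and raise a warning but are returned.
#'
#' @param cbfa_mean Mean arterial flow, mL/min.
#' @param cbfv_mean Mean sinus venous flow, mL/min (> 0).
#' @return The dimensionless alpha factor.
#' @export
alpha_factor <- function(cbfa_mean, cbfv_mean) {
  if (!is.numeric(cbfv_mean) || cbfv_mean <= 0)
    stop("mean venous flow must be positive")
  alpha <- cbfa_mean / cbfv_mean
  if (alpha < 1)
    warning("alpha factor below 1 (", signif(alpha, 4),
            "): venous mean exceeds arterial mean")
  alpha
}

#' Sinus participation in total cerebral venous drainage
#'
#' Converts the alpha factor into the percentage of total cerebral
#' drainage carried by the sinuses: `100 / alpha`. With alpha = 1 the
#' sinuses carry 100% (exclusive drainage); with alpha = 2 they carry
#' only 50%, the rest leaving by accessory routes.
#'
#' @param alpha Alpha factor (> 0; a value below 1 warns).
#' @return Sinus participation in percent.
#' @export
sinus_participation <- function(alpha) {
  if (!is.numeric(alpha) || alpha <= 0)
    stop("alpha must be positive")
  if (alpha < 1)
    warning("alpha below 1 implies sinus participation above 100%")
  100 / alpha
}

#' Alpha-corrected venous flow curve
#'
#' Scales the sinus venous curve by the alpha factor so that its temporal
#' mean matches the arterial mean: `corrected_CBFv = alpha * CBFv`. With
#' alpha = 1 the curve is unchanged.
#'
#' @param cbfv_curve Venous [flow_curve()].
#' @param alpha Alpha factor (> 0).
#' @return The scaled [flow_curve()].
#' @export
corrected_venous_curve <- function(cbfv_curve, alpha) {
  stopifnot_curve(cbfv_curve)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  flow_curve(alpha * cbfv_curve$values, cycle_s = cbfv_curve$cycle_s,
             compartment = "corrected_cerebral_venous",
             sign_convention = cbfv_curve$sign_convention)
}

#' Cerebral arteriovenous flow curve
#'
#' Pointwise difference between the arterial curve and the alpha-corrected
#' venous curve. Because the correction equalises the two means, the
#' arteriovenous curve has zero temporal mean by construction; its
#' positive early-cycle lobe is the systolic intracranial blood-volume
#' accumulation that CSF flushing and delayed venous outflow must buffer.
#'
#' @param cbfa_curve Arterial [flow_curve()].
#' @param corrected_cbfv_curve Alpha-corrected venous [flow_curve()].
#' @return A [flow_curve()] (net inflow positive).
#' @export
arteriovenous_curve <- function(cbfa_curve, corrected_cbfv_curve) {
  stopifnot_curve(cbfa_curve); stopifnot_curve(corrected_cbfv_curve)
  check_curves_compatible(cbfa_curve, corrected_cbfv_curve)
  flow_curve(cbfa_curve$values - corrected_cbfv_curve$values,
             cycle_s = cbfa_curve$cycle_s,
             compartment = "arteriovenous",
             sign_convention = "net_inflow_positive")
}

#' Arteriovenous (vascular) stroke volume
#'
#' The volume of blood that oscillates into and out of the cranial
#' compartment during one cardiac cycle: the stroke volume of the
#' (detrended) arteriovenous curve, reported in mL per cardiac cycle.
#'
#' @param av_curve Arteriovenous [flow_curve()].
#' @return SV_blood in mL per cardiac cycle.
#' @export
blood_stroke_volume <- function(av_curve) {
  stopifnot_curve(av_curve)
  stroke_volume(av_curve, detrend = TRUE) / 1000  # uL -> mL
}
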