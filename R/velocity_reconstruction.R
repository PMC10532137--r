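#' Convert stored phase codes to calibrated signed velocities
#'
#' Phase-contrast scanners store the velocity-encoded phase as signed
#' integer codes; the mapping to velocity is linear through the encoding
#' limit: `velocity = code / code_range * venc`.
#'
#' @param phase_codes Integer array `nx x ny x 32` of signed phase codes
#'   in `[-code_range, +code_range]`.
#' @param venc Velocity-encoding limit in cm/s.
#' @param code_range Positive integer; the code magnitude that maps to
#'   `venc`. Default 2048 (12-bit signed phase).
#' @param pixel_mm,cycle_s,compartment,sign_convention Metadata for the
#'   resulting [velocity_series()].
#' @return A [velocity_series()] in cm/s.
#' @export
phase_to_velocity <- function(phase_codes, venc, code_range = 2048L,
                              pixel_mm = 0.6, cycle_s = 1,
                              compartment = "unspecified",
                              sign_convention = "craniocaudal_positive") {
  if (!is.numeric(code_range) || code_range <= 0)
    stop("code_range must be a positive integer")
  if (any(abs(phase_codes) > code_range))
    stop("phase codes outside [-code_range, +code_range]")
  velocity_series(phase_codes / code_range * venc, pixel_mm = pixel_mm,
                  venc = venc, cycle_s = cycle_s, compartment = compartment,
                  sign_convention = sign_convention)
}

#' Correct velocity aliasing by temporal phase unwrapping
#'
#' Velocities beyond the encoding limit wrap by `2*venc`. This pass
#' unwraps each pixel's 32-phase time series: a jump between adjacent
#' cardiac phases larger than `venc` in magnitude is taken as a wrap event
#' and the subsequent samples are shifted by the compensating multiple of
#' `2*venc`. Alias-free series pass through unchanged (the operation is
#' idempotent), and a pixel that is wrapped at every phase shows no
#' temporal jump and cannot be recovered; such pixels are left unchanged.
#'
#' @param series A [velocity_series()].
#' @return The unwrapped [velocity_series()], with attribute
#'   `n_unwrapped` counting the corrected samples; the alias-warning flag
#'   is cleared when all unwrapped velocities fall within `venc`.
#' @export
unwrap_aliasing <- function(series) {
  if (!inherits(series, "velocity_series"))
    stop("expected a velocity_series")
  venc <- series$venc
  V <- .series_matrix(series)               # npix x 32
  D <- V[, -1L, drop = FALSE] - V[, -32L, drop = FALSE]
  steps <- (D > venc) - (D < -venc)         # wrap events per transition
  if (any(steps != 0)) {
    shift <- -2 * venc * t(apply(steps, 1L, cumsum))
    V[, -1L] <- V[, -1L] + shift
    n_corrected <- sum(shift != 0)
  } else {
    n_corrected <- 0L
  }
  out <- velocity_series(array(V, dim(series$v)),
                         pixel_mm = series$pixel_mm, venc = venc,
                         cycle_s = series$cycle_s,
                         compartment = series$compartment,
                         sign_convention = series$sign_convention,
                         alias_warning = max(abs(V)) > venc)
  attr(out, "n_unwrapped") <- n_corrected
  out
}

#' Subtract the static-tissue background velocity offset
#'
#' Eddy currents leave a small spatially smooth baseline on phase-contrast
#' velocities. This pass estimates a global offset as the median (robust
#' to segmentation spill) of the per-pixel temporal-mean velocity over a
#' user-supplied static-tissue mask, and subtracts it everywhere.
#'
#' @param series A [velocity_series()].
#' @param static_mask A [roi_mask()] (or logical matrix) of static-tissue
#'   pixels, disjoint from any flow region.
#' @return The corrected [velocity_series()], with attribute
#'   `offset_cm_s` recording the subtracted value.
#' @export
background_offset_correct <- function(series, static_mask) {
  if (!inherits(series, "velocity_series"))
    stop("expected a velocity_series")
  m <- if (inherits(static_mask, "roi_mask")) static_mask$mask
       else static_mask
  if (!any(m)) stop("static mask is empty")
  temporal_mean <- apply(series$v, c(1, 2), mean)
  offset <- stats::median(temporal_mean[m])
  out <- velocity_series(series$v - offset, pixel_mm = series$pixel_mm,
                         venc = series$venc, cycle_s = series$cycle_s,
                         compartment = series$compartment,
                         sign_convention = series$sign_convention,
                         alias_warning = series$alias_warning)
  attr(out, "offset_cm_s") <- offset
  out
}
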