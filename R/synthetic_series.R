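#' Synthetic acquisition-plane specification
#'
#' Describes one synthetic phase-contrast plane: grid, geometry of the
#' pulsatile region, velocity encoding and the noise/artefact model. The
#' defaults match routine craniospinal protocols: 0.6 mm square pixels and
#' compartment-specific Vencs of 60 cm/s (blood), 10 cm/s (aqueductal CSF),
#' 5 cm/s (other CSF) and 2 cm/s (tonsil motion).
#'
#' @param grid_size Integer vector `c(nx, ny)` (a scalar is squared).
#' @param pixel_mm Pixel edge length in mm.
#' @param venc Velocity-encoding limit in cm/s.
#' @param roi ROI geometry: a list with `type` one of `"disc"`
#'   (`center`, `radius_mm`), `"annulus"` (`center`, `r_inner_mm`,
#'   `r_outer_mm`) or `"multi_vessel"` (`vessels`, a list of discs each
#'   with `center`, `radius_mm` and optional `flow_fraction`). `center` is
#'   in pixel coordinates `c(x, y)`.
#' @param noise_sd Gaussian velocity-noise SD in cm/s (0 = noise-free).
#' @param noise_model `"gaussian"` adds white noise to velocities;
#'   `"phase"` perturbs the complex phasor encoding the velocity (Rician
#'   magnitude statistics, the phase-contrast noise mechanism).
#' @param velocity_profile `"uniform"` (plug flow; makes the ground-truth
#'   stroke volume exact) or `"parabolic"` (disc ROIs only).
#' @param aliasing If `TRUE`, velocities beyond `venc` wrap modulo
#'   `2*venc` as in a real phase-contrast reconstruction; if `FALSE`, such
#'   velocities are stored unchanged and the series is flagged.
#' @param offset_cm_s Global background velocity offset (eddy-current-like
#'   baseline error) added to every pixel, cm/s.
#' @param seed Integer RNG seed; generation is reproducible given the seed.
#' @return An object of class `plane_spec`.
#' @export
plane_spec <- function(grid_size = c(64L, 64L), pixel_mm = 0.6, venc = 5,
                       roi = list(type = "disc", center = c(32, 32),
                                  radius_mm = 4),
                       noise_sd = 0, noise_model = c("gaussian", "phase"),
                       velocity_profile = c("uniform", "parabolic"),
                       aliasing = FALSE, offset_cm_s = 0, seed = NULL) {
  if (length(grid_size) == 1L) grid_size <- rep(grid_size, 2L)
  grid_size <- as.integer(grid_size)
  if (any(grid_size < 8L)) stop("grid_size must be at least 8 pixels")
  if (pixel_mm <= 0) stop("pixel_mm must be > 0")
  if (venc <= 0) stop("venc must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(grid_size = grid_size, pixel_mm = pixel_mm, venc = venc,
                 roi = roi, noise_sd = noise_sd,
                 noise_model = match.arg(noise_model),
                 velocity_profile = match.arg(velocity_profile),
                 aliasing = isTRUE(aliasing), offset_cm_s = offset_cm_s,
                 seed = seed),
            class = "plane_spec")
}

# pixel-centre distances (mm) from a centre given in pixel coordinates
.pixel_dist_mm <- function(grid_size, pixel_mm, center) {
  x <- (seq_len(grid_size[1]) - center[1]) * pixel_mm
  y <- (seq_len(grid_size[2]) - center[2]) * pixel_mm
  sqrt(outer(x^2, y^2, `+`))
}

# resolve the ROI geometry into a list of component masks + flow fractions
.resolve_roi <- function(spec) {
  g <- spec$grid_size
  roi <- spec$roi
  comps <- switch(roi$type,
    disc = list(list(mask = .pixel_dist_mm(g, spec$pixel_mm, roi$center) <=
                       roi$radius_mm,
                     frac = 1, center = roi$center,
                     radius_mm = roi$radius_mm)),
    annulus = {
      d <- .pixel_dist_mm(g, spec$pixel_mm, roi$center)
      list(list(mask = d >= roi$r_inner_mm & d <= roi$r_outer_mm,
                frac = 1, center = roi$center, radius_mm = roi$r_outer_mm))
    },
    multi_vessel = {
      vs <- roi$vessels
      fr <- vapply(vs, function(v)
        if (is.null(v$flow_fraction)) NA_real_ else v$flow_fraction,
        numeric(1))
      masks <- lapply(vs, function(v)
        .pixel_dist_mm(g, spec$pixel_mm, v$center) <= v$radius_mm)
      if (all(is.na(fr))) {  # default: split flow by area
        ar <- vapply(masks, sum, numeric(1))
        fr <- ar / sum(ar)
      }
      if (abs(sum(fr) - 1) > 1e-9)
        stop("vessel flow_fractions must sum to 1")
      mapply(function(m, f, v) list(mask = m, frac = f, center = v$center,
                                    radius_mm = v$radius_mm),
             masks, fr, vs, SIMPLIFY = FALSE)
    },
    stop("unknown roi type: ", roi$type))
  union_mask <- Reduce(`|`, lapply(comps, `[[`, "mask"))
  if (!any(union_mask)) stop("ROI contains no pixels")
  if (any(union_mask[c(1, nrow(union_mask)), ]) ||
      any(union_mask[, c(1, ncol(union_mask))]))
    stop("ROI touches the grid border; enlarge the grid")
  list(components = comps, union = union_mask)
}

# spatial velocity weights within one ROI component; weights integrate to
# the component's area so v = Q * w / area gives total flow Q
.profile_weights <- function(comp, spec) {
  m <- comp$mask
  if (spec$velocity_profile == "uniform") {
    w <- m * 1
  } else {
    if (spec$roi$type != "disc")
      stop("parabolic profile is only supported for disc ROIs")
    d <- .pixel_dist_mm(spec$grid_size, spec$pixel_mm, comp$center)
    w <- ifelse(m, 2 * (1 - (d / comp$radius_mm)^2), 0)
    w[w < 0] <- 0
    # renormalise so the discrete weights average to 1 over the mask
    w <- w / mean(w[m])
  }
  w
}

# wrap velocities into (-venc, venc] as a phase-contrast recon would
.wrap_velocity <- function(v, venc) {
  ((v + venc) %% (2 * venc)) - venc
}

#' Generate a synthetic phase-contrast velocity series with known truth
#'
#' Embeds a pulsatile region carrying a prescribed total-flow waveform in a
#' static background, then applies the optional background offset, noise
#' and velocity-aliasing models. Pixels inside the ROI carry the waveform
#' flow divided by the ROI area (uniform profile by default), so the
#' ground-truth stroke volume and mean flow of the plane are exactly those
#' of the prescribed waveform.
#'
#' @param plane A [plane_spec()].
#' @param waveform A [waveform_spec()], or a [flow_curve()] giving the
#'   total flow through the ROI directly (mL/s).
#' @param compartment Label stored on the series.
#' @return A list with elements:
#'   \describe{
#'     \item{`series`}{the [velocity_series()] (noise, offset and aliasing
#'       applied).}
#'     \item{`truth_mask`}{ground-truth [roi_mask()] of the pulsatile
#'       region.}
#'     \item{`truth_curve`}{the prescribed total-flow [flow_curve()].}
#'     \item{`truth_sv_ul`}{its stroke volume, µL per cardiac cycle.}
#'     \item{`truth_mean_flow_ml_min`}{its temporal-mean flow, mL/min.}
#'   }
#' @export
make_velocity_series <- function(plane, waveform,
                                 compartment = "synthetic") {
  if (!inherits(plane, "plane_spec")) stop("expected a plane_spec")
  curve <- if (inherits(waveform, "flow_curve")) waveform
           else make_waveform(waveform, compartment = compartment)
  geo <- .resolve_roi(plane)
  g <- plane$grid_size
  a_pix_cm2 <- (plane$pixel_mm / 10)^2

  v <- array(0, dim = c(g[1], g[2], 32L))
  for (comp in geo$components) {
    w <- .profile_weights(comp, plane)
    area_cm2 <- sum(comp$mask) * a_pix_cm2
    for (k in seq_len(32L))
      v[, , k] <- v[, , k] + w * (comp$frac * curve$values[k] / area_cm2)
  }
  v <- v + plane$offset_cm_s

  if (!is.null(plane$seed)) set.seed(plane$seed)
  if (plane$noise_sd > 0) {
    if (plane$noise_model == "gaussian") {
      v <- v + array(stats::rnorm(length(v), sd = plane$noise_sd), dim(v))
    } else {
      # phase-noise model: the velocity is encoded as the phase of a unit
      # phasor; complex Gaussian noise on the phasor gives Rician
      # magnitude statistics and phase-wrapped velocity noise
      sd_phase <- pi * plane$noise_sd / plane$venc
      phi <- pi * v / plane$venc
      z <- complex(modulus = 1, argument = phi) +
        complex(real = stats::rnorm(length(v), sd = sd_phase),
                imaginary = stats::rnorm(length(v), sd = sd_phase))
      v <- array(Arg(z) / pi * plane$venc, dim(v))
    }
  }

  alias_warning <- FALSE
  if (max(abs(v)) > plane$venc) {
    if (plane$aliasing) {
      v <- .wrap_velocity(v, plane$venc)
    } else {
      alias_warning <- TRUE
      warning("velocities exceed venc = ", plane$venc,
              " cm/s but aliasing is disabled; series flagged")
    }
  }

  series <- velocity_series(v, pixel_mm = plane$pixel_mm,
                            venc = plane$venc, cycle_s = curve$cycle_s,
                            compartment = compartment,
                            sign_convention = curve$sign_convention,
                            alias_warning = alias_warning)
  list(series = series,
       truth_mask = roi_mask(geo$union, compartment = compartment,
                             provenance = list(source = "synthetic_truth")),
       truth_curve = curve,
       truth_sv_ul = stroke_volume(curve),
       truth_mean_flow_ml_min = mean_flow(curve, "ml_min"))
}
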