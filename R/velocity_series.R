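#' Signed-velocity image series for one acquisition plane
#'
#' Container for one cardiac-gated phase-contrast acquisition: a 2D slice
#' of signed velocities over the 32 phases of the cardiac cycle, with the
#' geometry and velocity-encoding metadata needed for flow quantification.
#'
#' @param velocities Numeric array `nx x ny x 32`, velocities in cm/s
#'   (signed along the through-plane direction).
#' @param pixel_mm Square pixel edge length in mm (> 0).
#' @param venc Velocity-encoding limit in cm/s; velocities beyond it alias.
#' @param cycle_s Cardiac cycle duration in seconds.
#' @param compartment Compartment label (e.g. `"aqueduct"`, `"cervical"`).
#' @param sign_convention Positive-direction tag (craniocaudal for
#'   CSF/tonsils, inflow for arteries, outflow for sinuses).
#' @param alias_warning Logical flag set by generators/readers when
#'   velocities may exceed `venc` without wrapping having been applied.
#' @return An object of class `velocity_series`.
#' @export
velocity_series <- function(velocities, pixel_mm, venc, cycle_s = 1,
                            compartment = "unspecified",
                            sign_convention = "craniocaudal_positive",
                            alias_warning = FALSE) {
  velocities <- as.array(velocities)
  d <- dim(velocities)
  if (length(d) != 3L || d[3] != 32L)
    stop("velocities must be an nx x ny x 32 array, got dims ",
         paste(d, collapse = " x "))
  if (!is.numeric(pixel_mm) || pixel_mm <= 0) stop("pixel_mm must be > 0")
  if (!is.numeric(venc) || venc <= 0) stop("venc must be > 0")
  if (cycle_s <= 0) stop("cycle_s must be > 0")
  structure(
    list(v = velocities, pixel_mm = pixel_mm, venc = venc,
         cycle_s = cycle_s, compartment = compartment,
         sign_convention = sign_convention,
         alias_warning = isTRUE(alias_warning)),
    class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("<velocity_series> %s: %d x %d px (%.2g mm), 32 phases\n",
              x$compartment, d[1], d[2], x$pixel_mm))
  cat(sprintf("  venc %.3g cm/s, cycle %.3g s%s\n", x$venc, x$cycle_s,
              if (x$alias_warning) " [ALIAS WARNING]" else ""))
  invisible(x)
}

#' Pixel area of a velocity series
#' @param series A [velocity_series()].
#' @param units `"mm2"` or `"cm2"`.
#' @return Pixel area in the requested units.
#' @export
pixel_area <- function(series, units = c("mm2", "cm2")) {
  units <- match.arg(units)
  a <- series$pixel_mm^2
  if (units == "cm2") a / 100 else a
}

# velocities as an (nx*ny) x 32 matrix, one row per pixel
.series_matrix <- function(series) {
  d <- dim(series$v)
  matrix(series$v, nrow = d[1] * d[2], ncol = d[3])
}

#' Write a velocity series as NIfTI plus JSON sidecar
#'
#' The image is stored as an `nx x ny x 32` NIfTI volume (third dimension
#' = cardiac phase) holding velocities in cm/s; acquisition metadata that
#' NIfTI cannot carry (venc, cycle duration, compartment, sign convention)
#' goes into a JSON sidecar next to it.
#'
#' @param series A [velocity_series()].
#' @param path Output path; `.nii.gz` is appended if missing, and the
#'   sidecar replaces the image extension with `.json`.
#' @return The image path, invisibly.
#' @export
write_velocity_series <- function(series, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  img <- RNifti::asNifti(series$v,
                         pixdim = c(series$pixel_mm, series$pixel_mm,
                                    series$cycle_s / 32))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(venc_cm_s = series$venc, pixel_mm = series$pixel_mm,
         cycle_s = series$cycle_s, compartment = series$compartment,
         sign_convention = series$sign_convention,
         alias_warning = series$alias_warning),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a velocity series written by [write_velocity_series()]
#' @param path Path to the NIfTI image (sidecar found by extension swap).
#' @return A [velocity_series()].
#' @export
read_velocity_series <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  v <- as.array(RNifti::readNifti(path))
  velocity_series(v, pixel_mm = meta$pixel_mm, venc = meta$venc_cm_s,
                  cycle_s = meta$cycle_s, compartment = meta$compartment,
                  sign_convention = meta$sign_convention,
                  alias_warning = isTRUE(meta$alias_warning))
}

#' Write / read a region-of-interest mask as NIfTI
#' @param mask A [roi_mask()].
#' @param path Image path (`.nii.gz` appended if missing).
#' @return `write_roi_mask()`: the path, invisibly; `read_roi_mask()`: a
#'   logical matrix.
#' @export
write_roi_mask <- function(mask, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask$mask),
                                           dim = dim(mask$mask))), path)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  as.array(RNifti::readNifti(path)) > 0
}
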