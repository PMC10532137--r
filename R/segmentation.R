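#' Region-of-interest mask for one acquisition plane
#'
#' @param mask Logical matrix matching the plane grid.
#' @param compartment Compartment label.
#' @param seed_point Integer `c(x, y)` seed pixel, if the mask came from
#'   seeded segmentation.
#' @param provenance List recording how the mask was obtained (threshold,
#'   noise floor, ...).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, compartment = "unspecified", seed_point = NULL,
                     provenance = list()) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix")
  structure(list(mask = mask, compartment = compartment,
                 seed_point = seed_point, provenance = provenance),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d / %d pixels\n", x$compartment,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

# connected component of `mask` containing `seed` (x, y), 8- or
# 4-connectivity; iterative BFS on the logical grid
.connected_component <- function(mask, seed, connectivity = 8L) {
  nx <- nrow(mask); ny <- ncol(mask)
  if (!mask[seed[1], seed[2]]) return(matrix(FALSE, nx, ny))
  offs <- if (connectivity == 8L)
    cbind(dx = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dy = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(dx = c(-1, 1, 0, 0), dy = c(0, 0, -1, 1))
  comp <- matrix(FALSE, nx, ny)
  comp[seed[1], seed[2]] <- TRUE
  frontier <- matrix(seed, ncol = 2)
  while (nrow(frontier) > 0) {
    nbrs <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
      cbind(frontier[, 1] + offs[i, 1], frontier[, 2] + offs[i, 2])))
    keep <- nbrs[, 1] >= 1 & nbrs[, 1] <= nx & nbrs[, 2] >= 1 &
      nbrs[, 2] <= ny
    nbrs <- nbrs[keep, , drop = FALSE]
    idx <- nbrs[, 1] + (nbrs[, 2] - 1) * nx
    new <- mask[idx] & !comp[idx]
    idx <- unique(idx[new])
    if (!length(idx)) break
    comp[idx] <- TRUE
    frontier <- cbind((idx - 1) %% nx + 1, (idx - 1) %/% nx + 1)
  }
  comp
}

#' Semi-automatic segmentation of a pulsatile flow region
#'
#' Delineates the region of interest around a user-supplied seed pixel by
#' temporal-waveform similarity: a reference waveform is averaged over the
#' 3x3 neighbourhood of the seed, and a pixel belongs to the region when
#' its velocity waveform (i) has temporal standard deviation above a noise
#' floor and (ii) correlates with the reference at `|r| >= threshold` in
#' absolute value (so counter-phase flow in the same acquisition, e.g.
#' venous next to arterial, is admitted). The mask returned is the
#' 8-connected component containing the seed.
#'
#' The default noise floor is 3x the median temporal SD of the grid-border
#' pixels, which are assumed static.
#'
#' @param series A [velocity_series()].
#' @param seed Integer `c(x, y)` pixel inside the pulsatile region.
#' @param threshold Correlation threshold in `[0, 1]`; pixels at exactly
#'   the threshold are included.
#' @param noise_floor Temporal-SD floor in cm/s; `NULL` (default) derives
#'   it from the border pixels.
#' @param connectivity 8 (default) or 4.
#' @return A [roi_mask()] with provenance recording the threshold and the
#'   noise floor used.
#' @export
segment_pulsatile <- function(series, seed, threshold = 0.7,
                              noise_floor = NULL, connectivity = 8L) {
  if (!inherits(series, "velocity_series"))
    stop("expected a velocity_series")
  d <- dim(series$v)
  seed <- as.integer(round(seed))
  if (any(seed < 1L) || seed[1] > d[1] || seed[2] > d[2])
    stop("seed pixel is outside the grid")
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")

  V <- .series_matrix(series)               # npix x 32
  px_sd <- apply(V, 1L, stats::sd)

  if (is.null(noise_floor)) {
    border <- matrix(FALSE, d[1], d[2])
    border[c(1, d[1]), ] <- TRUE
    border[, c(1, d[2])] <- TRUE
    noise_floor <- 3 * stats::median(px_sd[as.vector(border)])
  }

  nb_x <- pmin(pmax(seed[1] + (-1:1), 1L), d[1])
  nb_y <- pmin(pmax(seed[2] + (-1:1), 1L), d[2])
  nb_idx <- as.vector(outer(nb_x, (nb_y - 1L) * d[1], `+`))
  ref <- colMeans(V[unique(nb_idx), , drop = FALSE])
  if (stats::sd(ref) <= noise_floor)
    stop("no pulsatile signal at seed (reference waveform SD ",
         signif(stats::sd(ref), 3), " cm/s is below the noise floor ",
         signif(noise_floor, 3), " cm/s)")

  pulsatile <- px_sd > noise_floor
  r <- rep(0, nrow(V))
  if (any(pulsatile)) {
    Vc <- V[pulsatile, , drop = FALSE] - rowMeans(V[pulsatile, , drop = FALSE])
    refc <- ref - mean(ref)
    r[pulsatile] <- abs(as.vector(Vc %*% refc) /
                          (sqrt(rowSums(Vc^2)) * sqrt(sum(refc^2))))
  }
  cand <- matrix(pulsatile & r >= threshold, d[1], d[2])
  if (!cand[seed[1], seed[2]])
    stop("seed pixel does not meet the pulsatility/correlation criteria")

  comp <- .connected_component(cand, seed, connectivity)
  roi_mask(comp, compartment = series$compartment, seed_point = seed,
           provenance = list(threshold = threshold,
                             noise_floor = noise_floor,
                             connectivity = connectivity))
}

#' Area of a region of interest
#'
#' @param mask A [roi_mask()] (or logical matrix).
#' @param pixel_area_mm2 Area of one pixel in mm².
#' @return Area in mm² (pixel count times pixel area).
#' @export
roi_area <- function(mask, pixel_area_mm2) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  n <- sum(m)
  if (n == 0L) stop("empty mask has no area")
  n * pixel_area_mm2
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b [roi_mask()] objects or logical matrices of equal dimension.
#' @return `2|A∩B| / (|A| + |B|)`, in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  ma <- if (inherits(a, "roi_mask")) a$mask else a
  mb <- if (inherits(b, "roi_mask")) b$mask else b
  if (!identical(dim(ma), dim(mb))) stop("masks have different dimensions")
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}
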