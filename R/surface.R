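#' Detect the tissue surface in a reconstructed volume
#'
#' For every A-line, the shallowest depth at which the median-smoothed
#' linear intensity exceeds `noise floor + threshold_sigmas * sigma_noise`
#' (noise statistics from the volume's quietest depth planes). The
#' resulting height map is cleaned with a 3x3 lateral median filter.
#' A-lines with no supra-threshold sample are flagged and filled by the
#' median filter; if more than half of all A-lines are flagged the volume
#' is considered surface-free and detection fails.
#'
#' @param volume an `ocm_volume`.
#' @param threshold_sigmas threshold above the noise floor, in robust
#'   noise SDs. The default sits well above the exponential tail of pure
#'   speckle/detector noise yet far (tens of dB) below tissue signal.
#' @param smooth_k odd window length of the axial running-median smoother.
#' @return A `surface_map`: matrix of heights in um (tissue depth scale,
#'   `[a_scan, b_scan]`), with attributes `flagged` (logical matrix) and
#'   `threshold`.
#' @export
detect_surface <- function(volume, threshold_sigmas = 10, smooth_k = 5L) {
  I <- ocm_intensity(volume)
  d <- dim(I)
  nz <- d[1]
  thr <- volume$noise_floor$median + threshold_sigmas * volume$noise_floor$sigma
  ## degenerate (noiseless) volumes: fall back to a small fraction of the
  ## peak signal
  if (thr <= 0) thr <- 1e-3 * max(I)
  Im <- matrix(I, nrow = nz)
  ncol_tot <- ncol(Im)
  idx <- integer(ncol_tot)
  for (j in seq_len(ncol_tot)) {
    prof <- runmed(Im[, j], smooth_k)
    hit <- which(prof > thr)
    idx[j] <- if (length(hit)) hit[1L] else NA_integer_
  }
  flagged <- is.na(idx)
  if (mean(flagged) > 0.5)
    stop(sprintf(paste0("surface detection failed: %.0f%% of A-lines never ",
                        "exceed the noise floor + %g sigma"),
                 100 * mean(flagged), threshold_sigmas), call. = FALSE)
  h <- (idx - 1L) * volume$axial_spacing_tissue
  hm <- matrix(h, d[2], d[3])
  ## fill flagged A-lines with the global median before smoothing
  hm[is.na(hm)] <- median(hm, na.rm = TRUE)
  hm <- median_filter3(hm)
  structure(hm, class = "surface_map",
            flagged = matrix(flagged, d[2], d[3]), threshold = thr)
}

#' Surface-referenced en-face projection
#'
#' Mean linear intensity over the depth window
#' `[surface + offset, surface + offset + thickness)` for every lateral
#' position. Averaging is done in linear intensity; convert to dB for
#' display only. The default window is the first 50 um underneath the
#' tissue surface.
#'
#' @param volume an `ocm_volume`.
#' @param surface a [detect_surface()] map (um), or a single number for a
#'   flat reference.
#' @param offset window start below the surface, um (>= 0).
#' @param thickness window thickness, um.
#' @return An `enface_image`: `values` (linear intensity matrix
#'   `[a_scan, b_scan]`), `pixel_spacing`, window parameters.
#' @export
enface_projection <- function(volume, surface, offset = 0, thickness = 50) {
  stopifnot_scalar_num(offset, "offset", lower = 0)
  stopifnot_scalar_num(thickness, "thickness", lower = 1e-9)
  I <- ocm_intensity(volume)
  d <- dim(I)
  nz <- d[1]
  dz <- volume$axial_spacing_tissue
  if (length(surface) == 1L) surface <- matrix(surface, d[2], d[3])
  if (!all(dim(surface) == d[2:3]))
    stop("surface map does not match the volume raster", call. = FALSE)
  i1 <- round(as.numeric(surface + offset) / dz) + 1L
  nwin <- max(1L, round(thickness / dz))
  i2 <- i1 + nwin                               # right-open window
  if (any(i1 < 1L) || any(i2 > nz + 1L))
    stop("projection window exceeds the reconstructed depth range",
         call. = FALSE)
  Im <- matrix(I, nrow = nz)
  cs <- rbind(0, apply(Im, 2L, cumsum))
  vals <- (cs[cbind(i2, seq_along(i1))] - cs[cbind(i1, seq_along(i1))]) / nwin
  structure(list(values = matrix(vals, d[2], d[3]),
                 pixel_spacing = volume$lateral_spacing,
                 window_offset = offset, window_thickness = thickness,
                 projection_mode = "mean-linear"),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "enface_image: %d x %d px (%g x %g um/px), window %g-%g um, %s\n",
    d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2], x$window_offset,
    x$window_offset + x$window_thickness, x$projection_mode))
  invisible(x)
}

#' Depth-resolved attenuation map
#'
#' Single-scattering depth-resolved estimator: for every A-line,
#' `mu[i] = I[i] / (2 * delta * sum_{j > i} I[j])` with `delta` the axial
#' spacing in mm, so `mu` is in 1/mm. The estimator assumes that nearly
#' all light is attenuated within the recorded depth range; the deepest
#' `tail_fraction` of samples is reserved and masked invalid, as are
#' voxels whose tail sum vanishes.
#'
#' @param volume an `ocm_volume`.
#' @param tail_fraction fraction of the deepest samples masked invalid.
#' @param smooth lateral box-smoothing half-width in pixels (0 = none).
#' @return An `attenuation_map`: `mu` array (1/mm, NA where invalid) and
#'   logical `valid` array of the same shape.
#' @export
attenuation_map <- function(volume, tail_fraction = 0.1, smooth = 0) {
  I <- ocm_intensity(volume)
  d <- dim(I)
  nz <- d[1]
  if (any(I < 0)) stop("negative linear intensity", call. = FALSE)
  delta <- volume$axial_spacing_tissue / 1000
  Im <- matrix(I, nrow = nz)
  cs <- apply(Im, 2L, cumsum)
  tail_sum <- rep(cs[nz, ], each = nz) - cs       # sum_{j > i} I[j]
  mu <- Im / (2 * delta * tail_sum)
  valid <- tail_sum > 0
  n_tail <- max(1L, ceiling(nz * tail_fraction))
  valid[seq.int(nz - n_tail + 1L, nz), ] <- FALSE
  mu[!valid] <- NA_real_
  mu <- array(mu, dim = d)
  valid <- array(valid, dim = d)
  if (smooth >= 1 && d[2] > 1) {
    filled <- mu; filled[!valid] <- 0
    for (i in seq_len(nz))
      filled[i, , ] <- box_smooth(filled[i, , ], r = as.integer(smooth))
    mu <- filled
    mu[!valid] <- NA_real_
  }
  structure(list(mu = mu, valid = valid,
                 axial_spacing_tissue = volume$axial_spacing_tissue,
                 lateral_spacing = volume$lateral_spacing),
            class = "attenuation_map")
}
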