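## ---- spectral-domain reconstruction -----------------------------------
## Chain: resample_to_k -> shape_spectrum -> compensate_dispersion ->
## reconstruct_volume. Each stage is exposed with its own contract;
## ocm_reconstruct() streams the whole chain over B-scans for large
## volumes.

## Catmull-Rom (cubic convolution) resampling weights from a strictly
## increasing input axis onto arbitrary output positions, as a sparse
## matrix so one multiply resamples a whole volume. Exactly reproduces
## input samples when output nodes coincide with input nodes.
resample_weights <- function(x_in, x_out) {
  n <- length(x_in)
  u <- approx(x_in, seq_len(n), xout = x_out, rule = 2)$y
  i0 <- floor(u)
  t <- u - i0
  on_node <- t < 1e-12
  w_m1 <- -0.5 * t^3 + t^2 - 0.5 * t
  w_0  <-  1.5 * t^3 - 2.5 * t^2 + 1
  w_p1 <- -1.5 * t^3 + 2 * t^2 + 0.5 * t
  w_p2 <-  0.5 * t^3 - 0.5 * t^2
  w_m1[on_node] <- 0; w_0[on_node] <- 1
  w_p1[on_node] <- 0; w_p2[on_node] <- 0
  idx <- cbind(i0 - 1L, i0, i0 + 1L, i0 + 2L)
  w <- cbind(w_m1, w_0, w_p1, w_p2)
  ## clamp out-of-range taps onto the end samples (replicated edges)
  idx_c <- pmin(pmax(idx, 1L), n)
  m <- length(x_out)
  Matrix::sparseMatrix(i = rep(seq_len(m), 4L), j = as.integer(idx_c),
                       x = as.numeric(w), dims = c(m, n))
}

## Robust noise-floor estimate of a reconstructed intensity volume: the
## quietest depth plane (air gap above the surface, or the range beyond
## the slab) gives the noise level; the spread is the MAD over all planes
## near that level. Works whether or not tissue fills the depth range.
noise_floor_stats <- function(I) {
  Im <- if (is.matrix(I)) I else matrix(I, nrow = dim(I)[1])
  ## skip the first few planes, which can carry the residual DC response
  usable <- seq.int(min(6L, nrow(Im)), nrow(Im))
  plane_med <- apply(Im[usable, , drop = FALSE], 1L, median)
  m <- min(plane_med)
  near <- usable[plane_med <= 2 * m + .Machine$double.xmin]
  vals <- Im[near, , drop = FALSE]
  list(median = median(vals), sigma = mad(vals))
}

kspace_meta <- function(raw) {
  list(scan = raw$scan, source = raw$source, constants = raw$constants,
       origin = raw$origin)
}

#' Resample spectra to a uniform wavenumber grid
#'
#' Spectrometer data are sampled uniformly in wavelength; the Fourier
#' conjugate of depth is wavenumber `k = 2 pi / lambda`. This stage
#' resamples every spectrum onto a uniform k grid spanning the input's k
#' range, using cubic (Catmull-Rom) interpolation. If the input is already
#' uniform in k the data pass through unchanged.
#'
#' @param volume a [simulate_raw_volume()] result (or a compatible list
#'   with `spectra` and `wavelength_axis`).
#' @return An object of class `kspace_volume`: `spectra` (same array
#'   shape), `k_axis` (1/um, increasing) and the acquisition metadata.
#' @export
resample_to_k <- function(volume) {
  lambda <- volume$wavelength_axis
  if (any(diff(lambda) <= 0))
    stop("wavelength axis must be strictly increasing", call. = FALSE)
  k_in <- rev(2000 * pi / lambda)              # increasing in k
  nk <- length(k_in)
  k_out <- seq(k_in[1], k_in[nk], length.out = nk)
  W <- resample_weights(k_in, k_out)
  d <- dim(volume$spectra)
  ## reverse the spectral axis so it is increasing in k, then resample
  sp <- matrix(volume$spectra[rev(seq_len(nk)), , ], nrow = nk)
  sp <- as.matrix(W %*% sp)
  out <- structure(c(list(spectra = array(sp, dim = d), k_axis = k_out),
                     kspace_meta(volume)),
                   class = "kspace_volume")
  out
}

spectral_window <- function(window, n) {
  if (is.numeric(window)) {
    if (length(window) != n)
      stop("window length must match the number of spectral samples",
           call. = FALSE)
    w <- window
  } else {
    j <- seq_len(n) - 1L
    w <- switch(match.arg(window, c("hann", "hamming", "blackman",
                                    "rectangular")),
      hann = 0.5 - 0.5 * cos(2 * pi * j / (n - 1)),
      hamming = 0.54 - 0.46 * cos(2 * pi * j / (n - 1)),
      blackman = 0.42 - 0.5 * cos(2 * pi * j / (n - 1)) +
        0.08 * cos(4 * pi * j / (n - 1)),
      rectangular = rep(1, n))
  }
  if (all(w == 0)) stop("all-zero spectral window", call. = FALSE)
  w
}

#' Spectral shaping (background subtraction and apodization)
#'
#' Removes the per-A-line spectral mean (reference/DC background) and
#' multiplies every spectrum by an apodization window to suppress
#' point-spread-function side lobes. The default Hann window suppresses
#' the first side lobe of a single-reflector PSF well below the level left
#' by a rectangular window, at the cost of a wider main lobe.
#'
#' @param volume a `kspace_volume`.
#' @param window window name (`"hann"`, `"hamming"`, `"blackman"`,
#'   `"rectangular"`) or a numeric vector of per-sample weights.
#' @return The shaped `kspace_volume`.
#' @export
shape_spectrum <- function(volume, window = "hann") {
  nk <- length(volume$k_axis)
  w <- spectral_window(window, nk)
  d <- dim(volume$spectra)
  sp <- matrix(volume$spectra, nrow = nk)
  sp <- w * sweep(sp, 2L, colMeans(sp), "-")
  volume$spectra <- array(sp, dim = d)
  volume$shaped <- TRUE
  volume
}

#' Numerical dispersion compensation
#'
#' Multiplies every spectrum by `exp(-i phi(k))`, with `phi` a polynomial
#' (order <= 3) in `k - k0` about the centre wavenumber. Zero coefficients
#' are an exact pass-through of magnitudes. In simulation the fixture's
#' forward coefficients are known, so passing them here restores the
#' dispersion-free point spread function.
#'
#' @param volume a `kspace_volume`.
#' @param coefficients numeric `c(c2, c3)` (um^2, um^3), defaulting to the
#'   scan configuration's forward coefficients.
#' @return The compensated `kspace_volume` (complex spectra).
#' @export
compensate_dispersion <- function(volume,
                                  coefficients =
                                    volume$scan$dispersion_coefficients) {
  if (!is.numeric(coefficients) || length(coefficients) > 2L ||
      any(!is.finite(coefficients)))
    stop("'coefficients' must be finite c(c2, c3)", call. = FALSE)
  coefficients <- c(coefficients, rep(0, 2 - length(coefficients)))
  k0 <- 2000 * pi / volume$source$center_wavelength
  dk <- volume$k_axis - k0
  phi <- coefficients[1] * dk^2 + coefficients[2] * dk^3
  d <- dim(volume$spectra)
  sp <- matrix(volume$spectra, nrow = length(volume$k_axis))
  sp <- exp(-1i * phi) * sp
  volume$spectra <- array(sp, dim = d)
  volume
}

#' Fourier reconstruction of the depth profile
#'
#' Inverse Fourier transform along the spectral axis (normalized so that
#' Parseval's identity holds between the shaped spectrum and the full
#' A-line), retaining the positive-depth half. The depth axis is scaled to
#' geometric tissue depth using the group refractive index; the noise
#' floor is estimated from the deepest 10% of samples (median and MAD of
#' linear intensity).
#'
#' @param volume a `kspace_volume` (k-linear, shaped).
#' @param constants an [optical_constants()]; defaults to the volume's.
#' @param pad_factor integer zero-padding factor applied before the
#'   transform; values > 1 interpolate the depth profile (used when
#'   measuring sub-pixel PSF widths).
#' @param keep `"positive"` (default) keeps the physical positive-depth
#'   half; `"full"` keeps the whole transform (for energy checks).
#' @return An object of class `ocm_volume`: complex `amplitude` array
#'   `[depth, a_scan, b_scan]`, `axial_spacing_air` and
#'   `axial_spacing_tissue` (um), `lateral_spacing` (um), and
#'   `noise_floor` (`median`, `sigma` of linear intensity).
#' @export
reconstruct_volume <- function(volume, constants = volume$constants,
                               pad_factor = 1, keep = c("positive", "full")) {
  keep <- match.arg(keep)
  nk <- length(volume$k_axis)
  nkp <- as.integer(nk * pad_factor)
  d <- dim(volume$spectra)
  sp <- matrix(volume$spectra, nrow = nk)
  if (nkp > nk) sp <- rbind(sp, matrix(0, nkp - nk, ncol(sp)))
  amp <- mvfft(sp + 0i) / sqrt(nkp)
  nz <- if (keep == "positive") nkp %/% 2L else nkp
  amp <- amp[seq_len(nz), , drop = FALSE]
  dk <- (volume$k_axis[nk] - volume$k_axis[1]) / (nk - 1)
  dz_air <- pi / (nkp * dk)
  n_g <- constants$group_index_tissue
  nf <- noise_floor_stats(Mod(amp)^2)
  floor_med <- nf$median
  floor_sig <- nf$sigma
  structure(list(amplitude = array(amp, dim = c(nz, d[2], d[3])),
                 axial_spacing_air = dz_air,
                 axial_spacing_tissue = dz_air / n_g,
                 lateral_spacing = c(volume$scan$lateral_fov / d[2],
                                     volume$scan$lateral_fov / d[3]),
                 noise_floor = list(median = floor_med, sigma = floor_sig),
                 constants = constants, scan = volume$scan,
                 source = volume$source, origin = volume$origin),
            class = "ocm_volume")
}

#' @export
print.ocm_volume <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf(
    "ocm_volume: %d depth x %d x %d A-scans, dz = %.3f um (tissue)\n",
    d[1], d[2], d[3], x$axial_spacing_tissue))
  invisible(x)
}

#' Linear intensity of a reconstructed volume
#'
#' @param volume an `ocm_volume`.
#' @return numeric array `|amplitude|^2`.
#' @export
ocm_intensity <- function(volume) Mod(volume$amplitude)^2

#' Intensity in dB referenced to the volume noise floor
#'
#' `10 log10(I / noise_floor)`, with intensities floored at a small
#' fraction of the noise floor so the result is finite everywhere.
#'
#' @param volume an `ocm_volume`.
#' @param floor_frac lower flooring fraction of the noise-floor median.
#' @return numeric array in dB.
#' @export
ocm_intensity_db <- function(volume, floor_frac = 1e-6) {
  ref <- max(volume$noise_floor$median, .Machine$double.xmin)
  10 * log10(pmax(ocm_intensity(volume), floor_frac * ref) / ref)
}

#' One-call reconstruction of a raw volume
#'
#' Runs k-resampling, spectral shaping, dispersion compensation and the
#' Fourier transform, streaming over B-scans so large volumes stay within
#' memory. Equivalent to the four-stage chain, except that a recorded
#' source background (`reference_spectrum`, the reference-arm spectrum a
#' real system acquires as a background frame) is subtracted first when
#' the raw volume carries one, which suppresses the residual DC response
#' near zero depth well below what per-A-line mean removal alone can do.
#'
#' @param raw a [simulate_raw_volume()] result.
#' @param window apodization window (see [shape_spectrum()]).
#' @param dispersion compensation coefficients `c(c2, c3)`; defaults to
#'   the scan's forward coefficients; `c(0, 0)` disables.
#' @param pad_factor zero-padding factor (see [reconstruct_volume()]).
#' @param chunk number of B-scans per processing block (default: sized so
#'   working matrices stay modest).
#' @return An `ocm_volume`.
#' @export
ocm_reconstruct <- function(raw, window = "hann",
                            dispersion = raw$scan$dispersion_coefficients,
                            pad_factor = 1, chunk = NULL) {
  lambda <- raw$wavelength_axis
  if (any(diff(lambda) <= 0))
    stop("wavelength axis must be strictly increasing", call. = FALSE)
  k_in <- rev(2000 * pi / lambda)
  nk <- length(k_in)
  k_out <- seq(k_in[1], k_in[nk], length.out = nk)
  W <- resample_weights(k_in, k_out)
  w <- spectral_window(window, nk)
  dispersion <- c(dispersion, rep(0, 2 - length(dispersion)))
  k0 <- 2000 * pi / raw$source$center_wavelength
  phi <- dispersion[1] * (k_out - k0)^2 + dispersion[2] * (k_out - k0)^3
  ph <- exp(-1i * phi)
  d <- dim(raw$spectra)
  nkp <- as.integer(nk * pad_factor)
  nz <- nkp %/% 2L
  if (is.null(chunk)) chunk <- max(1L, floor(4e6 / (nkp * d[2])))
  amp <- array(0i, dim = c(nz, d[2], d[3]))
  rev_idx <- rev(seq_len(nk))
  ref_k <- if (!is.null(raw$reference_spectrum))
    as.numeric(W %*% raw$reference_spectrum[rev_idx]) else NULL
  for (b0 in seq(1L, d[3], by = chunk)) {
    b1 <- min(b0 + chunk - 1L, d[3])
    sp <- matrix(raw$spectra[rev_idx, , b0:b1], nrow = nk)
    sp <- as.matrix(W %*% sp)
    if (!is.null(ref_k)) sp <- sp - ref_k
    sp <- w * (sp - rep(colMeans(sp), each = nk))
    sp <- ph * sp
    if (nkp > nk) sp <- rbind(sp, matrix(0i, nkp - nk, ncol(sp)))
    a <- mvfft(sp + 0i)[seq_len(nz), , drop = FALSE] / sqrt(nkp)
    amp[, , b0:b1] <- a
  }
  dk <- (k_out[nk] - k_out[1]) / (nk - 1)
  dz_air <- pi / (nkp * dk)
  n_g <- raw$constants$group_index_tissue
  nf <- noise_floor_stats(Mod(matrix(amp, nrow = nz))^2)
  structure(list(amplitude = amp,
                 axial_spacing_air = dz_air,
                 axial_spacing_tissue = dz_air / n_g,
                 lateral_spacing = c(raw$scan$lateral_fov / d[2],
                                     raw$scan$lateral_fov / d[3]),
                 noise_floor = nf,
                 constants = raw$constants, scan = raw$scan,
                 source = raw$source, origin = raw$origin),
            class = "ocm_volume")
}

#' Measure the FWHM of an axial point spread function
#'
#' Full width at half maximum of the dominant peak of an A-line profile by
#' linear interpolation between samples. The profile should be the
#' amplitude envelope (modulus) of the reconstructed A-line; the
#' coherence-length figure [coherence_length()] refers to this envelope.
#'
#' @param ascan numeric profile with a unique interior global maximum.
#' @param spacing sample spacing in um (tissue or air, the result is in
#'   the same convention).
#' @return FWHM in um.
#' @export
measure_psf_fwhm <- function(ascan, spacing) {
  stopifnot_scalar_num(spacing, "spacing", lower = 1e-12)
  if (!is.numeric(ascan) || length(ascan) < 5L)
    stop("'ascan' must be a numeric profile", call. = FALSE)
  i0 <- which.max(ascan)
  if (i0 == 1L || i0 == length(ascan))
    stop("peak lies at the array boundary", call. = FALSE)
  fwhm_interp(ascan) * spacing
}
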