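#' Simulate a raw spectral-domain OCM acquisition
#'
#' Single-scattering forward model of spectral-domain interferometry. For
#' every A-scan the detected spectrum is
#' `envelope(k) * [DC + sum_z 2 sqrt(R(z)) cos(2 k n z_opt + phi(k))]` plus
#' additive zero-mean Gaussian detector noise. `R(z)` is the phantom
#' backscatter attenuated by round-trip Beer--Lambert absorption (with the
#' clearing factor dividing the attenuation coefficients), the sensitivity
#' roll-off multiplies reflector amplitudes by
#' `10^(-rolloff_db_per_mm * z_opt / 20)`, and `phi(k)` is the polynomial
#' dispersion phase of the scan configuration. The immersion medium above
#' the tissue is taken as index-matched, so the optical depth of a voxel at
#' tissue depth `z` under surface height `h` is `n (h + z)`. The noise
#' standard deviation is calibrated so that a unit reflector at zero depth
#' reconstructs with a signal-to-noise ratio equal to
#' `constants$sensitivity_db`.
#'
#' @param phantom a [build_phantom()] object.
#' @param spectrum a [source_spectrum()]; its axis length must equal
#'   `scan$samples_per_spectrum`.
#' @param constants an [optical_constants()].
#' @param scan a [scan_config()]; `scan$lateral_fov` is sampled with
#'   `a_scans` x `b_scans` A-lines.
#' @param origin lateral offset `c(x, y)` in um of the scanned field within
#'   the phantom (used for mosaic tiles).
#' @param noise logical; `FALSE` gives the noiseless forward model.
#' @param dc_level reference-arm DC level multiplying the envelope.
#' @return An object of class `raw_spectral_volume`: `spectra` (array
#'   `[spectral sample, a_scan, b_scan]`), `wavelength_axis`, plus the
#'   `scan`, `source`, `constants` and `origin` used.
#' @export
simulate_raw_volume <- function(phantom, spectrum, constants, scan,
                                origin = c(0, 0), noise = TRUE,
                                dc_level = 1) {
  nk <- scan$samples_per_spectrum
  if (length(spectrum$wavelength_axis) != nk)
    stop(sprintf(
      "wavelength axis length (%d) does not match samples_per_spectrum (%d)",
      length(spectrum$wavelength_axis), nk), call. = FALSE)
  if (origin[1] + scan$lateral_fov > phantom$extent[1] + 1e-9 ||
      origin[2] + scan$lateral_fov > phantom$extent[2] + 1e-9 ||
      any(origin < -1e-9))
    stop("scan field exceeds the phantom lateral extent", call. = FALSE)

  n_g <- constants$group_index_tissue
  lambda <- spectrum$wavelength_axis
  k <- 2000 * pi / lambda                      # 1/um, decreasing in lambda
  env <- spectrum$envelope
  zs <- (seq_len(dim(phantom$backscatter)[3]) - 0.5) * phantom$voxel[3]
  nz <- length(zs)
  dz_mm <- phantom$voxel[3] / 1000

  ## shared depth-kernel matrices (Nk x Nz)
  A <- outer(2 * k * n_g, zs)
  cosA <- cos(A); sinA <- sin(A)
  ## dispersion phase about the centre wavenumber
  k0 <- 2000 * pi / spectrum$center_wavelength
  dcf <- scan$dispersion_coefficients
  phi <- dcf[1] * (k - k0)^2 + dcf[2] * (k - k0)^3
  cphi <- cos(phi); sphi <- sin(phi)
  has_disp <- any(phi != 0)

  ## depth-dependent roll-off (separable in z and surface height)
  r_db <- constants$rolloff_db_per_mm
  gz <- 10^(-r_db * n_g * zs / 1000 / 20)

  ## detector noise calibrated to the sensitivity
  sigma <- if (noise) {
    sum(env) / (sqrt(nk) * 10^(constants$sensitivity_db / 20))
  } else 0

  na <- scan$a_scans; nb <- scan$b_scans
  dx <- scan$lateral_fov / na; dy <- scan$lateral_fov / nb
  xa <- origin[1] + (seq_len(na) - 0.5) * dx
  yb <- origin[2] + (seq_len(nb) - 0.5) * dy
  ix <- clamp(ceiling(xa / phantom$voxel[1]), 1L, dim(phantom$backscatter)[1])
  iy <- clamp(ceiling(yb / phantom$voxel[2]), 1L, dim(phantom$backscatter)[2])

  clear <- constants$clearing_depth_factor
  spectra <- array(0, dim = c(nk, na, nb))
  ## chunk B-scans so working matrices stay modest for large rasters
  chunk <- max(1L, min(nb, floor(4e6 / (nk * na))))

  with_seed(scan$noise_seed, {
    for (b0 in seq(1L, nb, by = chunk)) {
      bb <- b0:min(b0 + chunk - 1L, nb)
      nc <- length(bb) * na
      ## Nz x (Na * chunk) reflector matrices
      R <- matrix(aperm(array(phantom$backscatter[ix, iy[bb], ],
                              dim = c(na, length(bb), nz)), c(3, 1, 2)),
                  nrow = nz)
      mu <- matrix(aperm(array(phantom$attenuation[ix, iy[bb], ],
                               dim = c(na, length(bb), nz)), c(3, 1, 2)),
                   nrow = nz) / clear
      ## round-trip Beer-Lambert to the voxel centre
      od <- col_cumsum(mu) * dz_mm - mu * dz_mm / 2
      h <- as.numeric(phantom$surface_height[ix, iy[bb]])
      amp <- 2 * sqrt(R * exp(-2 * od)) * gz
      amp <- amp * rep(10^(-r_db * n_g * h / 1000 / 20), each = nz)
      P <- cosA %*% amp                                             # Nk x nc
      Q <- sinA %*% amp
      B <- outer(2 * k * n_g, h)
      cosB <- cos(B); sinB <- sin(B)
      Fc <- cosB * P - sinB * Q            # sum amp cos(A + B)
      if (has_disp) {
        Fs <- sinB * P + cosB * Q          # sum amp sin(A + B)
        Fc <- cphi * Fc - sphi * Fs        # sum amp cos(A + B + phi)
      }
      sp <- env * (dc_level + Fc)
      if (sigma > 0) sp <- sp + rnorm(nk * nc, 0, sigma)
      spectra[, , bb] <- sp
    }
  })

  structure(list(spectra = spectra, wavelength_axis = lambda,
                 scan = scan, source = spectrum, constants = constants,
                 origin = origin, noise_sigma = sigma,
                 reference_spectrum = env * dc_level),
            class = "raw_spectral_volume")
}

#' @export
print.raw_spectral_volume <- function(x, ...) {
  d <- dim(x$spectra)
  cat(sprintf("raw_spectral_volume: %d spectral samples x %d x %d A-scans\n",
              d[1], d[2], d[3]))
  invisible(x)
}
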