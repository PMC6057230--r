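## Shared fixtures for the test suite. Everything is generated in code;
## expensive objects are cached per session.

## A phantom that is empty except for delta reflectors: the workhorse for
## point-spread-function, roll-off and noise-calibration checks.
mirror_phantom <- function(z_um, slab = 300, dz = 1.25, R = 1,
                           extent = c(20, 20)) {
  fx <- fixture("control", cells = FALSE, texture_sd = 1e-9,
                surface_height = 0, surface_ripple = 0,
                parenchyma_backscatter = 0, parenchyma_attenuation = 0)
  ph <- build_phantom(fx, seed = 1, extent = extent, slab = slab,
                      voxel = c(10, 10, dz))
  ph$backscatter[] <- 0
  for (z in z_um) ph$backscatter[, , round(z / dz + 0.5)] <- R
  ph$attenuation[] <- 0
  ph$surface_height[] <- 0
  ph
}

## Uniform-parenchyma phantom with a flat surface at a given height.
slab_phantom <- function(seed = 1, extent = c(150, 150), slab = 72,
                         voxel = c(5, 5, 2.5), surface = 8, ripple = 0,
                         density = 0, ...) {
  fx <- fixture("aged_mouse", density = density, cells = FALSE,
                surface_height = surface, surface_ripple = ripple, ...)
  build_phantom(fx, seed = seed, extent = extent, slab = slab,
                voxel = voxel)
}

## Air-equivalent optical constants (mirror measurements).
air_constants <- function(rolloff = 0)
  optical_constants(group_index_tissue = 1, sensitivity_db = 91,
                    rolloff_db_per_mm = rolloff, clearing_depth_factor = 1)

## Desk-scale acquisition of a full phantom field of view.
acquire <- function(phantom, samples = 256,
                    wavelength_range = c(470, 640), lateral_um = 5,
                    constants = optical_constants(), noise_seed = 7,
                    dispersion = c(0, 0), noise = TRUE, window = "hann") {
  sp <- source_spectrum(wavelength_range = wavelength_range,
                        samples = samples)
  na <- round(phantom$extent[1] / lateral_um)
  sc <- scan_config(samples_per_spectrum = samples, a_scans = na,
                    b_scans = na, lateral_fov = phantom$extent[1],
                    slab_thickness = phantom$slab,
                    dispersion_coefficients = dispersion,
                    noise_seed = noise_seed)
  raw <- simulate_raw_volume(phantom, sp, constants, sc, noise = noise)
  list(raw = raw,
       vol = ocm_reconstruct(raw, window = window, dispersion = dispersion))
}

## A fabricated phantom-compatible object holding only plaque truth, for
## histology-geometry tests: a 3 x 4 grid of spheres.
grid_truth_phantom <- function(diameters = 30, z = 22, extent = c(480, 360),
                               voxel = c(2.5, 2.5, 1.25)) {
  gx <- seq(60, extent[1] - 60, length.out = 4)
  gy <- seq(60, extent[2] - 60, length.out = 3)
  g <- expand.grid(x = gx, y = gy)
  n <- nrow(g)
  truth <- data.frame(id = seq_len(n), x_um = g$x, y_um = g$y,
                      z_um = rep(z, n),
                      diameter_um = rep(diameters, length.out = n))
  truth$volume_um3 <- pi / 6 * truth$diameter_um^3
  structure(list(plaque_truth = truth, extent = extent, voxel = voxel,
                 slab = 72), class = "phantom")
}

## Cached small 3-D study used by the CNR / ROI tests (built once).
cached_volume_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture("mouse_ad_3d", density = 5500)
      cache <<- run_volume_study(fx, seed = 33, extent_um = 320,
                                 slab = 70)
    }
    cache
  }
})
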