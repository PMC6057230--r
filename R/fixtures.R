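## Named study fixtures. Each fixture bundles the plaque statistics and
## tissue composition that a phantom is generated from. Densities and size
## statistics follow the study conditions: aged APP-PS1 mouse cortex carries
## about 23 plaques/mm2 in a 50-um en-face window, young mice about 17;
## human late-stage AD cortex has larger (6600 +/- 1700 um3) but sparser
## plaques than aged mouse cortex (4500 +/- 1200 um3). Optical properties
## (backscatter multipliers relative to parenchyma, attenuation in 1/mm)
## are one-time modelling choices documented in the methods vignette.

fixture_table <- function() {
  base <- list(
    mode = "areal",
    density = 0,                    # plaques per mm^2 (areal) or mm^3
    diameter_range = c(10, 70),     # um
    diameter_meanlog = log(25),
    diameter_sdlog = 0.45,
    volume_mean_um3 = NULL,
    volume_sd_um3 = NULL,
    depth_range = c(10, 45),        # plaque centre depth below surface, um
    plaque_backscatter = 2.5,       # multiplier vs parenchyma
    plaque_attenuation = 8,         # 1/mm (2x parenchyma)
    parenchyma_backscatter = 1e-5,  # reflectivity vs unit mirror
    parenchyma_attenuation = 4,     # 1/mm, before clearing scaling
    texture_sd = 0.25,              # multiplicative parenchymal texture
    cell_backscatter = 0.3,
    cell_attenuation = 3,
    cell_density_mm3 = 20000,
    cells = TRUE,
    fibers = 0,                     # number of white-matter tracts
    vessel = FALSE,
    surface_height = 8,             # mean immersion gap above slab top, um
    surface_ripple = 3,             # ripple amplitude, um
    surface_period = 400,           # ripple period, um
    edge_um = 1                     # plaque soft-edge width, um
  )
  list(
    aged_mouse = modifyList(base, list(
      density = 23, diameter_meanlog = log(25), diameter_sdlog = 0.45)),
    young_mouse = modifyList(base, list(
      density = 17, diameter_meanlog = log(20), diameter_sdlog = 0.40)),
    human_ad = modifyList(base, list(
      mode = "volumetric", density = 1500,
      volume_mean_um3 = 6600, volume_sd_um3 = 1700,
      depth_range = c(NA, NA), plaque_backscatter = 3.5)),
    mouse_ad_3d = modifyList(base, list(
      mode = "volumetric", density = 2200,
      volume_mean_um3 = 4500, volume_sd_um3 = 1200,
      depth_range = c(NA, NA), plaque_backscatter = 2.5)),
    caa_vessel = modifyList(base, list(
      density = 8, vessel = TRUE)),
    control = modifyList(base, list(density = 0))
  )
}

#' Study fixtures for phantom generation
#'
#' A fixture names the statistical structure a phantom is drawn from:
#' plaque density (areal, plaques/mm2, counted in the standard 50-um
#' en-face window; or volumetric, plaques/mm3), the plaque size
#' distribution (lognormal diameter, truncated to 10--70 um, or a lognormal
#' per-plaque volume with given mean and SD), tissue composition
#' (hyposcattering cell bodies, white-matter tracts, a CAA-bearing vessel)
#' and the optical properties of each component. Available fixtures:
#' `aged_mouse` (23 plaques/mm2), `young_mouse` (17 plaques/mm2),
#' `human_ad` (volume 6600 +/- 1700 um3), `mouse_ad_3d` (volume
#' 4500 +/- 1200 um3), `caa_vessel`, `control`.
#'
#' @param name fixture name, or an existing fixture object to modify.
#' @param ... named overrides of individual fixture fields.
#' @return An object of class `ocm_fixture` (a named list).
#' @examples
#' fixture("aged_mouse")$density
#' fixture("young_mouse", density = 12)
#' @export
fixture <- function(name = "aged_mouse", ...) {
  if (inherits(name, "ocm_fixture")) {
    fx <- unclass(name)
  } else {
    tab <- fixture_table()
    if (!name %in% names(tab))
      stop(sprintf("unknown fixture '%s'; available: %s", name,
                   paste(names(tab), collapse = ", ")), call. = FALSE)
    fx <- tab[[name]]
    fx$name <- name
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), c(names(fx), "name"))
    if (length(unknown))
      stop("unknown fixture field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    fx <- modifyList(fx, dots)
  }
  if (!is.numeric(fx$density) || length(fx$density) != 1L || fx$density < 0)
    stop("fixture density must be a single non-negative number",
         call. = FALSE)
  structure(fx, class = "ocm_fixture")
}

#' @export
print.ocm_fixture <- function(x, ...) {
  unit <- if (x$mode == "areal") "plaques/mm2" else "plaques/mm3"
  cat(sprintf("ocm_fixture '%s': %s, density %g %s\n",
              x$name %||% "<custom>", x$mode, x$density, unit))
  if (x$mode == "volumetric" && !is.null(x$volume_mean_um3))
    cat(sprintf("  plaque volume %g +/- %g um3\n",
                x$volume_mean_um3, x$volume_sd_um3))
  invisible(x)
}
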