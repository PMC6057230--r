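#' Build a voxelized tissue phantom
#'
#' Generates a 3-D model of a cleared cortical slab: a backscatter map
#' (reflectivity relative to a unit mirror), an attenuation map (1/mm), a
#' component label map, a smooth surface-height map, and a ground-truth
#' table of every plaque. Plaques are non-overlapping spheres with a thin
#' soft edge; their count is Poisson with mean `density * area` (areal
#' fixtures, plaques placed so that each intersects the standard 0--50 um
#' en-face counting window) or `density * volume` (volumetric fixtures,
#' centres uniform in depth). Hyposcattering cell bodies, hyperscattering
#' white-matter tracts and a CAA-bearing vessel are added when the fixture
#' asks for them. Output is bit-identical for a fixed (fixture, seed).
#'
#' @param fixture a fixture name or [fixture()] object.
#' @param seed integer seed.
#' @param extent lateral extent `c(x, y)` in um.
#' @param slab slab thickness in um (z = 0 at the nominal slab top,
#'   increasing into the tissue).
#' @param voxel voxel spacing `c(dx, dy, dz)` in um.
#' @return An object of class `phantom` with fields `backscatter`,
#'   `attenuation`, `labels` (integer array, see `attr(,"levels")`),
#'   `surface_height` (um of immersion gap above the slab top),
#'   `plaque_truth` (data frame: id, x_um, y_um, z_um, diameter_um,
#'   volume_um3), `voxel`, `extent`, `slab`, `fixture`, `seed`.
#' @examples
#' ph <- build_phantom("aged_mouse", seed = 1, extent = c(300, 300),
#'                     slab = 80, voxel = c(5, 5, 2.5))
#' nrow(ph$plaque_truth)
#' @export
build_phantom <- function(fixture, seed, extent = c(500, 500), slab = 200,
                          voxel = c(2.5, 2.5, 1.25)) {
  fx <- if (inherits(fixture, "ocm_fixture")) fixture else fixture(fixture)
  if (fx$density < 0) stop("plaque density must be >= 0", call. = FALSE)
  dr <- fx$diameter_range
  if (dr[1] <= 0 || dr[2] > slab)
    stop(sprintf(
      "plaque diameter bounds [%g, %g] um must lie within (0, slab = %g] um",
      dr[1], dr[2], slab), call. = FALSE)
  if (length(extent) != 2L || any(extent <= 0) || length(voxel) != 3L ||
      any(voxel <= 0))
    stop("'extent' must be positive c(x, y) and 'voxel' positive c(dx,dy,dz)",
         call. = FALSE)

  nx <- max(2L, round(extent[1] / voxel[1]))
  ny <- max(2L, round(extent[2] / voxel[2]))
  nz <- max(2L, round(slab / voxel[3]))
  xs <- (seq_len(nx) - 0.5) * voxel[1]
  ys <- (seq_len(ny) - 0.5) * voxel[2]
  zs <- (seq_len(nz) - 0.5) * voxel[3]

  with_seed(seed, {
    ## -- plaque truth ----------------------------------------------------
    n_plaques <- if (fx$mode == "areal") {
      rpois(1L, fx$density * prod(extent) / 1e6)
    } else {
      rpois(1L, fx$density * prod(extent) * slab / 1e9)
    }
    truth <- draw_plaques(fx, n_plaques, extent, slab)

    ## -- base tissue -----------------------------------------------------
    ## multiplicative parenchymal texture: truncated lognormal, mean 1
    tex <- rlnorm(nx * ny * nz, -fx$texture_sd^2 / 2, fx$texture_sd)
    tex <- clamp(tex, 0.45, 2.2)
    tex <- tex / mean(tex)
    rel <- array(1, dim = c(nx, ny, nz))       # backscatter multiplier
    att <- array(fx$parenchyma_attenuation, dim = c(nx, ny, nz))
    lab <- array(1L, dim = c(nx, ny, nz))      # 1 = parenchyma

    paint_sphere <- function(cx, cy, cz, r, mult, mu, code, edge) {
      ix <- which(abs(xs - cx) <= r + edge)
      iy <- which(abs(ys - cy) <= r + edge)
      iz <- which(abs(zs - cz) <= r + edge)
      if (!length(ix) || !length(iy) || !length(iz)) return(0)
      dx2 <- (xs[ix] - cx)^2
      dy2 <- (ys[iy] - cy)^2
      dz2 <- (zs[iz] - cz)^2
      d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
      cov <- clamp((r - d) / edge + 0.5, 0, 1)
      sub <- rel[ix, iy, iz, drop = FALSE]
      rel[ix, iy, iz] <<- sub * (1 - cov) + mult * cov
      suba <- att[ix, iy, iz, drop = FALSE]
      att[ix, iy, iz] <<- suba * (1 - cov) + mu * cov
      subl <- lab[ix, iy, iz, drop = FALSE]
      subl[cov >= 0.9] <- code
      lab[ix, iy, iz] <<- subl
      sum(cov) * prod(voxel)
    }

    ## -- fibers (painted first so plaques sit on top) ---------------------
    if ((fx$fibers %||% 0) > 0) {
      for (f in seq_len(fx$fibers)) {
        th <- runif(1, 0, pi)
        x0 <- runif(1, 0, extent[1]); y0 <- runif(1, 0, extent[2])
        z0 <- runif(1, 0.3 * slab, 0.9 * slab)
        rf <- runif(1, 8, 15)
        ## perpendicular in-plane distance to the tract axis
        dperp <- abs(outer(xs - x0, rep(1, ny)) * sin(th) -
                     outer(rep(1, nx), ys - y0) * cos(th))
        for (k in seq_len(nz)) {
          d <- sqrt(dperp^2 + (zs[k] - z0)^2)
          cov <- clamp((rf - d) / fx$edge_um + 0.5, 0, 1)
          if (!any(cov > 0)) next
          rel[, , k] <- rel[, , k] * (1 - cov) + 3.0 * cov
          att[, , k] <- att[, , k] * (1 - cov) + 10 * cov
          lk <- lab[, , k]; lk[cov >= 0.9] <- 3L; lab[, , k] <- lk
        }
      }
    }

    ## -- vessel with CAA wall deposits ------------------------------------
    if (isTRUE(fx$vessel)) {
      vx <- extent[1] / 2; vy <- extent[2] / 2
      r_lumen <- 40; r_wall <- 55
      dxy <- sqrt(outer((xs - vx)^2, (ys - vy)^2, "+"))
      ang <- atan2(outer(rep(1, nx), ys - vy), outer(xs - vx, rep(1, ny)))
      n_seg <- 6L
      seg_on <- runif(n_seg) < 0.5
      seg_id <- pmin(floor((ang + pi) / (2 * pi) * n_seg) + 1L, n_seg)
      lum <- clamp((r_lumen - dxy) / fx$edge_um + 0.5, 0, 1)
      wall <- clamp((r_wall - dxy) / fx$edge_um + 0.5, 0, 1) * (1 - lum)
      dep2d <- wall * (dxy >= r_lumen + 2) * (dxy <= r_wall - 3) *
        seg_on[seg_id]
      for (k in seq_len(nz)) {
        rel[, , k] <- rel[, , k] * (1 - lum - wall) + 0.05 * lum +
          1.2 * wall
        att[, , k] <- att[, , k] * (1 - lum - wall) + 0.5 * lum + 5 * wall
        rel[, , k] <- rel[, , k] * (1 - dep2d) + 3.5 * dep2d
        att[, , k] <- att[, , k] * (1 - dep2d) + 8 * dep2d
        lk <- lab[, , k]
        lk[lum >= 0.9] <- 4L
        lk[dep2d >= 0.9] <- 5L
        lab[, , k] <- lk
      }
    }

    ## -- cell bodies -------------------------------------------------------
    if (isTRUE(fx$cells) && fx$cell_density_mm3 > 0) {
      n_cells <- rpois(1L, fx$cell_density_mm3 * prod(extent) * slab / 1e9)
      if (n_cells > 0) {
        cxy <- cbind(runif(n_cells, 0, extent[1]),
                     runif(n_cells, 0, extent[2]))
        cd <- clamp(rnorm(n_cells, 8, 1.2), 5, 12)
        cz <- runif(n_cells, cd / 2 + 1, slab - cd / 2 - 1)
        for (i in seq_len(n_cells)) {
          if (nrow(truth) &&
              any(sqrt((truth$x_um - cxy[i, 1])^2 +
                       (truth$y_um - cxy[i, 2])^2 +
                       (truth$z_um - cz[i])^2) <
                  truth$diameter_um / 2 + cd[i] / 2 + 1)) next
          paint_sphere(cxy[i, 1], cxy[i, 2], cz[i], cd[i] / 2,
                       fx$cell_backscatter, fx$cell_attenuation, 6L,
                       fx$edge_um)
        }
      }
    }

    ## -- plaques (last: nothing overwrites them) ---------------------------
    if (nrow(truth)) {
      vols <- numeric(nrow(truth))
      for (i in seq_len(nrow(truth))) {
        vols[i] <- paint_sphere(truth$x_um[i], truth$y_um[i], truth$z_um[i],
                                truth$diameter_um[i] / 2,
                                fx$plaque_backscatter,
                                fx$plaque_attenuation, 2L, fx$edge_um)
      }
      truth$volume_um3 <- vols
    }

    backscatter <- fx$parenchyma_backscatter * rel *
      array(tex, dim = c(nx, ny, nz))

    ## -- surface height ----------------------------------------------------
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    surf <- fx$surface_height + fx$surface_ripple *
      outer(sin(2 * pi * xs / fx$surface_period + ph1),
            sin(2 * pi * ys / fx$surface_period + ph2))

    levels <- c(background = 0L, parenchyma = 1L, plaque = 2L, fiber = 3L,
                vessel_lumen = 4L, caa_deposit = 5L, cell = 6L)
    attr(lab, "levels") <- levels
    structure(list(backscatter = backscatter, attenuation = att,
                   labels = lab, surface_height = surf,
                   plaque_truth = truth, voxel = voxel, extent = extent,
                   slab = slab, fixture = fx, seed = seed),
              class = "phantom")
  })
}

## Draw plaque centres and diameters: truncated lognormal sizes,
## dart-throwing placement that forbids sphere overlap (the Poisson count
## is preserved; a candidate that cannot be placed after many retries is
## accepted at its last position).
draw_plaques <- function(fx, n, extent, slab) {
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), diameter_um = numeric(0),
                      volume_um3 = numeric(0))
  if (n <= 0) return(empty)
  dr <- fx$diameter_range
  draw_d <- function(m) {
    if (fx$mode == "volumetric" && !is.null(fx$volume_mean_um3)) {
      mu <- fx$volume_mean_um3; s <- fx$volume_sd_um3
      sdl <- sqrt(log(1 + (s / mu)^2))
      mnl <- log(mu) - sdl^2 / 2
      v <- rlnorm(m, mnl, sdl)
      (6 * v / pi)^(1 / 3)
    } else {
      rlnorm(m, fx$diameter_meanlog, fx$diameter_sdlog)
    }
  }
  d <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {            # rejection sampling onto [dr1, dr2]
    cand <- draw_d(length(need))
    ok <- cand >= dr[1] & cand <= dr[2]
    d[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  for (i in seq_len(n)) {
    r <- d[i] / 2
    if (fx$mode == "areal" && !any(is.na(fx$depth_range))) {
      lo <- max(fx$depth_range[1], r + 1)
      hi <- min(fx$depth_range[2], slab - r - 1)
    } else {
      ## volumetric morphometry: spheres fully interior, clear of the
      ## surface transition and of the slab bottom
      lo <- r + 5; hi <- slab - r - 5
    }
    if (hi < lo) { lo <- hi <- clamp(mean(fx$depth_range %||% c(lo, hi),
                                          na.rm = TRUE), r, slab - r) }
    for (try in seq_len(100L)) {
      xi <- runif(1, 0, extent[1]); yi <- runif(1, 0, extent[2])
      zi <- runif(1, lo, hi)
      if (i == 1L) break
      j <- seq_len(i - 1L)
      if (all(sqrt((x[j] - xi)^2 + (y[j] - yi)^2 + (z[j] - zi)^2) >
              (d[j] + d[i]) / 2 + 1)) break
    }
    x[i] <- xi; y[i] <- yi; z[i] <- zi
  }
  data.frame(id = seq_len(n), x_um = x, y_um = y, z_um = z,
             diameter_um = d, volume_um3 = pi / 6 * d^3)
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$backscatter)
  cat(sprintf(
    "phantom '%s': %g x %g um x %g um slab (%d x %d x %d voxels), %d plaques\n",
    x$fixture$name %||% "<custom>", x$extent[1], x$extent[2], x$slab,
    d[1], d[2], d[3], nrow(x$plaque_truth)))
  invisible(x)
}

#' En-face projection of phantom backscatter truth
#'
#' Mean backscatter over a depth window below the slab top, straight from
#' the phantom (no interferometric simulation). Useful as a fast stand-in
#' image for segmentation property checks and as a visual ground truth.
#'
#' @param phantom a [build_phantom()] object.
#' @param offset,thickness depth window below the slab top, um.
#' @return An `enface_image` (see [enface_projection()]).
#' @export
phantom_enface <- function(phantom, offset = 0, thickness = 50) {
  zs <- (seq_len(dim(phantom$backscatter)[3]) - 0.5) * phantom$voxel[3]
  sel <- zs >= offset & zs < offset + thickness
  if (!any(sel)) stop("depth window outside the slab", call. = FALSE)
  vals <- apply(phantom$backscatter[, , sel, drop = FALSE], c(1, 2), mean)
  structure(list(values = vals,
                 pixel_spacing = phantom$voxel[1:2],
                 window_offset = offset, window_thickness = thickness,
                 projection_mode = "mean-linear"),
            class = "enface_image")
}
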