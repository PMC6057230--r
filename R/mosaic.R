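#' Plan a mosaic of overlapping tiles
#'
#' Covers a square area of side `side_length` with square tiles of field
#' of view `tile_fov` at a given overlap fraction. The tile pitch is
#' `tile_fov * (1 - overlap_fraction)`, the number of tiles per side is
#' `ceil((side_length - tile_fov) / pitch) + 1`, and the grid is centred
#' on the requested area, so the union of tiles covers it without gaps.
#' A 2.5-mm side with 0.5-mm tiles gives a 7 x 7 = 49-tile grid at
#' one-third overlap and a 6 x 6 = 36-tile grid at 0.2 overlap.
#'
#' @param side_length side of the square area, mm.
#' @param tile_fov tile field of view, mm.
#' @param overlap_fraction fractional overlap between neighbours, in
#'   [0, 1).
#' @return A `mosaic_plan`: `tile_fov_um`, `overlap_fraction`, `pitch_um`,
#'   `grid` (`c(nx, ny)`), `tile_centers` (data frame, um) and
#'   `tile_origins` (lower-left corners, um, relative to the area's
#'   lower-left corner at 0).
#' @examples
#' plan_mosaic(2.5, 0.5, 1/3)$grid   # 7 x 7
#' plan_mosaic(2.5, 0.5, 0.2)$grid   # 6 x 6
#' @export
plan_mosaic <- function(side_length, tile_fov, overlap_fraction) {
  stopifnot_scalar_num(side_length, "side_length", lower = 1e-9)
  stopifnot_scalar_num(tile_fov, "tile_fov", lower = 1e-9)
  stopifnot_scalar_num(overlap_fraction, "overlap_fraction", lower = 0,
                       upper = 1 - 1e-9)
  if (tile_fov > side_length + 1e-12)
    stop("'tile_fov' must not exceed 'side_length'", call. = FALSE)
  pitch <- tile_fov * (1 - overlap_fraction)
  n_side <- if (side_length <= tile_fov + 1e-12) 1L else
    as.integer(ceiling((side_length - tile_fov) / pitch - 1e-9)) + 1L
  span <- tile_fov + (n_side - 1L) * pitch
  start <- (side_length - span) / 2          # centre the grid on the area
  orig <- (start + (seq_len(n_side) - 1L) * pitch) * 1000
  centers <- orig + tile_fov * 500
  grid <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side))
  structure(list(tile_fov_um = tile_fov * 1000,
                 overlap_fraction = overlap_fraction,
                 pitch_um = pitch * 1000,
                 side_length_um = side_length * 1000,
                 grid = c(nx = n_side, ny = n_side),
                 tile_centers = data.frame(ix = grid$ix, iy = grid$iy,
                                           x_um = centers[grid$ix],
                                           y_um = centers[grid$iy]),
                 tile_origins = data.frame(ix = grid$ix, iy = grid$iy,
                                           x_um = orig[grid$ix],
                                           y_um = orig[grid$iy])),
            class = "mosaic_plan")
}

#' @export
print.mosaic_plan <- function(x, ...) {
  cat(sprintf(
    "mosaic_plan: %d x %d = %d tiles of %g um, overlap %.3f (pitch %g um)\n",
    x$grid[1], x$grid[2], nrow(x$tile_centers), x$tile_fov_um,
    x$overlap_fraction, x$pitch_um))
  invisible(x)
}

#' Stitch tiles into a mosaic
#'
#' Places tiles at their planned positions, optionally refining each
#' placement by translation registration against the already-placed
#' overlap region, and blends overlaps with linear distance-to-edge
#' weights. A refinement shift larger than the overlap width falls back
#' to the nominal position with a warning. Tiles are expected in the
#' row-major order of `plan$tile_origins`.
#'
#' @param tiles list of `enface_image`s or numeric matrices (equal size).
#' @param plan a [plan_mosaic()].
#' @param refine logical; register each tile against the mosaic so far.
#' @return A list: `mosaic` (numeric matrix), `pixel_um`, `shifts`
#'   (applied per-tile refinement shifts, px).
#' @export
stitch_tiles <- function(tiles, plan, refine = TRUE) {
  if (length(tiles) != nrow(plan$tile_origins))
    stop(sprintf("plan expects %d tiles, got %d",
                 nrow(plan$tile_origins), length(tiles)), call. = FALSE)
  mats <- lapply(tiles, function(t)
    if (inherits(t, "enface_image")) t$values else t)
  np <- nrow(mats[[1]])
  if (any(vapply(mats, function(m) any(dim(m) != dim(mats[[1]])), TRUE)))
    stop("all tiles must have identical dimensions", call. = FALSE)
  px <- plan$tile_fov_um / np                  # um per pixel
  n_out <- ceiling(plan$side_length_um / px)
  acc <- matrix(0, n_out, n_out)
  wacc <- matrix(0, n_out, n_out)
  ## linear ramp weights: distance to the nearest tile edge
  wi <- pmin(seq_len(np), rev(seq_len(np)))
  wt <- outer(wi, wi, pmin)
  overlap_px <- round((plan$tile_fov_um - plan$pitch_um) / px)
  shifts <- matrix(0, length(mats), 2)
  for (t in seq_along(mats)) {
    i0 <- round(plan$tile_origins$x_um[t] / px)
    j0 <- round(plan$tile_origins$y_um[t] / px)
    m <- mats[[t]]
    if (refine && t > 1L && overlap_px >= 4L) {
      ii <- (i0 + 1):(i0 + np); jj <- (j0 + 1):(j0 + np)
      sel <- ii >= 1 & ii <= n_out
      selj <- jj >= 1 & jj <= n_out
      placed <- matrix(0, np, np)
      placed[sel, selj] <- acc[ii[sel], jj[selj]] /
        pmax(wacc[ii[sel], jj[selj]], 1e-12)
      have <- matrix(FALSE, np, np)
      have[sel, selj] <- wacc[ii[sel], jj[selj]] > 0
      if (sum(have) > 0.02 * np * np && sd(placed[have]) > 0) {
        mm <- m; mm[!have] <- 0
        pp <- placed; pp[!have] <- 0
        sh <- tryCatch(register_translation(pp, mm,
                                            max_shift = overlap_px),
                       error = function(e) c(0, 0))
        if (max(abs(sh)) > overlap_px) {
          warning(sprintf(
            "tile %d: refinement shift (%.1f, %.1f) exceeds overlap; using nominal position",
            t, sh[1], sh[2]))
          sh <- c(0, 0)
        }
        sh <- round(sh)
        i0 <- i0 - sh[1]; j0 <- j0 - sh[2]
        shifts[t, ] <- -sh
      }
    }
    ii <- (i0 + 1):(i0 + np); jj <- (j0 + 1):(j0 + np)
    sel <- ii >= 1 & ii <= n_out; selj <- jj >= 1 & jj <= n_out
    acc[ii[sel], jj[selj]] <- acc[ii[sel], jj[selj]] +
      m[sel, selj] * wt[sel, selj]
    wacc[ii[sel], jj[selj]] <- wacc[ii[sel], jj[selj]] + wt[sel, selj]
  }
  mosaic <- acc / pmax(wacc, 1e-12)
  list(mosaic = mosaic, pixel_um = px, shifts = shifts)
}
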