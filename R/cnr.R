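#' Contrast-to-noise ratio of a plaque against its background
#'
#' `CNR = |mu_P - mu_B| / sqrt(var_P + var_B)`, with `mu_P`, `var_P` the
#' mean and variance of the linear intensity inside the plaque and
#' `mu_B`, `var_B` those of the surrounding parenchyma at the same depth.
#' The ratio is invariant under any affine intensity transform
#' `x -> a x + b` with `a > 0` applied to the whole volume.
#'
#' @param inputs a list or data frame with elements/columns `mu_p`,
#'   `mu_b`, `var_p`, `var_b` (vectorized).
#' @return numeric CNR value(s).
#' @examples
#' compute_cnr(list(mu_p = 10, mu_b = 4, var_p = 5, var_b = 4))  # 2
#' @export
compute_cnr <- function(inputs) {
  need <- c("mu_p", "mu_b", "var_p", "var_b")
  if (!all(need %in% names(inputs)))
    stop("'inputs' needs mu_p, mu_b, var_p, var_b", call. = FALSE)
  vp <- inputs$var_p; vb <- inputs$var_b
  if (any(vp < 0) || any(vb < 0))
    stop("variances must be non-negative", call. = FALSE)
  if (any(vp + vb == 0))
    stop("var_p + var_b must be positive (CNR undefined)", call. = FALSE)
  abs(inputs$mu_p - inputs$mu_b) / sqrt(vp + vb)
}

#' Sample plaque ROIs with depth-matched background annuli
#'
#' Draws `n` plaques without replacement from a 3-D segmentation and, for
#' each, collects the intensity statistics needed for [compute_cnr()]: the
#' plaque voxels, and a background annulus around the plaque restricted to
#' the plaque's own depth slab, excluding every segmented plaque voxel.
#' The annulus spans lateral radii `1.2 r` to `(1.2 + annulus_factor) r`
#' around the plaque centroid (`r` = equivalent radius).
#'
#' @param seg a `plaque_segmentation` from [segment_plaques()] on an
#'   `ocm_volume` (must carry the binned intensity volume).
#' @param n number of plaques to sample.
#' @param seed integer seed for the draw.
#' @param annulus_factor annulus width in units of the plaque radius.
#' @return A data frame (one row per ROI): id, mu_p, mu_b, var_p, var_b,
#'   cnr, z_min_um, z_max_um, n_bg.
#' @export
sample_plaque_rois <- function(seg, n, seed = NULL, annulus_factor = 2) {
  if (is.null(seg$intensity))
    stop("'seg' must come from segment_plaques() on an ocm_volume",
         call. = FALSE)
  tab <- seg$table
  if (n == 0) return(data.frame(id = integer(0), mu_p = numeric(0),
                                mu_b = numeric(0), var_p = numeric(0),
                                var_b = numeric(0), cnr = numeric(0),
                                z_min_um = numeric(0), z_max_um = numeric(0),
                                n_bg = integer(0)))
  if (nrow(tab) < n)
    stop(sprintf("requested %d plaques but only %d are segmented",
                 n, nrow(tab)), call. = FALSE)
  ids <- with_seed(seed, sample(tab$id, n))
  d <- dim(seg$labels)
  sp <- seg$spacing
  zb <- (seq_len(d[1]) - 0.5) * sp[1]
  xs <- (seq_len(d[2]) - 0.5) * sp[2]
  ys <- (seq_len(d[3]) - 0.5) * sp[3]
  out <- lapply(ids, function(id) {
    row <- tab[tab$id == id, ]
    vox <- seg$labels == id
    ivox <- seg$intensity[vox]
    iz <- which(zb >= row$z_min_um & zb <= row$z_max_um)
    r <- row$eq_diameter_um / 2
    r_in <- 1.2 * r; r_out <- r_in + annulus_factor * r
    dx2 <- (xs - row$x_um)^2
    dlat <- sqrt(outer(dx2, (ys - row$y_um)^2, "+"))
    ann2d <- dlat >= r_in & dlat <= r_out
    bg_sel <- array(FALSE, dim = d)
    bg_sel[iz, , ] <- rep(ann2d, each = length(iz))
    bg_sel <- bg_sel & seg$labels == 0L
    if (!is.null(seg$in_tissue)) bg_sel <- bg_sel & seg$in_tissue
    ibg <- seg$intensity[bg_sel]
    data.frame(id = id, mu_p = mean(ivox), mu_b = mean(ibg),
               var_p = if (length(ivox) > 1) var(ivox) else 0,
               var_b = if (length(ibg) > 1) var(ibg) else 0,
               z_min_um = row$z_min_um, z_max_um = row$z_max_um,
               n_bg = length(ibg))
  })
  out <- do.call(rbind, out)
  out$cnr <- compute_cnr(out)
  out[, c("id", "mu_p", "mu_b", "var_p", "var_b", "cnr",
          "z_min_um", "z_max_um", "n_bg")]
}
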