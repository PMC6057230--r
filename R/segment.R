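## ---- plaque segmentation and morphometry ------------------------------

## Connected-component labeling of a logical 2-D/3-D mask with full
## (8- or 26-) connectivity, via igraph components on the foreground
## adjacency graph. Labels are renumbered in order of first occurrence.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  nd <- length(d)
  coord <- arrayInd(fg, d)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  strides <- cumprod(c(1, d[-nd]))
  ei <- integer(0); ej <- integer(0)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    ok <- rep(TRUE, length(fg))
    for (kk in seq_len(nd))
      ok <- ok & coord[, kk] + off[kk] >= 1L & coord[, kk] + off[kk] <= d[kk]
    if (!any(ok)) next
    nb <- fg[ok] + sum(off * strides)
    pos <- findInterval(nb, fg)
    hit <- pos > 0L & fg[pmax(pos, 1L)] == nb
    ei <- c(ei, which(ok)[hit]); ej <- c(ej, pos[hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(ei)) g <- igraph::add_edges(g, rbind(ei, ej))
  memb <- igraph::components(g)$membership
  memb <- match(memb, unique(memb))   # stable order of first occurrence
  lab[fg] <- memb
  lab
}

#' Plaque morphometry from a label map
#'
#' Tabulates every labeled component: centroid (um), pixel/voxel count
#' scaled to area (2-D) or volume (3-D), equivalent diameter
#' (`2 sqrt(A / pi)` in 2-D; the equivalent-sphere diameter
#' `(6 V / pi)^(1/3)` in 3-D) and mean linear intensity.
#'
#' @param labels integer label array (2-D or 3-D), 0 = background.
#' @param spacing pixel/voxel spacing in um (length 2 or 3, matching
#'   `labels`; for volumes the order is `c(dz, dx, dy)` as in the
#'   reconstructed array layout).
#' @param intensity optional array of the same shape for mean intensities.
#' @param source provenance tag stored per row.
#' @return A `plaque_table` data frame with columns id, x_um, y_um, z_um,
#'   area_um2, eq_diameter_um, volume_um3, mean_intensity, source.
#' @export
plaque_morphometry <- function(labels, spacing, intensity = NULL,
                               source = "ocm-2d") {
  d <- dim(labels)
  nd <- length(d)
  if (length(spacing) != nd || any(spacing <= 0))
    stop("'spacing' must be positive and match the label array rank",
         call. = FALSE)
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), area_um2 = numeric(0),
                      eq_diameter_um = numeric(0), volume_um3 = numeric(0),
                      mean_intensity = numeric(0),
                      source = character(0))
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(structure(empty, class = c("plaque_table",
                                                      "data.frame")))
  fg <- which(labels > 0L)
  memb <- labels[fg]
  coord <- arrayInd(fg, d)
  counts <- tabulate(memb, nbins = max(ids))[ids]
  cent <- sapply(seq_len(nd), function(k)
    (tapply(coord[, k], memb, mean)[as.character(ids)] - 0.5) * spacing[k])
  cent <- matrix(cent, ncol = nd)
  mi <- if (!is.null(intensity))
    as.numeric(tapply(intensity[fg], memb, mean)[as.character(ids)])
  else rep(NA_real_, length(ids))
  unit <- prod(spacing)
  if (nd == 2L) {
    area <- counts * unit
    out <- data.frame(id = seq_along(ids), x_um = cent[, 1], y_um = cent[, 2],
                      z_um = NA_real_, area_um2 = area,
                      eq_diameter_um = 2 * sqrt(area / pi),
                      volume_um3 = NA_real_, mean_intensity = mi,
                      source = source)
  } else {
    vol <- counts * unit
    zmin <- (tapply(coord[, 1], memb, min)[as.character(ids)] - 1) * spacing[1]
    zmax <- tapply(coord[, 1], memb, max)[as.character(ids)] * spacing[1]
    out <- data.frame(id = seq_along(ids), x_um = cent[, 2], y_um = cent[, 3],
                      z_um = cent[, 1], area_um2 = NA_real_,
                      eq_diameter_um = (6 * vol / pi)^(1 / 3),
                      volume_um3 = vol, mean_intensity = mi,
                      source = source)
    out$z_min_um <- as.numeric(zmin)
    out$z_max_um <- as.numeric(zmax)
  }
  structure(out, class = c("plaque_table", "data.frame"), spacing = spacing)
}

seg_core <- function(img, spacing, threshold_sigmas, size_range, pre_smooth,
                     include = NULL, source = "ocm-2d",
                     diameter_mode = "threshold") {
  sm <- if (pre_smooth >= 1) box_smooth(img, as.integer(pre_smooth)) else img
  vals <- if (is.null(include)) as.numeric(sm) else sm[include]
  if (length(vals) < 100L)
    stop("too few background samples to estimate statistics", call. = FALSE)
  med <- median(vals); sig <- mad(vals)
  if (sig == 0) {
    warning("constant image: no plaques segmented")
    lab <- array(0L, dim = dim(img))
    return(list(labels = lab,
                table = plaque_morphometry(lab, spacing, source = source),
                threshold = med, background = c(median = med, sigma = 0)))
  }
  thr <- med + threshold_sigmas * sig
  mask <- sm > thr
  if (!is.null(include)) mask[!include] <- FALSE
  lab <- label_components(mask)
  tab <- plaque_morphometry(lab, spacing, intensity = img, source = source)
  if (diameter_mode == "halfmax" && nrow(tab)) {
    ## The en-face footprint of a spherical deposit follows its chord
    ## profile, whose full width at half maximum is sqrt(3)/2 of the true
    ## diameter regardless of how much the depth window dilutes the
    ## contrast. Sizing each component at its own half-contrast level and
    ## applying the spherical-chord factor therefore removes the
    ## depth-dependent shrinkage of the fixed global threshold.
    ids <- sort(unique(lab[lab > 0L]))
    fg <- which(lab > 0L)
    memb <- lab[fg]; v <- sm[fg]
    peak <- tapply(v, memb, quantile, probs = 0.98)
    lvl <- (med + peak) / 2                  # named by component id
    n_half <- tapply(v > lvl[as.character(memb)], memb, sum)
    area_fwhm <- as.numeric(n_half[as.character(ids)]) * prod(spacing)
    tab$area_um2 <- area_fwhm * 4 / 3
    tab$eq_diameter_um <- 2 * sqrt(tab$area_um2 / pi)
  }
  keep <- tab$eq_diameter_um >= size_range[1] &
    tab$eq_diameter_um <= size_range[2]
  drop_ids <- tab$id[!keep]
  if (length(drop_ids)) lab[lab %in% drop_ids] <- 0L
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab)) {
    lab <- array(match(lab, c(0L, tab$id)) - 1L, dim = dim(lab))
    tab$id <- seq_len(nrow(tab))
  }
  rownames(tab) <- NULL
  list(labels = lab, table = tab, threshold = thr,
       background = c(median = med, sigma = sig))
}

#' Segment hyperscattering plaques
#'
#' Robust-threshold segmentation: background statistics (median and MAD)
#' are estimated over the (lightly smoothed) image, pixels above
#' `median + threshold_sigmas * sigma` are kept, connected components are
#' labeled (8-connectivity in 2-D, 26-connectivity in 3-D) and components
#' whose equivalent diameter falls outside `size_range` are discarded.
#'
#' For reconstructed volumes the method masks everything above the
#' detected tissue surface, divides every depth plane by its in-tissue
#' median (compensating attenuation and roll-off with depth), and bins the
#' fine axial sampling to approximately `axial_target` before
#' thresholding, so that voxels are near-isotropic.
#'
#' @param x an `enface_image`, `ocm_volume`, matrix or 3-D array.
#' @param threshold_sigmas threshold above background in robust SDs.
#' @param size_range equivalent-diameter gate in um (default the 10--70 um
#'   range in which cortical plaques are observed).
#' @param pre_smooth box pre-smoothing half-width in pixels (0 disables).
#' @param spacing pixel spacing in um (matrices/arrays only).
#' @param ... passed to methods.
#' @return A `plaque_segmentation`: `labels` (integer array), `table`
#'   (a `plaque_table`), `threshold`, `background`, `spacing`, and for
#'   volumes `intensity` (binned linear intensity) plus `in_tissue` mask.
#' @export
segment_plaques <- function(x, threshold_sigmas = 3, size_range = c(10, 70),
                            pre_smooth = 1, ...) {
  UseMethod("segment_plaques")
}

#' @rdname segment_plaques
#' @param diameter_mode 2-D sizing convention: `"halfmax"` (default)
#'   reports the projected area from each component's footprint at its
#'   own half-contrast level with the spherical-chord correction factor
#'   4/3 on area, which is unbiased for spherical deposits however deep
#'   they sit in the projection window; `"threshold"` reports the raw
#'   supra-threshold footprint.
#' @export
segment_plaques.enface_image <- function(x, threshold_sigmas = 3,
                                         size_range = c(10, 70),
                                         pre_smooth = 1,
                                         diameter_mode = c("halfmax",
                                                           "threshold"),
                                         ...) {
  diameter_mode <- match.arg(diameter_mode)
  res <- seg_core(x$values, x$pixel_spacing, threshold_sigmas, size_range,
                  pre_smooth, source = "ocm-2d",
                  diameter_mode = diameter_mode)
  res$spacing <- x$pixel_spacing
  structure(res, class = "plaque_segmentation")
}

#' @rdname segment_plaques
#' @export
segment_plaques.matrix <- function(x, threshold_sigmas = 3,
                                   size_range = c(10, 70), pre_smooth = 1,
                                   spacing = c(1, 1),
                                   diameter_mode = c("halfmax",
                                                     "threshold"), ...) {
  diameter_mode <- match.arg(diameter_mode)
  res <- seg_core(x, spacing, threshold_sigmas, size_range, pre_smooth,
                  source = "ocm-2d", diameter_mode = diameter_mode)
  res$spacing <- spacing
  structure(res, class = "plaque_segmentation")
}

#' @rdname segment_plaques
#' @export
segment_plaques.array <- function(x, threshold_sigmas = 3,
                                  size_range = c(10, 70), pre_smooth = 1,
                                  spacing = c(1, 1, 1), ...) {
  res <- seg_core(x, spacing, threshold_sigmas, size_range, pre_smooth,
                  source = "ocm-3d")
  res$spacing <- spacing
  structure(res, class = "plaque_segmentation")
}

#' @rdname segment_plaques
#' @param surface optional precomputed [detect_surface()] map.
#' @param surface_margin um below the detected surface where segmentation
#'   starts (excludes the surface transition response).
#' @param axial_target target axial pitch in um after binning (default:
#'   half the lateral spacing).
#' @param depth_normalize divide every depth plane by its in-tissue median
#'   before thresholding; planes whose median does not clear the noise
#'   floor (times `tissue_snr_min`) are treated as beyond the tissue.
#' @param tissue_snr_min minimum plane-median-to-noise-floor ratio for a
#'   depth plane to count as tissue.
#' @param exclude_boundary drop components touching the axial limits of
#'   the tissue region (objects cut by the surface or by the bottom of
#'   the usable depth range cannot be measured).
#' @param boundary `"halfmax"` (default) refines every component's extent
#'   to the voxels above the level halfway between the local background
#'   and the component core before morphometry -- the full-width-half-
#'   maximum sizing convention, which removes the contrast dependence of
#'   a fixed detection threshold; `"threshold"` keeps the raw
#'   supra-threshold extent.
#' @export
segment_plaques.ocm_volume <- function(x, threshold_sigmas = 3,
                                       size_range = c(10, 70),
                                       pre_smooth = 0, surface = NULL,
                                       surface_margin = 4,
                                       axial_target = NULL,
                                       depth_normalize = TRUE,
                                       tissue_snr_min = 8,
                                       exclude_boundary = TRUE,
                                       boundary = c("halfmax", "threshold"),
                                       ...) {
  boundary <- match.arg(boundary)
  I <- ocm_intensity(x)
  d <- dim(I)
  dz <- x$axial_spacing_tissue
  if (is.null(surface)) surface <- detect_surface(x)
  if (is.null(axial_target)) axial_target <- min(x$lateral_spacing) / 2
  f <- max(1L, round(axial_target / dz))
  nzb <- d[1] %/% f
  ## bin axially by mean
  Ib <- array(colMeans(matrix(I[seq_len(nzb * f), , ], nrow = f)),
              dim = c(nzb, d[2], d[3]))
  dzb <- dz * f
  ## in-tissue mask: below surface + margin, above the depth where the
  ## signal sinks into the noise floor
  zb <- (seq_len(nzb) - 0.5) * dzb
  surf <- rep(as.numeric(surface) + surface_margin, each = nzb)
  in_tissue <- array(zb > surf, dim = c(nzb, d[2], d[3]))
  Imat <- matrix(Ib, nrow = nzb)
  Tmat <- matrix(in_tissue, nrow = nzb)
  plane_med <- rep(NA_real_, nzb)
  for (i in seq_len(nzb)) {
    v <- Imat[i, Tmat[i, ]]
    if (length(v) >= 50L) plane_med[i] <- median(v)
  }
  floor_med <- max(x$noise_floor$median, .Machine$double.xmin)
  valid_plane <- !is.na(plane_med) &
    plane_med > tissue_snr_min * floor_med
  ## the slab bottom announces itself as a cliff in the plane medians
  ## (attenuation alone cannot drop the signal several-fold within one
  ## binned plane); everything below the cliff is edge leakage, not
  ## tissue
  iv <- which(valid_plane)
  if (length(iv) > 3L) {
    r <- plane_med[iv[-1]] / plane_med[iv[-length(iv)]]
    cliff <- which(r < 1 / 3)
    if (length(cliff))
      valid_plane[iv[(cliff[1] + 1L)]:nzb] <- FALSE
  }
  in_tissue[!valid_plane, , ] <- FALSE
  if (depth_normalize) {
    for (i in which(valid_plane))
      if (plane_med[i] > 0) Imat[i, ] <- Imat[i, ] / plane_med[i]
    Iw <- array(Imat, dim = dim(Ib))
  } else Iw <- Ib
  spacing <- c(dzb, x$lateral_spacing)
  res <- seg_core(Iw, spacing, threshold_sigmas, size_range, pre_smooth,
                  include = in_tissue, source = "ocm-3d")
  if (boundary == "halfmax" && nrow(res$table)) {
    lab <- res$labels
    fg <- which(lab > 0L)
    vals <- Iw[fg]; memb <- lab[fg]
    core <- tapply(vals, memb, quantile, probs = 0.8)
    bgm <- if (depth_normalize) 1 else unname(res$background["median"])
    ## the point spread function blurs the backscattered field, so the
    ## unbiased half-maximum sits halfway up the amplitude profile:
    ## in intensity that is ((sqrt(bg) + sqrt(core)) / 2)^2
    thr_c <- pmax(((sqrt(bgm) + sqrt(core)) / 2)^2, res$threshold)
    thr_vox <- thr_c[match(memb, as.numeric(names(thr_c)))]
    lab[fg[vals <= thr_vox]] <- 0L
    tab <- plaque_morphometry(lab, spacing, intensity = Iw,
                              source = "ocm-3d")
    orig_ids <- sort(unique(lab[lab > 0L]))
    keep <- tab$eq_diameter_um >= size_range[1] &
      tab$eq_diameter_um <= size_range[2]
    keep_orig <- orig_ids[keep]
    lab[!(lab %in% keep_orig)] <- 0L
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab)) {
      lab <- array(match(lab, c(0L, keep_orig)) - 1L, dim = dim(lab))
      tab$id <- seq_len(nrow(tab))
    }
    rownames(tab) <- NULL
    res$labels <- lab
    res$table <- tab
  }
  if (exclude_boundary && nrow(res$table)) {
    ## a voxel whose axial neighbour is outside the tissue mask marks a
    ## cut object
    below <- in_tissue[c(1L, seq_len(nzb - 1L)), , , drop = FALSE]
    above <- in_tissue[c(seq_len(nzb - 1L) + 1L, nzb), , , drop = FALSE]
    border <- in_tissue & (!below | !above)
    ## the array edges themselves are boundaries
    border[1L, , ] <- in_tissue[1L, , ]
    border[nzb, , ] <- in_tissue[nzb, , ]
    cut_ids <- setdiff(unique(res$labels[border]), 0L)
    if (length(cut_ids)) {
      res$labels[res$labels %in% cut_ids] <- 0L
      res$table <- res$table[!res$table$id %in% cut_ids, , drop = FALSE]
      if (nrow(res$table)) {
        res$labels <- array(match(res$labels, c(0L, res$table$id)) - 1L,
                            dim = dim(res$labels))
        res$table$id <- seq_len(nrow(res$table))
      }
      rownames(res$table) <- NULL
    }
  }
  res$spacing <- spacing
  res$intensity <- Ib
  res$in_tissue <- in_tissue
  res$surface <- surface
  structure(res, class = "plaque_segmentation")
}

#' @export
print.plaque_segmentation <- function(x, ...) {
  cat(sprintf("plaque_segmentation: %d components (threshold %.3g)\n",
              nrow(x$table), x$threshold))
  invisible(x)
}

#' Plaque load
#'
#' Plaque count per unit area (2-D, plaques/mm2) or volume (3-D,
#' plaques/mm3). Returned unrounded; round at the reporting layer.
#'
#' @param table a `plaque_table` (or anything with rows).
#' @param extent area in mm2 or volume in mm3 (> 0).
#' @return count / extent.
#' @examples
#' plaque_load(data.frame(id = 1:230), extent = 10)  # 23 per mm2
#' @export
plaque_load <- function(table, extent) {
  stopifnot_scalar_num(extent, "extent", lower = .Machine$double.xmin)
  nrow(table) / extent
}
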