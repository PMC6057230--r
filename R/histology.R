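## ---- synthetic immunohistochemistry -----------------------------------

#' Standard hematoxylin / DAB stain vectors
#'
#' Unit-norm optical-density vectors (rows) for hematoxylin and DAB, the
#' widely used values for brightfield H-DAB unmixing.
#'
#' @return 2 x 3 matrix with rownames `hematoxylin`, `dab`.
#' @export
hdab_stain_vectors <- function() {
  m <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
             dab = c(0.268, 0.570, 0.776))
  m / sqrt(rowSums(m^2))
}

#' Render a matched synthetic histology stack
#'
#' Produces RGB slides emulating anti-amyloid DAB immunohistochemistry
#' with hematoxylin counterstain on thin sections through the phantom:
#' plaque cross-sections (analytic circles from the truth spheres) carry
#' DAB optical density, scattered nuclei and a faint background carry
#' hematoxylin, and the RGB image follows Beer-Lambert transmission
#' through the stain matrix. Sections are cut every
#' `(slice_gap + 1) * slice_thickness` um of depth (default every third
#' 3-um section, so five slides span 45 um, matching the 50-um en-face
#' window). Each slide gets an independent rigid translation jitter to
#' exercise registration; truth masks are returned jittered identically.
#'
#' @param phantom a [build_phantom()] object.
#' @param n_slices number of slides.
#' @param slice_thickness section thickness in um.
#' @param slice_gap number of skipped sections between used ones.
#' @param depth_offset depth of the first section below the slab top, um.
#' @param matched_window depth (um) of the OCM en-face window the stack
#'   must stay within (checked as a precondition).
#' @param pixel_um slide pixel size in um.
#' @param jitter_px maximum |rigid jitter| per slide, in pixels.
#' @param dab_od peak DAB optical density inside plaques.
#' @param hema_od background hematoxylin optical density.
#' @param nuclei_density_mm2 areal density of stained nuclei.
#' @param seed integer seed for jitter, nuclei and noise.
#' @return A `histology_stack`: `slides` (list of H x W x 3 arrays in
#'   [0, 1]), `masks` (list of logical truth masks), `offsets` (data frame
#'   of the applied jitters, px), `slice_z` (um), `pixel_um`,
#'   `slice_thickness`, `stain_vectors`.
#' @export
render_histology_stack <- function(phantom, n_slices = 5,
                                   slice_thickness = 3, slice_gap = 2,
                                   depth_offset = 0, matched_window = 50,
                                   pixel_um = phantom$voxel[1],
                                   jitter_px = 3, dab_od = 0.9,
                                   hema_od = 0.15,
                                   nuclei_density_mm2 = 400, seed = NULL) {
  if (n_slices <= 0) stop("'n_slices' must be positive", call. = FALSE)
  pitch <- (slice_gap + 1) * slice_thickness
  if (depth_offset + n_slices * pitch > matched_window + 1e-9)
    stop(sprintf(
      "%d slices at pitch %g um exceed the %g-um matched en-face window",
      n_slices, pitch, matched_window), call. = FALSE)
  nxp <- max(2L, round(phantom$extent[1] / pixel_um))
  nyp <- max(2L, round(phantom$extent[2] / pixel_um))
  xs <- (seq_len(nxp) - 0.5) * pixel_um
  ys <- (seq_len(nyp) - 0.5) * pixel_um
  M <- hdab_stain_vectors()
  truth <- phantom$plaque_truth
  slice_z <- depth_offset + slice_thickness / 2 + (seq_len(n_slices) - 1) *
    pitch
  with_seed(seed, {
    offsets <- data.frame(slice = seq_len(n_slices),
                          dx = sample(-jitter_px:jitter_px, n_slices,
                                      replace = TRUE),
                          dy = sample(-jitter_px:jitter_px, n_slices,
                                      replace = TRUE))
    slides <- vector("list", n_slices)
    masks <- vector("list", n_slices)
    for (s in seq_len(n_slices)) {
      z <- slice_z[s]
      dabmap <- matrix(0, nxp, nyp)
      mask <- matrix(FALSE, nxp, nyp)
      if (nrow(truth)) {
        for (i in seq_len(nrow(truth))) {
          dzc <- z - truth$z_um[i]
          r2 <- (truth$diameter_um[i] / 2)^2 - dzc^2
          if (r2 <= 0) next
          rc <- sqrt(r2)                     # cross-section radius
          ix <- which(abs(xs - truth$x_um[i]) <= rc + pixel_um)
          iy <- which(abs(ys - truth$y_um[i]) <= rc + pixel_um)
          if (!length(ix) || !length(iy)) next
          dlat <- sqrt(outer((xs[ix] - truth$x_um[i])^2,
                             (ys[iy] - truth$y_um[i])^2, "+"))
          cov <- clamp((rc - dlat) / pixel_um + 0.5, 0, 1)
          dabmap[ix, iy] <- pmax(dabmap[ix, iy], dab_od * cov)
          mask[ix, iy] <- mask[ix, iy] | cov >= 0.5
        }
      }
      ## hematoxylin: faint background plus nuclei
      hem <- matrix(hema_od, nxp, nyp)
      n_nuc <- rpois(1L, nuclei_density_mm2 * prod(phantom$extent) / 1e6)
      if (n_nuc > 0) {
        nx0 <- runif(n_nuc, 0, phantom$extent[1])
        ny0 <- runif(n_nuc, 0, phantom$extent[2])
        nr <- runif(n_nuc, 2.5, 4.5)
        for (i in seq_len(n_nuc)) {
          ix <- which(abs(xs - nx0[i]) <= nr[i] + pixel_um)
          iy <- which(abs(ys - ny0[i]) <= nr[i] + pixel_um)
          if (!length(ix) || !length(iy)) next
          dlat <- sqrt(outer((xs[ix] - nx0[i])^2, (ys[iy] - ny0[i])^2, "+"))
          cov <- clamp((nr[i] - dlat) / pixel_um + 0.5, 0, 1)
          hem[ix, iy] <- hem[ix, iy] + 0.6 * cov
        }
      }
      ## rigid jitter (same shift for slide and truth mask)
      dabmap <- shift_matrix(dabmap, offsets$dx[s], offsets$dy[s])
      hem <- shift_matrix(hem, offsets$dx[s], offsets$dy[s], fill = hema_od)
      mask <- shift_matrix(mask, offsets$dx[s], offsets$dy[s], fill = FALSE)
      od <- array(0, dim = c(nxp, nyp, 3))
      for (cch in 1:3)
        od[, , cch] <- hem * M["hematoxylin", cch] + dabmap * M["dab", cch]
      rgb <- 10^(-od)
      rgb <- rgb * array(clamp(rnorm(length(rgb), 1, 0.01), 0.9, 1.1),
                         dim = dim(rgb))
      slides[[s]] <- clamp(rgb, 0, 1)
      masks[[s]] <- mask
    }
    structure(list(slides = slides, masks = masks, offsets = offsets,
                   slice_z = slice_z, pixel_um = pixel_um,
                   slice_thickness = slice_thickness,
                   stain_vectors = M),
              class = "histology_stack")
  })
}

## integer-pixel rigid translation with constant fill
shift_matrix <- function(m, dx, dy, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_i <- seq_len(nr) - dx; src_j <- seq_len(nc) - dy
  ok_i <- src_i >= 1 & src_i <= nr; ok_j <- src_j >= 1 & src_j <= nc
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

#' @export
print.histology_stack <- function(x, ...) {
  d <- dim(x$slides[[1]])
  cat(sprintf(
    "histology_stack: %d slides of %d x %d px (%g um/px) at z = %s um\n",
    length(x$slides), d[1], d[2], x$pixel_um,
    paste(round(x$slice_z, 1), collapse = ", ")))
  invisible(x)
}

#' Color deconvolution of a brightfield slide
#'
#' Converts RGB transmittance to optical density
#' (`OD = -log10(max(RGB, 1/255))`, with RGB scaled to [0, 1]) and
#' projects every pixel onto the stain basis by least squares; negative
#' concentrations are clipped at zero.
#'
#' @param slide H x W x 3 numeric array in [0, 1] (or 0--255).
#' @param stain_vectors rows of unit-norm stain OD vectors (default
#'   [hdab_stain_vectors()]).
#' @return H x W x n_stains array of per-stain optical densities, with the
#'   stain names in the third dimension names.
#' @export
color_deconvolve <- function(slide, stain_vectors = hdab_stain_vectors()) {
  if (length(dim(slide)) != 3L || dim(slide)[3] != 3L)
    stop("'slide' must be an H x W x 3 RGB array", call. = FALSE)
  if (max(slide) > 1.5) slide <- slide / 255
  M <- stain_vectors
  if (qr(M)$rank < nrow(M))
    stop("stain vectors are collinear", call. = FALSE)
  od <- -log10(pmax(slide, 1 / 255))
  d <- dim(od)
  odm <- matrix(od, ncol = 3L)                 # pixels x 3
  conc <- odm %*% t(M) %*% solve(M %*% t(M))   # least squares, pixels x n
  conc[conc < 0] <- 0
  out <- array(conc, dim = c(d[1], d[2], nrow(M)))
  dimnames(out) <- list(NULL, NULL, rownames(M))
  out
}

#' Rigid translation registration by cross-correlation
#'
#' Integer-pixel shift maximizing the circular cross-correlation of the
#' mean-subtracted images, refined to sub-pixel precision by quadratic
#' interpolation of the correlation peak. The returned shift `c(dx, dy)`
#' is the displacement of `moving` relative to `reference` (i.e.
#' translating `moving` by `-c(dx, dy)` aligns it).
#'
#' @param reference,moving numeric matrices of identical shape.
#' @param max_shift optional bound (px) on the plausible shift; the
#'   correlation peak is then searched only within it, which makes the
#'   registration robust for sparse images.
#' @return numeric `c(dx, dy)` in pixels.
#' @export
register_translation <- function(reference, moving, max_shift = NULL) {
  if (!all(dim(reference) == dim(moving)))
    stop("images must have identical shape", call. = FALSE)
  if (sd(reference) == 0 || sd(moving) == 0)
    stop("cannot register a constant image", call. = FALSE)
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  Fa <- fft(a); Fb <- fft(b)
  cc <- Re(fft(Fa * Conj(Fb), inverse = TRUE))
  if (!is.null(max_shift)) {
    ms <- as.integer(max_shift)
    allow_i <- unique(((c(-ms:ms)) %% nrow(cc)) + 1L)
    allow_j <- unique(((c(-ms:ms)) %% ncol(cc)) + 1L)
    mask <- matrix(-Inf, nrow(cc), ncol(cc))
    mask[allow_i, allow_j] <- 0
    cc <- cc + mask
  }
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(cc); nc <- ncol(cc)
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  di <- wrap(pk[1] - 1, nr); dj <- wrap(pk[2] - 1, nc)
  im <- ((pk[1] - 2) %% nr) + 1; ip <- (pk[1] %% nr) + 1
  jm <- ((pk[2] - 2) %% nc) + 1; jp <- (pk[2] %% nc) + 1
  off_i <- quad_peak_offset(cc[im, pk[2]], cc[pk[1], pk[2]], cc[ip, pk[2]])
  off_j <- quad_peak_offset(cc[pk[1], jm], cc[pk[1], pk[2]], cc[pk[1], jp])
  c(dx = -(di + off_i), dy = -(dj + off_j))
}

#' Segment a histology stack and pool the slides
#'
#' Registers every slide to the first (rigid translation on the DAB
#' optical-density channel), thresholds the DAB channel (Otsu by default),
#' OR-combines the per-slide binaries (a plaque appearing in several of
#' the thin sections is counted once), size-filters the union components
#' and tabulates them.
#'
#' @param stack a [render_histology_stack()] (or compatible list with
#'   `slides`, `pixel_um`, `stain_vectors`).
#' @param dab_threshold optical-density threshold; `NULL` for Otsu on the
#'   pooled DAB channel.
#' @param size_range equivalent-diameter gate in um.
#' @param content_min minimum peak DAB OD for a slide to carry
#'   registerable immunoreactivity; slides below it are kept at their
#'   nominal position.
#' @param max_shift largest plausible rigid shift in px; a larger
#'   recovered shift counts as a registration failure and excludes the
#'   slide.
#' @return A list: `union` (logical matrix), `table` (a `plaque_table`
#'   with `source = "histology"`), `labels`, `shifts` (per-slide recovered
#'   shifts), `dab_threshold`.
#' @export
segment_histology_stack <- function(stack, dab_threshold = NULL,
                                    size_range = c(10, 70),
                                    content_min = 0.1, max_shift = 16) {
  ns <- length(stack$slides)
  if (ns < 1L) stop("stack has no slides", call. = FALSE)
  dab <- lapply(stack$slides, function(s)
    color_deconvolve(s, stack$stain_vectors)[, , "dab"])
  shifts <- matrix(0, ns, 2)
  aligned <- dab
  ## chain registration on the DAB channel: each slide is registered to
  ## the nearest preceding slide that actually carries immunoreactivity
  ref <- NULL
  for (s in seq_len(ns)) {
    if (max(dab[[s]]) < content_min) next     # nothing to register
    if (is.null(ref)) { ref <- dab[[s]]; next }
    sh <- tryCatch(register_translation(ref, dab[[s]], max_shift = max_shift),
                   error = function(e) NULL)
    if (is.null(sh) || max(abs(sh)) > max_shift) {
      warning(sprintf("slide %d could not be registered; excluded", s))
      aligned[s] <- list(NULL)
      next
    }
    shifts[s, ] <- sh
    aligned[[s]] <- shift_matrix(dab[[s]], -round(sh[1]), -round(sh[2]))
    ref <- aligned[[s]]
  }
  aligned <- Filter(Negate(is.null), aligned)
  if (is.null(dab_threshold)) {
    pooled <- unlist(lapply(aligned, as.numeric))
    dab_threshold <- EBImage::otsu(matrix(pooled, ncol = 1),
                                   range = range(pooled), levels = 256)
  }
  union <- Reduce(`|`, lapply(aligned, function(m) m > dab_threshold))
  lab <- label_components(union)
  tab <- plaque_morphometry(lab, rep(stack$pixel_um, 2),
                            intensity = Reduce(`+`, aligned) / length(aligned),
                            source = "histology")
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
  list(union = union, table = tab, labels = lab, shifts = shifts,
       dab_threshold = as.numeric(dab_threshold))
}
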