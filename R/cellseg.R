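#' Segment cells from the wall channel by seeded 3D watershed
#'
#' The tissue mask is obtained by Otsu-thresholding the smoothed wall channel
#' and filling the enclosed cell interiors (background connected components
#' not reaching the image border). Seeds are the regional minima of the
#' h-minima transform of the smoothed wall intensity inside the tissue
#' (suppressing minima shallower than a fraction `h_frac` of the wall-channel
#' dynamic range, the standard over-segmentation guard), and cells are grown
#' by seeded watershed flooding. Labels are renumbered by centroid (z, y, x)
#' sort so repeated runs give identical volumes.
#'
#' @param stack an [image_stack()] with a `wall` channel.
#' @param h_frac h-minima depth as a fraction of the wall-channel dynamic
#'   range inside the tissue (default 0.1).
#' @param smooth_sigma Gaussian pre-smoothing sigma (micrometres); keep near
#'   the optical PSF width for crisp boundary placement, raise towards ~1
#'   for noisy stacks.
#' @return an object of class `cell_label_map`: list with `label_volume`
#'   (integer array, 0 = background), `cells` (data frame: `label`, centroid
#'   `x, y, z` in micrometres, `n_voxels`, `footprint_area` in square
#'   micrometres, `is_L1`), `spacing`, `origin`.
#' @export
segment_cells <- function(stack, h_frac = 0.1, smooth_sigma = 0.4) {
  wall <- stack_channel(stack, "wall")
  sp <- stack$spacing
  wsm <- gauss_smooth3d(wall, rep(smooth_sigma, 3), sp)
  wallmask <- wsm > otsu_threshold(wsm)
  if (!any(wallmask)) stop("empty tissue mask")
  # fill enclosed cell interiors: background components that neither touch
  # the border nor exceed a cell-scale size cap (a large enclosed void --
  # e.g. the space beneath a dome-shaped shell -- is not tissue)
  bg_lab <- .cc_label_3d(!wallmask)
  d <- dim(wallmask)
  border_labs <- unique(c(bg_lab[c(1, d[1]), , ], bg_lab[, c(1, d[2]), ],
                          bg_lab[, , c(1, d[3])]))
  border_labs <- border_labs[border_labs > 0]
  hole_sizes <- tabulate(bg_lab[bg_lab > 0])
  max_hole <- 0.01 * prod(d)
  fillable <- setdiff(which(hole_sizes <= max_hole), border_labs)
  tissue <- wallmask | (bg_lab > 0 & bg_lab %in% fillable)
  if (!any(tissue)) stop("empty tissue mask")

  rng <- range(wsm[tissue])
  h <- h_frac * diff(rng)
  recon <- .grey_reconstruct_erosion(wsm + h, wsm)
  # minima are taken over the full array, then restricted to the tissue:
  # restricting first would promote mask-boundary voxels to spurious minima
  seeds <- .regional_minima_3d(recon, array(TRUE, dim(recon)))
  seeds[!tissue] <- 0L
  lab <- .watershed_seeded_3d(wsm, seeds, tissue)
  lab <- relabel_by_centroid(lab)
  new_label_map(lab, stack)
}

relabel_by_centroid <- function(lab) {
  labs <- sort(unique(lab[lab > 0]))
  if (length(labs) == 0) return(lab)
  idx <- which(lab > 0)
  ijk <- arrayInd(idx, dim(lab))
  f <- factor(lab[idx], levels = labs)
  cx <- tapply(ijk[, 1], f, mean)
  cy <- tapply(ijk[, 2], f, mean)
  cz <- tapply(ijk[, 3], f, mean)
  ord <- order(round(cz, 6), round(cy, 6), round(cx, 6))
  lut <- integer(max(labs))
  lut[labs[ord]] <- seq_along(labs)
  out <- lab
  out[idx] <- lut[lab[idx]]
  out
}

new_label_map <- function(lab, stack_or_map) {
  sp <- stack_or_map$spacing
  org <- stack_or_map$origin
  labs <- sort(unique(lab[lab > 0]))
  if (length(labs) == 0) {
    cells <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0), n_voxels = integer(0),
                        footprint_area = numeric(0), is_L1 = logical(0))
    return(structure(list(label_volume = lab, cells = cells, spacing = sp,
                          origin = org), class = "cell_label_map"))
  }
  idx <- which(lab > 0)
  ijk <- arrayInd(idx, dim(lab))
  f <- factor(lab[idx], levels = labs)
  pos <- voxel_to_um(ijk, list(spacing = sp, origin = org))
  cells <- data.frame(label = labs,
                      x = as.numeric(tapply(pos[, 1], f, mean)),
                      y = as.numeric(tapply(pos[, 2], f, mean)),
                      z = as.numeric(tapply(pos[, 3], f, mean)),
                      n_voxels = as.integer(table(f)))
  fp <- project_labels(list(label_volume = lab))
  fp_counts <- table(factor(fp[fp > 0], levels = labs))
  cells$footprint_area <- as.numeric(fp_counts) * sp[1] * sp[2]
  cells$is_L1 <- NA
  structure(list(label_volume = lab, cells = cells, spacing = sp,
                 origin = org), class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("cell_label_map: %d cells, %s L1-flagged\n",
              nrow(x$cells),
              if (all(is.na(x$cells$is_L1))) "not yet"
              else sprintf("%d", sum(x$cells$is_L1))))
  invisible(x)
}

#' Top-down projection of a label volume
#'
#' Orthographic projection along the optical axis: each (x, y) column takes
#' the label of its topmost labelled voxel (0 where the column is empty).
#' Projected footprints are the basis of all 2D area, growth and
#' division-angle measurements.
#'
#' @param map a `cell_label_map` (or any list with `label_volume`).
#' @return integer matrix `[x, y]` of top-view labels.
#' @export
project_labels <- function(map) {
  lab <- map$label_volume
  d <- dim(lab)
  out <- matrix(0L, d[1], d[2])
  for (k in seq_len(d[3])) {       # ascending z: later (higher) wins
    sl <- lab[, , k]
    upd <- sl > 0L
    out[upd] <- sl[upd]
  }
  out
}

#' Flag L1 (epidermal) cells
#'
#' A cell belongs to the outermost layer when enough of its boundary shares
#' the outer tissue surface. "Outer" background is defined as background
#' visible from the objective side: voxels whose whole column above is also
#' background. This distinguishes the imaged surface from any unlabelled
#' space beneath the segmented shell (a convex dome shadows the latter).
#' L1 is then every cell whose interface area with outer background reaches
#' `min_area`.
#'
#' @param map a `cell_label_map`.
#' @param min_area minimal exposed area in square micrometres (default 3).
#' @return the map with `cells$is_L1` filled.
#' @export
extract_L1 <- function(map, min_area = 3) {
  lab <- map$label_volume
  d <- dim(lab)
  labs <- map$cells$label
  # outer background: background along an unobstructed line of sight from top
  outer <- array(FALSE, d)
  outer[, , d[3]] <- lab[, , d[3]] == 0L
  for (k in (d[3] - 1):1) outer[, , k] <- lab[, , k] == 0L & outer[, , k + 1]
  area <- rep(0, length(labs))
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  face <- c(map$spacing[2] * map$spacing[3], map$spacing[2] * map$spacing[3],
            map$spacing[1] * map$spacing[3], map$spacing[1] * map$spacing[3],
            map$spacing[1] * map$spacing[2], map$spacing[1] * map$spacing[2])
  for (i in seq_along(dirs)) {
    nb_outer <- shift3d(outer, -dirs[[i]], FALSE)
    exposed <- lab > 0L & nb_outer
    cnt <- table(factor(lab[exposed], levels = labs))
    area <- area + as.numeric(cnt) * face[i]
  }
  map$cells$is_L1 <- area >= min_area
  map
}

#' Triangulated outer surface with per-vertex and per-cell curvature
#'
#' Builds the outer tissue surface as a height map over the top-down plane
#' (one vertex per tissue column, grid triangulation), smooths it, and
#' computes the mean curvature of the height-map graph analytically from its
#' first and second derivatives. The sign convention makes a dome positive:
#' a spherical cap of radius R has curvature 1/R. Per-cell curvature averages
#' the vertices of the cell's footprint, skipping near-vertical rim vertices
#' (slope above ~63 degrees) where the height-map representation degenerates.
#'
#' @param map a `cell_label_map` with L1 flags (see [extract_L1()]).
#' @param smooth_sigma height-map smoothing sigma in micrometres.
#' @return an object of class `surface_mesh`: `vertices` (n x 3, um),
#'   `faces` (m x 3 vertex indices), `vertex_curvature` (1/um),
#'   `cell_curvature` (data frame `label`, `curvature`).
#' @export
estimate_curvature <- function(map, smooth_sigma = 4) {
  lab <- map$label_volume
  sp <- map$spacing
  d <- dim(lab)
  fp <- project_labels(map)
  hmap <- matrix(NA_real_, d[1], d[2])
  tis2d <- fp > 0L
  # topmost tissue voxel per column
  topk <- matrix(0L, d[1], d[2])
  for (k in seq_len(d[3])) {
    sl <- lab[, , k] > 0L
    topk[sl] <- k
  }
  hmap[tis2d] <- map$origin[3] + (topk[tis2d] - 1) * sp[3]
  if (!any(tis2d)) stop("no tissue")
  if (diff(range(hmap[tis2d])) < 2 * sp[3]) {
    warning("degenerate (flat) surface: zero curvature")
  }
  # normalised-convolution smoothing restricted to the footprint
  m <- tis2d * 1
  hz <- ifelse(tis2d, hmap, 0)
  sm <- gauss_smooth2d(hz, smooth_sigma, sp[1:2])
  wm <- gauss_smooth2d(m, smooth_sigma, sp[1:2])
  hs <- ifelse(wm > 1e-6, sm / wm, NA)

  zx <- central_diff(hs, 1, sp[1]); zy <- central_diff(hs, 2, sp[2])
  zxx <- central_diff(zx, 1, sp[1]); zyy <- central_diff(zy, 2, sp[2])
  zxy <- central_diff(zx, 2, sp[2])
  Hm <- -((1 + zy^2) * zxx - 2 * zx * zy * zxy + (1 + zx^2) * zyy) /
    (2 * (1 + zx^2 + zy^2)^1.5)
  slope2 <- zx^2 + zy^2
  valid <- tis2d & is.finite(Hm) & slope2 < 4

  vid <- matrix(0L, d[1], d[2])
  vij <- which(tis2d, arr.ind = TRUE)
  vid[vij] <- seq_len(nrow(vij))
  verts <- cbind(map$origin[1] + (vij[, 1] - 1) * sp[1],
                 map$origin[2] + (vij[, 2] - 1) * sp[2],
                 hmap[vij])
  vcurv <- Hm[vij]
  faces <- grid_triangles(vid)
  labs <- map$cells$label
  use_l1 <- !all(is.na(map$cells$is_L1))
  cellcurv <- data.frame(label = labs, curvature = NA_real_)
  fpv <- fp
  for (i in seq_along(labs)) {
    if (use_l1 && isFALSE(map$cells$is_L1[i])) next
    sel <- which(fpv == labs[i] & valid)
    if (length(sel) > 0) cellcurv$curvature[i] <- mean(Hm[sel])
  }
  structure(list(vertices = verts, faces = faces, vertex_curvature = vcurv,
                 cell_curvature = cellcurv),
            class = "surface_mesh")
}

gauss_smooth2d <- function(a, sigma_um, spacing) {
  d <- dim(a)
  sv <- sigma_um / spacing
  kern1 <- function(n, s) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  K <- outer(kern1(d[1], sv[1]), kern1(d[2], sv[2]))
  Re(fft(fft(a) * fft(K), inverse = TRUE)) / prod(d)
}

central_diff <- function(a, axis, h) {
  d <- dim(a)
  out <- matrix(NA_real_, d[1], d[2])
  if (axis == 1) {
    out[2:(d[1] - 1), ] <- (a[3:d[1], ] - a[1:(d[1] - 2), ]) / (2 * h)
  } else {
    out[, 2:(d[2] - 1)] <- (a[, 3:d[2]] - a[, 1:(d[2] - 2)]) / (2 * h)
  }
  out
}

grid_triangles <- function(vid) {
  d <- dim(vid)
  a <- vid[1:(d[1] - 1), 1:(d[2] - 1)]
  b <- vid[2:d[1], 1:(d[2] - 1)]
  cc <- vid[1:(d[1] - 1), 2:d[2]]
  dd <- vid[2:d[1], 2:d[2]]
  full <- a > 0 & b > 0 & cc > 0 & dd > 0
  rbind(cbind(a[full], b[full], dd[full]),
        cbind(a[full], dd[full], cc[full]))
}

#' Meristem radius from incipient-primordium annotations
#'
#' The meristem radius is the radius of the circle through the two incipient
#' primordia I1 and I2 centred on the geometrical centre of the meristem
#' surface: operationally, the mean of the planar (top-down projected)
#' distances from the centre to I1 and to I2.
#'
#' @param i1,i2 numeric length-2 (or 3; z ignored) annotation positions in
#'   micrometres.
#' @param center numeric length-2, expert-defined meristem centre; if `NULL`
#'   and `surface` is given, the centroid of the surface vertices projected
#'   to the top-down plane is used.
#' @param surface optional `surface_mesh` used to derive the centre.
#' @return radius in micrometres.
#' @export
measure_meristem_radius <- function(i1, i2, center = NULL, surface = NULL) {
  if (is.null(i1) || is.null(i2))
    stop("I1 and I2 annotations are required")
  if (is.null(center)) {
    if (is.null(surface)) stop("provide a center or a surface to derive it")
    center <- colMeans(surface$vertices[, 1:2, drop = FALSE])
  }
  d1 <- sqrt(sum((i1[1:2] - center[1:2])^2))
  d2 <- sqrt(sum((i2[1:2] - center[1:2])^2))
  (d1 + d2) / 2
}

#' Write a label map to disk (TIFF labels + CSV cell table)
#'
#' @param map a `cell_label_map`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_label_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- map$label_volume
  mx <- max(1L, max(lab))
  pages <- lapply(seq_len(dim(lab)[3]), function(k) t(lab[, , k]) / mx)
  tiff::writeTIFF(pages, file.path(dir, "labels.tif"), bits.per.sample = 32L)
  jsonlite::write_json(list(max_label = mx, spacing = map$spacing,
                            origin = map$origin),
                       file.path(dir, "labels.tif.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(map$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}
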