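#' Specification of a synthetic shoot apical meristem
#'
#' Builds the parameter object from which [generate_sam_stack()] and
#' [generate_timelapse()] render synthetic multi-channel meristem images with
#' full ground truth. The synthetic tissue is a dome-shaped L1 cell layer
#' (spherical cap, single shell of cells) tiled by a relaxed Voronoi
#' tessellation, with one nucleus per cell carrying stoichiometric two-channel
#' intensities that encode a spatial signaling field: the noiseless
#' sensor/reference intensity ratio of a nucleus equals `3 - S` where `S` is
#' the signaling value of the cell's region, so the analysis pipeline's
#' `3 - ratio` readout recovers the field exactly (a round-trip by
#' construction).
#'
#' Regions follow meristem anatomy: the central zone (CZ, a disc of radius
#' `cz_radius` at the summit), primordia (P, discs at stated azimuth and
#' radial distance whose radius grows with stage) and the inter-primordia
#' region (IPR, everything else in the periphery). The default signaling
#' field is high in the IPR, intermediate in the CZ and low in primordia.
#'
#' @param dome_radius dome (cap sphere) radius, micrometres.
#' @param voxel_spacing voxel spacing `(x, y, z)` in micrometres.
#' @param n_cells_L1 number of L1 cells tiling the dome.
#' @param cz_radius central-zone radius in micrometres (must be smaller than
#'   `dome_radius`).
#' @param primordia data frame with columns `azimuth_deg`, `distance_um`,
#'   `stage` (1 = youngest emerged primordium). A primordium is a disc of
#'   radius `4 + 1.5 * stage` micrometres at that position.
#' @param signaling_field named numeric, target signaling value in `[0, 3]`
#'   for regions `CZ`, `IPR`, `P`.
#' @param channel_gains named numeric `(sensor, reference)`: peak nucleus
#'   intensity scale per channel, arbitrary units. The stoichiometric
#'   `sensor/reference = 3 - S` identity holds when both gains are equal
#'   (the default); unequal gains rescale the measured ratio by their
#'   quotient, emulating an uncalibrated detector.
#' @param noise_sd additive Gaussian noise standard deviation, arbitrary
#'   units (0 disables).
#' @param poisson_noise logical, replace each noiseless voxel value by a
#'   Poisson draw with that mean (shot noise).
#' @param division_angle_params per-region circular distribution of division
#'   plane angles: named list with entries `CZ`, `IPR`, `P`, each
#'   `list(mode_deg =, kappa =)` for a von Mises law (mode measured from the
#'   radial direction; `kappa = 0` is uniform).
#' @param division_fraction fraction of cells dividing per frame interval.
#' @param growth_field named numeric, relative projected-area growth rate per
#'   hour for `CZ` and `IPR` (primordia share the peripheral rate; the
#'   growth transport map is radially symmetric).
#' @param wall_sigma Gaussian blur sigma (micrometres) applied to the
#'   rendered wall channel, emulating the microscope point-spread function.
#' @param anisotropic_stretch length-2 numeric: additional global linear
#'   stretch factors along image x and y applied per interval (1, 1 =
#'   isotropic). Sets the ground-truth growth anisotropy.
#' @param interval_h hours between consecutive frames.
#' @param l1_thickness L1 shell thickness in micrometres.
#' @param nucleus_sigma Gaussian nucleus blob sigma in micrometres.
#' @param interior `"none"` (hollow dome, default) or `"shell"` (a second
#'   cell layer beneath L1, for layer-extraction tests).
#' @param drift_translation,drift_rotation_deg maximal rigid drift between
#'   consecutive frames: translation (micrometres, per axis) and rotation
#'   about the optical axis (degrees). Actual drift is drawn uniformly
#'   within these bounds and recorded in the ground truth.
#' @param margin_um background margin around the dome, micrometres.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `sam_spec`.
#' @export
sam_spec <- function(dome_radius = 50,
                     voxel_spacing = c(1, 1, 1),
                     n_cells_L1 = 120,
                     cz_radius = 12,
                     primordia = data.frame(
                       azimuth_deg = (137.5 * (5:1)) %% 360,
                       distance_um = dome_radius * 0.78,
                       stage = 1:5),
                     signaling_field = c(CZ = 1.5, IPR = 2.5, P = 1.0),
                     channel_gains = c(sensor = 100, reference = 100),
                     noise_sd = 0,
                     poisson_noise = FALSE,
                     division_angle_params = list(
                       CZ = list(mode_deg = 90, kappa = 0),
                       IPR = list(mode_deg = 90, kappa = 4),
                       P = list(mode_deg = 90, kappa = 0)),
                     division_fraction = 0.15,
                     growth_field = c(CZ = 0.015, IPR = 0.035),
                     anisotropic_stretch = c(1, 1),
                     interval_h = 10,
                     l1_thickness = 6,
                     nucleus_sigma = 1.5,
                     wall_sigma = 0.5,
                     interior = c("none", "shell"),
                     drift_translation = 5,
                     drift_rotation_deg = 10,
                     margin_um = 6,
                     seed = 1L) {
  interior <- match.arg(interior)
  spec <- list(dome_radius = dome_radius, voxel_spacing = as.numeric(voxel_spacing),
               n_cells_L1 = as.integer(n_cells_L1), cz_radius = cz_radius,
               primordia = primordia, signaling_field = signaling_field,
               channel_gains = channel_gains, noise_sd = noise_sd,
               poisson_noise = poisson_noise,
               division_angle_params = division_angle_params,
               division_fraction = division_fraction,
               growth_field = growth_field,
               anisotropic_stretch = as.numeric(anisotropic_stretch),
               wall_sigma = wall_sigma,
               interval_h = interval_h, l1_thickness = l1_thickness,
               nucleus_sigma = nucleus_sigma, interior = interior,
               drift_translation = drift_translation,
               drift_rotation_deg = drift_rotation_deg,
               margin_um = margin_um, seed = as.integer(seed))
  class(spec) <- "sam_spec"
  validate_sam_spec(spec)
  spec
}

validate_sam_spec <- function(spec) {
  with(spec, {
    if (dome_radius <= 0 || cz_radius <= 0 || l1_thickness <= 0 ||
        nucleus_sigma <= 0 || margin_um <= 0 || interval_h <= 0)
      stop("all lengths and intervals must be positive")
    if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
    if (cz_radius >= dome_radius) stop("cz_radius must be < dome_radius")
    if (any(signaling_field < 0 | signaling_field > 3))
      stop("signaling_field values must lie in [0, 3]")
    if (!all(c("CZ", "IPR", "P") %in% names(signaling_field)))
      stop("signaling_field needs CZ, IPR and P entries")
    if (division_fraction < 0 || division_fraction > 1)
      stop("division_fraction must be in [0, 1]")
    # mean cell diameter (projected) must span >= ~3 voxels to be resolvable
    cell_diam <- 2 * sqrt((0.92 * dome_radius)^2 / n_cells_L1)
    if (cell_diam < 3 * max(voxel_spacing))
      stop(sprintf(
        "unresolvable spec: mean cell diameter %.2f um is below 3 voxels",
        cell_diam))
  })
  invisible(spec)
}

#' @export
print.sam_spec <- function(x, ...) {
  cat(sprintf(
    "sam_spec: dome R=%g um, %d L1 cells, CZ radius %g um, %d primordia\n",
    x$dome_radius, x$n_cells_L1, x$cz_radius, nrow(x$primordia)))
  cat(sprintf("  signaling field: CZ=%g IPR=%g P=%g; noise sd=%g; seed=%d\n",
              x$signaling_field["CZ"], x$signaling_field["IPR"],
              x$signaling_field["P"], x$noise_sd, x$seed))
  invisible(x)
}

# ---- circular angle utilities ------------------------------------------------

#' Fold an angle to the acute range [0, 90] degrees
#'
#' A division-plane orientation is a line, not a vector: angles are defined
#' modulo 180 degrees and only the acute angle to the reference axis is kept,
#' mapping a raw angle `theta` to `min(|theta| mod 180, 180 - |theta| mod 180)`.
#'
#' @param theta_deg numeric vector of raw angles in degrees (any sign).
#' @return angles in `[0, 90]` degrees.
#' @export
fold_angle <- function(theta_deg) {
  a <- abs(theta_deg) %% 180
  pmin(a, 180 - a)
}

# von Mises sampler (Best & Fisher rejection scheme); mu in radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  if (kappa > 1e6) return(rep(mu %% (2 * pi), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- stats::runif(1)
      i <- i + 1L
      out[i] <- (sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f))) + mu) %% (2 * pi)
    }
  }
  out
}

#' Sample division-plane angles for a region
#'
#' Draws raw orientations from the region's von Mises circular distribution
#' (mode measured from the radial axis) and folds them to the acute range.
#' Uses the current R RNG state; seed upstream for reproducibility.
#'
#' @param n number of draws.
#' @param params `list(mode_deg =, kappa =)`; `kappa = 0` gives a uniform
#'   orientation distribution, large `kappa` concentrates at the mode.
#' @return numeric vector of angles in `[0, 90]` degrees.
#' @export
sample_division_angle <- function(n, params) {
  stopifnot(params$kappa >= 0)
  raw <- rvonmises(n, params$mode_deg * pi / 180, params$kappa) * 180 / pi
  fold_angle(raw)
}

# ---- geometry helpers --------------------------------------------------------

# Region geometry: CZ disc + primordium discs in the top-down plane.
# Used both by the generator (ground truth) and the analysis (classify_region).
sam_geometry <- function(center, cz_radius, primordia_xy = NULL) {
  structure(list(center = as.numeric(center), cz_radius = cz_radius,
                 primordia = primordia_xy), class = "sam_geometry")
}

primordia_to_xy <- function(primordia, center) {
  if (is.null(primordia) || nrow(primordia) == 0) return(NULL)
  th <- primordia$azimuth_deg * pi / 180
  data.frame(x = center[1] + primordia$distance_um * cos(th),
             y = center[2] + primordia$distance_um * sin(th),
             radius = 4 + 1.5 * primordia$stage,
             stage = primordia$stage)
}

# relaxed 2D Voronoi seeds in a disc (Lloyd iterations against dense samples)
relaxed_disc_seeds <- function(n, radius, iters = 5, m_per_seed = 250) {
  m <- n * m_per_seed
  rr <- radius * sqrt(stats::runif(m))
  tt <- stats::runif(m, 0, 2 * pi)
  pts <- cbind(rr * cos(tt), rr * sin(tt))
  sel <- sample.int(m, n)
  seeds <- pts[sel, , drop = FALSE]
  for (it in seq_len(iters)) {
    assign <- nearest_seed(pts, seeds)
    for (s in seq_len(n)) {
      w <- assign == s
      if (any(w)) seeds[s, ] <- colMeans(pts[w, , drop = FALSE])
    }
  }
  seeds
}

# index of nearest seed for each row of pts (2 columns); loop over seeds
nearest_seed <- function(pts, seeds) {
  n <- nrow(pts)
  best <- rep.int(1L, n)
  bestd <- (pts[, 1] - seeds[1, 1])^2 + (pts[, 2] - seeds[1, 2])^2
  for (s in seq_len(nrow(seeds))[-1]) {
    d <- (pts[, 1] - seeds[s, 1])^2 + (pts[, 2] - seeds[s, 2])^2
    upd <- d < bestd
    best[upd] <- s
    bestd[upd] <- d[upd]
  }
  best
}

dome_surface_z <- function(rho, R) sqrt(pmax(R^2 - pmin(rho, R)^2, 0))

# ---- frame rendering ---------------------------------------------------------

# Render one frame given planar seeds (n x 2, in um relative to dome centre),
# per-seed region labels, dome radius and rigid placement.
# Returns stack, label volume and nucleus ground truth.
render_sam_frame <- function(spec, seeds, labels, regions, dome_R,
                             center_xy, z0) {
  sp <- spec$voxel_spacing
  half_w <- spec$dome_radius * 1.3 + spec$margin_um
  nx <- as.integer(ceiling(2 * half_w / sp[1]))
  ny <- as.integer(ceiling(2 * half_w / sp[2]))
  nz <- as.integer(ceiling((spec$dome_radius * 1.3 + z0 + spec$margin_um) / sp[3]))
  xs <- (seq_len(nx) - 1) * sp[1] - half_w   # physical coords, origin shifted
  ys <- (seq_len(ny) - 1) * sp[2] - half_w
  zs <- (seq_len(nz) - 1) * sp[3]
  origin <- c(-half_w, -half_w, 0)

  # squared planar radius about the dome centre for every (x, y) column
  dx <- xs - center_xy[1]
  dy <- ys - center_xy[2]
  rho2 <- outer(dx^2, dy^2, "+")

  shells <- if (spec$interior == "shell") 2L else 1L
  lab <- array(0L, c(nx, ny, nz))
  n1 <- nrow(seeds)
  for (sh in seq_len(shells)) {
    r_out <- dome_R - (sh - 1) * spec$l1_thickness
    r_in <- r_out - spec$l1_thickness
    for (k in seq_len(nz)) {
      h <- zs[k] - z0
      if (h < 0) next
      r2 <- rho2 + h^2
      inshell <- r2 <= r_out^2 & r2 > r_in^2
      if (!any(inshell)) next
      ij <- which(inshell, arr.ind = TRUE)
      px <- xs[ij[, 1]] - center_xy[1]
      py <- ys[ij[, 2]] - center_xy[2]
      a <- nearest_seed(cbind(px, py), seeds)
      lab[cbind(ij, k)] <- labels[a] + (sh - 1L) * n1
    }
  }
  tissue <- lab > 0L

  # wall channel: label boundaries + tissue surface, blurred
  wall <- array(0, c(nx, ny, nz))
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb_lab <- shift3d(lab, s, 0L)
    nb_tis <- shift3d(tissue, s, FALSE)
    wall <- pmax(wall, (tissue & (!nb_tis | nb_lab != lab)) * 1)
  }
  wall <- gauss_smooth3d(wall * 255, rep(spec$wall_sigma, 3), sp)

  # nuclei: Gaussian blobs at mid-shell above each seed
  sensor <- array(0, c(nx, ny, nz))
  reference <- array(0, c(nx, ny, nz))
  domain <- array(0, c(nx, ny, nz))
  sig <- spec$signaling_field
  gains <- spec$channel_gains
  nsig <- spec$nucleus_sigma
  rad_vox <- ceiling(3 * nsig / sp)
  nuc <- data.frame(label = labels, x = NA_real_, y = NA_real_, z = NA_real_,
                    sensor = NA_real_, reference = NA_real_,
                    ratio = NA_real_, signaling = NA_real_,
                    region = regions, stringsAsFactors = FALSE)
  clv_sigma <- spec$cz_radius / 1.2
  for (s in seq_len(n1)) {
    rho_s <- sqrt(sum(seeds[s, ]^2))
    zn <- z0 + dome_surface_z(rho_s, dome_R) - spec$l1_thickness / 2
    cx <- center_xy[1] + seeds[s, 1]
    cy <- center_xy[2] + seeds[s, 2]
    Sv <- unname(sig[regions[s]])
    ratio <- 3 - Sv
    amp_ref <- unname(gains["reference"])
    amp_sen <- unname(gains["sensor"]) * ratio
    amp_dom <- 150 * exp(-rho_s^2 / (2 * clv_sigma^2))
    i0 <- max(1L, round((cx - origin[1]) / sp[1]) + 1L - rad_vox[1])
    i1 <- min(nx, round((cx - origin[1]) / sp[1]) + 1L + rad_vox[1])
    j0 <- max(1L, round((cy - origin[2]) / sp[2]) + 1L - rad_vox[2])
    j1 <- min(ny, round((cy - origin[2]) / sp[2]) + 1L + rad_vox[2])
    k0 <- max(1L, round(zn / sp[3]) + 1L - rad_vox[3])
    k1 <- min(nz, round(zn / sp[3]) + 1L + rad_vox[3])
    if (i0 > i1 || j0 > j1 || k0 > k1) next
    gx <- exp(-(xs[i0:i1] - cx)^2 / (2 * nsig^2))
    gy <- exp(-(ys[j0:j1] - cy)^2 / (2 * nsig^2))
    gz <- exp(-(zs[k0:k1] - zn)^2 / (2 * nsig^2))
    blob <- outer(outer(gx, gy), gz)
    sensor[i0:i1, j0:j1, k0:k1] <- sensor[i0:i1, j0:j1, k0:k1] + amp_sen * blob
    reference[i0:i1, j0:j1, k0:k1] <- reference[i0:i1, j0:j1, k0:k1] + amp_ref * blob
    domain[i0:i1, j0:j1, k0:k1] <- domain[i0:i1, j0:j1, k0:k1] + amp_dom * blob
    nuc$x[s] <- cx; nuc$y[s] <- cy; nuc$z[s] <- zn
    nuc$sensor[s] <- amp_sen; nuc$reference[s] <- amp_ref
    nuc$ratio[s] <- ratio; nuc$signaling[s] <- Sv
  }

  chans <- list(wall = wall, sensor = sensor, reference = reference,
                domain = domain)
  if (spec$poisson_noise)
    chans <- lapply(chans, function(a) {
      array(stats::rpois(length(a), pmax(a, 0)), dim(a))
    })
  if (spec$noise_sd > 0)
    chans <- lapply(chans, function(a) {
      pmax(a + stats::rnorm(length(a), 0, spec$noise_sd), 0)
    })
  stack <- image_stack(chans, spacing = sp, origin = origin)

  dom_w <- 150 * exp(-(rowSums(seeds^2)) / (2 * clv_sigma^2))
  clv3_centroid <- c(
    sum((center_xy[1] + seeds[, 1]) * dom_w) / sum(dom_w),
    sum((center_xy[2] + seeds[, 2]) * dom_w) / sum(dom_w))

  list(stack = stack, label_volume = lab, nuclei = nuc,
       clv3_centroid = clv3_centroid, origin = origin)
}

region_of_seeds <- function(seeds, geom_rel) {
  # seeds are relative to the dome centre; geom_rel$primordia likewise
  rho <- sqrt(rowSums(seeds^2))
  reg <- rep("IPR", nrow(seeds))
  reg[rho <= geom_rel$cz_radius] <- "CZ"
  pr <- geom_rel$primordia
  if (!is.null(pr)) for (i in seq_len(nrow(pr))) {
    d <- sqrt((seeds[, 1] - pr$x[i])^2 + (seeds[, 2] - pr$y[i])^2)
    reg[d <= pr$radius[i] & reg != "CZ"] <- "P"
  }
  reg
}

#' Generate one synthetic meristem stack with ground truth
#'
#' Renders a 4-channel 3D stack (`wall`, `sensor`, `reference`, `domain`) of a
#' dome-shaped L1 tissue tiled by `n_cells_L1` cells, one Gaussian nucleus per
#' cell whose noiseless sensor/reference intensity ratio equals `3 - S(region)`
#' for the spec's signaling field `S`. Deterministic given the spec's seed.
#'
#' @param spec a [sam_spec()].
#' @return a list with elements `stack` (an [image_stack()]) and `truth`, a
#'   `sam_ground_truth` list holding `label_volume` (integer array, 0 =
#'   background), `cells` (per-cell table: label, planar seed position,
#'   region, rim flag), `nuclei` (per-nucleus table with true intensities,
#'   ratio and signaling), `sam_center`, `clv3_centroid`, `geometry` (a
#'   region-classification geometry for [classify_region()]) and `dome`
#'   parameters.
#' @export
generate_sam_stack <- function(spec) {
  validate_sam_spec(spec)
  set.seed(spec$seed)
  frame <- synth_first_frame(spec)
  list(stack = frame$render$stack, truth = frame$truth)
}

synth_first_frame <- function(spec) {
  R <- spec$dome_radius
  seeds <- relaxed_disc_seeds(spec$n_cells_L1, 0.92 * R)
  labels <- seq_len(spec$n_cells_L1)
  geom_rel <- list(cz_radius = spec$cz_radius,
                   primordia = primordia_to_xy(spec$primordia, c(0, 0)))
  regions <- region_of_seeds(seeds, geom_rel)
  center_xy <- c(0, 0)
  z0 <- 2
  render <- render_sam_frame(spec, seeds, labels, regions, R, center_xy, z0)
  truth <- build_truth(spec, render, seeds, labels, regions, R, center_xy, z0)
  list(render = render, truth = truth, seeds = seeds, labels = labels,
       regions = regions, dome_R = R, center_xy = center_xy, z0 = z0)
}

build_truth <- function(spec, render, seeds, labels, regions, dome_R,
                        center_xy, z0, extra = list()) {
  rho <- sqrt(rowSums(seeds^2))
  cell_rad <- sqrt((0.92 * dome_R)^2 / length(labels))
  cells <- data.frame(label = labels,
                      x = center_xy[1] + seeds[, 1],
                      y = center_xy[2] + seeds[, 2],
                      region = regions,
                      rim = rho + 1.6 * cell_rad > 0.92 * dome_R,
                      stringsAsFactors = FALSE)
  pr_abs <- primordia_to_xy(spec$primordia, center_xy)
  geom <- sam_geometry(center_xy, spec$cz_radius, pr_abs)
  truth <- c(list(label_volume = render$label_volume, cells = cells,
                  nuclei = render$nuclei, sam_center = center_xy,
                  clv3_centroid = render$clv3_centroid,
                  geometry = geom,
                  dome = list(radius = dome_R, z0 = z0),
                  origin = render$origin),
             extra)
  class(truth) <- "sam_ground_truth"
  truth
}

# radial area-growth transport map: returns a function rho -> rho' realising
# local planar area factor 1 + g(rho) * dt, with g = CZ rate inside cz_radius,
# peripheral rate outside, linear blend over a 4 um band.
radial_growth_map <- function(spec) {
  g_cz <- unname(spec$growth_field["CZ"])
  g_pe <- unname(spec$growth_field["IPR"])
  dt <- spec$interval_h
  cz <- spec$cz_radius
  band <- 6   # blend over about one cell diameter so the map is cell-smooth
  gfun <- function(r) {
    w <- pmin(1, pmax(0, (r - (cz - band / 2)) / band))
    (1 - w) * g_cz + w * g_pe
  }
  rmax <- spec$dome_radius * 1.3
  grid <- seq(0, rmax, by = 0.1)
  integrand <- grid * (1 + gfun(grid) * dt)
  cum <- c(0, cumsum((integrand[-1] + integrand[-length(grid)]) / 2 * 0.1))
  psi_tab <- sqrt(2 * cum)
  list(psi = function(r) stats::approx(grid, psi_tab, r, rule = 2)$y,
       gfun = gfun, dt = dt)
}

# deformation gradient of the full growth map (radial transport + global
# stretch) at planar point p (relative to centre)
growth_F_at <- function(p, map, stretch) {
  r <- sqrt(sum(p^2))
  if (r < 1e-9) {
    J <- diag(2) * sqrt(1 + map$gfun(0) * map$dt)
  } else {
    psi_r <- map$psi(r)
    eps <- 0.05
    dpsi <- (map$psi(r + eps) - map$psi(pmax(r - eps, 0))) /
      (r + eps - pmax(r - eps, 0))
    u <- p / r
    P <- outer(u, u)
    J <- (psi_r / r) * (diag(2) - P) + dpsi * P
  }
  diag(stretch) %*% J
}

#' Generate a synthetic meristem time-lapse with lineage ground truth
#'
#' Successive frames are related by (i) a radially symmetric growth transport
#' realising the spec's per-region area growth rates, plus an optional global
#' anisotropic stretch, (ii) cell divisions: a stated fraction of cells divide
#' per interval, with division-plane angles drawn from the per-region circular
#' law and daughter walls passing through the parent centroid, and (iii) a
#' recorded rigid drift (translation + rotation about the optical axis)
#' emulating specimen re-mounting. Ground truth for each frame beyond the
#' first records the lineage (parent to children), the division events with
#' their true angles, the drift transform and each cell's imposed area factor
#' and deformation gradient.
#'
#' @param spec a [sam_spec()].
#' @param n_frames number of frames (at least 2).
#' @return list of `n_frames` elements, each `list(stack =, truth =)`. Frame
#'   `t >= 2` truth additionally holds `lineage` (data frame `parent`,
#'   `child`), `divisions` (one row per event: parent, midpoint, wall
#'   direction, `true_angle_deg`, region, wall endpoints), `transform` (the
#'   drift mapping frame `t-1` image coordinates to frame `t`:
#'   `x2 = R(theta) (x1 - c) + c + tr`) and per-cell `growth_truth`.
#' @export
generate_timelapse <- function(spec, n_frames) {
  stopifnot(n_frames >= 2)
  validate_sam_spec(spec)
  gmax <- max(spec$growth_field) * spec$interval_h
  if ((1 + gmax) < 0.2)
    stop("growth rates collapse cells below resolution")
  set.seed(spec$seed)
  f1 <- synth_first_frame(spec)
  frames <- list(list(stack = f1$render$stack, truth = f1$truth))

  seeds <- f1$seeds; labels <- f1$labels
  dome_R <- f1$dome_R; center_xy <- f1$center_xy; z0 <- f1$z0
  next_label <- max(labels) + 1L
  map <- radial_growth_map(spec)
  stretch <- spec$anisotropic_stretch

  for (t in 2:n_frames) {
    # 1. growth transport (in dome-centred planar coordinates)
    r_old <- sqrt(rowSums(seeds^2))
    r_new <- map$psi(r_old)
    scale_r <- ifelse(r_old > 1e-9, r_new / r_old, 1)
    seeds_g <- seeds * scale_r
    seeds_g <- sweep(seeds_g, 2, stretch, "*")
    growth_truth <- data.frame(
      label = labels,
      area_factor = (1 + map$gfun(r_old) * map$dt) * prod(stretch),
      f11 = NA_real_, f12 = NA_real_, f21 = NA_real_, f22 = NA_real_,
      aniso_true = NA_real_)
    for (i in seq_along(labels)) {
      Fm <- growth_F_at(seeds[i, ], map, stretch)
      sv <- svd(Fm)$d
      growth_truth[i, c("f11", "f12", "f21", "f22")] <- as.vector(t(Fm))
      growth_truth$aniso_true[i] <- (sv[1] - sv[2]) / (sv[1] + sv[2])
    }
    dome_R_new <- max(dome_R, max(sqrt(rowSums(seeds_g^2))) / 0.92)

    # 2. divisions
    geom_rel <- list(cz_radius = spec$cz_radius,
                     primordia = primordia_to_xy(transport_primordia(
                       spec$primordia, map, stretch), c(0, 0)))
    regions_g <- region_of_seeds(seeds_g, geom_rel)
    divide <- stats::runif(length(labels)) < spec$division_fraction
    cell_rad <- sqrt((0.92 * dome_R_new)^2 / length(labels))
    new_seeds <- list(); new_labels <- integer(0); new_regions <- character(0)
    lineage <- data.frame(parent = integer(0), child = integer(0))
    divisions <- data.frame()
    for (i in seq_along(labels)) {
      p <- seeds_g[i, ]
      if (!divide[i]) {
        ch <- next_label; next_label <- next_label + 1L
        new_seeds[[length(new_seeds) + 1L]] <- p
        new_labels <- c(new_labels, ch)
        new_regions <- c(new_regions, regions_g[i])
        lineage <- rbind(lineage, data.frame(parent = labels[i], child = ch))
      } else {
        pars <- spec$division_angle_params[[regions_g[i]]]
        ang <- sample_division_angle(1, pars)
        # raw signed orientation: keep sampled fold but random side
        sgn <- if (stats::runif(1) < 0.5) 1 else -1
        rr <- sqrt(sum(p^2))
        u <- if (rr > 1e-9) p / rr else c(1, 0)
        a_rad <- sgn * ang * pi / 180
        w <- c(cos(a_rad) * u[1] - sin(a_rad) * u[2],
               sin(a_rad) * u[1] + cos(a_rad) * u[2])     # wall direction
        nrm <- c(-w[2], w[1])                              # wall normal
        delta <- 0.45 * cell_rad
        ch1 <- next_label; ch2 <- next_label + 1L
        next_label <- next_label + 2L
        new_seeds[[length(new_seeds) + 1L]] <- p + delta * nrm
        new_seeds[[length(new_seeds) + 1L]] <- p - delta * nrm
        new_labels <- c(new_labels, ch1, ch2)
        new_regions <- c(new_regions, regions_g[i], regions_g[i])
        lineage <- rbind(lineage,
                         data.frame(parent = labels[i], child = c(ch1, ch2)))
        L <- 1.6 * cell_rad
        divisions <- rbind(divisions, data.frame(
          parent = labels[i], child1 = ch1, child2 = ch2,
          mx = p[1], my = p[2], wx = w[1], wy = w[2],
          ex1 = p[1] - L / 2 * w[1], ey1 = p[2] - L / 2 * w[2],
          ex2 = p[1] + L / 2 * w[1], ey2 = p[2] + L / 2 * w[2],
          true_angle_deg = ang, region = regions_g[i],
          stringsAsFactors = FALSE))
      }
    }
    seeds2 <- do.call(rbind, new_seeds)

    # 3. rigid drift, recorded; applied about the current dome centre
    theta <- stats::runif(1, -spec$drift_rotation_deg, spec$drift_rotation_deg)
    tr <- stats::runif(3, -spec$drift_translation, spec$drift_translation)
    th <- theta * pi / 180
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    seeds2_img <- seeds2 %*% t(Rm)                   # still dome-centred
    center_new <- center_xy + tr[1:2]
    z0_new <- z0 + tr[3]
    # divisions / midpoints into drifted image coordinates
    if (nrow(divisions) > 0) {
      rot2 <- function(xy) sweep(as.matrix(xy) %*% t(Rm), 2, center_new, "+")
      mm <- rot2(divisions[, c("mx", "my")])
      e1 <- rot2(divisions[, c("ex1", "ey1")])
      e2 <- rot2(divisions[, c("ex2", "ey2")])
      wv <- as.matrix(divisions[, c("wx", "wy")]) %*% t(Rm)
      divisions$mx <- mm[, 1]; divisions$my <- mm[, 2]
      divisions$ex1 <- e1[, 1]; divisions$ey1 <- e1[, 2]
      divisions$ex2 <- e2[, 1]; divisions$ey2 <- e2[, 2]
      divisions$wx <- wv[, 1]; divisions$wy <- wv[, 2]
    }
    transform <- list(theta_deg = theta, center = c(center_xy, z0),
                      translation = tr)

    spec_t <- spec
    spec_t$primordia <- transport_primordia(spec$primordia, map, stretch)
    spec_t$primordia$azimuth_deg <- (spec_t$primordia$azimuth_deg + theta) %% 360
    render <- render_sam_frame(spec_t, seeds2_img, new_labels, new_regions,
                               dome_R_new, center_new, z0_new)
    truth <- build_truth(spec_t, render, seeds2_img, new_labels, new_regions,
                         dome_R_new, center_new, z0_new,
                         extra = list(lineage = lineage, divisions = divisions,
                                      transform = transform,
                                      growth_truth = growth_truth,
                                      interval_h = spec$interval_h))
    frames[[t]] <- list(stack = render$stack, truth = truth)

    seeds <- seeds2_img; labels <- new_labels
    dome_R <- dome_R_new; center_xy <- center_new; z0 <- z0_new
    # keep region geometry of the drifted frame for the next iteration
    spec <- spec_t
  }
  frames
}

transport_primordia <- function(primordia, map, stretch) {
  if (is.null(primordia) || nrow(primordia) == 0) return(primordia)
  out <- primordia
  th <- primordia$azimuth_deg * pi / 180
  x <- primordia$distance_um * cos(th) * stretch[1]
  y <- primordia$distance_um * sin(th) * stretch[2]
  r_new <- map$psi(primordia$distance_um)
  sc <- r_new / primordia$distance_um
  x <- x * sc; y <- y * sc
  out$distance_um <- sqrt(x^2 + y^2)
  out$azimuth_deg <- (atan2(y, x) * 180 / pi) %% 360
  out
}

#' Write ground truth tables to plain-text files
#'
#' Writes the nucleus table and (if present) division events as CSV and the
#' frame metadata (centre, dome, drift transform) as JSON into `dir`.
#'
#' @param truth a `sam_ground_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$nuclei, file.path(dir, "nuclei_truth.csv"),
                   row.names = FALSE)
  if (!is.null(truth$divisions) && nrow(truth$divisions) > 0)
    utils::write.csv(truth$divisions, file.path(dir, "divisions_truth.csv"),
                     row.names = FALSE)
  meta <- list(sam_center = truth$sam_center,
               clv3_centroid = truth$clv3_centroid,
               dome = truth$dome, transform = truth$transform)
  jsonlite::write_json(meta, file.path(dir, "frame_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
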