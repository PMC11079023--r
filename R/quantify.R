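#' Configuration for nucleus detection and ratiometric quantification
#'
#' @param detection_scale_range length-2 numeric, min and max blob scale
#'   (Gaussian sigma, micrometres) for multi-scale Laplacian-of-Gaussian
#'   detection.
#' @param n_scales number of geometrically spaced scales.
#' @param min_blob_distance minimal distance between detections
#'   (micrometres); closer maxima are merged, keeping the stronger.
#' @param background_percentile percentile (0-100) of non-tissue voxels used
#'   as the per-channel background estimate.
#' @param aggregation_radius radius (micrometres) of the sphere over which
#'   per-nucleus channel intensities are averaged.
#' @param min_reference minimal background-subtracted reference mean for a
#'   record to be kept; `NULL` (default) uses 3x the background MAD, which
#'   avoids ratio blow-up at dim nuclei.
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(detection_scale_range = c(1.0, 2.2),
                         n_scales = 3,
                         min_blob_distance = 3,
                         background_percentile = 5,
                         aggregation_radius = 1.5,
                         min_reference = NULL) {
  stopifnot(length(detection_scale_range) == 2,
            all(detection_scale_range > 0),
            detection_scale_range[1] <= detection_scale_range[2],
            min_blob_distance > 0, aggregation_radius > 0,
            background_percentile > 0, background_percentile < 100)
  structure(list(detection_scale_range = detection_scale_range,
                 n_scales = as.integer(n_scales),
                 min_blob_distance = min_blob_distance,
                 background_percentile = background_percentile,
                 aggregation_radius = aggregation_radius,
                 min_reference = min_reference),
            class = "quant_config")
}

# linear z-resampling to (approximately) isotropic spacing; x/y spacing must
# already agree (confocal anisotropy is axial)
resample_isotropic <- function(stack) {
  sp <- stack$spacing
  if (abs(sp[1] - sp[2]) > 1e-9)
    stop("x and y spacing must be equal")
  if (abs(sp[3] - sp[1]) < 1e-9) return(stack)
  d <- dim(stack$channels[[1]])
  z_old <- (seq_len(d[3]) - 1) * sp[3]
  z_new <- seq(0, max(z_old), by = sp[1])
  chans <- lapply(stack$channels, function(a) {
    out <- array(0, c(d[1], d[2], length(z_new)))
    for (k in seq_along(z_new)) {
      pos <- z_new[k] / sp[3] + 1
      k0 <- floor(pos); w <- pos - k0
      k1 <- min(k0 + 1, d[3])
      out[, , k] <- (1 - w) * a[, , k0] + w * a[, , k1]
    }
    out
  })
  image_stack(chans, spacing = c(sp[1], sp[2], sp[1]), origin = stack$origin)
}

# per-channel background level and MAD from non-tissue voxels (below the
# channel's Otsu threshold); falls back to the whole channel when flat
channel_background <- function(a, percentile) {
  thr <- otsu_threshold(a)
  bgv <- a[a <= thr]
  if (length(bgv) < 100) bgv <- as.vector(a)
  list(level = unname(stats::quantile(bgv, percentile / 100)),
       mad = stats::mad(bgv))
}

#' Detect nuclei in 3D on the reference channel
#'
#' Multi-scale Laplacian-of-Gaussian blob detection run on the GA-insensitive
#' reference channel, so that detection is not biased by signaling level.
#' Anisotropic stacks are resampled to isotropic spacing first. Maxima closer
#' than `min_blob_distance` are merged (the stronger survives); detections are
#' sorted by (z, y, x) for reproducibility.
#'
#' @param stack an [image_stack()] with a `reference` channel.
#' @param cfg a [quant_config()].
#' @return data frame with columns `id`, `x`, `y`, `z` (centroid, physical
#'   micrometres). Empty (zero rows) for a flat image.
#' @export
detect_nuclei <- function(stack, cfg = quant_config()) {
  stack <- resample_isotropic(stack)
  a <- stack_channel(stack, "reference")
  sp <- stack$spacing
  empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0))
  if (max(a) - min(a) <= 0) return(empty)
  scales <- exp(seq(log(cfg$detection_scale_range[1]),
                    log(cfg$detection_scale_range[2]),
                    length.out = cfg$n_scales))
  resp <- NULL
  for (s in scales) {
    sm <- gauss_smooth3d(a, rep(s, 3), sp)
    lap <- (shift3d(sm, c(1, 0, 0), 0) + shift3d(sm, c(-1, 0, 0), 0) -
              2 * sm) / sp[1]^2 +
      (shift3d(sm, c(0, 1, 0), 0) + shift3d(sm, c(0, -1, 0), 0) -
         2 * sm) / sp[2]^2 +
      (shift3d(sm, c(0, 0, 1), 0) + shift3d(sm, c(0, 0, -1), 0) -
         2 * sm) / sp[3]^2
    r <- -s^2 * lap                      # scale-normalised, positive at blobs
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  bg <- channel_background(a, cfg$background_percentile)
  sm_fine <- gauss_smooth3d(a, rep(scales[1], 3), sp)
  cand <- which(local_maxima3d(resp) & resp > 0 &
                  sm_fine > bg$level + 8 * bg$mad + 0.02 * max(a))
  if (length(cand) == 0) return(empty)
  ijk <- arrayInd(cand, dim(a))
  strength <- resp[cand]
  ord <- order(strength, decreasing = TRUE)
  ijk <- ijk[ord, , drop = FALSE]
  pos <- voxel_to_um(ijk, stack)
  keep <- logical(0)
  kept_pos <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(pos))) {
    if (nrow(kept_pos) == 0) ok <- TRUE
    else ok <- min(sqrt(rowSums(sweep(kept_pos, 2, pos[i, ])^2))) >=
        cfg$min_blob_distance
    keep[i] <- ok
    if (ok) kept_pos <- rbind(kept_pos, pos[i, ])
  }
  pos <- pos[keep, , drop = FALSE]
  ord2 <- order(pos[, 3], pos[, 2], pos[, 1])
  pos <- pos[ord2, , drop = FALSE]
  data.frame(id = seq_len(nrow(pos)), x = pos[, 1], y = pos[, 2],
             z = pos[, 3])
}

#' Measure per-nucleus channel intensities and ratios
#'
#' Averages background-subtracted sensor and reference intensities over a
#' sphere of `aggregation_radius` around each detected centroid, computes the
#' sensor/reference ratio and the signaling value `3 - ratio`. Records whose
#' reference mean falls below `min_reference` (or whose aggregation sphere
#' lies fully outside the image) are dropped and counted in the QC attribute.
#'
#' @param stack an [image_stack()] with `sensor` and `reference` channels.
#' @param nuclei data frame from [detect_nuclei()] (columns `id, x, y, z`).
#' @param cfg a [quant_config()].
#' @return data frame of nucleus records (`id, x, y, z, sensor_mean,
#'   reference_mean, ratio, signaling, out_of_range`) with a `qc` attribute
#'   listing dropped counts and background estimates.
#' @export
measure_intensities <- function(stack, nuclei, cfg = quant_config()) {
  sen <- stack_channel(stack, "sensor")
  ref <- stack_channel(stack, "reference")
  sp <- stack$spacing
  d <- dim(sen)
  bg_s <- channel_background(sen, cfg$background_percentile)
  bg_r <- channel_background(ref, cfg$background_percentile)
  min_ref <- if (is.null(cfg$min_reference)) 3 * bg_r$mad else cfg$min_reference
  rv <- ceiling(cfg$aggregation_radius / sp)
  offs <- expand.grid(di = -rv[1]:rv[1], dj = -rv[2]:rv[2], dk = -rv[3]:rv[3])
  keep_off <- (offs$di * sp[1])^2 + (offs$dj * sp[2])^2 +
    (offs$dk * sp[3])^2 <= cfg$aggregation_radius^2
  offs <- as.matrix(offs[keep_off, , drop = FALSE])

  n <- nrow(nuclei)
  sensor_mean <- reference_mean <- rep(NA_real_, n)
  dropped_outside <- 0L
  for (i in seq_len(n)) {
    c_idx <- round((c(nuclei$x[i], nuclei$y[i], nuclei$z[i]) -
                      stack$origin) / sp) + 1
    vox <- sweep(offs, 2, c_idx, "+")
    ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
      vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
    if (!any(ok)) { dropped_outside <- dropped_outside + 1L; next }
    vox <- vox[ok, , drop = FALSE]
    sensor_mean[i] <- mean(sen[vox]) - bg_s$level
    reference_mean[i] <- mean(ref[vox]) - bg_r$level
  }
  rec <- data.frame(id = nuclei$id, x = nuclei$x, y = nuclei$y, z = nuclei$z,
                    sensor_mean = sensor_mean,
                    reference_mean = reference_mean)
  dim_ref <- !is.na(rec$reference_mean) &
    (rec$reference_mean <= 0 | rec$reference_mean < min_ref)
  out <- rec[!is.na(rec$reference_mean) & !dim_ref, , drop = FALSE]
  out$ratio <- pmax(out$sensor_mean, 0) / out$reference_mean
  sig <- compute_signaling(out$ratio)
  out$signaling <- as.numeric(sig)
  out$out_of_range <- attr(sig, "out_of_range") %||% rep(FALSE, nrow(out))
  attr(out, "qc") <- list(n_detected = n,
                          n_dropped_dim = sum(dim_ref),
                          n_dropped_outside = dropped_outside,
                          background = list(sensor = bg_s, reference = bg_r),
                          min_reference = min_ref)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GA signaling value from an intensity ratio
#'
#' The biosensor's GA-sensitive channel is degraded upon GA perception while
#' the reference channel is stable, so signaling activity is read out as
#' `3 - sensor/reference`: 3 covers the observed ratio range, making 3 the
#' maximal-signaling value (sensor fully degraded, ratio 0). Values below 0
#' indicate a ratio above 3, i.e. miscalibration; they are flagged via the
#' `out_of_range` attribute, never silently clipped.
#'
#' @param ratio numeric vector of non-negative finite sensor/reference
#'   ratios.
#' @return numeric vector `3 - ratio` with logical attribute `out_of_range`.
#' @export
compute_signaling <- function(ratio) {
  if (any(!is.finite(ratio)))
    stop("ratio must be finite")
  if (any(ratio < 0))
    stop("ratio must be non-negative")
  s <- 3 - ratio
  oor <- s < 0
  if (any(oor))
    warning(sprintf("%d signaling value(s) below 0 (ratio > 3): flagged, not clipped",
                    sum(oor)))
  attr(s, "out_of_range") <- oor
  s
}

#' Standardize per-image ratio distributions
#'
#' Divides every nucleus ratio by the per-image mean ratio so that ratio
#' distributions are centred on 1, making distributions from different images
#' (e.g. sensor versus constitutive control lines) directly comparable. The
#' unstandardized ratio is kept in `ratio_raw`; the signaling column (which
#' is defined on the raw, calibrated ratio) is left untouched.
#'
#' @param records nucleus record data frame with a `ratio` column.
#' @return the records with `ratio` standardized (mean exactly 1) and
#'   `ratio_raw` added.
#' @export
standardize_ratios <- function(records) {
  if (nrow(records) < 1) stop("need at least one record")
  m <- mean(records$ratio)
  if (!is.finite(m) || m <= 0) stop("mean ratio must be positive")
  records$ratio_raw <- records$ratio
  records$ratio <- records$ratio / m
  records
}

#' Write nucleus records and the QC report
#'
#' @param records output of [measure_intensities()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_nucleus_records <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records, file.path(dir, "nuclei.csv"), row.names = FALSE)
  qc <- attr(records, "qc") %||% list()
  jsonlite::write_json(qc, file.path(dir, "qc.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
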