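#' Multi-channel 3D image stack
#'
#' The universal input container of the pipeline: a named list of 3D intensity
#' arrays (one per channel) on a common voxel grid with physical voxel spacing.
#' Arrays are indexed `[x, y, z]`; voxel `(i, j, k)` (1-based) has its centre at
#' `origin + (c(i, j, k) - 1) * spacing` in micrometres. The optical axis is
#' `z`, with the meristem apex towards high `z`; all top-down projections are
#' orthographic along `z`.
#'
#' Channel roles follow the acquisition this emulates: `wall` (cell-wall stain,
#' PI-like), `sensor` (GA-sensitive VENUS-like), `reference` (GA-insensitive
#' TagBFP-like) and optionally `domain` (stem-cell domain, CLV3-reporter-like).
#'
#' @param channels named list of 3D numeric arrays with identical dimensions.
#' @param spacing numeric length-3, voxel spacing in micrometres `(x, y, z)`.
#' @param origin numeric length-3, physical position of voxel `(1,1,1)` in
#'   micrometres. Default `c(0, 0, 0)`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("all channels must be 3D arrays")
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) all(d == d0), TRUE)))
    stop("all channels must share the same dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (x, y, z) in micrometres")
  structure(list(channels = channels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d x %d x %d voxels, %d channel(s) [%s]\n",
              d[1], d[2], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  spacing (um): x=%.3g y=%.3g z=%.3g\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

stack_channel <- function(stack, role) {
  if (!role %in% names(stack$channels))
    stop(sprintf("stack has no '%s' channel", role))
  stack$channels[[role]]
}

#' Physical coordinates of voxel indices
#'
#' @param idx matrix with 3 columns of 1-based voxel indices `(i, j, k)`.
#' @param stack an `image_stack`.
#' @return matrix of physical `(x, y, z)` coordinates in micrometres.
#' @keywords internal
voxel_to_um <- function(idx, stack) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, stack$spacing, "*"), 2, stack$origin, "+")
}

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Channels are written as consecutive z-page blocks of one 32-bit float
#' multi-page TIFF (page order: all z of channel 1, then channel 2, ...), with
#' spacing, origin and channel names in `<path>.json`.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns the
#'   `image_stack`.
#' @export
write_stack <- function(stack, path) {
  pages <- list()
  for (ch in stack$channels) {
    for (k in seq_len(dim(ch)[3])) {
      # TIFF rows are y; transpose so x runs along columns
      pages[[length(pages) + 1L]] <- t(ch[, , k])
    }
  }
  mx <- max(1, max(vapply(pages, max, 0)))
  pages <- lapply(pages, function(p) pmin(pmax(p / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(channels = names(stack$channels), dim = dim(stack$channels[[1]]),
               spacing = stack$spacing, origin = stack$origin, scale = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$dim
  chans <- list()
  p <- 0L
  for (nm in meta$channels) {
    a <- array(0, d)
    for (k in seq_len(d[3])) {
      p <- p + 1L
      a[, , k] <- t(pages[[p]]) * meta$scale
    }
    chans[[nm]] <- a
  }
  image_stack(chans, spacing = meta$spacing, origin = meta$origin)
}

# ---- shared raster utilities -------------------------------------------------

# 3D Gaussian smoothing by FFT circular convolution; sigma in um per axis.
# Wrap-around is negligible because stacks carry a background margin.
gauss_smooth3d <- function(a, sigma_um, spacing) {
  d <- dim(a)
  sig_vox <- sigma_um / spacing
  kern1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  kx <- kern1(d[1], sig_vox[1]); ky <- kern1(d[2], sig_vox[2])
  kz <- kern1(d[3], sig_vox[3])
  K <- outer(outer(kx, ky), kz)
  Re(fft(fft(a) * fft(K), inverse = TRUE)) / prod(d)
}

# 26-connected local maxima of a 3D array (strictly greater than or equal to
# all neighbours and strictly greater than at least one).
local_maxima3d <- function(a) {
  d <- dim(a)
  pad <- array(-Inf, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  ismax <- array(TRUE, d)
  anyless <- array(FALSE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz]
    ismax <- ismax & (a >= nb)
    anyless <- anyless | (nb < a)
  }
  ismax & anyless
}

# Otsu threshold on an intensity vector (256-bin histogram).
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(256L, 1L + as.integer(255 * (v - r[1]) / diff(r))), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (1:256))
  mu_t <- mu[256]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  t_bin <- which.max(sb2)
  r[1] + (t_bin / 256) * diff(r)
}

# Binary closing (6-connectivity ball of given voxel radius) via distance-free
# dilate/erode with max/min filters implemented by shifting.
shift3d <- function(a, s, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- list(); dst <- list()
  for (ax in 1:3) {
    n <- d[ax]; sh <- s[ax]
    if (abs(sh) >= n) return(out)
    if (sh >= 0) { src[[ax]] <- 1:(n - sh); dst[[ax]] <- (1 + sh):n }
    else { src[[ax]] <- (1 - sh):n; dst[[ax]] <- 1:(n + sh) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

binary_dilate3d <- function(m, r) {
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= r^2, , drop = FALSE]
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs)))
    out <- out | shift3d(m, c(offs$dx[i], offs$dy[i], offs$dz[i]), FALSE)
  out
}

binary_erode3d <- function(m, r) !binary_dilate3d(!m, r)

binary_close3d <- function(m, r) binary_erode3d(binary_dilate3d(m, r), r)
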