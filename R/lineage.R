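#' Rigid registration of consecutive time points on the wall channel
#'
#' Estimates the rigid drift between two frames as a rotation about the
#' optical axis plus a 3D translation (dissected meristems are re-mounted
#' approximately upright, so in-plane rotation suffices). The in-plane part
#' is found by maximising the normalised cross-correlation of the two wall
#' max-projections over a coarse-to-fine rotation grid with FFT translation
#' search at each angle; the axial translation then comes from correlating
#' the z intensity profiles.
#'
#' The returned transform maps frame-t coordinates to frame-t2 coordinates:
#' `x2 = R(theta) (x1 - c) + c + t` with `c` the image centre (micrometres).
#'
#' @param stack_t,stack_t2 [image_stack()]s with `wall` channels.
#' @param rot_range_deg half-width of the rotation search window (degrees).
#' @param min_score minimal normalised correlation at the optimum; below it
#'   registration is declared failed.
#' @return an object of class `rigid_transform`: `theta_deg`, `center`
#'   (length 3), `translation` (length 3), `score`.
#' @export
register_timepoints <- function(stack_t, stack_t2, rot_range_deg = 12,
                                min_score = 0.2) {
  w1 <- stack_channel(stack_t, "wall")
  w2 <- stack_channel(stack_t2, "wall")
  sp <- stack_t$spacing
  p1 <- apply(w1, c(1, 2), max)
  p2 <- apply(w2, c(1, 2), max)
  p1 <- p1 - mean(p1)                     # zero-mean: score must reflect
                                          # structure, not shared brightness
  d <- dim(p1)
  cpx <- (d + 1) / 2                      # rotation centre, pixel units

  eval_theta <- function(theta) {
    p2r <- rotate2d(p2, theta, cpx)       # sample frame2 at forward-rotated coords
    xc <- cross_correlate2d(p1, p2r - mean(p2r))
    list(score = xc$score, shift_px = xc$shift)
  }
  thetas <- seq(-rot_range_deg, rot_range_deg, by = 1)
  res <- lapply(thetas, eval_theta)
  sc <- vapply(res, `[[`, 0, "score")
  th0 <- thetas[which.max(sc)]
  thetas2 <- seq(th0 - 1, th0 + 1, by = 0.2)
  res2 <- lapply(thetas2, eval_theta)
  sc2 <- vapply(res2, `[[`, 0, "score")
  best <- which.max(sc2)
  theta <- thetas2[best]
  if (sc2[best] < min_score) stop("registration failed")
  s_px <- res2[[best]]$shift_px           # shift in frame-1 pixel units
  th <- theta * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t_xy <- as.numeric(Rm %*% (s_px * sp[1:2]))

  # axial translation from z profiles
  z1 <- apply(w1, 3, sum); z2 <- apply(w2, 3, sum)
  kmax <- min(20, length(z1) - 2)
  best_dz <- 0; best_c <- -Inf
  for (dz in -kmax:kmax) {
    i1 <- max(1, 1 - dz):min(length(z1), length(z2) - dz)
    i2 <- i1 + dz
    if (length(i1) < 3) next
    v <- suppressWarnings(stats::cor(z1[i1], z2[i2]))
    if (is.finite(v) && v > best_c) { best_c <- v; best_dz <- dz }
  }
  c_um <- stack_t$origin[1:2] + (cpx[1:2] - 1) * sp[1:2]
  structure(list(theta_deg = theta,
                 center = c(c_um, 0),
                 translation = c(t_xy, best_dz * sp[3]),
                 score = sc2[best]),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "rigid_transform: rotation %.2f deg about z, translation (%.2f, %.2f, %.2f) um\n",
    x$theta_deg, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity rigid transform
#' @param center rotation centre (length 3, micrometres).
#' @return a `rigid_transform` with zero rotation and translation.
#' @export
identity_transform <- function(center = c(0, 0, 0)) {
  structure(list(theta_deg = 0, center = center, translation = c(0, 0, 0),
                 score = 1), class = "rigid_transform")
}

#' Apply or invert a rigid transform
#'
#' `apply_transform` maps points from the earlier to the later frame;
#' `invert_transform` returns the inverse transform.
#'
#' @param points n x 2 or n x 3 matrix of coordinates (micrometres).
#' @param tf a `rigid_transform`.
#' @return transformed points (same shape).
#' @export
apply_transform <- function(points, tf) {
  pts <- if (is.matrix(points)) points else matrix(points, nrow = 1)
  th <- tf$theta_deg * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- sweep(pts[, 1:2, drop = FALSE], 2, tf$center[1:2])
  xy <- xy %*% t(Rm)
  xy <- sweep(xy, 2, tf$center[1:2] + tf$translation[1:2], "+")
  out <- pts
  out[, 1:2] <- xy
  if (ncol(pts) >= 3) out[, 3] <- pts[, 3] + tf$translation[3]
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  th <- -tf$theta_deg * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t_inv_xy <- -as.numeric(Rm %*% tf$translation[1:2])
  structure(list(theta_deg = -tf$theta_deg, center = tf$center,
                 translation = c(t_inv_xy, -tf$translation[3]),
                 score = tf$score),
            class = "rigid_transform")
}

# bilinear rotation sampling: out(x) = img at c + R(theta) (x - c)
rotate2d <- function(img, theta_deg, center_px) {
  d <- dim(img)
  th <- theta_deg * pi / 180
  gx <- rep(seq_len(d[1]), d[2]) - center_px[1]
  gy <- rep(seq_len(d[2]), each = d[1]) - center_px[2]
  sx <- center_px[1] + cos(th) * gx - sin(th) * gy
  sy <- center_px[2] + sin(th) * gx + cos(th) * gy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(ix, iy) {
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
    v <- numeric(length(ix))
    v[ok] <- img[cbind(ix[ok], iy[ok])]
    v
  }
  v <- (1 - fx) * (1 - fy) * val(x0, y0) + fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) + fx * fy * val(x0 + 1, y0 + 1)
  matrix(v, d[1], d[2])
}

# FFT cross-correlation; returns integer-pixel shift s maximising
# sum a(x) b(x + s) and a normalised score
cross_correlate2d <- function(a, b) {
  d <- dim(a)
  A <- fft(a); B <- fft(b)
  cc <- Re(fft(Conj(A) * B, inverse = TRUE)) / prod(d)
  pk <- which.max(cc)
  ij <- arrayInd(pk, d) - 1
  s <- ifelse(ij > d / 2, ij - d, ij)
  list(shift = as.numeric(s),      # displacement of b's content relative to a
       score = max(cc) / (sqrt(sum(a^2) * sum(b^2)) + 1e-12))
}

#' Build cell lineages across two segmented time points
#'
#' Each frame-t2 cell is assigned to the frame-t cell with which its
#' projected footprint maximally overlaps after mapping through the inverse
#' of the registration transform; parents with two or more children mark
#' divisions. An expert corrections table (`parent`, `child`) overrides the
#' automatic assignment verbatim. Children with no tissue overlap are
#' orphans, logged in the QC attribute rather than raising an error.
#'
#' @param labels_t,labels_t2 `cell_label_map`s of consecutive frames.
#' @param transform `rigid_transform` from frame t to t2 (e.g. from
#'   [register_timepoints()]).
#' @param corrections optional data frame `parent`, `child`.
#' @param interval_h hours between the frames.
#' @return an object of class `lineage_map`: `pairs` (data frame `parent`,
#'   `child`), `transform`, `interval_h`, and a `qc` attribute with orphan
#'   labels.
#' @export
build_lineage <- function(labels_t, labels_t2, transform,
                          corrections = NULL, interval_h = 10) {
  fp1 <- project_labels(labels_t)
  fp2 <- project_labels(labels_t2)
  sp1 <- labels_t$spacing; sp2 <- labels_t2$spacing
  inv <- invert_transform(transform)
  idx2 <- which(fp2 > 0L, arr.ind = TRUE)
  pos2 <- cbind(labels_t2$origin[1] + (idx2[, 1] - 1) * sp2[1],
                labels_t2$origin[2] + (idx2[, 2] - 1) * sp2[2])
  pos1 <- apply_transform(pos2, inv)
  i1 <- round((pos1[, 1] - labels_t$origin[1]) / sp1[1]) + 1
  j1 <- round((pos1[, 2] - labels_t$origin[2]) / sp1[2]) + 1
  d1 <- dim(fp1)
  ok <- i1 >= 1 & i1 <= d1[1] & j1 >= 1 & j1 <= d1[2]
  par_lab <- integer(nrow(idx2))
  par_lab[ok] <- fp1[cbind(i1[ok], j1[ok])]
  child_lab <- fp2[idx2]
  tab <- table(child = child_lab, parent = par_lab)
  children <- as.integer(rownames(tab))
  pairs <- data.frame(parent = integer(0), child = integer(0))
  orphans <- integer(0)
  for (r in seq_along(children)) {
    counts <- tab[r, ]
    pars <- as.integer(colnames(tab))
    counts[pars == 0] <- 0                     # background does not parent
    if (all(counts == 0)) { orphans <- c(orphans, children[r]); next }
    pairs <- rbind(pairs, data.frame(parent = pars[which.max(counts)],
                                     child = children[r]))
  }
  if (!is.null(corrections) && nrow(corrections) > 0) {
    for (r in seq_len(nrow(corrections))) {
      ch <- corrections$child[r]
      pairs <- pairs[pairs$child != ch, , drop = FALSE]
      pairs <- rbind(pairs, data.frame(parent = corrections$parent[r],
                                       child = ch))
      orphans <- setdiff(orphans, ch)
    }
  }
  pairs <- pairs[order(pairs$parent, pairs$child), , drop = FALSE]
  rownames(pairs) <- NULL
  out <- structure(list(pairs = pairs, transform = transform,
                        interval_h = interval_h), class = "lineage_map")
  attr(out, "qc") <- list(orphans = orphans)
  out
}

#' @export
print.lineage_map <- function(x, ...) {
  ndiv <- sum(table(x$pairs$parent) >= 2)
  cat(sprintf("lineage_map: %d children of %d parents, %d division(s), interval %g h\n",
              nrow(x$pairs), length(unique(x$pairs$parent)), ndiv,
              x$interval_h))
  invisible(x)
}

# 3-cell wall junction points of a projected label image, aggregated per
# label-set key; positions in um
junctions2d <- function(fp, spacing, origin, relabel = NULL) {
  d <- dim(fp)
  a <- fp[1:(d[1] - 1), 1:(d[2] - 1)]
  b <- fp[2:d[1], 1:(d[2] - 1)]
  cc <- fp[1:(d[1] - 1), 2:d[2]]
  dd <- fp[2:d[1], 2:d[2]]
  cand <- which(!(a == b & a == cc & a == dd))
  if (length(cand) == 0)
    return(data.frame(key = character(0), x = numeric(0), y = numeric(0)))
  quad <- cbind(a[cand], b[cand], cc[cand], dd[cand])
  if (!is.null(relabel)) {
    nz <- quad > 0
    quad[nz] <- relabel[quad[nz]]
  }
  keys <- apply(quad, 1, function(v) {
    u <- sort(unique(v[v > 0]))
    if (length(u) < 3) return(NA_character_)
    paste(u, collapse = "-")
  })
  keep <- !is.na(keys)
  if (!any(keep))
    return(data.frame(key = character(0), x = numeric(0), y = numeric(0)))
  ij <- arrayInd(cand[keep], d - 1L)
  xs <- origin[1] + (ij[, 1] - 0.5) * spacing[1]
  ys <- origin[2] + (ij[, 2] - 0.5) * spacing[2]
  agg_x <- tapply(xs, keys[keep], mean)
  agg_y <- tapply(ys, keys[keep], mean)
  data.frame(key = names(agg_x), x = as.numeric(agg_x), y = as.numeric(agg_y),
             stringsAsFactors = FALSE)
}

#' Per-cell surface growth intensity and growth anisotropy
#'
#' Growth intensity is the relative projected-area increment per hour:
#' `(area_t2 - area_t) / (area_t * interval_h)`, where `area_t2` sums the
#' footprints of all children (so a dividing cell is measured with its
#' daughters). Growth anisotropy comes from the best-fit linear map of the
#' parent footprint onto the union of its children's footprints, estimated
#' from matched 3-cell wall junction points (identified across frames by the
#' identity sets of their adjacent cells, mapped through the lineage), with a
#' second-moment (inertia-tensor) fallback when fewer than three junctions
#' match. With singular values `s1 >= s2` of the map, anisotropy is
#' `(s1 - s2) / (s1 + s2)` (0 for isotropic scaling or pure rotation) and
#' the principal direction is the leading singular direction in the
#' projection plane.
#'
#' @param labels_t,labels_t2 `cell_label_map`s of consecutive frames.
#' @param lineage a `lineage_map` from [build_lineage()].
#' @param log_growth if `TRUE`, report `log(area_t2 / area_t) / interval_h`
#'   instead of the relative increment.
#' @param anisotropy_method `"auto"` (junction matching with second-moment
#'   fallback, the default), `"junctions"` (junctions only; cells without
#'   enough matches get `NA`) or `"moments"`.
#' @return data frame, one row per parent: `parent`, `area_t`, `area_t2`,
#'   `growth_intensity` (per hour), `anisotropy`, `dir_x`, `dir_y`,
#'   `n_junctions`, `method` ("junctions" or "moments"). Parents with zero
#'   projected area are skipped (QC attribute).
#' @export
compute_growth <- function(labels_t, labels_t2, lineage, log_growth = FALSE,
                           anisotropy_method = c("auto", "junctions",
                                                 "moments")) {
  anisotropy_method <- match.arg(anisotropy_method)
  fp1 <- project_labels(labels_t)
  fp2 <- project_labels(labels_t2)
  sp1 <- labels_t$spacing; sp2 <- labels_t2$spacing
  pxa1 <- sp1[1] * sp1[2]; pxa2 <- sp2[1] * sp2[2]
  pairs <- lineage$pairs
  parents <- sort(unique(pairs$parent))
  max2 <- max(fp2, 1L)
  plut <- integer(max(max2, max(pairs$child)))
  plut[pairs$child] <- pairs$parent

  a1 <- table(factor(fp1[fp1 > 0], levels = parents))
  area_t <- as.numeric(a1) * pxa1
  names(area_t) <- parents
  fp2p <- fp2
  nz <- fp2p > 0L & fp2p <= length(plut)
  fp2p[nz] <- plut[fp2p[nz]]              # children expressed as parents
  a2 <- table(factor(fp2p[fp2p > 0], levels = parents))
  area_t2 <- as.numeric(a2) * pxa2
  names(area_t2) <- parents

  j1 <- junctions2d(fp1, sp1, labels_t$origin)
  j2 <- junctions2d(fp2, sp2, labels_t2$origin, relabel = plut)
  common <- intersect(j1$key, j2$key)
  j1m <- j1[match(common, j1$key), , drop = FALSE]
  j2m <- j2[match(common, j2$key), , drop = FALSE]
  key_sets <- strsplit(common, "-")

  skipped <- integer(0)
  rows <- vector("list", length(parents))
  for (pi in seq_along(parents)) {
    p <- parents[pi]
    at <- area_t[[pi]]; at2 <- area_t2[[pi]]
    if (is.na(at) || at <= 0) { skipped <- c(skipped, p); next }
    gi <- if (log_growth) log(at2 / at) / lineage$interval_h
      else (at2 - at) / (at * lineage$interval_h)
    touch <- vapply(key_sets, function(k) as.character(p) %in% k, TRUE)
    Fm <- NULL; meth <- "moments"; nj <- sum(touch)
    if (anisotropy_method != "moments" && nj >= 3) {
      P1 <- as.matrix(j1m[touch, c("x", "y")])
      P2 <- as.matrix(j2m[touch, c("x", "y")])
      if (qr(scale(P1, scale = FALSE))$rank == 2) {
        fit <- stats::lsfit(P1, P2)
        Fm <- t(fit$coefficients[-1, , drop = FALSE])
        meth <- "junctions"
      }
    }
    if (is.null(Fm) && anisotropy_method == "junctions") {
      rows[[pi]] <- data.frame(parent = p, area_t = at, area_t2 = at2,
                               growth_intensity = gi, anisotropy = NA_real_,
                               dir_x = NA_real_, dir_y = NA_real_,
                               n_junctions = nj, method = "junctions",
                               stringsAsFactors = FALSE)
      next
    }
    if (is.null(Fm)) {
      ij1 <- which(fp1 == p, arr.ind = TRUE)
      ij2 <- which(fp2p == p, arr.ind = TRUE)
      if (nrow(ij1) < 4 || nrow(ij2) < 4) { skipped <- c(skipped, p); next }
      X1 <- sweep(cbind(ij1[, 1] * sp1[1], ij1[, 2] * sp1[2]), 2,
                  c(mean(ij1[, 1]) * sp1[1], mean(ij1[, 2]) * sp1[2]))
      X2 <- sweep(cbind(ij2[, 1] * sp2[1], ij2[, 2] * sp2[2]), 2,
                  c(mean(ij2[, 1]) * sp2[1], mean(ij2[, 2]) * sp2[2]))
      C1 <- crossprod(X1) / nrow(X1)
      C2 <- crossprod(X2) / nrow(X2)
      Fm <- sqrtm2(C2) %*% solve(sqrtm2(C1))
    }
    sv <- svd(Fm)
    s <- sv$d
    rows[[pi]] <- data.frame(parent = p, area_t = at, area_t2 = at2,
                             growth_intensity = gi,
                             anisotropy = (s[1] - s[2]) / (s[1] + s[2]),
                             dir_x = sv$u[1, 1], dir_y = sv$u[2, 1],
                             n_junctions = nj, method = meth,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame()
  attr(out, "qc") <- list(skipped = skipped)
  out
}

# symmetric positive-definite square root of a 2x2 matrix
sqrtm2 <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
}
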