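#' Align multiple meristems on the stem-cell domain
#'
#' Each meristem is brought into a common "atlas" frame by a rigid 2D
#' transform: translate its CLV3-domain centroid to the origin, then rotate
#' so that the azimuth of a designated reference primordium (the youngest
#' annotated one) is zero. The CLV3 domain itself is rotationally symmetric,
#' so the primordium annotation is what fixes the rotation.
#'
#' @param sams list of meristem samples; each a list with `observations` (a
#'   data frame with at least `x`, `y` positions in micrometres plus any
#'   per-cell quantity columns), `clv3_centroid` (length 2) and
#'   `ref_primordium` (length 2, position of the reference primordium).
#'   Samples missing the CLV3 reference are skipped with a warning.
#' @return list with `observations` (combined data frame with `sam`, atlas
#'   `x`, `y`, polar `r`, `azimuth_deg` and all quantity columns) and
#'   `transforms` (per-sample list `translation`, `rotation_deg`).
#' @export
align_sams <- function(sams) {
  obs_all <- list(); transforms <- list()
  for (s in seq_along(sams)) {
    sam <- sams[[s]]
    if (is.null(sam$clv3_centroid)) {
      warning(sprintf("sample %d has no CLV3 reference: skipped", s))
      next
    }
    th <- if (!is.null(sam$ref_primordium)) {
      v <- sam$ref_primordium[1:2] - sam$clv3_centroid[1:2]
      atan2(v[2], v[1])
    } else 0
    Rm <- matrix(c(cos(-th), sin(-th), -sin(-th), cos(-th)), 2)
    ob <- sam$observations
    xy <- cbind(ob$x - sam$clv3_centroid[1], ob$y - sam$clv3_centroid[2])
    xy <- xy %*% t(Rm)
    ob$x <- xy[, 1]; ob$y <- xy[, 2]
    ob$r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
    ob$azimuth_deg <- (atan2(xy[, 2], xy[, 1]) * 180 / pi) %% 360
    ob <- cbind(data.frame(sam = s), ob)
    obs_all[[length(obs_all) + 1L]] <- ob
    transforms[[s]] <- list(translation = -sam$clv3_centroid[1:2],
                            rotation_deg = -th * 180 / pi)
  }
  if (length(obs_all) == 0) stop("no alignable samples")
  list(observations = do.call(rbind, obs_all), transforms = transforms)
}

#' Average aligned per-cell quantities onto a polar atlas grid
#'
#' Population-scale maps: per-bin unweighted means across all contributing
#' cells of all aligned meristems, on a polar grid (radius x azimuth) about
#' the CLV3 centroid. Bins with no data are masked (`NA`), not zero.
#'
#' @param observations aligned observation table from [align_sams()] (needs
#'   `r`, `azimuth_deg`, `sam` and the quantity columns).
#' @param quantities character vector of observation columns to average.
#' @param r_max outer radius of the grid (default: max observed).
#' @param dr radial bin width, micrometres (default 2).
#' @param daz azimuthal bin width, degrees (default 5).
#' @return an object of class `sam_atlas`: `r_edges`, `az_edges`, `n`
#'   (counts matrix, radius x azimuth), `mean` (named list of matrices),
#'   `n_sams`.
#' @export
average_map <- function(observations, quantities, r_max = NULL, dr = 2,
                        daz = 5) {
  if (nrow(observations) == 0) stop("empty observation set")
  if (is.null(r_max)) r_max <- max(observations$r)
  r_edges <- seq(0, r_max + dr, by = dr)
  az_edges <- seq(0, 360, by = daz)
  ri <- pmin(findInterval(observations$r, r_edges,
                          rightmost.closed = TRUE), length(r_edges) - 1)
  ai <- pmin(findInterval(observations$azimuth_deg %% 360, az_edges,
                          rightmost.closed = TRUE), length(az_edges) - 1)
  nr <- length(r_edges) - 1; na <- length(az_edges) - 1
  idx <- (ai - 1) * nr + ri
  n <- matrix(0L, nr, na)
  cnt <- table(factor(idx, levels = seq_len(nr * na)))
  n[] <- as.integer(cnt)
  means <- lapply(quantities, function(q) {
    sums <- tapply(observations[[q]], factor(idx, levels = seq_len(nr * na)),
                   sum)
    m <- matrix(as.numeric(sums) / ifelse(n > 0, n, NA), nr, na)
    m
  })
  names(means) <- quantities
  structure(list(r_edges = r_edges, az_edges = az_edges, n = n,
                 mean = means, n_sams = length(unique(observations$sam))),
            class = "sam_atlas")
}

#' @export
print.sam_atlas <- function(x, ...) {
  cat(sprintf(
    "sam_atlas: %d x %d polar bins (dr = %g um, daz = %g deg), %d meristem(s), quantities: %s\n",
    length(x$r_edges) - 1, length(x$az_edges) - 1, diff(x$r_edges[1:2]),
    diff(x$az_edges[1:2]), x$n_sams, paste(names(x$mean), collapse = ", ")))
  cat(sprintf("  populated bins: %d of %d\n", sum(x$n > 0), length(x$n)))
  invisible(x)
}

#' Per-region means of an observation quantity
#'
#' @param observations data frame with a `region` column.
#' @param quantity column name.
#' @return named numeric vector of per-region means.
#' @export
region_means <- function(observations, quantity) {
  tapply(observations[[quantity]], observations$region, mean)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (exclusion of the central
#' zone, where used, is applied upstream via a region filter). Constant
#' input yields an undefined coefficient, returned as `NA` with
#' `flagged = TRUE` rather than an error.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return list `rho`, `p`, `flagged`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, flagged = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|`, with the exact p-value for small samples and
#' the asymptotic one otherwise (two-sided).
#'
#' @param a,b non-empty numeric samples.
#' @return list `D`, `p`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Critical two-sample KS distance
#'
#' Asymptotic critical value `c(alpha) * sqrt((n + m) / (n * m))` with
#' `c(alpha) = sqrt(-log(alpha / 2) / 2)`.
#'
#' @param alpha significance level.
#' @param n,m sample sizes.
#' @return critical D.
#' @export
ks_critical <- function(alpha, n, m) {
  sqrt(-log(alpha / 2) / 2) * sqrt((n + m) / (n * m))
}

#' PCA of per-cell observations
#'
#' Principal component analysis on z-scored variables (typically signaling,
#' growth intensity, growth anisotropy and CLV3 expression), components
#' ordered by explained variance. The sign convention — each loading
#' vector's largest-magnitude entry is positive — makes repeated runs
#' bit-identical. Zero-variance variables are dropped with a warning.
#'
#' @param observations data frame of per-cell observations.
#' @param variables character vector of (at least 2) column names.
#' @return list `loadings` (variables x components), `explained_pct`,
#'   `scores`.
#' @export
pca_cells <- function(observations, variables) {
  stopifnot(length(variables) >= 2)
  X <- as.matrix(observations[, variables, drop = FALSE])
  stopifnot(nrow(X) > length(variables))
  v <- apply(X, 2, stats::sd)
  if (any(v == 0)) {
    warning(sprintf("dropping zero-variance variable(s): %s",
                    paste(variables[v == 0], collapse = ", ")))
    X <- X[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  L <- pc$rotation
  S <- pc$x
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]; S[, j] <- -S[, j]
    }
  }
  list(loadings = L,
       explained_pct = 100 * pc$sdev^2 / sum(pc$sdev^2),
       scores = S)
}

#' IPR to non-IPR mean intensity ratio
#'
#' Ratio of the mean intensity over the inter-primordia region to the mean
#' over the non-IPR (primordia excluded from the non-IPR side), a per-image
#' scalar used to quantify IPR enrichment of a fluorescent signal.
#'
#' @param values numeric vector of intensities (e.g. voxel or nucleus
#'   values).
#' @param regions character vector of the same length (`"CZ"`, `"IPR"`,
#'   `"P"`).
#' @return the IPR / non-IPR mean-intensity ratio.
#' @export
region_intensity_ratio <- function(values, regions) {
  stopifnot(length(values) == length(regions))
  ipr <- values[regions == "IPR"]
  non <- values[regions != "IPR" & regions != "P"]
  if (length(ipr) == 0 || length(non) == 0)
    stop("IPR and non-IPR regions must both be non-empty")
  mean(ipr) / mean(non)
}

#' Standard group-comparison tests (thin wrappers)
#'
#' `welch_t` is the two-sided Welch two-sample t-test; `kruskal_wallis` the
#' Kruskal-Wallis rank-sum test across groups. Both delegate to the standard
#' routines and return `statistic` and `p`.
#'
#' @param x,y numeric samples.
#' @return list `statistic`, `p`.
#' @export
welch_t <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}

#' @rdname welch_t
#' @param values numeric vector.
#' @param groups grouping factor of the same length.
#' @export
kruskal_wallis <- function(values, groups) {
  kt <- stats::kruskal.test(values, as.factor(groups))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Write atlas and observation tables
#'
#' @param atlas a `sam_atlas`.
#' @param observations aligned observation table.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, observations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  nr <- length(atlas$r_edges) - 1; na <- length(atlas$az_edges) - 1
  for (q in names(atlas$mean)) {
    m <- atlas$mean[[q]]
    df <- data.frame(quantity = q,
                     r_lo = rep(atlas$r_edges[-(nr + 1)], na),
                     az_lo = rep(atlas$az_edges[-(na + 1)], each = nr),
                     mean = as.vector(m), n = as.vector(atlas$n))
    rows[[q]] <- df[df$n > 0, , drop = FALSE]
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "atlas.csv"),
                   row.names = FALSE)
  utils::write.csv(observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  invisible(dir)
}
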