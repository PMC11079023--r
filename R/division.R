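#' Detect new cell walls between two time points
#'
#' For every lineage parent with two or more children, the new wall is the
#' shared boundary of each child pair in the top-down projection: the crack
#' points between 4-adjacent pixels of the two children, reduced to an
#' ordered polyline (skeleton) along the wall's principal axis. A parent with
#' three children (two division rounds in one interval) yields one event per
#' child pair that actually shares a boundary; child pairs without a shared
#' boundary are dropped and logged.
#'
#' @param labels_t,labels_t2 `cell_label_map`s of consecutive frames.
#' @param lineage a `lineage_map`.
#' @return an object of class `division_events`: a list of events, each with
#'   `parent`, `children` (length 2), `polyline` (n x 2 matrix, micrometres,
#'   frame-t2 coordinates), `midpoint` (the polyline point nearest the wall
#'   centroid). A `qc` attribute lists dropped child pairs.
#' @export
detect_new_walls <- function(labels_t, labels_t2, lineage) {
  fp2 <- project_labels(labels_t2)
  sp <- labels_t2$spacing
  org <- labels_t2$origin
  d <- dim(fp2)
  pairs <- lineage$pairs
  divs <- split(pairs$child, pairs$parent)
  divs <- divs[vapply(divs, length, 1L) >= 2]
  events <- list()
  dropped <- list()
  for (pname in names(divs)) {
    chs <- divs[[pname]]
    for (a in seq_along(chs)) for (b in seq_along(chs)) {
      if (a >= b) next
      ca <- chs[a]; cb <- chs[b]
      pts <- shared_boundary_points(fp2, ca, cb, sp, org)
      if (is.null(pts) || nrow(pts) < 2) {
        dropped[[length(dropped) + 1L]] <- c(as.integer(pname), ca, cb)
        next
      }
      poly <- order_polyline(pts)
      cen <- colMeans(poly)
      mid <- poly[which.min((poly[, 1] - cen[1])^2 + (poly[, 2] - cen[2])^2), ]
      events[[length(events) + 1L]] <- list(parent = as.integer(pname),
                                            children = c(ca, cb),
                                            polyline = poly,
                                            midpoint = as.numeric(mid))
    }
  }
  structure(events, class = "division_events",
            qc = list(dropped_pairs = dropped))
}

shared_boundary_points <- function(fp, la, lb, spacing, origin) {
  d <- dim(fp)
  pts <- NULL
  # vertical cracks (neighbours along x)
  m <- fp[1:(d[1] - 1), ] == la & fp[2:d[1], ] == lb |
    fp[1:(d[1] - 1), ] == lb & fp[2:d[1], ] == la
  ij <- which(m, arr.ind = TRUE)
  if (nrow(ij) > 0)
    pts <- rbind(pts, cbind(origin[1] + (ij[, 1] - 0.5) * spacing[1],
                            origin[2] + (ij[, 2] - 1) * spacing[2]))
  # horizontal cracks (neighbours along y)
  m <- fp[, 1:(d[2] - 1)] == la & fp[, 2:d[2]] == lb |
    fp[, 1:(d[2] - 1)] == lb & fp[, 2:d[2]] == la
  ij <- which(m, arr.ind = TRUE)
  if (nrow(ij) > 0)
    pts <- rbind(pts, cbind(origin[1] + (ij[, 1] - 1) * spacing[1],
                            origin[2] + (ij[, 2] - 0.5) * spacing[2]))
  pts
}

order_polyline <- function(pts) {
  cen <- colMeans(pts)
  X <- sweep(pts, 2, cen)
  v <- svd(X)$v[, 1]
  pts[order(X %*% v), , drop = FALSE]
}

#' Measure a division-plane angle relative to the radial axis
#'
#' The wall's orientation is the principal direction of a total-least-squares
#' line fit to its polyline points (robust to curved skeletons; an
#' endpoint-to-endpoint chord variant is available). The angle to the radial
#' direction (meristem centre to wall midpoint) is folded to the acute range:
#' 0 degrees is a radial wall, 90 degrees a circumferential/transverse one.
#'
#' @param event one element of [detect_new_walls()] output (or any list with
#'   `polyline` and `midpoint`).
#' @param sam_center length-2 meristem centre, micrometres.
#' @param method `"tls"` (default) or `"chord"`.
#' @return angle in degrees, `[0, 90]`.
#' @export
measure_division_angle <- function(event, sam_center, method = c("tls", "chord")) {
  method <- match.arg(method)
  poly <- event$polyline
  if (is.null(poly) || nrow(poly) < 2) stop("wall polyline needs >= 2 points")
  if (method == "tls") {
    X <- sweep(poly, 2, colMeans(poly))
    if (all(abs(X) < 1e-12)) stop("zero-length wall")
    w <- svd(X)$v[, 1]
  } else {
    w <- poly[nrow(poly), ] - poly[1, ]
    if (sqrt(sum(w^2)) < 1e-12) stop("zero-length wall")
  }
  r <- event$midpoint[1:2] - sam_center[1:2]
  nr <- sqrt(sum(r^2))
  if (nr < 1e-9) stop("midpoint coincides with the meristem centre")
  cosang <- abs(sum(w * r)) / (sqrt(sum(w^2)) * nr)
  acos(pmin(1, pmax(0, cosang))) * 180 / pi
}

#' Classify positions into meristem regions
#'
#' Central zone (CZ): within `cz_radius` of the meristem centre. Primordium
#' (P): inside any primordium disc. Inter-primordia region (IPR): everything
#' else (peripheral-zone cells between primordia). All in the top-down plane.
#'
#' @param position n x 2 matrix (or length-2 vector) of positions,
#'   micrometres.
#' @param geometry a `sam_geometry` (e.g. `truth$geometry` from the
#'   generator, or built from a CLV3 centroid and primordium annotations via
#'   [sam_geometry_from()]).
#' @return character vector: `"CZ"`, `"IPR"` or `"P"`.
#' @export
classify_region <- function(position, geometry) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  dx <- pos[, 1] - geometry$center[1]
  dy <- pos[, 2] - geometry$center[2]
  reg <- rep("IPR", nrow(pos))
  reg[sqrt(dx^2 + dy^2) <= geometry$cz_radius] <- "CZ"
  pr <- geometry$primordia
  if (!is.null(pr)) for (i in seq_len(nrow(pr))) {
    d <- sqrt((pos[, 1] - pr$x[i])^2 + (pos[, 2] - pr$y[i])^2)
    reg[d <= pr$radius[i] & reg != "CZ"] <- "P"
  }
  reg
}

#' Build a region-classification geometry from annotations
#'
#' @param center meristem centre (e.g. CLV3-domain centroid), length 2.
#' @param cz_radius central-zone radius, micrometres.
#' @param primordia optional data frame `x`, `y`, `radius` (and optionally
#'   `stage`) of primordium discs, micrometres.
#' @return a `sam_geometry`.
#' @export
sam_geometry_from <- function(center, cz_radius, primordia = NULL) {
  sam_geometry(center, cz_radius, primordia)
}

#' Frequency histogram of division-plane angles
#'
#' Counts angles in nine 10-degree bins, right-open except the last
#' (`[0,10), ..., [70,80), [80,90]` — keeping 90-degree events, the most
#' informative class, countable), and expresses them as percentages of the
#' cohort.
#'
#' @param angles numeric vector of angles in `[0, 90]` degrees.
#' @param cohort label for the cohort (e.g. `"SAM"`, `"IPR"`, `"non-IPR"`).
#' @return an object of class `angle_histogram`: `bin_edges` (0, 10, ...,
#'   90), `frequencies` (percent, summing to 100), `counts`, `n_events`,
#'   `cohort`.
#' @export
division_histogram <- function(angles, cohort = "SAM") {
  if (length(angles) == 0) stop("empty cohort")
  if (any(!is.finite(angles) | angles < 0 | angles > 90))
    stop("angles must lie in [0, 90]")
  bin <- pmin(floor(angles / 10) + 1, 9)
  counts <- tabulate(bin, 9)
  structure(list(bin_edges = seq(0, 90, by = 10),
                 frequencies = 100 * counts / sum(counts),
                 counts = counts, n_events = length(angles),
                 cohort = cohort),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat(sprintf("angle_histogram (%s): n = %d\n", x$cohort, x$n_events))
  lab <- sprintf("%d-%d", x$bin_edges[-10], x$bin_edges[-1])
  cat(paste(sprintf("  %s: %5.2f%%", lab, x$frequencies), collapse = "\n"),
      "\n")
  invisible(x)
}

#' @export
plot.angle_histogram <- function(x, ...) {
  graphics::barplot(x$frequencies, names.arg = sprintf("%d-%d",
                    x$bin_edges[-10], x$bin_edges[-1]),
                    xlab = "division angle to radial axis (deg)",
                    ylab = "frequency (%)", main = x$cohort, ...)
  invisible(x)
}

#' Cell division frequency per region
#'
#' Number of division events per cell per frame interval, by region.
#'
#' @param event_regions character vector, region of each division event.
#' @param cell_regions character vector, region of each cell at the earlier
#'   frame.
#' @return data frame `region`, `n_divisions`, `n_cells`, `frequency`
#'   (divisions per cell per interval; `NA` with a warning where a region
#'   has no cells).
#' @export
division_frequency <- function(event_regions, cell_regions) {
  regs <- sort(unique(c(event_regions, cell_regions)))
  nd <- table(factor(event_regions, levels = regs))
  nc <- table(factor(cell_regions, levels = regs))
  freq <- as.numeric(nd) / as.numeric(nc)
  empty <- as.numeric(nc) == 0
  if (any(empty)) {
    warning(sprintf("region(s) with no cells: %s",
                    paste(regs[empty], collapse = ", ")))
    freq[empty] <- NA_real_
  }
  data.frame(region = regs, n_divisions = as.integer(nd),
             n_cells = as.integer(nc), frequency = freq)
}

#' Table of division events with angles and regions
#'
#' Convenience wrapper running [measure_division_angle()] and
#' [classify_region()] over a set of events.
#'
#' @param events a `division_events` list.
#' @param sam_center length-2 meristem centre, micrometres.
#' @param geometry optional `sam_geometry` for region classification.
#' @return data frame `parent`, `child1`, `child2`, `mx`, `my`,
#'   `angle_deg`, `region`.
#' @export
division_table <- function(events, sam_center, geometry = NULL) {
  if (length(events) == 0)
    return(data.frame(parent = integer(0), child1 = integer(0),
                      child2 = integer(0), mx = numeric(0), my = numeric(0),
                      angle_deg = numeric(0), region = character(0)))
  rows <- lapply(events, function(ev) {
    data.frame(parent = ev$parent, child1 = ev$children[1],
               child2 = ev$children[2], mx = ev$midpoint[1],
               my = ev$midpoint[2],
               angle_deg = measure_division_angle(ev, sam_center),
               region = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(geometry))
    out$region <- classify_region(as.matrix(out[, c("mx", "my")]), geometry)
  out
}
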