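drift_spec <- function(seed, dt, dr) {
  sam_spec(dome_radius = 40, n_cells_L1 = 120, cz_radius = 10, seed = seed,
           division_fraction = 0, growth_field = c(CZ = 0, IPR = 0),
           drift_translation = dt, drift_rotation_deg = dr)
}

test_that("identical stacks register to the identity", {
  g <- seg_sam()
  reg <- register_timepoints(g$stack, g$stack)
  expect_equal(reg$theta_deg, 0, tolerance = 0.21)
  expect_true(all(abs(reg$translation) <= 1))
  expect_gt(reg$score, 0.95)
})

test_that("imposed rigid drift is recovered within a voxel and a degree", {
  tl <- drift_fixture()
  tt <- tl[[2]]$truth$transform
  reg <- register_timepoints(tl[[1]]$stack, tl[[2]]$stack)
  expect_lt(abs(reg$theta_deg - tt$theta_deg), 1)
  # compare as point maps (rotation centres differ between truth and
  # estimate; the induced map is what matters)
  set.seed(1)
  pts <- cbind(runif(50, -25, 25), runif(50, -25, 25), runif(50, 5, 35))
  th <- tt$theta_deg * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  truth <- cbind(sweep(sweep(pts[, 1:2], 2, tt$center[1:2]) %*% t(Rm), 2,
                       tt$center[1:2] + tt$translation[1:2], "+"),
                 pts[, 3] + tt$translation[3])
  rec <- apply_transform(pts, reg)
  expect_lt(max(abs(truth - rec)), 1)
})

test_that("pure rotation is recovered within a degree", {
  tl <- generate_timelapse(drift_spec(11, 1e-3, 8), 2)
  tt <- tl[[2]]$truth$transform
  reg <- register_timepoints(tl[[1]]$stack, tl[[2]]$stack)
  expect_lt(abs(reg$theta_deg - tt$theta_deg), 1)
})

test_that("registration fails loudly on unrelated content", {
  g <- seg_sam()
  set.seed(3)
  junk <- image_stack(list(wall = array(runif(prod(dim(g$stack))), dim(g$stack))),
                      spacing = g$stack$spacing, origin = g$stack$origin)
  expect_error(register_timepoints(g$stack, junk, min_score = 0.5),
               "registration failed")
})

test_that("transforms compose consistently over a three-frame series", {
  tl <- generate_timelapse(drift_spec(14, 3, 6), 3)
  r12 <- register_timepoints(tl[[1]]$stack, tl[[2]]$stack)
  r23 <- register_timepoints(tl[[2]]$stack, tl[[3]]$stack)
  r13 <- register_timepoints(tl[[1]]$stack, tl[[3]]$stack)
  set.seed(2)
  pts <- cbind(runif(30, -20, 20), runif(30, -20, 20), runif(30, 5, 30))
  composed <- apply_transform(apply_transform(pts, r12), r23)
  direct <- apply_transform(pts, r13)
  expect_lt(max(abs(composed - direct)), 2)
})

test_that("apply/invert transform round-trips points", {
  tf <- structure(list(theta_deg = 7, center = c(3, -2, 0),
                       translation = c(4, -3, 1), score = 1),
                  class = "rigid_transform")
  set.seed(4)
  pts <- cbind(runif(20, -30, 30), runif(20, -30, 30), runif(20, 0, 20))
  back <- apply_transform(apply_transform(pts, tf), invert_transform(tf))
  expect_equal(back, pts, tolerance = 1e-10)
})

test_that("overlap lineage is the identity without division or drift", {
  g <- small_sam()
  m <- label_map_from_truth(g)
  lin <- build_lineage(m, m, identity_transform(), interval_h = 10)
  expect_equal(lin$pairs$parent, lin$pairs$child)
  expect_equal(nrow(lin$pairs), 50)
})

test_that("overlap lineage tracks cells and divisions across a real interval", {
  spec <- sam_spec(dome_radius = 40, n_cells_L1 = 120, cz_radius = 10,
                   seed = 5, division_fraction = 0.12,
                   growth_field = c(CZ = 0.005, IPR = 0.01),
                   drift_translation = 3, drift_rotation_deg = 5)
  tl <- generate_timelapse(spec, 2)
  m1 <- label_map_from_truth(tl[[1]])
  m2 <- label_map_from_truth(tl[[2]])
  lin <- build_lineage(m1, m2, transform_from_truth(tl[[2]]), interval_h = 10)
  mm <- merge(lin$pairs, tl[[2]]$truth$lineage, by = "child",
              suffixes = c("_rec", "_true"))
  expect_gt(mean(mm$parent_rec == mm$parent_true), 0.95)
  # every true division parent has two children in the recovered lineage
  divp <- unique(tl[[2]]$truth$divisions$parent)
  nch <- table(lin$pairs$parent)
  expect_gt(mean(nch[as.character(divp)] == 2, na.rm = TRUE), 0.8)
})

test_that("corrections override the automatic assignment verbatim", {
  g <- small_sam()
  m <- label_map_from_truth(g)
  corr <- data.frame(parent = 7, child = 3)
  lin <- build_lineage(m, m, identity_transform(), corrections = corr)
  expect_equal(lin$pairs$parent[lin$pairs$child == 3], 7)
  expect_true(all(lin$pairs$parent[lin$pairs$child != 3] ==
                    lin$pairs$child[lin$pairs$child != 3]))
})

test_that("growth intensity follows the areal increment formula", {
  # two hand-built frames: a 10x10 square footprint growing to 10x20
  lab1 <- array(0L, c(40, 40, 3))
  lab1[11:20, 11:20, 2] <- 1L
  lab2 <- array(0L, c(40, 40, 3))
  lab2[11:20, 11:30, 2] <- 1L
  m1 <- gasigmap:::new_label_map(lab1, list(spacing = c(1, 1, 1),
                                            origin = c(0, 0, 0)))
  m2 <- gasigmap:::new_label_map(lab2, list(spacing = c(1, 1, 1),
                                            origin = c(0, 0, 0)))
  lin <- structure(list(pairs = data.frame(parent = 1L, child = 1L),
                        transform = identity_transform(), interval_h = 10),
                   class = "lineage_map")
  gr <- compute_growth(m1, m2, lin)
  expect_equal(gr$growth_intensity, (200 - 100) / (100 * 10))
  # pure uniaxial stretch x2: anisotropy (2-1)/(2+1)
  expect_equal(gr$anisotropy, 1 / 3, tolerance = 0.05)
  # no change: growth 0, anisotropy ~0
  gr0 <- compute_growth(m1, m1, lin)
  expect_equal(gr0$growth_intensity, 0)
  expect_lt(gr0$anisotropy, 0.05)
  # log-growth option
  grl <- compute_growth(m1, m2, lin, log_growth = TRUE)
  expect_equal(grl$growth_intensity, log(2) / 10)
})

test_that("anisotropy is invariant under rotation and isotropic scaling", {
  # 3x3 grid of cells rotated rigidly: junction matching identifies the map
  # as a rotation (singular values equal), so anisotropy stays ~0
  grid_lab <- function(theta_deg, scale = 1) {
    lab <- array(0L, c(60, 60, 3))
    th <- theta_deg * pi / 180
    for (i in 1:60) for (j in 1:60) {
      # inverse-map the pixel into the unrotated frame
      x <- ((i - 30.5) * cos(-th) - (j - 30.5) * sin(-th)) / scale
      y <- ((i - 30.5) * sin(-th) + (j - 30.5) * cos(-th)) / scale
      if (abs(x) <= 15 && abs(y) <= 15) {
        cx <- min(floor((x + 15) / 10), 2)
        cy <- min(floor((y + 15) / 10), 2)
        lab[i, j, 2] <- 1L + cx + 3L * cy
      }
    }
    lab
  }
  # a 5-degree base orientation keeps the 4-cell corners generically
  # stair-stepped, so junction keys match across frames
  geom <- list(spacing = c(1, 1, 1), origin = c(0, 0, 0))
  m1 <- gasigmap:::new_label_map(grid_lab(5), geom)
  m2 <- gasigmap:::new_label_map(grid_lab(25), geom)
  lin <- structure(list(pairs = data.frame(parent = 1:9, child = 1:9),
                        transform = identity_transform(), interval_h = 10),
                   class = "lineage_map")
  gr <- compute_growth(m1, m2, lin)
  centre <- gr[gr$parent == 5, ]        # inner cell: 4 junctions
  expect_equal(centre$method, "junctions")
  expect_lt(centre$anisotropy, 0.05)
  expect_equal(centre$growth_intensity, 0, tolerance = 0.01)
  # isotropic scaling x1.2: anisotropy ~0, growth (1.2^2 - 1)/10
  m3 <- gasigmap:::new_label_map(grid_lab(5, scale = 1.2), geom)
  gr3 <- compute_growth(m1, m3, lin)
  c3 <- gr3[gr3$parent == 5, ]
  expect_lt(c3$anisotropy, 0.05)
  expect_equal(c3$growth_intensity, (1.2^2 - 1) / 10, tolerance = 0.03)
})

test_that("parents without footprint are skipped and logged", {
  lab1 <- array(0L, c(20, 20, 3)); lab1[5:10, 5:10, 2] <- 1L
  m1 <- gasigmap:::new_label_map(lab1, list(spacing = c(1, 1, 1),
                                            origin = c(0, 0, 0)))
  lin <- structure(list(pairs = data.frame(parent = c(1L, 9L),
                                           child = c(1L, 9L)),
                        transform = identity_transform(), interval_h = 10),
                   class = "lineage_map")
  gr <- compute_growth(m1, m1, lin)
  expect_equal(nrow(gr), 1)
  expect_equal(attr(gr, "qc")$skipped, 9)
})

test_that("imposed growth and anisotropy are recovered per region", {
  sc <- growth_scenario()
  gi <- sc$growth
  counts <- table(gi$region)
  for (r in names(counts)[counts >= 30]) {
    rec <- mean(gi$growth_intensity[gi$region == r])
    tru <- mean((gi$area_factor[gi$region == r] - 1) / 10)
    expect_equal(rec, tru, tolerance = 0.1)
  }
  expect_lt(abs(mean(gi$anisotropy) - mean(gi$aniso_true)), 0.05)
})
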