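toy_obs <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(x = runif(n, -20, 20), y = runif(n, -20, 20),
             signaling = runif(n, 1, 3))
}

test_that("a single meristem aligns onto its own CLV3 centroid", {
  ob <- toy_obs()
  al <- align_sams(list(list(observations = ob, clv3_centroid = c(5, -3),
                             ref_primordium = c(25, -3))))
  expect_equal(al$transforms[[1]]$translation, c(-5, 3))
  expect_equal(al$transforms[[1]]$rotation_deg, 0)
  expect_equal(al$observations$x, ob$x - 5)
  expect_equal(al$observations$y, ob$y + 3)
})

test_that("a rotated copy is brought back by the primordium azimuth", {
  ob <- toy_obs()
  th <- 40 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy_rot <- as.matrix(ob[, c("x", "y")]) %*% t(Rm)
  ob_rot <- ob; ob_rot$x <- xy_rot[, 1]; ob_rot$y <- xy_rot[, 2]
  ref <- c(30, 0); ref_rot <- as.numeric(ref %*% t(Rm))
  al <- align_sams(list(
    list(observations = ob, clv3_centroid = c(0, 0), ref_primordium = ref),
    list(observations = ob_rot, clv3_centroid = c(0, 0),
         ref_primordium = ref_rot)))
  r1 <- al$transforms[[1]]$rotation_deg %% 360
  r2 <- al$transforms[[2]]$rotation_deg %% 360
  expect_equal((r1 - r2) %% 360, 40, tolerance = 1)
  # and the two copies land on identical atlas coordinates
  o1 <- al$observations[al$observations$sam == 1, ]
  o2 <- al$observations[al$observations$sam == 2, ]
  expect_equal(o1$x, o2$x, tolerance = 1e-8)
  expect_equal(o1$y, o2$y, tolerance = 1e-8)
})

test_that("samples without a CLV3 reference are skipped with a warning", {
  ob <- toy_obs()
  expect_warning(al <- align_sams(list(
    list(observations = ob, clv3_centroid = c(0, 0), ref_primordium = c(30, 0)),
    list(observations = ob))), "skipped")
  expect_equal(unique(al$observations$sam), 1)
  expect_error(suppressWarnings(align_sams(list(list(observations = ob)))),
               "no alignable")
})

test_that("polar averaging masks empty bins and averages across meristems", {
  ob1 <- data.frame(sam = 1, x = 5, y = 0, r = 5, azimuth_deg = 0,
                    signaling = 2.0)
  atl1 <- average_map(ob1, "signaling", r_max = 20)
  expect_equal(sum(atl1$n), 1)
  expect_equal(atl1$mean$signaling[atl1$n > 0], 2.0)
  expect_true(all(is.na(atl1$mean$signaling[atl1$n == 0])))
  # two meristems with constant values 2.0 and 2.4: every populated bin 2.2
  ob <- toy_obs(60)
  ob$r <- sqrt(ob$x^2 + ob$y^2)
  ob$azimuth_deg <- (atan2(ob$y, ob$x) * 180 / pi) %% 360
  two <- rbind(cbind(sam = 1, ob[, c("x", "y", "r", "azimuth_deg")],
                     signaling = 2.0),
               cbind(sam = 2, ob[, c("x", "y", "r", "azimuth_deg")],
                     signaling = 2.4))
  atl2 <- average_map(two, "signaling")
  expect_equal(unique(atl2$mean$signaling[atl2$n > 0]), 2.2)
  # atlas of k identical copies equals the single-meristem map bin-by-bin
  one <- cbind(sam = 1, ob[, c("x", "y", "r", "azimuth_deg")], signaling = 2.0)
  three <- do.call(rbind, lapply(1:3, function(s) {
    o <- one; o$sam <- s; o
  }))
  a1 <- average_map(one, "signaling", r_max = 30)
  a3 <- average_map(three, "signaling", r_max = 30)
  expect_equal(a3$mean$signaling, a1$mean$signaling)
  expect_error(average_map(two[0, ], "signaling"), "empty")
})

test_that("atlas averaging is invariant to meristem order", {
  ob <- toy_obs(50)
  ob$r <- sqrt(ob$x^2 + ob$y^2)
  ob$azimuth_deg <- (atan2(ob$y, ob$x) * 180 / pi) %% 360
  ob$sam <- rep(1:2, 25)
  a12 <- average_map(ob, "signaling", r_max = 30)
  a21 <- average_map(ob[order(-ob$sam), ], "signaling", r_max = 30)
  expect_equal(a12$mean$signaling, a21$mean$signaling)
})

test_that("Spearman matches the brute-force rank formula", {
  expect_equal(spearman_cor(1:10, 1:10)$rho, 1)
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  # independent oracle: Pearson correlation of average ranks
  rho_oracle <- cor(rank(x), rank(y))
  expect_equal(spearman_cor(x, y)$rho, rho_oracle, tolerance = 1e-12)
  set.seed(5)
  a <- rnorm(9); b <- rnorm(9)
  expect_equal(spearman_cor(a, b)$rho, cor(rank(a), rank(b)),
               tolerance = 1e-12)
  cst <- spearman_cor(rep(1, 5), rnorm(5))
  expect_true(cst$flagged)
  expect_true(is.na(cst$rho))
})

test_that("KS statistic matches an exhaustive ECDF sweep", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(0, 1)$D, 1)
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  # oracle: evaluate |ECDF_a - ECDF_b| on the pooled points
  grid <- sort(unique(c(a, b)))
  D_oracle <- max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), 0)))
  expect_equal(ks_two_sample(a, b)$D, D_oracle)
  set.seed(6)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  grid <- sort(c(x, y))
  D_oracle <- max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), 0)))
  expect_equal(ks_two_sample(x, y)$D, D_oracle)
  expect_lt(ks_two_sample(x, x)$p - 1, 1e-12)
})

test_that("PCA orders components, fixes signs, drops degenerate variables", {
  set.seed(7)
  z <- rnorm(200)
  ob <- data.frame(a = z, b = 2 * z + 1, c = rnorm(200))
  pc <- pca_cells(ob, c("a", "b"))
  expect_equal(pc$explained_pct[1], 100, tolerance = 1e-8)
  pc2 <- pca_cells(ob, c("a", "b", "c"))
  expect_true(all(diff(pc2$explained_pct) <= 1e-12))
  # sign convention: largest-magnitude loading positive, runs bit-identical
  pc3 <- pca_cells(ob, c("a", "b", "c"))
  expect_identical(pc2$loadings, pc3$loadings)
  for (j in seq_len(ncol(pc2$loadings)))
    expect_gt(pc2$loadings[which.max(abs(pc2$loadings[, j])), j], 0)
  ob$d <- 1
  expect_warning(pc4 <- pca_cells(ob, c("a", "c", "d")), "zero-variance")
  expect_equal(nrow(pc4$loadings), 2)
  # independent variables at large n: near-equal explained shares
  set.seed(8)
  big <- data.frame(u = rnorm(1e5), v = rnorm(1e5), w = rnorm(1e5))
  pc5 <- pca_cells(big, c("u", "v", "w"))
  expect_true(all(abs(pc5$explained_pct - 100 / 3) < 2))
})

test_that("region intensity ratio contrasts IPR against the rest", {
  vals <- c(20, 20, 10, 10, 99)
  regs <- c("IPR", "IPR", "CZ", "CZ", "P")     # primordia excluded
  expect_equal(region_intensity_ratio(vals, regs), 2)
  expect_equal(region_intensity_ratio(rep(7, 6),
                                      rep(c("IPR", "CZ"), 3)), 1)
  expect_error(region_intensity_ratio(1:3, rep("P", 3)), "non-empty")
})

test_that("group-test wrappers agree with the standard routines", {
  set.seed(10)
  x <- rnorm(20); y <- rnorm(25, 0.4)
  expect_equal(welch_t(x, y)$p, t.test(x, y)$p.value)
  v <- c(x, y); g <- rep(c("a", "b"), c(20, 25))
  expect_equal(kruskal_wallis(v, g)$p, kruskal.test(v, as.factor(g))$p.value)
})

test_that("atlas tables are written as CSV", {
  ob <- toy_obs(50)
  ob$r <- sqrt(ob$x^2 + ob$y^2)
  ob$azimuth_deg <- (atan2(ob$y, ob$x) * 180 / pi) %% 360
  ob$sam <- 1
  atl <- average_map(ob, "signaling")
  dir <- tempfile()
  write_atlas(atl, ob, dir)
  out <- read.csv(file.path(dir, "atlas.csv"))
  expect_equal(sum(out$n), 50)
  expect_true(file.exists(file.path(dir, "observations.csv")))
  unlink(dir, recursive = TRUE)
})
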