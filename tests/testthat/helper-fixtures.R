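# Shared fixtures, built once per test run and cached. All synthetic: the
# generator is the package's own first-class module, so fixtures are code.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small noiseless dome: 50 cells, 3 primordia; the workhorse single-frame
small_spec <- function(seed = 42, ...) {
  sam_spec(dome_radius = 25, n_cells_L1 = 50, cz_radius = 8,
           primordia = data.frame(azimuth_deg = c(0, 137.5, 275),
                                  distance_um = 19, stage = c(3, 2, 1)),
           seed = seed, ...)
}

small_sam <- function() fixture("small_sam", function() {
  generate_sam_stack(small_spec())
})

# high-SNR dome used for the segmentation agreement checks: same 50 cells on
# a larger dome so cells span ~10 um
seg_spec <- function(seed = 42, ...) {
  sam_spec(dome_radius = 40, n_cells_L1 = 50, cz_radius = 10, seed = seed, ...)
}

seg_sam <- function() fixture("seg_sam", function() {
  generate_sam_stack(seg_spec())
})

seg_map <- function() fixture("seg_map", function() {
  segment_cells(seg_sam()$stack)
})

# growth/anisotropy recovery scenario: 180 cells, imposed per-region growth
# plus a global 1.10 x stretch, analysed with the expert (generator) lineage
growth_scenario <- function() fixture("growth_scenario", function() {
  spec <- sam_spec(dome_radius = 40, n_cells_L1 = 180, cz_radius = 17,
                   voxel_spacing = rep(0.75, 3), seed = 5,
                   division_fraction = 0.12,
                   growth_field = c(CZ = 0.015, IPR = 0.035),
                   anisotropic_stretch = c(1.10, 1.0),
                   drift_translation = 3, drift_rotation_deg = 5)
  tl <- generate_timelapse(spec, 2)
  f1 <- tl[[1]]; f2 <- tl[[2]]
  m1 <- label_map_from_truth(f1)
  m2 <- label_map_from_truth(f2)
  lin <- lineage_from_truth(f2, interval_h = spec$interval_h)
  gr <- compute_growth(m1, m2, lin)
  g <- merge(gr, f2$truth$growth_truth, by.x = "parent", by.y = "label")
  g <- merge(g, f1$truth$cells[, c("label", "region", "rim")],
             by.x = "parent", by.y = "label")
  list(frames = tl, growth = g[!g$rim, ])
})

# wrap a ground-truth label volume as a cell_label_map
label_map_from_truth <- function(frame) {
  gasigmap:::new_label_map(frame$truth$label_volume, frame$stack)
}

# rigid_transform from the recorded drift
transform_from_truth <- function(frame) {
  tt <- frame$truth$transform
  structure(list(theta_deg = tt$theta_deg, center = tt$center,
                 translation = tt$translation, score = 1),
            class = "rigid_transform")
}

# expert lineage (the generator's own), fed through the corrections path
lineage_from_truth <- function(frame, interval_h = 10) {
  tp <- frame$truth$lineage
  structure(list(pairs = tp[order(tp$parent, tp$child), ],
                 transform = transform_from_truth(frame),
                 interval_h = interval_h),
            class = "lineage_map")
}

# best-bipartite (greedy) voxelwise label agreement against ground truth
label_agreement <- function(truth_vol, seg_vol) {
  both <- truth_vol > 0 & seg_vol > 0
  tab <- as.matrix(table(truth_vol[both], seg_vol[both]))
  agree <- 0
  while (length(tab) > 0 && max(tab) > 0) {
    w <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    agree <- agree + tab[w[1], w[2]]
    tab <- tab[-w[1], -w[2], drop = FALSE]
  }
  agree / sum(truth_vol > 0)
}

# division events measured through the full pipeline for one 2-frame run
measured_divisions <- function(spec) {
  tl <- generate_timelapse(spec, 2)
  f1 <- tl[[1]]; f2 <- tl[[2]]
  ev <- detect_new_walls(label_map_from_truth(f1), label_map_from_truth(f2),
                         lineage_from_truth(f2, spec$interval_h))
  list(table = division_table(ev, f2$truth$sam_center, f2$truth$geometry),
       truth = f2$truth$divisions, events = ev, frames = tl)
}

# region of each measured nucleus taken from its nearest ground-truth
# nucleus (separates intensity-recovery checks from geometric
# region-classification checks)
truth_region_of <- function(records, truth) {
  tr <- truth$nuclei
  nn <- vapply(seq_len(nrow(records)), function(i) {
    which.min((tr$x - records$x[i])^2 + (tr$y - records$y[i])^2 +
                (tr$z - records$z[i])^2)
  }, 0L)
  tr$region[nn]
}

# drift-only two-frame series (static biology, rigid drift) for registration
drift_fixture <- function() fixture("drift_fixture", function() {
  generate_timelapse(sam_spec(dome_radius = 40, n_cells_L1 = 120,
                              cz_radius = 10, seed = 12,
                              division_fraction = 0,
                              growth_field = c(CZ = 0, IPR = 0),
                              drift_translation = 4, drift_rotation_deg = 8),
                     2)
})

# numeric CDF of the folded von Mises law on [0, 90] (independent oracle:
# integrates the circular density directly on a fine grid)
folded_vm_cdf <- function(mode_deg, kappa) {
  th <- seq(0, 360, length.out = 14401)[-14401]
  dens <- exp(kappa * cos((th - mode_deg) * pi / 180))
  dens <- dens / sum(dens)
  fold <- pmin(abs(th) %% 180, 180 - abs(th) %% 180)
  function(q) vapply(q, function(a) sum(dens[fold <= a]), 0)
}
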