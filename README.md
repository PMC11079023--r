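# gasigmap

Quantitative image analysis of ratiometric gibberellin (GA) signaling
biosensors in the Arabidopsis shoot apical meristem (SAM), for plant
developmental biologists who need to turn multi-channel confocal stacks
into per-cell signaling, growth and division statistics.

The biosensor co-expresses a GA-degradable sensor fluorophore and a
GA-insensitive nuclear reference fluorophore stoichiometrically, so GA
signaling activity of a nucleus is read out from its channel intensities
as

    S = 3 − I_sensor / I_reference,

with S = 3 the maximal-signaling value (sensor fully degraded) and
negative values flagged as miscalibration. Around this readout the package
provides the full pipeline:

* **quantify** — 3D multi-scale LoG nucleus detection on the reference
  channel, background-subtracted sphere intensities, signaling values,
  per-image ratio standardization (`detect_nuclei()`,
  `measure_intensities()`, `compute_signaling()`, `standardize_ratios()`);
* **cellseg** — seeded 3D watershed from the cell-wall stain (C++
  flooding core), L1 layer extraction, surface-mesh curvature, meristem
  radius from incipient-primordium annotations (`segment_cells()`,
  `extract_L1()`, `estimate_curvature()`, `measure_meristem_radius()`);
* **lineage** — rigid temporal registration on the wall channel, overlap
  lineages with expert corrections, per-cell surface growth intensity and
  growth anisotropy from junction matching (`register_timepoints()`,
  `build_lineage()`, `compute_growth()`);
* **division** — new-wall detection between time points, division-plane
  angles relative to the radial axis folded to [0, 90]°, region
  classification (CZ / IPR / P), angle histograms and division
  frequencies (`detect_new_walls()`, `measure_division_angle()`,
  `division_histogram()`, `division_frequency()`);
* **atlas / stats** — alignment of multiple meristems on the CLV3 domain,
  polar-grid population averaging, Spearman, two-sample KS, PCA, region
  intensity ratios (`align_sams()`, `average_map()`, `spearman_cor()`,
  `ks_two_sample()`, `pca_cells()`, `region_intensity_ratio()`);
* **synthgen** — a synthetic SAM generator (`sam_spec()`,
  `generate_sam_stack()`, `generate_timelapse()`) producing 4-channel
  stacks (wall, sensor, reference, stem-cell domain), time-lapses with
  growth, divisions and recorded drift, and complete ground truth, so the
  entire pipeline is testable without microscopy data.

## Worked example

Simulate a meristem, quantify signaling per region, segment the cells, and
measure division-plane angles across a 10 h interval:

```r
library(gasigmap)

spec <- sam_spec(dome_radius = 40, n_cells_L1 = 120, cz_radius = 10,
                 noise_sd = 2, seed = 1)
sim <- generate_sam_stack(spec)
sim$stack
#> image_stack: 116 x 116 x 60 voxels, 4 channel(s) [wall, sensor, reference, domain]
#>   spacing (um): x=1 y=1 z=1

nuclei  <- detect_nuclei(sim$stack)
records <- measure_intensities(sim$stack, nuclei)
records$region <- classify_region(cbind(records$x, records$y),
                                  sim$truth$geometry)
round(tapply(records$signaling, records$region, mean), 2)
#>  CZ IPR   P
#> 1.5 2.5 1.0
```

The recovered per-region means match the simulated signaling field (high
in the inter-primordia region, intermediate in the central zone, low in
primordia). Segmentation and division statistics:

```r
seg <- extract_L1(segment_cells(sim$stack))
seg
#> cell_label_map: 120 cells, 120 L1-flagged

tl <- generate_timelapse(sam_spec(dome_radius = 40, n_cells_L1 = 120,
        cz_radius = 10, seed = 2, division_fraction = 0.3,
        growth_field = c(CZ = 0.01, IPR = 0.02)), 2)
m1 <- segment_cells(tl[[1]]$stack); m2 <- segment_cells(tl[[2]]$stack)
reg <- register_timepoints(tl[[1]]$stack, tl[[2]]$stack)
reg
#> rigid_transform: rotation -3.60 deg about z, translation (-2.93, 1.19, -2.00) um
lin <- build_lineage(m1, m2, reg, interval_h = 10)
lin
#> lineage_map: 155 children of 116 parents, 32 division(s), interval 10 h

events <- detect_new_walls(m1, m2, lin)
angles <- division_table(events, tl[[2]]$truth$sam_center,
                         tl[[2]]$truth$geometry)
division_histogram(angles$angle_deg[angles$region == "IPR"], cohort = "IPR")
#> angle_histogram (IPR): n = 29
#>   0-10:  6.90%
#>   10-20:  3.45%
#>   20-30:  0.00%
#>   30-40:  3.45%
#>   40-50:  3.45%
#>   50-60: 24.14%
#>   60-70: 20.69%
#>   70-80: 17.24%
#>   80-90: 20.69%
```

90° means a circumferential/transverse division, 0° a radial one: the IPR
cohort is skewed transverse, as simulated (the generator imposed 32 of 34
divisions recoverable here through the fully automatic
registration-segmentation-lineage path).

See the methods vignette (`vignettes/gasigmap-methods.Rmd`) for the model
conventions, parameter defaults, estimator design and known limitations.

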