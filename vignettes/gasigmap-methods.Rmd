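---
title: "Quantitative mapping of GA signaling in the shoot apical meristem: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative mapping of GA signaling in the shoot apical meristem: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasigmap)
```

# The measurement problem

A degradation-based ratiometric biosensor for gibberellin (GA) signaling
co-expresses, from one promoter through a self-cleaving peptide, a
GA-degradable sensor fluorophore (VENUS-like) and a GA-insensitive nuclear
reference fluorophore (TagBFP-like) in stoichiometric amounts. Where GA
signaling is high the sensor protein is degraded, so the sensor/reference
intensity ratio falls. Signaling activity is read out as

$$ S \;=\; 3 - \frac{I_\text{sensor}}{I_\text{reference}}, $$

a convention in which 3 is chosen to cover the observed ratio range: a
nucleus whose sensor pool is fully degraded (ratio 0) reads the maximal
value 3, and ratios above 3 produce negative values that indicate
miscalibration. `compute_signaling()` therefore *flags* negative values via
an attribute but never clips them — clipping would silently hide a
calibration problem.

Around this readout the package implements the full quantitative pipeline
used to map signaling in the shoot apical meristem (SAM): 3D nucleus
detection and ratio quantification, 3D watershed segmentation of cells from
a wall stain, L1 (epidermis) extraction and surface curvature, rigid
temporal registration with lineage-based growth and growth-anisotropy
measurement, division-plane angle statistics relative to the meristem's
radial axis, and population-scale atlas averaging of several meristems
aligned on the stem-cell (CLV3) domain.

# The synthetic meristem generator

Real SAM stacks are large, manually annotated, and unavailable at test
time, so every stage is exercised against a synthetic generator
(`sam_spec()`, `generate_sam_stack()`, `generate_timelapse()`) that
produces images *and* complete ground truth. It emulates:

* a dome-shaped L1 layer — a spherical-cap shell (default radius 50 µm,
  thickness 6 µm) tiled by a Lloyd-relaxed Voronoi tessellation of
  `n_cells_L1` cells;
* a wall channel: cell boundaries and the tissue surface rendered as
  ridges and blurred with a Gaussian point-spread proxy (`wall_sigma`,
  default 0.5 µm);
* one Gaussian nucleus per cell (sigma 1.5 µm) whose noiseless
  sensor/reference ratio equals exactly `3 - S(region)` — the inverse of
  the pipeline's readout, which turns field recovery into a round-trip
  test;
* meristem anatomy: a central zone (CZ) disc, primordia (P) discs whose
  radius grows with stage, and the inter-primordia region (IPR)
  elsewhere; the default signaling field is IPR-high (2.5), CZ
  intermediate (1.5), P low (1.0), matching the qualitative pattern the
  sensor reports in planta;
* a CLV3-like domain channel with a Gaussian radial profile, giving both
  a per-nucleus "CLV3 expression" covariate and the alignment reference;
* time-lapse dynamics: per-region areal growth, cell divisions with
  von Mises-distributed plane orientations folded to [0, 90] degrees, and
  a recorded rigid drift (≤ 5 µm, ≤ 10°) between frames;
* optional additive Gaussian and Poisson noise.

What it deliberately does **not** emulate: photobleaching, chromatic
aberration or depth-dependent attenuation; curved interior tissue (L2/L3
are at most a second plain shell); primordium bulging (primordia are
region labels, not geometric bumps); and cell mechanics (walls are Voronoi
bisectors, not force-balanced shapes). Passing tests therefore demonstrate
correctness of the measurement machinery under controlled conditions, not
robustness to every artefact of live confocal imaging.

## Growth model

`growth_field` is stated per region, but a position-dependent area growth
cannot be realised as a *smooth* transport map while taking different
values for P and IPR at the same radius. The generator therefore
uses an azimuthally symmetric radial transport: the CZ rate applies inside
`cz_radius`, the peripheral (IPR) rate outside, blended linearly over a
6 µm band (about one cell diameter, so the map is smooth at the cell
scale); primordia share the peripheral rate. A global anisotropic stretch
(`anisotropic_stretch`) adds a controlled direction to growth. Ground
truth records each cell's *exact* imposed area factor and 2×2 deformation
gradient from the map's Jacobian, so recovery tests compare against what
was actually imposed, not the nominal region label.

Division geometry: a dividing cell's daughters are seeded symmetrically
about the parent centroid, perpendicular to the sampled wall direction, so
the Voronoi bisector between them *is* the new wall, passing through the
parent centroid at the sampled angle — the simplest model consistent with
angle measurement in projection. The circular (von Mises) family for
division angles is a modelling choice for testing; the true generative law
in planta is unknown.

# Quantification

Nucleus detection (`detect_nuclei()`) is multi-scale Laplacian-of-Gaussian
blob detection run **on the reference channel**, because that channel is
GA-insensitive and present in every nucleus — detection must not be biased
by signaling level. Anisotropic stacks are linearly resampled to isotropic
spacing first; detections closer than `min_blob_distance` (default 3 µm)
merge, keeping the stronger; output is sorted by (z, y, x) so runs are
reproducible. Intensities (`measure_intensities()`) are background-
subtracted means over a sphere of `aggregation_radius` (default 1.5 µm,
matching the nucleus scale). Background is the 5th percentile of
non-tissue voxels (voxels below the channel's Otsu threshold); records
whose reference mean falls below `min_reference` (default 3× the
background MAD) are dropped and counted in a QC log rather than allowed to
produce exploding ratios.

Per-image standardization (`standardize_ratios()`) divides every ratio by
the image mean so that ratio distributions are centred on 1, which makes
distributions comparable between sensor and constitutive control lines;
the raw ratio is kept alongside.

# Cell segmentation and geometry

`segment_cells()` is a seeded 3D watershed on the smoothed wall channel.
The tissue mask is the Otsu-thresholded wall signal with enclosed
cell-interior holes filled; holes above 1% of the stack volume are treated
as voids (e.g. the space beneath a hollow shell), not tissue. Seeds are
the regional minima of the h-minima transform (depth `h_frac`, default 10%
of the wall dynamic range — the standard over-segmentation guard).
Regional minima are computed on the full array and then restricted to the
tissue: restricting first would promote mask-boundary voxels into spurious
minima. Flooding uses a priority queue ordered by intensity with FIFO
tie-breaking, and labels are renumbered by centroid sort, making the
output deterministic. The voxel-level primitives (connected components,
grayscale reconstruction, seeded watershed) are implemented in C++ because
no installed R routine floods a 3D volume as one connected body.

Parameter guidance: `smooth_sigma` (default 0.4 µm) should stay near the
optical PSF width — heavier smoothing visibly degrades boundary placement
— and rise towards ~1 µm only for noisy stacks, where a shallower
`h_frac` (~0.05) also helps keep thin rim walls separating.

L1 extraction defines "outer" background as background visible along an
unobstructed vertical line of sight from the top of the stack (the
objective side); a cell is L1 if its interface with that outer background
reaches `min_area` (3 µm²). This distinguishes the imaged surface from
interior voids even where a curved shell makes the void face sideways.

Surface curvature (`estimate_curvature()`) builds a height map of the
outer surface, smooths it (normalized convolution, default sigma 4 µm —
comparable to the z-quantization terraces a 1 µm grid produces on a dome,
and to the cell scale at which curvature is interpreted) and evaluates the
mean curvature of the graph analytically from its derivatives; a dome is
positive, a sphere of radius R reads 1/R. Near-vertical rim vertices
(slope above ~63°) are excluded from per-cell averages because a height
map cannot represent them; per-cell values are reliable for cells away
from the dome rim, and a flat surface warns and reads zero. The meristem
radius follows the incipient-primordium convention: the mean planar
distance from the (expert or surface-derived) centre to I1 and I2.

# Registration, lineage and growth

`register_timepoints()` estimates a rigid drift — rotation about the
optical axis plus 3D translation — by maximising normalised
cross-correlation of the wall max-projections over a coarse-to-fine
rotation grid (FFT translation search at each angle, zero-mean images so
the score reflects structure, not shared brightness), then correlating z
profiles for the axial shift. The rotation search is restricted to the
optical axis because dissected meristems are re-mounted approximately
upright. The estimator is accurate to well under a voxel and a degree for
rigid drift between near-identical frames; when the tissue grows strongly
between frames (tens of percent in area per interval) no rigid transform
fits the data and the correlation landscape flattens, which is the regime
in which the original protocol relies on expert lineages — `build_lineage()`
accepts a corrections table for exactly this reason, and the growth
analyses in the tests feed the generator's lineage through that path.

`build_lineage()` assigns each later-frame cell to the earlier-frame cell
with maximal projected-footprint overlap after inverse-transforming
through the registration; parents with two or more children mark
divisions; children with no tissue overlap are logged as orphans, not
errors.

`compute_growth()` measures, per parent, the relative projected-area
increment per hour, `(A(t2) - A(t)) / (A(t) * interval)`, with daughters'
footprints summed (a log-growth variant is an option). Growth anisotropy
comes from the best-fit linear map of the parent footprint onto its
children's union: singular values s1 ≥ s2 give `(s1 - s2)/(s1 + s2)`, zero
for isotropic scaling or pure rotation. The map is estimated from matched
3-cell wall junction points — identified across frames by the identity
sets of their adjacent cells mapped through the lineage — with a
second-moment (inertia tensor) fallback when fewer than three junctions
match. Junction matching is preferred because it tracks real material
points and therefore sees rotations as rotations; the moment method
equates shape change with deformation and cannot distinguish a rotation
from a stretch. Both estimators share a caveat: anisotropy is a
non-negative spread statistic, so pixel-quantization noise inflates it by
a few hundredths at 1 µm-scale sampling of ~8 µm cells; recovery tests
therefore use an absolute 0.05 band around the imposed value.

All 2D measurements (footprints, angles, atlas coordinates) use
orthographic projection along the optical axis, consistent with the
max-projection-based manual protocol the pipeline reproduces.

# Division-plane statistics

New walls are the shared projected boundaries of sibling pairs
(`detect_new_walls()`), reduced to an ordered polyline; the division angle
is the acute angle between the wall's principal direction — a total-least-
squares line fit, robust to curved skeletons (an endpoint chord is an
option) — and the radial direction from the meristem centre to the wall
midpoint. Angles fold to [0, 90]: 0° is radial, 90° circumferential/
transverse. Histograms use nine 10° bins, right-open except the last, so
90° events — the most informative class — stay countable; frequencies are
percentages of the cohort. Region classification is geometric: CZ within
`cz_radius` of the centre, P inside annotated primordium discs, IPR
otherwise. Division frequency is events per cell per interval and is
reported per region.

# Atlas and statistics

`align_sams()` puts each meristem into a common frame by translating its
CLV3-domain centroid to the origin and rotating the azimuth of a
designated reference primordium (the youngest annotated one) to zero —
the CLV3 domain itself is rotationally symmetric, so a primordium is
needed to fix the rotation. `average_map()` bins aligned per-cell values
onto a polar grid (defaults 2 µm × 5°, a compromise between spatial detail
and per-bin occupancy at typical cell densities) as unweighted means over
cells — meristems contributing more cells weigh more; bins with no data
are masked, never zero-filled.

The statistical operations — Spearman rank correlation with average ranks,
two-sample Kolmogorov–Smirnov (exact p at small n), PCA on z-scored
variables with a deterministic sign convention (each loading vector's
largest-magnitude entry positive), Welch t and Kruskal–Wallis — are thin,
contract-tested wrappers over the standard R routines; the test suite
cross-checks them against brute-force oracles (explicit rank formula,
exhaustive ECDF sweeps). The IPR/non-IPR intensity ratio excludes
primordia from the non-IPR side, following the readout used to show IPR
enrichment of a GA-fluorescein tracer.

# Reproducibility and problem sizes

Every generator run is fully determined by its spec and seed (identical
spec + seed gives bit-identical voxels), and every analysis step is
deterministic given its input, so the whole pipeline is reproducible from
a single integer. The test-suite study conditions were chosen once as
realistic desk-scale meristems: 50-cell domes of radius 25–40 µm at 1 µm
isotropic voxels for detection/segmentation round trips; a 180-cell dome
at 0.75 µm voxels with CZ rate 0.015 h⁻¹, peripheral rate 0.035 h⁻¹ and a
1.10 global stretch over a 10 h interval for growth recovery; ~200 pooled
division events for distribution recovery; 15% division fraction per 10 h
(a realistic level of division activity for this tissue); drift within ±5 µm and ±10°.

# Known limitations

* Rigid registration degrades under strong between-frame growth (by
  design it is rigid); use expert/ground-truth lineages there.
* Curvature is restricted to surface patches a height map can represent;
  the near-vertical dome rim is excluded per cell.
* The anisotropy estimators carry a small positive quantization bias
  (see above).
* Overlap lineage assumes cell displacement below about one cell radius
  per interval after registration; beyond that, corrections are required.
* Primordium positions and stages are annotations (or generator truth):
  no automatic primordium detection is provided.
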