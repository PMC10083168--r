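---
title: "Nulla-centered retinal volumetry: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nulla-centered retinal volumetry: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retvol)
```

## The measurement problem

Cynomolgus monkeys are the standard non-human primate in preclinical ocular
studies because, like humans, they have a fovea. OCT volumetry of the macula
must be anchored to an anatomical landmark, since the animals cannot fixate:
any scan-placement offset otherwise propagates into the readout. The pipeline
implemented here anchors everything to the **nulla**, the deepest point of
the inner limiting membrane (ILM) inside the foveolar depression, and then
measures retinal volume inside a 3000 µm cylinder centered on it.

The pipeline has four stages:

1. **Segmentation** — every pixel of every B-scan is labelled vitreous,
   retina, choroid or sclera. In production this labelling comes from a
   validated learned segmenter; this package ships a deterministic
   intensity-threshold segmenter with the identical output contract so the
   full pipeline is testable offline, and ingests external label maps
   directly (`read_label_volume()`).
2. **Nulla detection** — the ILM is the first retina pixel per A-scan; the
   nulla is the argmax (most posterior point) of the median-smoothed ILM
   depth map (`extract_ilm()`, `find_nulla()`).
3. **Grid construction** — a 3 mm-diameter footprint around the nulla is
   partitioned into three concentric zones Z1–Z3 (ring diameters 1, 2,
   3 mm), four 90° quadrants Q1–Q4 bounded by the ±45° diagonals, and nine
   slices: the central disc S1 (identical to Z1 by definition), four
   inner-ring sectors S2–S5 and four outer-ring sectors S6–S9
   (`build_region_masks()`).
4. **Volumetry** — retina-labelled voxels are counted per region and scaled
   by the physical voxel volume (`compute_region_volumes()`).

On top of the per-eye measurements, the reference-database statistics
(`summarize_volumes()`, `correlation_block_summary()`, `pca_slices()`,
`manova_slices()`, `anova_per_slice()`) characterise a cohort: grouped
summaries, Pearson correlation blocks among the three region families,
covariance PCA of the slice volumes, and two-factor (sex × origin) MANOVA
and per-slice ANOVA with Bonferroni-corrected significance stars.

## Scan geometry and units

The default `scan_geometry()` encodes a 20° 25-line macular raster from a
spectral-domain device: 25 B-scans at 221 µm spacing, 512 × 496 px per
B-scan, 5.3 mm scan length, 1.9 mm scan depth. Everything physical follows
from three pixel pitches — lateral 5.3/512 ≈ 10.35 µm, slow-axis 221 µm,
axial 1.9/496 ≈ 3.83 µm — giving a voxel volume of 8.76 × 10⁻⁶ mm³. Each
A-scan column represents a lateral-pitch × 221 µm en-face footprint: with a
25-line raster the slow axis is by far the coarsest dimension, and several
numerical consequences below follow from that.

## The phantom

`synthesize_label_volume()` builds label volumes with exactly known ground
truth. The ILM carries a single Gaussian pit,

$$z_\mathrm{ILM}(r) = z_0 + d\,e^{-r^2 / 2\sigma^2},$$

with depth `pit_depth_um` (default 120 µm) and width `pit_sigma_um`
(default 400 µm); a Gaussian is the simplest shape with a unique,
controllable deepest point. Retinal thickness follows a radial profile
interpolated linearly between r = 0, 1.0 and 2.5 mm. The default profile —
212 µm foveal, 358 µm parafoveal, 312 µm peripheral — was calibrated
analytically (closed-form annulus integrals of the piecewise-linear profile)
so that the zone volumes equal the normative means 0.205, 0.768 and
1.375 mm³ to within 0.15%. `true_region_volumes()` integrates the same
continuous profile by radial midpoint quadrature at 0.25 µm steps — about
40× finer than the lateral pixel pitch and independent of the voxel-counting
code path — and serves as the analytic oracle throughout the tests.

What the phantom does **not** emulate: OCT speckle, vascular shadowing,
curvature of the posterior pole, pathology, or the error characteristics of
a learned segmenter. Tests passing on phantoms therefore demonstrate the
correctness of the measurement geometry and statistics, not robustness to
real-scan artifacts.

## The cohort simulator

`simulate_cohort()` operates directly at the volume level — statistics need
distributional structure, not pixels — drawing per-eye 9-slice vectors from
a multivariate normal. Defaults reproduce the normative study conditions:
187 animals × 2 eyes = 374 eyes; 39.3% female eyes; 4.3% of animals of
unknown origin (these exercise the exclusion rule in the MANOVA/ANOVA
stages) and 55.6% of the remainder Mauritian; slice means and CVs at the
normative right-eye table values; uniform 0.5 between-slice correlation
(the observed mean among-slice correlation is 0.49). The real study drew
374 eyes from 203 animals; the simulator keeps a rectangular design (every
animal contributes both eyes) for simplicity. Sex and origin act as additive
per-slice offsets, zero by default and injectable for power studies.

Zones and quadrants are linear in the slices: Z1 = S1, Z2 = S2+…+S5,
Z3 = S6+…+S9, and Q_k = S1/4 + inner + outer sector slice. The quadrant
rule is confirmed by the normative quadrant means, which equal the
corresponding slice sums to print precision.

Fellow eyes share an animal-level random intercept with intraclass
correlation `icc` (default 0.8, marginal covariance unchanged). No published
value exists for the fellow-eye covariance of these volumes; 0.8 is a
plausible stand-in for a bilateral anatomical trait and is configurable. The
analyses treat eyes as independent, as the reference analysis does, so the
ICC affects only the simulator's effective sample size, not the estimators.

## Numerical choices

- **Column-center-in-region assignment.** An A-scan column belongs to a
  region iff its en-face center lies inside it; no partial-area weighting.
  All radial and angular intervals are half-open for deterministic boundary
  assignment. Consequence: at 221 µm slab spacing the discrete footprint of
  the 0.5 mm-radius central disc centered on a B-scan line is 361 columns =
  0.8259 mm², a **+5.15% positive bias** against π·0.25 mm² (an exact
  combinatorial count, not an implementation artifact). The bias falls to
  +1.1% at 2× and below 0.1% at 4× A-scan/B-scan density; the outer rings,
  quadrants and zones Z2/Z3 are far less affected (≲2%). Users comparing S1
  or Z1 against continuous-geometry references should expect this
  discretization scale. No interpolation between B-scans is performed.
- **"Deepest" = largest axial row index**, since B-scans render vitreous at
  the top.
- **Median smoothing before the argmax** (default window 5, odd, 1
  disables): first along each B-scan, then across B-scans, ignoring invalid
  columns; robust to isolated segmentation errors.
- **Plateau-centroid tie-break.** ILM depths are integer rows, so the
  smoothed depth maximum is typically a plateau of tied columns (~60–70 µm
  radius for the default pit). Ties are broken by distance to the plateau
  centroid — the unbiased estimate of the pit center — then by distance to
  the scan center, then by B-scan/A-scan index. On a flat ILM the plateau
  spans the whole search window, so the rule reduces to "nearest valid
  column to the scan center". A nearest-scan-center-first rule would drag an
  offset nulla toward the scan center by the plateau radius (~7 A-scans).
  No sub-pixel refinement is attempted; the 221 µm slow-axis quantization is
  accepted and the recovery guarantee is ±1 A-scan / ±1 B-scan.
- **Segmentation cleanup.** Pixels are assigned to the nearest class mean;
  a per-column axial median-3 pass removes isolated flips (which would
  otherwise split a class's largest run and displace the rebuilt boundary by
  many pixels); then the largest contiguous run per class defines the
  boundaries, enforced monotone top-to-bottom. Columns without a retina run,
  or with out-of-order runs, are flagged but still labelled.
- **Clipped ROI policy.** When the 3 mm footprint exceeds the scan, volumes
  are computed on the available columns and the clipped fraction (share of
  ideal footprint centers outside the scan) is reported; no extrapolation.
- **Full-depth cylinders.** Retina voxels are counted over the entire
  columns assigned to a region; the retina/choroid boundary, not an axial
  crop, bounds the count.
- **Cohort CSV at 9 decimal places** (mm³), so a write→read round trip is
  the identity to better than 10⁻⁹ mm³.

## Statistical choices

- **Type II sums of squares** for the unbalanced two-factor design, for both
  MANOVA (Wilks' Λ with Rao's F, exact at one hypothesis df) and the
  per-slice ANOVAs. The fit-with-interaction / drop-if-insignificant /
  refit-additive workflow is the type II scenario. Interactions are retained
  only below p = 0.01 (MANOVA) and p = 0.01/9 (per-slice ANOVA), matching
  the reference workflow. Both implementations are direct model-comparison
  computations on shared QR decompositions (fast enough for the replicated
  power studies) and are cross-checked in the test suite against
  `stats::anova.mlm` and `car::Anova(type = "II")`.
- **PCA on the covariance matrix**, not the correlation matrix: all nine
  slices share mm³ units. Eigenvector signs are fixed by making each
  component's largest-magnitude coefficient positive. Explained variance is
  the robust, comparable quantity; coefficient magnitudes depend on
  normalization conventions and are not emphasised.
- **Bonferroni stars** divide the significance levels by the nine slice
  tests, with strict inequalities: `***` p < 0.001/9, `**` p < 0.01/9,
  `*` p < 0.05/9.
- **Eyes as independent observations**, per the reference analysis; OD and
  OS are analysed separately for PCA/MANOVA/ANOVA and pooled (configurably)
  for the correlation blocks. Unknown-origin records are excluded before any
  factor analysis, and left/right counts are always reported per side rather
  than assumed.
- Age and weight are carried as metadata but not used as covariates.

## Problem sizes in the test suite

Unit tests run on a reduced raster (25 × 127 × 200 px; the odd A-scan count
puts a column center exactly at the lateral scan center, preserving the
rotational symmetries being tested). The acceptance checks use the full
device raster, a 5 × 5 grid of pit offsets spanning ±1 mm, 200 simulated
cohorts of 374 eyes for the injected-effect power study and 500 for the
null-calibration study. The convergence checks double and quadruple the
A-scan/B-scan density.

## Known limitations

- The slow axis is sampled at 221 µm by the device; central-disc volumes
  carry the +5% discretization bias quantified above, and nulla localisation
  in the slow axis is quantized to one B-scan.
- The rule-based segmenter is a contract-compatible stand-in, not a model of
  a learned segmenter's errors.
- The uniform-correlation default of the cohort simulator reproduces the
  *average* between-slice correlation, not the anatomical correlation
  structure; component patterns beyond the leading "global size" factor
  (e.g. axis-specific contrasts) are not identifiable from it and require
  real per-eye data.
- Single-device geometry; no claims of inter-device comparability.
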