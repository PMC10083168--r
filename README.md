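# retvol

Nulla-centered retinal volumetry and normative reference-database statistics
for cynomolgus monkey OCT.

Cynomolgus monkeys (*Macaca fascicularis*) are the standard non-human
primate in preclinical ocular research because they have a fovea. Unlike
human subjects they cannot fixate, so macular OCT measurements must be
anchored to an anatomical landmark rather than to scan placement. `retvol`
implements that measurement pipeline and the statistics used to build a
normative reference database from it, for ophthalmic imaging scientists and
preclinical study teams:

1. **Semantic labels** — every B-scan pixel is labelled vitreous / retina /
   choroid / sclera. External label maps (e.g. from a learned segmenter) are
   ingested directly; a deterministic intensity-threshold segmenter with the
   same output contract is included so the pipeline runs end-to-end offline.
2. **Nulla detection** — the inner limiting membrane (ILM) is the first
   retina pixel per A-scan; the *nulla* is its deepest (most posterior)
   point, found as the argmax of the median-smoothed ILM depth map.
3. **Nulla-centered grid** — a 3000 µm cylinder around the nulla is
   partitioned into zones **Z1–Z3** (ring diameters 1, 2, 3 mm), quadrants
   **Q1–Q4** (±45° diagonal boundaries, nasal/temporal mirrored between OD
   and OS) and slices **S1–S9** (central disc S1 ≡ Z1, four inner-ring and
   four outer-ring sectors).
4. **Volumetry** — regional volume = (retina voxels in the region's
   columns) × voxel volume; for the default 25-line raster (221 µm spacing,
   512 × 496 px, 5.3 × 1.9 mm) one voxel is (5.3/512) × 0.221 × (1.9/496) =
   8.76 × 10⁻⁶ mm³.
5. **Reference-database statistics** — grouped summaries (mean, SD, median,
   range, CV), Pearson correlation blocks among the three region families,
   covariance PCA of S1–S9, two-factor (sex × origin) MANOVA with Wilks' Λ,
   and per-slice type II ANOVA with Bonferroni-corrected stars
   (`***` p < 0.001/9, `**` p < 0.01/9, `*` p < 0.05/9).

A parametric digital phantom (Gaussian foveal pit + radial thickness
profile, with an analytic volume oracle) and a cohort simulator with
injectable sex/origin effects make every stage testable without scanner
data. See the methods vignette (`vignettes/retinal-volumetry.Rmd`) for the
models, numerical choices and limitations.

## Worked example

Measure one synthetic eye end-to-end, then analyse a simulated cohort:

```r
library(retvol)

geom <- scan_geometry()                          # 25 x 512 x 496, 221 um
vol  <- synthesize_label_volume(geom, phantom_params())
eye  <- process_eye(vol, eye = "OD")
eye[c("Z1", "Z2", "Z3", "nulla_b", "nulla_x", "clipped_fraction")]
#> # A tibble: 1 x 6
#>      Z1    Z2    Z3 nulla_b nulla_x clipped_fraction
#>   <dbl> <dbl> <dbl>   <int>   <int>            <dbl>
#> 1 0.216 0.768  1.34      13     256                0
```

The nulla is recovered at the central B-scan/A-scan and the zone volumes
land on the normative means (0.205 / 0.768 / 1.375 mm³) up to the raster's
discretization: the central disc spans only five B-scans at 221 µm spacing,
which carries a quantified +5% footprint bias on Z1 (see the vignette); the
outer zones are within ~2%.

```r
cohort <- simulate_cohort(effect_design(seed = 7))   # 374 eyes, 187 animals
summarize_volumes(cohort, "Z1")
#> # A tibble: 1 x 8
#>   region count  mean    std   min median   max     cv
#>   <chr>  <int> <dbl>  <dbl> <dbl>  <dbl> <dbl>  <dbl>
#> 1 Z1       374 0.205 0.0166 0.158  0.205 0.256 0.0810
```

The simulated central-zone volume reproduces the configured normative
distribution: mean 0.205 mm³ with a CV of ~8%. Fitted-model results come as
tidy tibbles:

```r
tidy(pca_slices(cohort, "OD"))[1:3, ]
#> # A tibble: 3 x 4
#>   component eigenvalue explained_fraction cumulative_fraction
#>   <chr>          <dbl>              <dbl>               <dbl>
#> 1 PC1         0.00113              0.581                0.581
#> 2 PC2         0.000228             0.118                0.699
#> 3 PC3         0.000155             0.0798               0.779

tidy(manova_slices(cohort, "OD"))
#> # A tibble: 2 x 6
#>   term   wilks statistic   df1   df2 p.value
#>   <chr>  <dbl>     <dbl> <dbl> <dbl>   <dbl>
#> 1 sex    0.933     1.38      9   173   0.200
#> 2 origin 0.973     0.528     9   173   0.853
```

Here no group effects were injected, so Wilks' Λ stays near 1 and nothing is
significant — inject effects through `effect_design(sex_effect_mm3 = ...,
origin_effect_mm3 = ...)` to study power. `autoplot()` (PCA scree),
`plot_cohort_volumes()` (grouped boxplots) and `plot_region_masks()`
(en-face grid raster) cover the standard figures, and
`read_cohort_table()` / `write_cohort_table()` move cohorts through a
canonical CSV schema, including ingestion of foreign per-eye tables via a
column map.

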