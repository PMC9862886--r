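# fhnquant

3D quantification of femoral head necrosis (FHN / avascular necrosis) from
segmentation label maps, in R.

Clinical staging of FHN leans on 2D angular surrogates such as the modified
Kerboul angle — the sum of the necrotic arc angles in the midcoronal and
midsagittal MR planes, measured at the femoral head centre. Given 3D
segmentations of the necrotic and unaffected bone (labels: 0 background,
1 unaffected, 2 necrotic), lesion burden can instead be measured directly.
This package implements that measurement protocol and everything needed to
validate it without patient data:

* **Volumetry & surface protocol** — voxel volumetry at native spacing;
  triangulated outer-surface extraction (marching tetrahedra on a smoothed
  indicator); consensus fitting of the flat neck-cut plane where the
  segmentation ends; removal of every face within 3 mm of that plane; and
  per-face tissue attribution, yielding the six parameters per hip:
  necrotic volume `V_n`, unaffected volume `V_u`, `%V_n = 100·V_n/(V_n+V_u)`,
  necrotic surface `S_n`, head surface `S_h`, and `%S_n = 100·S_n/S_h`.
* **Modified Kerboul angle** — least-squares head-sphere fit, mid-plane
  slice selection, and the angular span of the necrotic boundary at the
  head centre, summed over the coronal and sagittal planes.
* **Synthetic phantoms with closed-form truth** — spherical-sector lesions
  (volume `(2/3)πR³(1−cosθ)`, cap area `2πR²(1−cosθ)`, trimmed head zone
  `2πR(R+d−3)`, Kerboul `4θ`) on a 0.8 mm isotropic grid or a
  160×30×160-voxel 0.44×2.4×0.44 mm coronal grid, plus a Dice-calibrated
  boundary-noise model emulating automatic segmentation and an
  early/advanced cohort generator.
* **Statistics** — per-label Dice, paired t-tests with 95% CIs and Pearson
  correlations, exact/corrected Mann–Whitney U group comparisons with
  medians and IQRs, and CSV/JSON report tables.
* **Pipeline & CLI** — `run_pipeline()` (simulate → quantify → kerboul →
  compare) with one JSON config, per-stage reuse, checksummed manifests;
  subcommands via `inst/cli/fhnquant`.

## Worked example

```r
library(fhnquant)

# a 25 mm femoral head with a 45-degree superior necrotic sector,
# neck cut 15 mm below the centre, 0.8 mm isotropic grid
ph <- generate_phantom(phantom_spec(head_radius = 25, wedge_half_angle = 45))

quantify_case(ph$volume)
#> <necrosis_metrics> Vn 9.48 cm^3 | Vu 50.70 cm^3 | %Vn 15.7% |
#>                    Sn 11.58 cm^2 | Sh 59.75 cm^2 | %Sn 19.4%

modified_kerboul(ph$volume)
#> <kerboul> coronal 91.0 + sagittal 91.0 = 182.0 degrees
```

The closed-form truth for this phantom is `V_n = 9.58 cm³`,
`S_n = 11.50 cm²`, trimmed `S_h = 58.12 cm²`, and a modified Kerboul angle
of `4·45 = 180°`: the pipeline recovers the volume within ~1%, the surfaces
within ~3%, and the angle within 2°. Emulating an automatic segmentation at
the calibration Dice levels:

```r
auto <- perturb_segmentation(ph$volume, noise_spec(0.75, 0.91, seed = 7))
attr(auto, "achieved_dice")
#>   necrotic unaffected
#>  0.7660025  0.9073228
```

A full synthetic study (30 hips, three segmentation sources each, all
report tables) is one call:

```r
res <- run_pipeline(run_config("runs/demo", seed = 1))
res$report$group   # early-vs-advanced medians, IQRs, Mann-Whitney p
```

## Layout

```
R/                  mask I/O + containers, phantoms, quantification,
                    Kerboul, statistics, pipeline, CLI
src/surface.cpp     smoothing, marching tetrahedra, field sampling (Rcpp)
tests/testthat/     unit + property tests; test-acceptance.R holds the
                    acceptance criteria
scripts/acceptance.R
vignettes/fhn-quantification-methods.Rmd   methods & design rationale
inst/cli/fhnquant   command-line entry point
```
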