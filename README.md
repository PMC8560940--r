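# gmaxff

Automated quantification of intramuscular fat (IMF) in the gluteus maximus
(GMAX) from two-point Dixon MRI, with the full cohort statistics used to
relate muscle fat infiltration to physical activity and hip pain.

## Who this is for

Musculoskeletal imaging groups measuring muscle quality from Dixon scans.
A Dixon acquisition yields co-registered water (W) and fat (F) images; the
voxelwise **fat fraction**

    FF = F / (W + F)

is a quantitative marker of IMF. Given a 3D muscle label map and two bone
landmarks, the package computes per-muscle summary metrics:

- **mean FF** over the *muscle bulk* — the GMAX portion between the axial
  slice of the lesser-trochanter (LT) tip and the slice at the level of the
  anterior superior iliac spine (ASIS), both slices included;
- **volume** (labelled bulk voxels x voxel volume) and
  **lean volume** = volume x (1 − FF), a proxy for contractile tissue;
- both volumes normalized by **lean body mass** from the Boer formula
  (male `0.407 w + 0.267 h − 19.2`; female `0.252 w + 0.473 h − 48.3`,
  w in kg, h in cm).

Because real scans of this kind are rarely shareable, the package also ships
a **synthetic Dixon phantom and cohort generator** with exact ground truth
(`W = PD(1 − ff)`, `F = PD·ff`, so the noiseless ratio reproduces the true
field), which is how every pipeline stage is validated.

The statistics module implements the full analysis of an activity-group
study: Shapiro–Wilk normality gates; descriptive mean ± SD / median (IQR)
tables by group and sex; tie-corrected Kruskal–Wallis omnibus tests (exact
permutation p-values at small n) with rank-based Tukey HSD post hocs; paired
left/right Wilcoxon signed-rank tests (exact under ties via the signed-rank
generating function); the Q3 + 1.5·IQR high-FF outlier rule; a hierarchical
linear regression (`ff_hlm`) entering gender, BMI, age, activity level, OHS
grade, side and pain side sequentially with ΔR² and block-F retention;
logistic models (`ff_logistic`) for activity and hip-pain status with Wald
odds-ratio intervals; and two-group sample-size and ΔR² (partial-F) power
calculators.

## Worked example

```r
library(gmaxff)

# a noisy Dixon phantom with known constant FF = 0.22
spec <- phantom_spec(ff_field = list(type = "constant", p = 0.22),
                     noise = list(type = "gaussian", sd = 2), seed = 42)
b <- generate_phantom(spec, subject_id = "demo")

ffm <- compute_ff_map(b$study)
m <- muscle_metrics(ffm, extract_bulk(b$label, b$landmarks, "left"), 1)
print(m)
#> GMAX_left: FF 21.99%, 14380 voxels (0 undefined), volume 6.2 ml, lean 4.8 ml
#>   bulk slices: 6-41 (0-based, inclusive)
```

The estimated mean FF (21.99 %) recovers the injected 22 % despite channel
noise; 14380 bulk voxels at the 0.47 × 0.47 × 1.95 mm protocol resolution
give 6.2 ml of muscle, of which 4.8 ml is lean tissue.

```r
boer_lbm("male", 80, 180)
#> [1] 61.42
```

A synthetic 70-subject cohort (groups of 19/13/18/20; hip-pain patients and
low/mid/high-activity healthy subjects) generated from a known linear model
and fed to the hierarchical regression:

```r
sim <- generate_cohort_table(cohort_spec(seed = 1))
fit <- ff_hlm(sim$table)
summary(fit)
#> Step table:
#>  step          label delta_r2 cum_r2  p_value retained
#>     1  Gender (male) 1.35e-01  0.135 8.02e-06     TRUE
#>     2            BMI 3.10e-01  0.445 6.68e-15     TRUE
#>     3            Age 2.14e-02  0.467 2.08e-02     TRUE
#>     4 Activity level 1.46e-01  0.613 2.79e-09     TRUE
#>     5      OHS grade 9.64e-04  0.614 5.67e-01    FALSE
#>     6   Side (right) 5.53e-02  0.669 7.02e-06     TRUE
#>     7      Pain side 7.86e-07  0.669 9.86e-01    FALSE
```

The blocks that truly drive FF in the generating model (gender, BMI, age,
activity, side) are retained; the null blocks (OHS grade, pain side) are
excluded by the ΔR²-and-significance rule. The fitted coefficients (e.g.
male −4.07, BMI 0.98, Pain +6.34, right side −3.54, in FF percentage points)
estimate the generator's −3.8 / 0.9 / 7.2 / −3.0 within sampling error.

The full imaging path — simulate phantoms, quantify each subject, assemble
the cohort, run every statistic — is:

```r
sim <- simulate_bundles(cohort_spec(seed = 7),
                        phantom_spec(noise = list(type = "gaussian", sd = 2)))
tab <- quantify_cohort(sim$bundles, metadata = sim$cohort$subjects)
report <- cohort_report(tab, seed = 7)
print(report)
```

A thin CLI over the same functions lives in `inst/cli/gmaxff.R`
(`simulate`, `quantify-subject`, `run-cohort`, `stats` subcommands).

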