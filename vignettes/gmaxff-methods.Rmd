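---
title: "Measuring gluteus maximus fat infiltration from Dixon MRI: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gluteus maximus fat infiltration from Dixon MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmaxff)
```

## The measurement model

Two-point Dixon MRI separates the proton signal into a water image $W$ and a
fat image $F$ on the same grid. The voxelwise fat fraction

$$\mathrm{FF} = \frac{F}{W + F}$$

is a quantitative measure of intramuscular fat (IMF): the adipose tissue
between and among muscle fibres within the muscle bed, as opposed to
intermuscular adipose tissue (IMAT) lying between muscle groups. Labelling
voxels *inside* the muscle is what keeps IMAT out of the measurement; the
labels themselves are an input to this package, not something it computes.

Given a 3D label map for left and right gluteus maximus (GMAX) and two bone
landmarks per side, the package measures the **muscle bulk**: the axial
slices from the one containing the tip of the lesser trochanter (LT) up to
the one at the level of the anterior superior iliac spine (ASIS), inclusive
at both ends. Restricting to the bulk standardizes the measurement and
avoids the tendinous inferior portion of the muscle. Per muscle we report

- mean FF over the labelled bulk voxels with defined FF,
- volume $V = n_{\text{voxels}} \cdot v_{\text{voxel}}$ (ml),
- lean volume $V(1 - \mathrm{FF})$,
- both volumes divided by Boer lean body mass (ml/kg), making muscle size
  comparable across body compositions.

Subject-level FF is the unweighted mean of the left and right bulk means
(not a pooled voxel mean), so a smaller muscle contributes equally to the
bilateral summary.

### Assumptions

* Water/fat separation has already been performed correctly; we never model
  the Dixon reconstruction itself (echoes, fat spectrum, $B_0$).
* All channels and the label map are co-registered; readers verify shape
  equality and affine agreement within $10^{-4}$ mm and refuse to resample.
* Intensities are non-negative and finite.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `signal_floor` | 0 | signal units | voxels with $W + F \le$ floor have undefined FF |
| `erosion_voxels` | 0 | voxels | optional 6-connected mask erosion before measuring |
| voxel size | 0.47 × 0.47 × 1.95 | mm | protocol resolution; always read from the header |
| `alpha` | 0.05 | — | significance level for every test and the retention rule |
| `quantile_rule` | `linear` | — | quartile convention (`hinges` selectable) |

**Undefined-FF voxels.** $W = F = 0$ gives 0/0. Such voxels (background,
air, or below `signal_floor`) are excluded from every FF average but still
counted in the volume, which is anatomical rather than signal-dependent. The
undefined count is reported per muscle so the exclusion can be audited. This
choice avoids arbitrary 0/0 artifacts while keeping volumes stable; the
alternative (dropping them from volume too) would make volume depend on coil
shading.

**Erosion.** Dixon-based labelling inside the muscle has inherently low
IMAT cross-talk, so no erosion is applied by default; the option exists for
users who want a guard band at the fascia.

**Boundary conventions.** Activity hours partition as $[0,4)$ Low,
$[4,8]$ Mid, $(8,\infty)$ High — the boundary values 4 and 8 are Mid, the
only partition consistent with "less than 4", "between 4 and 8" and "more
than 8". OHS totals grade as 0–19 Severe, 20–29 Moderate, 30–39 Mild,
40–48 Satisfactory. Landmark voxel coordinates are 0-based and slice ranges
are inclusive at both ends.

**Boer coefficients** (male $0.407w + 0.267h - 19.2$; female
$0.252w + 0.473h - 48.3$) are hard-coded from the 1984 reference with a
`coefficients` escape hatch.

## The synthetic phantom: what it emulates and what it does not

`generate_phantom()` builds a two-channel study from a known FF field using
the signal model $W = \mathrm{PD}(1-\mathrm{ff})$, $F = \mathrm{PD}\cdot
\mathrm{ff}$, which makes the noiseless ratio reproduce the field exactly —
so any noiseless pipeline error is a code defect, not a modelling artifact.
Muscles are ellipsoids (sufficient to exercise masking, landmark slicing
and volumetrics; not anatomical), the FF field is constant, a linear
superior–inferior gradient, or constant plus Gaussian texture, and channel
noise is Gaussian per channel by default with a Rician (magnitude) option.
At the SNR of muscle imaging the FF ratio is insensitive to that choice,
which is why Gaussian is the default. The default grid is 96 × 96 × 48 at
the protocol voxel size, giving ≈ 1.4 × 10⁴ bulk voxels per muscle —
large enough that estimator noise is far below biological contrasts, small
enough for seconds-scale tests. Real GMAX labels average ~10⁶ voxels, so
phantom-scale error bounds are conservative for real data.

Every phantom carries a truth record computed *inside the generator* by
direct summation of the stored field over the label and slice range — a
code path independent of the quantification module, so truth-vs-pipeline
comparisons are genuine dual-route checks.

What passing phantom tests does **not** show about real data: segmentation
quality (labels are inputs), bias-field and motion artifacts, Dixon
water–fat swaps, and partial-volume effects at the fascia are all outside
the simulation.

## The synthetic cohort

`generate_cohort_table()` draws a four-group cohort — hip-pain patients and
Low/Mid/High-activity healthy subjects — with group sizes 19/13/18/20,
gender splits 7/12, 8/5, 7/11, 16/4, and the observed age ranges and BMI
distributions as defaults. FF (percentage points) is generated either from
the linear model

$$\mathrm{ff} = \beta_0 + \beta_{male} + \beta_{BMI}\,\mathrm{BMI} +
\beta_{age}\,\mathrm{age} + \beta_{group} + \beta_{right} + \varepsilon$$

with default coefficients −3.8 (male), 0.9 (BMI), 0.1 (age), 7.2/5.2/1.8
(Pain/Low/Mid vs High) and −3.0 (right side), $\varepsilon \sim N(0, 4)$ —
the magnitudes reported for this kind of cohort, so recovery tests run at a
realistic signal-to-noise — or from per-group lognormal draws (group
medians sitting below group means in observed data suggest right skew;
normal is selectable) plus a per-subject additive side offset. No intercept
is reported for such models in the literature we mirror; the default
$\beta_0 = -5.7$ was chosen once so that predicted group means land in the
observed 13–28 % range, and is not revisited. Generated FF is truncated to
[0, 100]; under the default parameters truncation affects well under 1 % of
draws.

Healthy subjects carry OHS grade 4 ("Satisfactory"): they have no hip
dysfunction, and a numeric 1–4 grade must be defined on every row for the
grade to be usable as a cohort-wide predictor. This makes the OHS grade
partially collinear with patient status by construction — exactly the
situation the retention rule is meant to adjudicate.

Normalized volume is generated higher in the High-activity group and in
men, and lean volume is derived from volume and FF, so volume statistics
exercise realistic group contrasts without asserting literature values.

`generate_imaging_cohort()` closes the loop: each subject's tabular FF
becomes the constant field of their phantom, so the imaging pipeline can be
validated against the tabular analysis end-to-end.

## Statistical procedures and numerical choices

**Kruskal–Wallis.** Tie-corrected $H$ referred to $\chi^2_{k-1}$; for total
$n \le 9$ (or on request) the p-value is exact by full enumeration of the
$\binom{n}{n_1, \dots, n_k}$ distinct group assignments. The omnibus test
runs on subject-level (side-averaged) values.

**Post hoc.** Tukey's HSD applied to the rank-transformed data, keeping the
post hoc consistent with the nonparametric omnibus test; raw-scale HSD is
selectable. All $k(k-1)/2$ pairs are reported with familywise-adjusted p.

**Wilcoxon signed-rank** for left/right pairing. Zero differences are
dropped before ranking (Pratt's method selectable). For $n \le 25$ the
p-value is exact, computed from the generating function
$\prod_i (1 + x^{2r_i})/2^n$ of the signed-rank sum — midranks are doubled
to land on an integer grid, so the distribution stays exact under ties,
where the classical no-ties tables do not apply. Above that, a normal
approximation with continuity correction and the midrank-based variance
$\sum r_i^2 / 4$ is used. The reported effect is the median paired
difference.

**Outliers.** Threshold $Q_3 + 1.5\,\mathrm{IQR}$ over the healthy
subjects, flagging strictly greater values. The quartile rule matters at
these sample sizes, hence the `linear`/`hinges` switch; published
thresholds of this kind are generally not reproducible without knowing the
rule, and we do not treat any particular printed threshold as ground truth.

**Hierarchical regression.** OLS models grow by blocks in a fixed entry
order; side-level rows count as independent observations (a deliberate
replication of the source design — a mixed model with a subject random
effect would be the modern alternative and is a known limitation). The
activity reference level is High, so Pain/Low/Mid coefficients are
increases over the most active group. A block is retained iff its block-F
p-value is below α *and* it strictly increases $R^2$; coefficient tables
are reported both at the step of entry and in the final refit, since
either convention appears in published tables. Collinear blocks either
abort (default) or are flagged and skipped (`on_collinear = "skip"`, used
by the report driver) — never silently dropped.

**Logistic models.** Subject-level rows; outcomes Not-Active (Pain + Low)
vs Active (Mid + High) and Pain vs healthy. Wald 95 % CIs on the log-odds
scale (profile likelihood would be asymmetric; Wald matches the symmetric
intervals conventional in this literature). Separation and
non-convergence are detected and reported.

**Power calculators.** The two-group sample size uses
$n = 2(z_{1-\alpha/2} + z_{1-\beta})^2 (\sigma/\delta)^2$ with an optional
noncentral-t refinement. At δ = 3 FF points, σ = 4, power 0.8, two-sided
α = 0.05 this gives 28 per group. The ΔR² power uses the partial-F
noncentral distribution with $f^2 = \Delta R^2 / (1 - R^2_{full})$ and
$\lambda = f^2 n$.

**Degenerate inputs.** All-identical observations: $H = 0$, $p = 1$,
flagged. All-zero paired differences: $p = 1$, flagged. Empty muscle
labels, all-undefined FF, empty bulks and empty strata are errors or
explicit flags, never silent NaNs.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: masked
means against an explicit triple loop; exact Kruskal–Wallis against a
differently-coded enumeration scored by `stats::kruskal.test`; exact
Wilcoxon against brute-force $2^n$ sign patterns and `stats::wilcox.test`;
phantom truth against direct re-summation; regression recovery against the
generator's coefficients (exact on noiseless data, unbiased within 3 Monte
Carlo SEs at residual sd 4 with 500 replicates of 140 side-rows); the
single-binary-predictor odds ratio against the 2 × 2 cross-product; and
test calibration at 2000 null replicates per test (empirical size within 3
binomial SEs of 0.05). The two-group imaging benchmark uses 8 + 8 subjects
with channel noise at 2 % of proton density and requires the estimated
group FF difference to err by less than 0.6 percentage points, the error
bound quoted for automated tools of this class; with > 10⁴ bulk voxels per
muscle the observed error is two orders of magnitude below the bound.
These sizes were chosen as the smallest that make the Monte Carlo bands
meaningful.

## Known limitations

- Sides are treated as independent observations in the side-level
  regression; within-subject correlation is not modelled.
- No multiplicity control beyond the HSD family; descriptive and paired
  tests are reported unadjusted.
- Phantoms do not simulate segmentation error, bias fields, motion, or
  water–fat swaps.
- The DICOM series import of a scanner workflow is out of scope: NIfTI is
  the on-disk format.
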