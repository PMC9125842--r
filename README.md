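# wmcvol

White matter change (WMC) volumetry on FLAIR-like brain images and
analysis of its association with outcome after shunt surgery in
idiopathic normal pressure hydrocephalus (iNPH).

Hyperintense white matter lesions on FLAIR MRI are common in iNPH and
it has long been debated whether they should discourage shunt surgery.
Answering that requires (a) measuring lesion volumes — total WMC, its
periventricular (PVH) and deep (DWMH) compartments, and the lateral
ventricles — and (b) relating those volumes to the postoperative change
in symptoms. `wmcvol` implements both halves as a tested, reproducible
pipeline, aimed at researchers who want to run, audit or extend this
kind of volumetric outcome study.

## What it computes

**Volumetry.** Images are rescaled so the in-brain maximum is 100%;
WMC are the voxels of a search mask with normalised intensity in
[min%, 100], where the per-subject minimum is operator-chosen or
suggested by a robust deterministic rule. Scripted brush strokes
(spatial + intensity-range weighted, the semi-automatic editing model)
clean the segmentation; seeded region growing delineates the lateral
ventricles; a pencil-thin ependymal rim — a normal ageing finding — is
removed by a distance-transform rule. The PVH compartment is WMC inside
a ventricle-adjacency mask (ventricles dilated by a per-subject width);
DWMH is the remainder, so with volume `V(·) = voxels × voxel volume`:

    V(DWMH) = V(WMC) − V(PVH)        (exact, by construction)

The continuity-to-ventricle rule (whole lesion is PVH iff it touches
the ventricle surface) is provided as a comparator.

**Clinical scoring.** The 0–100 iNPH scale total is the
gait-double-weighted mean of the available domain scores
(gait×2, balance, continence, cognition); the outcome is
Δtotal = total₁₂ₘ − total₀, and Δtotal ≥ 5 defines a shunt responder.

**Statistics.** Per (outcome, volume) pair an OLS model
`outcome ~ log2(volume) + covariates` (B = change per volume doubling);
Mann–Whitney U for responder contrasts; paired t / Wilcoxon signed-rank
for pre–post change; Spearman correlation; ICC(A,1) with McGraw–Wong
CIs and Bland–Altman limits of agreement for method comparison.

**Synthetic truth.** A geometric FLAIR phantom (ventricles, halo, caps,
deep spheres, ependymal rim, Gaussian noise) with voxel-exact truth
masks, and a cohort simulator with configurable outcome model — so
every stage is validated against known ground truth.

## Worked example

Measure a noisy phantom and check against its exact truth:

```r
library(wmcvol)

ph <- generate_phantom(jittered_phantom_spec(seed = 1, noise_sd = 8))
res <- quantify_wmc(
  ph$image, ph$truth$brain_mask, ph$truth$ventricle_seeds,
  pvh_width_mm = 10, search_mask = ph$truth$wm_mask
)
res$volumes
#> # A tibble: 1 × 4
#>   total_wmc_ml pvh_ml dwmh_ml ventricles_ml
#>          <dbl>  <dbl>   <dbl>         <dbl>
#> 1         17.4   15.3    2.14          114.
ph$truth$volumes
#> # A tibble: 5 × 2
#>   compartment     ml
#>   <chr>        <dbl>
#> 1 total_wmc    17.7
#> 2 pvh          15.5
#> 3 dwmh          2.18
#> 4 ventricles  115.
#> 5 rim          22.6
```

Every compartment is recovered within ~2% despite noise at 20% of the
white-matter/lesion contrast gap, and the 22.6 ml hyperintense rim is
correctly excluded from the WMC total. With `noise_sd = 0` recovery is
voxel-exact.

Simulate a registry, apply exclusions, score it and fit the headline
outcome model:

```r
cohort <- generate_cohort(cohort_spec(
  n = 262, seed = 11, n_exclude_event = 6, n_exclude_artifact = 3
))
kept <- apply_exclusions(cohort)
kept$report
#> # A tibble: 3 × 2
#>   reason              n
#>   <chr>           <int>
#> 1 artifact            3
#> 2 non-shunt event     6
#> 3 retained          253

scored <- score_cohort(kept$cohort)
fit_outcome_model(scored, "delta_total", "pvh_ml", adjusted = TRUE)
#> delta_total ~ log2(pvh_ml) + 6 covariates: B = -1.515, p = 0.00618, n = 253

spearman_corr(scored, pvh_ml, dwmh_ml)
#> # A tibble: 1 × 3
#>     r_s p_value     n
#>   <dbl>   <dbl> <int>
#> 1 0.746       0   253
```

The fitted B is the change in the total iNPH score per *doubling* of
PVH volume, adjusted for age, sex, waiting time, preoperative total
score, Evans' index and DESH — here ≈ −1.5 points per doubling, a
noisy draw around this simulated cohort's generating coefficient of
−1.2. `build_report()` assembles the full battery (responder
contrasts, 18 change-score models, baseline and biomarker models,
paired tests) into one object; `run_pipeline()` executes
phantoms → segmentation → partition → cohort → scoring → report as a
single seeded run with a hashed manifest.

Agreement between two volume-measurement methods:

```r
icc_agreement(data.frame(a = c(1, 2, 3), b = c(2, 3, 4)), a, b)
#> ICC(A,1) = 0.667 (95% CI NA to NA), n = 3 pairs
```

(The CI is undefined here because the three pairs fit the two-way
model with zero residual; `autoplot(bland_altman(...))` draws the
companion Bland–Altman plot.)

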