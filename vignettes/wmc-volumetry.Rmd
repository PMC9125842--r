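---
title: "White matter change volumetry and shunt-outcome analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White matter change volumetry and shunt-outcome analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`wmcvol` implements a complete analysis chain for studying whether the
volume of white matter changes (WMC) on FLAIR-like brain images predicts
the outcome of shunt surgery in idiopathic normal pressure hydrocephalus
(iNPH):

1. semi-automatic volumetry — intensity normalisation, threshold
   segmentation within brain masks, scripted brush editing, ventricle
   region growing, removal of the pencil-thin ependymal lining;
2. partition of WMC into periventricular (PVH) and deep (DWMH)
   compartments, by a ventricle-adjacency mask (default) or by the
   continuity-to-ventricle rule (comparator);
3. clinical scoring on the 0–100 iNPH scale, shunt-responder
   classification, exclusion bookkeeping;
4. method-agreement statistics (intraclass correlation, Bland–Altman);
5. the covariate-adjusted regression battery relating log2 volumes to
   change scores, baseline scores and CSF biomarkers.

Because no patient images or per-patient tables are available, the
package ships two synthetic-data generators with exact ground truth: a
geometric FLAIR phantom and a cohort simulator. Every pipeline stage is
validated against those truths; only population-level emulation of the
clinical distributions is claimed.

## The segmentation model

The intensity model is deliberately minimal: each tissue class
(background, CSF, normal white matter, grey matter, WMC) has a constant
mean intensity plus additive Gaussian noise. On FLAIR, CSF is dark and
WMC are the brightest parenchymal class, so a per-subject intensity
window captures them.

**Normalisation.** `normalize_intensity()` maps the in-brain minimum to
0 and the maximum to 100, putting every subject on a percent-of-maximum
scale with the maximum fixed at 100; the threshold's upper bound is
therefore always 100. A robust variant (0.1/99.9 percentile limits) is
available for inputs with extreme outlier voxels, but the default
pipeline keeps min/max limits so that no intensity can exceed the
upper threshold bound.

**Threshold choice.** The lower threshold is a per-subject operating
point; in the original interactive procedure an operator chose it so
that all WMC were included. `suggest_min_percent()` provides a
deterministic default: normal-tissue centre and scale are estimated by
the in-mask median and MAD (normal tissue dominates the search mask, so
these are robust to the lesion fraction); the lesion centre is the
median of intensities more than 3 MAD above the normal centre; the
threshold is the midpoint of the two centres plus 0.35 × scale. The
upward offset encodes an asymmetry we measured on phantoms with known
truth: below the midpoint, the (vastly more numerous) normal-tissue
voxels flood the segmentation with false-positive clusters large enough
to survive the component-size filter, and the error grows explosively;
above it, the only loss is a thin false-negative skin on lesion
boundaries, growing gently. The 0.35 offset was calibrated once on the
phantom family at the generator's nominal noise level and then frozen.
On a noise-free image the scale term vanishes and the rule reduces to
the exact class midpoint, which recovers the true lesion mask
voxel-exactly.

**Scripted editing.** `paint()` replaces the interactive brush: a
stroke is a voxel set plus a spatial radius (mm) and an intensity range
width. The membership weight is the product of two linear falloffs —
in Euclidean distance to the nearest stroke voxel and in absolute
intensity difference from the stroke's mean intensity — clamped to
zero beyond either reach; voxels with weight ≥ 0.5 are added or
removed, in full 3D. Any strictly monotone kernel satisfies the
behavioural contract (locality, class selectivity, add/remove
inversion); the bilinear product is the simplest such kernel and is
isolated in one function. `filter_small_components()` stands in for
the operator's removal of scattered misclassified voxels; the default
floor of 10 voxels (80 mm³ at 2 mm isotropic) is far below the
smallest simulated lesion (≈ 1 ml) and far above the size that noise
speckle reaches.

**Ventricles.** `segment_ventricles()` region-grows CSF from one seed
per lateral ventricle, bounded by an intensity window (mean seed
intensity ± `tolerance`, default 15 percent points). Seed intensities
are averaged over each seed's 3×3×3 neighbourhood and growth starts
from that whole neighbourhood: during stress testing, a single noisy
seed voxel falling outside the window silently suppressed an entire
ventricle in roughly one phantom in two hundred, which these two
changes eliminate. Seeds whose neighbourhood mean exceeds
`csf_ceiling` (default 35) are rejected by name — a seed placed in a
lesion is a user error, not something to grow from. Connectivity
defaults to 26-neighbourhood; growth is subcritical for site
percolation at the false-inclusion rates the window implies, so single
noisy boundary voxels do not cause floods.

**Pencil-thin lining.** A thin hyperintense ependymal rim along the
ventricle wall is a normal ageing finding and must not count as WMC.
`remove_pencil_thin_lining()` works on the Euclidean distance transform
from the (segmented) ventricles. Candidates are WMC voxels within
`max_thickness` (default 3 mm) of the surface belonging to a component
that touches the surface. Cores are WMC voxels beyond `max_thickness`,
kept only in components of at least `core_min_voxels` (default 10) so
isolated noise voxels cannot anchor anything. A candidate survives only
if it is *geodesically* reachable from a core through the WMC mask
within a bounded number of one-voxel steps. Two simpler rules fail in
characteristic ways: deciding per connected component retains the whole
rim whenever a sparse chain of noise voxels bridges the gap to a thick
lesion, and a Euclidean distance-to-core criterion trims the tapering
contact ring of caps sitting on sharply curved ventricle poles.
Geodesic anchoring handles both, because a free-standing rim has no
lesion path to any core whatever the Euclidean gap, while a cap's taper
is contiguous with its own core. When the lining is truly confluent
with a thick lesion over its whole extent it is retained — a
conservative failure mode shared with any thickness-based criterion.

## Partition into PVH and DWMH

The study's operational definition is mask-based: a per-subject *PVH
mask* containing everything adjacent to the lateral ventricles, whose
width follows the observed width of the periventricular changes.
`build_pvh_mask(ventricles, brain, width_mm)` thresholds the distance
transform (isotropic in mm under anisotropic voxels, unlike iterated
structuring elements) and intersects with the brain mask. PVH = WMC
inside the mask; DWMH = the rest, so DWMH volume is total WMC minus
PVH by construction and conservation is exact at the voxel-count
level. The mask width has no published numeric rule, so it is an
explicit required parameter (10 mm in all phantom experiments here,
comfortably wider than the 8 mm halo the generator draws).

`continuity_partition()` implements the common alternative: a whole
connected lesion is PVH iff any voxel touches the ventricle surface.
The two rules agree on cleanly separated lesions and disagree on
confluent ones (continuity assigns them wholly to PVH; the mask rule
splits them), which is exactly what the agreement module is for.

Volumes are voxel counts × single-voxel volume, reported in ml.

## The phantom generator

`phantom_spec()`/`generate_phantom()` render an ellipsoidal cerebrum
(default semi-axes 65×82×60 mm, ≈ 1.3 l) with a thin grey-matter
ribbon, two ellipsoidal lateral ventricles (default 18×50×17 mm each,
≈ 128 ml total — matching typical iNPH ventriculomegaly), a
periventricular halo (default 8 mm wide) restricted to a band around
the ventricle body, hyperintense caps on the anterior poles, isolated
deep spheres (≈ 2 ml total), and a one-voxel ependymal rim. Default
grid 80×96×80 voxels at 2 mm. Two geometric idealisations matter:

* the rim is generated with a 6 mm clearance to halo and caps, so
  truth compartments are distinct components and voxel-exact scoring
  of the lining removal is possible (real linings are confluent);
* the halo excludes a midline slab around the septum — anatomically
  there is no white matter between the ventricles, and a curved
  exclusion surface would create sub-lining-thickness halo slivers
  that no thickness-based operator could attribute.

Deep lesions are validated at generation time: every sphere must lie
further than the halo width plus two voxels from the ventricle
surface, or generation aborts with a diagnostic. Truth volumes are
exact voxel counts; the same spec and seed reproduce bit-identical
images. `jittered_phantom_spec(seed)` scales ventricle axes, halo
width and cap radii by seeded ±8% factors, giving a family of
distinct but individually exact phantoms.

What the phantom does *not* emulate: partial-volume averaging, bias
fields, multi-sequence contrast, scanner differences, anatomically
shaped (non-ellipsoidal) ventricles, and lesion intensity
heterogeneity. Passing the phantom suite therefore demonstrates the
correctness of the operators and their noise robustness under the
stated intensity model — not clinical segmentation accuracy on real
FLAIR data.

```{r phantom-example}
library(wmcvol)
ph <- generate_phantom(jittered_phantom_spec(seed = 1, noise_sd = 8))
res <- quantify_wmc(
  ph$image, ph$truth$brain_mask, ph$truth$ventricle_seeds,
  pvh_width_mm = 10, search_mask = ph$truth$wm_mask
)
res$volumes
ph$truth$volumes
```

## The cohort simulator

`cohort_spec()`/`generate_cohort()` draw one registry row per simulated
patient. The default parameterisation reproduces the population-level
anchors of a large single-centre iNPH shunt series: age ≈ 75 (range
50–89), 56% male, waiting time log-normal with median 6 months (IQR
4–8), Evans' index truncated-normal in (0.2, 0.5), comorbidity
prevalences (64% hypertension, 25% diabetes, …), baseline total iNPH
score 49.8 (SD 19.0), MMSE median 25, and CSF biomarkers (T-tau,
P-tau, Aβ1-42, NfL) log-normal with the reported medians and IQRs.

**Volumes** are log-normal (strictly positive, right-skewed, median far
below the mean as the reported summaries show), with log2-scale
parameters moment-matched from the reported medians and IQRs (PVH
median ≈ 15 ml, DWMH ≈ 1.7 ml, ventricles mean ≈ 130 ml), a
multivariate-normal dependence giving a PVH–DWMH Spearman correlation
of ≈ 0.75, and a centred log2 shift for hypertensive patients so that
lesion volumes are larger with hypertension without changing the
marginal medians.

**Scores.** A latent severity S is drawn from a normal truncated to
[0, 100]; the pre-truncation parameters are solved (fixed-point on the
truncated-normal moment equations) so the *post-truncation* mean and SD
equal the specified 49.8/19.0. Domain scores are S plus fixed offsets
(so gait is worst, balance best, as reported) plus residuals whose raw
variances are solved through the weighted-mean-zero projection so the
marginal domain SDs hit their targets; bounded scores are then obtained
by iteratively redistributing any clamping deficit so that the
gait-double-weighted total equals S by construction. Scores are
truncated (clamped), never resampled, keeping the generating regression
coefficients recoverable away from the bounds. Missingness is
independent per domain (cognition missing in ≈ 61%, matching the
reported per-variable n), with a small extra follow-up rate.

**Outcome.** The change in total score is generated as
intercept + Σ coefficients × covariates + B·log2(volume) + noise
(default B = −1.2 on log2 PVH, residual SD 15, intercept set so that
about half the cohort improves by ≥ 5 points). Per-domain changes add
weighted-mean-zero scatter around the total change. Responder status
is *not* stored; it is derived downstream, like every other analysis
quantity.

## Clinical scoring

`total_inph_score()` is the gait-double-weighted mean over available
domains (weights 2/1/1/1, denominator = the summed weights of assessed
domains). When the assessed-domain sets differ between baseline and
follow-up, each time point's total uses its own available domains — the
scale is defined per assessment — with `strict = TRUE` available as a
sensitivity analysis restricted to the common set. The responder
threshold is inclusive (change ≥ 5). The 24-item Stroop conversion used
for a subset of patients in the original study has no published table;
no default is shipped and the cognitive domain is consumed as given.
`apply_exclusions()` is a pure filter with a per-reason report.

## Statistics

All volumes and CSF biomarkers are log2-transformed in every model, so
an unstandardised coefficient B is the outcome change per volume
doubling (and, for biomarkers, a log2-on-log2 elasticity; a toggle fits
raw biomarker outcomes instead). One OLS model is fitted per
(outcome, volume) pair — the three volumes are strongly
inter-correlated (Spearman ≈ 0.75), so a joint model would answer a
different question. Covariate sets are fixed per outcome family:
change scores adjust for age, sex, waiting time, preoperative total
score, Evans' index and DESH; baseline scores and biomarkers for age,
sex, Evans' index and DESH. Fits are complete-case, so n varies by
outcome; constant or collinear design columns abort with the column
named.

Group contrasts use the two-sided Mann–Whitney U test (exact for
combined n ≤ 20 without ties, otherwise the normal approximation with
tie and continuity corrections); pre/post changes use the paired t-test
for the total score and the Wilcoxon signed-rank test (zeros dropped,
exact for ≤ 25 untied non-zero differences) for MMSE and domains;
PVH–DWMH correlation uses Spearman's coefficient with average ranks.
These are delegated to the standard `stats` implementations and are
verified in the test suite against independent brute-force
enumerations (all label assignments for Mann–Whitney at combined
n ≤ 10, all sign patterns for the signed-rank test at n ≤ 8, the
rank-difference formula and full permutation distributions for
Spearman). No multiple-testing correction is applied anywhere, and the
report says so explicitly.

`icc_agreement()` computes ICC(A,1) — two-way random effects, absolute
agreement, single measurement — from the two-way ANOVA mean squares,
with the F-distribution confidence interval of McGraw & Wong; the
consistency form ICC(C,1) is available because the original variant is
not named in print. `bland_altman()` reports the mean difference and
1.96-SD limits of agreement with per-subject plotting coordinates
(`autoplot()` draws the conventional plot). One pair per subject is
assumed; there is no repeated-measures correction.

## Reproducibility and numerical choices

* Segmentation runs entirely in voxel space; world coordinates are
  used only for IO and reporting. Distance transforms use the exact
  separable squared-distance algorithm with physical spacing, so
  dilation and thickness are isotropic in mm under anisotropic voxels.
* Connectivity defaults to 26-neighbourhood everywhere (6 available).
  Threshold intervals are closed on both ends.
* All randomness flows from explicit integer seeds; generators save
  and restore the caller's RNG state. `run_pipeline()` derives fixed
  per-stage substreams from one master seed and writes a manifest with
  md5 hashes; re-running a config reproduces identical hashes.
* Degenerate inputs fail loudly: constant images, empty masks (a
  warning and an empty result for an empty search mask), zero total
  variance in the ICC, all-zero differences in the signed-rank test,
  seeds outside CSF intensity.

Problem sizes in the shipped validation: ten jittered full-size
phantoms per noise condition (zero noise must recover every compartment
voxel-exactly; Gaussian noise at 20% of the WM–WMC intensity gap must
stay within 5% of truth per compartment), one hundred simulated
cohorts of n = 250 for coefficient-recovery coverage, one thousand
null replicates at group sizes 129/124 for the Mann–Whitney size, and
an n = 10,000 cohort for the baseline-moment convergence checks. These
sizes make the whole suite run in well under a minute while leaving
the Monte-Carlo tolerances meaningful.

## Known limitations

* The phantom's constant-intensity tissue model omits partial volume
  and bias fields, so the 5% noise-recovery margin should not be read
  as expected clinical accuracy.
* The threshold-suggestion offset (0.35 × scale) is calibrated for
  noise levels up to ~20% of the tissue-contrast gap; heavier noise
  regimes warrant operator-chosen thresholds.
* The lining-removal rule retains a lining that is confluent with
  thick lesions along its entire extent.
* Only population-level emulation of the clinical cohort is claimed:
  the published per-patient data are unavailable, so printed
  regression coefficients (e.g. B for PVH on the total-score change)
  cannot be reproduced numerically, only the recovery of *known*
  generating coefficients can be — and is — demonstrated.
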