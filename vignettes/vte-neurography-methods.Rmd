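---
title: "Methods: simulated vTE neurography and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated vTE neurography and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtenerve)
```

`vtenerve` implements a quantitative MR-neurography analysis of the
sciatic nerve in hereditary transthyretin amyloidosis (ATTRv): pseudo-T2*
relaxometry from a dual-echo variable echo time (vTE) acquisition, ROI
morphometry of nerve sub-structures, two-rater reliability metrics, and
the covariate-adjusted group statistics used to compare patients with
healthy controls. Because no imaging data ship with the package, every
stage is driven by a seeded synthetic phantom-and-cohort generator whose
defaults are calibrated to the published group-level distributions. This
vignette is the package's account of the underlying models, the defaults
and why they were chosen, and what the passing test suite does and does
not demonstrate about real data.

## The two-point pseudo-T2* estimator

The vTE sequence acquires two gradient echoes, the first at a very short
echo time (defaults TE1/TE2 = 1.05/5.37 ms). Under mono-exponential
transverse decay, the voxel signal is $S(t) = A\,e^{-t/T_2^*}$, and the
two echo intensities $i_{TE1}, i_{TE2}$ determine the effective decay
constant

$$
\mathrm{pT_2^*} \;=\; \frac{-\Delta TE}{\ln\!\left(i_{TE2}/i_{TE1}\right)},
\qquad \Delta TE = TE_2 - TE_1 .
$$

`compute_pt2star()` applies this voxelwise. Three properties follow
directly and are enforced by tests:

* **Inverse identity.** If echoes are constructed as
  $i_{TE2} = i_{TE1} e^{-\Delta TE/T}$, the estimator returns $T$ to
  machine precision.
* **Scale invariance.** Only the intensity ratio matters, so the
  amplitude $A$ — which absorbs proton density, T1, TR and flip-angle
  weighting — cancels. This is why the simulator never needs T1 values.
* **Validity.** The estimator is defined only for a positive, decaying
  signal ($0 < i_{TE2} < i_{TE1}$). Voxels violating this (noise
  dominated, or non-decaying) are flagged invalid and excluded from ROI
  means rather than clipped; the valid fraction is always reported so
  exclusions are visible. There is deliberately no upper cap on pT2*:
  capping near-unity ratios would bias ROI means downward.

### Voxelwise versus ROI-signal summaries

Whether to estimate pT2* per voxel and average over the ROI, or to
average the echo signals over the ROI first and apply the estimator
once, is genuinely open: both are defensible readings of "per-ROI pT2*
quantification". The package computes the voxelwise-then-average form by
default (`pt2star_method = "voxelwise"`) and exposes the ROI-signal form
as an option; the two agree exactly in the noiseless limit, which is
tested.

The two forms differ under noise. The log of a noisy ratio is a convex
transform, so the voxelwise estimator carries a positive bias of
approximately $T \cdot \mathrm{var}(u)/u^2$ with $u = -\Delta TE/T$,
where $\mathrm{var}(u)$ is the variance of the log-ratio. At the default
SNR of 50 (defined as the noiseless fascicle TE1 signal over the
Gaussian noise sigma per channel) this is about 1.3% of $T$ at the
healthy-control fascicle value of 14.74 ms and grows roughly
quadratically in $T/\Delta TE$, reaching about 2% near 18–19 ms. The
test suite characterizes this by simulation against known truth rather
than asserting it to be zero, and the calibrated-cohort recovery test
(below) passes with this bias included. ROI averaging reduces variance
but not this bias; the `"roi_signal"` option nearly eliminates it
because the averaged signals have far smaller relative noise.

### Slice exclusion

The first and last slices of the slab are excluded before any ROI
summary to avoid signal changes from field inhomogeneities at the slab
edges: `select_analysis_slices(12)` retains the central 10 slices of the
default 12-slice, 5-mm acquisition (a 6 cm slab). The rule generalizes
as "drop exactly the first and last slice" for any slice count of at
least 3.

## The phantom generator

`build_phantom()` renders one subject: a ground-truth label map
(0 background/muscle, 1 inner epineurium, 2 fascicles; the whole nerve
is the union of 1 and 2) and the two echo volumes.

**Grid.** The default grid is 96 x 96 x 12 voxels at 0.6 x 0.6 x 5.0 mm,
keeping the acquisition's voxel size, slice count and slab coverage
while cropping the in-plane field of view to a neighbourhood of the
nerve. The nerve physics is unaffected by the crop; it only keeps
desk-scale runtimes.

**Compartments.** Three tissue classes are rendered, each with a TE = 0
amplitude and a T2*: fascicles and epineurium use the subject's drawn
values, muscle background a fixed 25 ms. Amplitudes (fascicle 1.0,
epineurium 0.6, muscle 0.7) are chosen so fascicles are hyperintense and
the epineurium hypointense at both echoes, as on the vTE images; their
absolute scale is irrelevant to the estimator. Fat is not rendered at
all: the acquisition suppresses fat with binomial excitation, and
simulating a suppressed compartment adds nothing testable. Decay is
mono-exponential per compartment. Myelin water and free water would in
reality produce bi-exponential behaviour within fascicles, but no
published compartment fractions or short-T2* values are available for
this nerve at this sequence, so the generator deliberately does not
guess them; this is a stated limitation, not a modelling claim.

**Nerve geometry.** The whole-nerve cross-section is an ellipse with a
subject-specific area, random aspect ratio (1–1.6) and orientation. The
rendered nerve is the set of $N = \mathrm{round}(\mathrm{CSA}/(dx\,dy))$
voxels with the smallest ellipse metric, so the rendered area matches
the true CSA to within half a voxel, with ties broken deterministically
by voxel index. Fascicles are rendered by drawing 5–9 spaced centres
inside the ellipse and labelling the fraction of nerve voxels closest to
any centre as fascicle — the nearest-centre partition makes the
fascicles disjoint disc-like regions separated by an epineurial web and
rim. This construction was chosen over rejection-packing of rigid discs
because the study's printed area fractions (fascicular/whole-nerve about
0.84 in patients and 0.76 in controls) are well above what random
non-overlapping disc packing can reach inside a small ellipse (about
0.55); distance thresholding hits any target fraction to within one
voxel while preserving the fascicle/epineurium morphology that matters
to the analysis. Per-slice nerve-centre jitter is rounded to whole
voxels, so per-slice areas are exactly preserved while the nerve
wobbles along the slab.

**Noise.** Magnitude-MRI noise is Rician by default:
$\sqrt{(S+\sigma Z_1)^2 + (\sigma Z_2)^2}$ with independent standard
normals per voxel and echo; Gaussian noise is available for analytic
tests. The SNR is defined at the noiseless fascicle TE1 signal; the
default of 50 is a realistic value for a 3 T gradient-echo acquisition
at this voxel size and is the setting used by the calibration-recovery
tests.

## Cohort calibration

`group_distributions()` carries the per-group normal distributions of
subject truth, with defaults set once to the published group summaries:

| quantity | ATTRv | HC | units |
|---|---|---|---|
| fascicle pT2* | 18.35 ± 3.48 | 14.74 ± 3.21 | ms |
| epineurium pT2* | 9 ± 2 | 9 ± 2 | ms |
| whole-nerve CSA | 49.32 ± 19.63 | 37.89 ± 12.92 | mm² |
| fascicular fraction | 0.842 ± 0.04 | 0.763 ± 0.04 | — |

The fascicular fraction means are the ratios of the printed fascicular
areas to the printed CSAs, so that simulated mean fascicular areas land
on the printed 41.53 and 28.91 mm². Epineurial pT2* was not printed; the
study reported its group difference as non-significant, so both groups
share N(9, 2²) ms, a value short enough to be consistent with the
epineurium's connective-tissue composition and chosen so that simulated
whole-nerve means fall near the printed 15.65/12.64 ms given the area
fractions. Draws are truncated at positive floors (1 ms for T2*, 5 mm²
for CSA) that are essentially never active under the defaults; a floor
above mean + 6 sd raises an error rather than silently producing a
point mass.

**Clinical covariates.** `covariate_model()` generates age, sex, NIS,
NIS-LL, PND, CMAPs, SNAP and NCVs through a Gaussian copula tied to the
fascicle-pT2* latent normal: a target Spearman correlation $\rho_s$ is
converted to the latent Pearson correlation $r = 2\sin(\pi\rho_s/6)$,
which is exact for bivariate normal latents, and each covariate's latent
is transformed through its marginal quantile function. Monotone marginal
transforms preserve Spearman correlations exactly for continuous
marginals, so the configured targets (for patients: CMAP peroneal/tibial
−0.592/−0.715, sural SNAP −0.552, NCVs −0.519/−0.531, NIS/NIS-LL/PND
+0.544/+0.545/+0.592) are reproduced to sampling error. NIS and NIS-LL
are lognormal with medians matched to the published 18 and 11 and
clipped to their scale bounds (their true marginal shapes are not
recoverable from the publication); the ordinal PND score thresholds its
latent at the published cohort frequencies 10/6/2 across grades 1/2/3;
amplitude-like NCS measures are lognormal (strictly positive, skewed)
and velocities normal, with patient levels in clinically reduced ranges
and control levels in normal ranges. Controls score 0 on the clinical
scales and have all rank targets at 0.

**Determinism.** `simulate_cohort_truth()`, `run_cohort()` and
`generate_cohort()` derive one sub-seed per subject from the master seed
and reseed before each subject, so truth tables and label maps are
byte-identical across runs and any subject can be regenerated in
isolation.

### What the generator does not emulate

Passing recovery tests show that the pipeline's computations are
faithful to their definitions and that the estimator recovers known
truth under the modelled acquisition. They do not show robustness to
features of real neurography that the phantom deliberately lacks:
partial-volume voxels at structure borders (labels are crisp),
B0/B1 inhomogeneity beyond the slice-exclusion convention, motion,
bi-exponential fascicle decay, inter-rater segmentation behaviour
(the perturbation model is a boundary-noise caricature), or any real
anatomy of fascicle shape. The published patient-derived numbers that
depend on real segmentations (the ICC/Dice values near 0.9, specific
p-values at n = 18 vs 21) are not reproducible from simulation and are
not targets of the test suite.

## Morphometry

Areas are pure voxel counts times the in-plane voxel area, with no
contour interpolation or sub-voxel correction — matching what manual ROI
exports produce at this resolution. Per-subject aggregates are the
arithmetic mean over the analysis slices, the same reduction used for
ROI pT2*; the publication reports single per-subject values without
stating its reduction, and the mean is the least surprising choice.
Because labels partition the nerve, fascicular plus epineurial area
equals whole-nerve area exactly, per slice and in aggregate — an
invariant the tests enforce on every generated mask.

## Reliability

`dice_coefficient()` implements $2|A\cap B|/(|A|+|B|)$ per structure,
with the convention that two empty sets have Dice 1 (two raters agreeing
a structure is absent), documented rather than left undefined so that
slices without a structure do not crash batch summaries.
`icc_two_rater()` computes the single-measure ICC from the two-way ANOVA
mean squares and returns those mean squares for audit. The default is
the absolute-agreement form ICC(2,1), because the scientific question is
whether two raters' absolute measurements are interchangeable, and
absolute agreement correctly penalizes systematic between-rater bias;
the consistency form ICC(3,1) is available. A constant table is flagged
degenerate instead of returning a spurious coefficient.
`perturb_mask()` supplies the synthetic second rater by flipping only
boundary voxels at a configured rate, each flipped voxel taking a
neighbouring label, so the output remains a valid partition.

## The statistical layer

* **Group comparisons controlling for sex and age** are fixed-effects
  linear models `measure ~ group + age + sex`. The publication's wording
  ("general linear mixed-effects models adjusted for age and sex") names
  no random effect, and with one observation per subject a mixed model
  is unidentifiable, so a fixed-effects model is the faithful,
  identifiable reading; the discrepancy is noted here on purpose.
  Because published "R" values controlling for covariates can be either
  the model's multiple correlation or a partial correlation, both are
  returned (`r_model`, `r_partial`).
* **Two-sample tests** report Welch's t (the variance assumption is
  unstated in the source, and unequal variances are the safe default)
  alongside the Mann-Whitney U. The CSA comparison is one-tailed with
  patients larger, as published.
* **The severity analysis** mirrors the published, statistically
  heterodox pairing: a parametric one-way ANOVA omnibus across
  HC / mild / moderate-severe strata (NIS-LL bands 1–20 / 21–61 / 62–88,
  moderate and severe pooled) followed by Dunn's rank-based pairwise
  z-tests. Dunn's test conventionally follows Kruskal-Wallis; both
  layers are therefore reported side by side and are separately
  testable — the Dunn statistics are checked against a brute-force
  rank-sum oracle, and the omnibus against its nominal type-I error.
  Post hoc p-values are unadjusted by default (as published) with Holm
  adjustment available.
* **Correlations** "controlling for sex and age" are partial
  correlations by residualization: both variables are regressed on the
  covariates and the residuals correlated with the requested method.
* Rows with missing fields are dropped per analysis with `n` reported,
  and `exclude_subjects()` implements the enrolled-to-analysis-set
  filter with a conserved exclusion log.

## Problem sizes and numerical conventions

The calibration-recovery test simulates 500 subjects per group at SNR 50
on the default grid and requires each cohort mean (fascicle pT2* per
group, HC CSA, patient fascicular area) within two standard errors of
its configured value; type-I error calibration uses 1000 null replicates
per test at small n; copula fidelity uses 5000 draws per target. These
sizes were chosen to make the Monte-Carlo tolerances meaningful while
keeping the default test run a few minutes long. All slice indices are
1-based along the third array axis; ellipse and fascicle ties are broken
by voxel index; per-subject seeds stay below 2^31.

## Known limitations

Mono-exponential decay per compartment; crisp labels without partial
volume; a boundary-flip caricature of rater disagreement; clinical
marginals only partially constrained by published summaries; no DICOM
ingestion or scanner-side reconstruction effects; no multi-echo (three
or more points) fitting, B0/B1 correction or denoising. Within those
bounds, every number the package reports is recomputed from seeded
simulation and is reproducible to the byte.
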