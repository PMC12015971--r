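# vtenerve

Quantitative variable echo time (vTE) MR neurography of the peripheral
nerve, as an end-to-end simulated and tested R pipeline.

Hereditary transthyretin amyloidosis (ATTRv) causes a progressive
polyneuropathy in which misfolded transthyretin deposits in peripheral
nerves. A dual-echo vTE gradient-echo acquisition, with a very short
first echo (TE1/TE2 = 1.05/5.37 ms), is sensitive to the short-T2*
components of the nerve and lets the sciatic nerve's inner structures —
hyperintense endoneurial fascicles and hypointense inner epineurium — be
segmented and quantified. From the two echo intensities the effective
transverse relaxation time is estimated voxelwise as

```
pT2* = -ΔTE / ln(iTE2 / iTE1),    ΔTE = TE2 - TE1
```

and summarized over each structure's ROI across the central slices of
the slab, alongside per-slice cross-sectional areas (CSA, fascicular
area, epineurial area). Fascicle pT2* and morphometry separate patients
from controls and track clinical severity (NIS, NIS-LL, PND) and
nerve-conduction measures (CMAP, SNAP, NCV).

The package is aimed at researchers who want to analyze such
acquisitions (NIfTI volumes plus integer label masks), or to study the
estimator and its statistics under controlled conditions. It provides:

* `synthetic cohorts` — `run_cohort()`, `generate_cohort()`: seeded
  dual-echo phantoms with ground-truth label maps and Gaussian-copula
  clinical covariates, calibrated by default to the published ATTRv/HC
  group distributions;
* `relaxometry` — `compute_pt2star()`, `select_analysis_slices()`,
  `roi_mean_pt2star()`;
* `morphometry` — `csa_per_slice()`, `aggregate_areas()`;
* `reliability` — `dice_coefficient()`, `icc_two_rater()` (ICC(2,1)
  from ANOVA mean squares, with ICC(3,1) as an option);
* `group statistics` — `adjusted_group_comparison()`,
  `two_sample_tests()`, `severity_anova()` with `dunn_test()` post hoc,
  `correlate()` (plain or partial), `cohort_stat_report()`;
* an orchestrated, manifest-checksummed file pipeline
  `run_nerve_pipeline()` with YAML configuration and a thin CLI at
  `inst/cli/vtenerve`.

All tabular results are tibbles; fitted objects have `tidy()`/`glance()`
methods; `plot_slice()`, `plot_group_comparison()`, `plot_correlation()`
and `autoplot()` give quick ggplot2 views.

## Worked example

Simulate a study-sized cohort (20 patients, 21 controls), drop two
motion-corrupted patients, and run the full statistical battery:

```r
library(vtenerve)

cc <- run_cohort(20, 21, seed = 42)
glance(cc)
#> # A tibble: 2 × 6
#>   group     n fascicle_pt2star_ms nerve_pt2star_ms csa_mm2 fascicular_area_mm2
#>   <chr> <int>               <dbl>            <dbl>   <dbl>               <dbl>
#> 1 ATTRv    20                18.7             17.4    45.2                39.0
#> 2 HC       21                14.9             13.5    43.3                32.5

cohort <- exclude_subjects(cc$cohort, c("P004", "P011"), "motion artifact")
#> Excluded 2 of 41 subjects (39 analyzed).

report <- cohort_stat_report(cohort)
dplyr::filter(report, analysis == "adjusted_group_comparison")
#>   measure               contrast    estimate coefficient  p_value     n
#> 1 nerve_pt2star_ms      ATTRv - HC     3.25        0.546  0.0115     39
#> 2 fascicle_pt2star_ms   ATTRv - HC     3.23        0.453  0.0386     39
#> 3 epineurium_pt2star_ms ATTRv - HC    -0.454       0.352  0.587      39
```

Measured fascicle pT2* is about 3.2 ms higher in patients after
adjusting for age and sex (p < 0.05 at this cohort size), the epineurium
shows no group effect — both mirroring the generator's calibration — and
`coefficient` is the model's multiple correlation R. The same report
contains the one-tailed CSA comparison, the severity ANOVA with Dunn
pairs, and the clinical/NCS correlations; at n = 39 a single simulated
cohort will not make every contrast significant (the CSA test here has
p = 0.43: with the calibrated spread, its power is only moderately above
one half), which is exactly the small-sample behaviour the simulator is
for. At n = 500 per group the pipeline recovers every calibrated group
mean to within two standard errors (see the acceptance script below).

The file-based pipeline does the same from NIfTI volumes on disk and
writes every intermediate plus a checksummed manifest:

```r
cfg <- run_config(seed = 7)          # or read_run_config("config.yaml")
run_nerve_pipeline(cfg, out_dir = "run1")
```

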