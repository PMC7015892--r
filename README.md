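# saqc — automated quality control for short-axis cine cardiac MR stacks

Large population imaging studies acquire cine cardiac MR at a rate that
makes visual quality assessment impossible. `saqc` implements a fully
automated quality-control pipeline for short-axis (SA) cine stacks and
the cohort-level statistics used to relate image quality to acquisition
details and subject phenotypes. It is written for imaging scientists who
need per-stack quality metrics with auditable exclusion accounting, and
for methodologists who want a fully testable synthetic environment for
such pipelines.

## The three checks

Given the fused apex `A` and mitral-valve `M` landmarks (axis direction
`d = (M − A)/L`, length `L = ‖M − A‖`) and cavity/myocardium masks:

* **Heart coverage** — the percent portion of the apex-to-valve segment
  spanned by the SA slice centres,
  `coverage = 100 · (L − g_a − g_b + o_a + o_b) / L`,
  with basal/apical gaps `g` (landmark outside the stack) and overhangs
  `o` (stack past the landmark); over-abundant stacks exceed 100%.
* **Inter-slice misalignment** — per slice between the landmarks, the
  magnitude in mm of the in-plane displacement of the cavity centre of
  mass from the reference position given by a 3-D line fitted through
  the long-axis (LA) cavity centroids; averaged overall and by region
  (apical = first 2 slices, basal = last 2, mid = rest).
* **Cardiac image contrast** — per slice,
  `100 · (mean blood intensity − mean myocardium intensity) / dynamic range`,
  averaged over the between-landmark slices.

Stacks are classified against validated thresholds (coverage <100%
sub-optimal, <90% severe; average misalignment ≥3.4 mm motion-corrupt;
contrast <30% low, <20% very low), and sanity checks on landmarks and
segmentations exclude unreliable inputs from each metric, with the
exclusions counted and reported.

Because the learned landmark/segmentation model used on real scans is
out of scope, the package ships (a) a classical three-class Otsu
extractor that works end-to-end on its phantoms, (b) a ground-truth
injection path, and (c) an analytic ellipsoidal LV phantom generator and
a synthetic cohort generator with exactly calibrated covariate–metric
associations (Gaussian copula, `ρ = sin(πτ/2)`), so that every stage is
validated by parameter recovery rather than by eye.

## Worked example

Simulate a stack with a 12 mm basal truncation and one slice shifted by
(3, 4) mm, then run the full pipeline on the images alone (masks and
landmarks extracted, nothing injected):

```r
library(saqc)
spec <- phantom_spec(basal_truncation = 12,
                     per_slice_shift = rbind(matrix(0, 5, 2), c(3, 4)),
                     noise_sd = 4, seed = 1)
ph <- generate_phantom(spec)
report <- qc_subject(ph$stack, ph$la_views)
cat(sprintf("coverage: %.1f%% (basal gap %.1f mm, apical gap %.1f mm)\n",
            report$coverage$coverage, report$coverage$basal_gap,
            report$coverage$apical_gap))
cat(sprintf("misalignment: %.2f mm average (apical %.2f, mid %.2f, basal %.2f)\n",
            report$motion$average_mm, report$motion$apical_mm,
            report$motion$mid_mm, report$motion$basal_mm))
cat(sprintf("contrast: %.1f%% of dynamic range\n", report$contrast$average_pct))
cat("flags:", paste(names(report$flags)[report$flags], collapse = ", "), "\n")
```

which prints:

```
coverage: 77.8% (basal gap 20.0 mm, apical gap 0.0 mm)
misalignment: 0.71 mm average (apical 0.00, mid 1.65, basal 0.00)
contrast: 52.9% of dynamic range
flags: coverage_suboptimal, coverage_severe
```

Reading the numbers: the requested 12 mm basal truncation is realised as
a 20 mm gap (slices step in 10 mm increments from the apical end), so
coverage is 100·(90−20)/90 = 77.8%, below both coverage thresholds. The
single shifted slice is recovered at its true 5 mm magnitude, diluted to
0.71 mm when averaged over the seven assessed slices — below the 3.4 mm
corruption threshold, so no motion flag. Contrast stays high, as the
tissue intensities were not degraded (the value sits below the noise-free
60% because noise widens the dynamic-range normaliser).

## The analysis workflow

The `analysis/` scripts run the package end-to-end and write their
tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_phantoms.R` | 40 phantom subjects across the defect spectrum → NIfTI + truth sidecars under `scratch/phantoms/` |
| `02_qc_phantoms.R` | full image-only QC on each subject; per-subject reports, cohort summary with exclusion accounting, recovery check against truth |
| `03_simulate_cohort.R` | 10,000-subject cohort table with calibrated associations; Anderson–Darling normality screen |
| `04_association_battery.R` | rank-sum + Hodges–Lehmann CIs, Kendall τ-b, per-family Bonferroni correction (motion family: 19 tests, p_corr = 0.0026) |

Run them in order from the repository root with `Rscript`.

## Scope

The hybrid decision forests that produce landmarks and probabilistic
segmentations on real scans are delegated to their own publication and
deliberately not reimplemented; DICOM conversion, motion *correction*,
out-of-plane motion and transient within-cycle artefacts are out of
scope. See `vignettes/cine-stack-qc.Rmd` for the full methods account
and design rationale.
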