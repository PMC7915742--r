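---
title: "Methods: test–retest repeatability of PET radiomics features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test–retest repeatability of PET radiomics features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistical model

A single static PET acquisition detects N coincidence events; per voxel,
N is well modeled as Poisson with mean proportional to local tracer
activity. Splitting the event stream into odd- and even-time-stamp halves
and reconstructing each half separately yields two images of the same
anatomy whose noise realizations are independent. `petrepeat` emulates
this split as Bernoulli(1/2) thinning of the per-voxel counts: for Poisson
counts, thinning gives two *exactly* independent Poisson variables with
half the mean, and the halves sum to the original counts voxel for voxel.
A deterministic alternating split (`method = "alternate"`) is available
for sensitivity analysis; it conserves counts but its halves are strongly
negatively coupled, which is exactly why the thinning model is the
default — the target of the dual reconstruction is statistical
independence, and thinning achieves it in distribution, not just
approximately.

Tomographic reconstruction itself (OSEM, attenuation, scatter, randoms,
decay correction) is out of scope: image formation is modeled as
`expected counts = exposure × PSF-blurred activity`, and reconstruction as
`counts / exposure` with optional Gaussian post-smoothing. This preserves
the two properties the repeatability analysis depends on — unbiasedness
for the underlying activity and Poisson noise scaling with 1/exposure —
while ignoring the spatial noise correlations a real iterative
reconstruction introduces. Consequences of that simplification are listed
under *Limitations*.

Feature repeatability is quantified per feature by arranging the cohort as
an n-subjects × 2-measurements rating matrix and computing the two-way
absolute-agreement single-measure intraclass correlation

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \frac{k}{n}(MS_C - MS_E)},$$

where \(MS_R\), \(MS_C\), \(MS_E\) are the two-way ANOVA mean squares for
rows (subjects), columns (measurements) and error. The absolute-agreement
form penalizes a systematic test–retest shift (through \(MS_C\)), which is
the right convention here: the two halves are exchangeable
reconstructions, and any systematic difference between them is itself a
repeatability failure. The 95% CI is the exact F-based interval of the
McGraw–Wong construction for this ICC form; the point estimates and
intervals are validated in the test suite against a frozen battery of 100
random matrices computed with the established Python reliability
implementation (point estimates to 1e-6; its printed CI, which that
implementation rounds to two decimals, at that printed precision) and
against an independent full-precision transcription of the interval.

A feature is classified from its CI: *repeatable* if both limits lie in
[0.91, 1.00]; *moderately repeatable* if the upper limit lies in
[0.91, 1.00] and the lower in [0.75, 1.00]; otherwise *not repeatable*.
Combinations matching no band — including negative lower limits and
undefined (degenerate) intervals — are conservatively *not repeatable*,
and "repeatable" takes precedence over "moderate" where both match.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| grid shape / spacing | 96³ / 2 mm | voxels / mm | plausible brain-PET reconstruction grid; the scanner's true voxel size is not public, so this is a configurable placeholder, not an inferred value |
| `background_uptake` | 1.0 | SUV | healthy-brain FET uptake is the natural SUV reference |
| `tbr_contrast` | 2.0 (2.5 wildtype / 2.0 mutant in cohorts) | ratio | above the 1.6 segmentation threshold, as a detectable glioma must be |
| `tumor_radius` | 15 | mm | 14.1 mL sphere — the size class the volume analysis centers on |
| `texture_scale`, `texture_amplitude` | 6 mm, 0.2 (0.30/0.15 by genotype) | mm, fraction | Gaussian-smoothed multiplicative field; gives texture features nonzero dynamic range with a correlation length above the PSF |
| `psf_fwhm` | 4 | mm | high-resolution brain PET point spread |
| `exposure` | 400 | counts per SUV per voxel | sets count statistics so that half-count images carry visible but not overwhelming Poisson noise |
| TBR threshold | 1.6 | ratio | biopsy-validated tumor/brain cutoff for FET |
| background sphere | 30 | mm diameter | 14.1 mL reference volume in contralateral brain |
| sphere series | 10, 16, 20, 24, 30, 35, 40 | mm diameter | spans ≈ 0.5–33.5 mL; the exact clinical series is not published, so the set is configurable |
| bin width | 0.15 | SUV | the recommended fixed bin width for PET discretization |
| LoG sigmas | 1–5 | mm | the five band-pass scales of the filtered feature bank |
| wavelet kernel | coif1 | — | the reference radiomics implementation's default; the clinical analysis does not name one |
| ICC `alpha` | 0.05 | — | 95% CI, as the classification bands require |
| `min_n` | 5 | subjects | below this, CI-band classification is too unstable to report |

Cohort defaults (30 wildtype / 20 mutant subjects; lognormal tumor volumes
with group means 21.4 and 16.7 mL, CV 0.6) mirror the published cohort
structure: volumes in glioma cohorts are strictly positive and
right-skewed, and the wildtype group carries the larger, more
heterogeneous lesions.

## What the generator emulates — and what it does not

The synthetic cohort reproduces the *statistical shape* of the clinical
analysis: independent Poisson halves, a contoured lesion above TBR 1.6, a
background sphere, the sphere-diameter series, two genotype groups
differing in volume and texture. It does **not** emulate anatomy (gray /
white matter structure), reconstruction noise correlations, scatter or
attenuation artifacts, patient motion, or dynamic tracer kinetics (only a
static 20–40 min-equivalent frame is simulated). A green directional test
therefore establishes that the pipeline's machinery behaves correctly and
that the published *trends* (repeatability rising with VOI volume and
with count statistics; genotype clusters separating on repeatable
features; tumor-vs-background cross-comparison yielding no repeatable
features) emerge under the stated noise model — it does not certify the
clinical percentages, which depend on the unavailable patient data.

## Numerical conventions

* **Discretization.** Fixed bin width anchored at the VOI minimum,
  `level = floor((x − min)/w) + 1`, half-open bins with a closed top edge
  (a maximum exactly on an edge stays in the last occupied bin). The
  nominal "64 bins with fixed width 0.15" is contradictory as a general
  rule; the fixed width governs, and the realized bin count is reported
  with a warning when it differs from 64
  (`options(petrepeat.warn_bins = FALSE)` silences it in bulk runs).
  Discretization is anchored per half independently, mirroring feature
  extraction run separately on test and retest images. Whether clinical
  intensities entering discretization were SUV or TBR-normalized is not
  stated; SUV is assumed, as it is the normalization the segmentation
  section defines.
* **Texture matrices.** GLCM and GLRLM use the 13 unique 3D directions at
  distance 1; feature values are averaged over directions (matrices are
  not merged), matching the reference implementation's default. GLSZM
  zones and the auto-contour's connected components use 26-connectivity.
  GLDM uses distance 1 and similarity tolerance 0, with column index
  = dependence + 1 so that formulas dividing by the column index are
  well defined. NGTDM counts only voxels with at least one in-mask
  neighbor.
* **Degenerate values.** Features whose formula divides by zero on the
  given VOI (skewness of a constant VOI, pair-based families on a single
  voxel) return `NaN` — flagged and excluded from ICC denominators with
  counts logged — rather than a fabricated 0, which would manufacture
  perfect repeatability. Named degenerate conventions follow the field's
  reference implementations: NGTDM coarseness capped at 1e6, GLCM
  correlation 1 on zero variance, NGTDM contrast 0 for a single occupied
  level.
* **Tie-breaks.** The sphere-series center is the argmax-SUV voxel in the
  tumor mask, ties broken at the lowest linear index with a warning; Ward
  merges inherit `hclust`'s deterministic ordering.
* **Boundaries.** LoG kernels are spacing-aware, sampled analytically,
  mean-corrected to zero DC, applied with reflective padding; the
  stationary wavelet transform uses periodic boundaries, the convention of
  undecimated transforms. Filtered variants stay on the source grid so
  VOI masks transfer unchanged.
* **Segmentation transfer.** All VOIs are defined once on the full-count
  reference image (the mean of the two halves, which reconstructs the
  summed counts exactly) and reused voxel-for-voxel on both halves —
  never re-segmented per half, since mask variation would contaminate the
  noise-only comparison (and is why shape features are excluded: they are
  identical by construction).

## Design decisions that were genuinely open

* **Component selection in auto-contouring.** Whether the clinical tool
  kept the component containing the maximum or the largest component is
  unstated; this package seeds at the lesion (component containing the
  global maximum), like clinical region-growing tools.
* **CI construction.** The clinical text names the ICC form but not the
  interval; the exact F-based interval is the construction its named
  software family uses, so that is implemented and cross-checked.
* **Clustering input.** Whether subjects were clustered on test, retest
  or summed-image features is unstated; default: test-half values,
  configurable.
* **Config format.** Pipeline configs are JSON (jsonlite), not YAML — no
  YAML parser exists in the supported R stack; the config schema is
  otherwise as specified.
* **NIfTI I/O.** No NIfTI package exists in the supported R stack, so the
  package ships a minimal, round-trip-tested NIfTI-1 reader/writer
  (float64, axis-aligned sform) rather than a full implementation.

## Limitations

Reconstruction is a noise-equivalent stand-in: real OSEM introduces
spatially correlated, object-dependent noise and resolution that this
model's independent Poisson voxels do not carry, so absolute repeatable
fractions from synthetic cohorts should be read as pipeline diagnostics,
not clinical estimates. The texture field is stationary Gaussian and
multiplicative — real intratumoral heterogeneity (necrosis, infiltration
gradients) is neither. ICC assumes approximate normality of
subject and error effects; heavy-tailed features (e.g. energy-like
quantities spanning orders of magnitude) may classify differently after a
variance-stabilizing transform, which the pipeline does not apply. The
minimum reporting size (n = 5) keeps the CI defined but small cohorts
yield wide intervals and conservative (rarely "repeatable")
classifications by construction.
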