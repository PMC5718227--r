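---
title: "Adaptive-threshold PET tumor delineation: model, calibration and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-threshold PET tumor delineation: model, calibration and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PETseg)
```

## The model

A PET lesion has no sharp boundary: scanner blur (here, a clinical spatial
resolution of 7 mm FWHM) spreads activity over several 4 x 4 mm² pixels, so
the "right" cut-off intensity depends on the lesion's uptake, its size, and
the surrounding background. PETseg implements an adaptive-thresholding
strategy in which the cut-off is expressed relative to the region's mean
uptake,

$$\%T_{mean} = 100 \cdot \frac{Threshold}{T_{mean}},$$

and a *threshold-adjustment function* predicts $\%T_{mean}$ from two
image-derived parameters: $T_{mean}$ (or $T_{max}$), the mean (maximum)
intensity of the segmented target, and $B_{min}$, the minimum intensity in
the lung fields. $B_{min}$ is an empirical background proxy with no direct
physical meaning; it is used because it correlates well with the other
parameters and can be measured fully automatically from a CT-derived lung
mask, which makes the method operator-independent.

The package ships the eight published functions (`predefinedModel(1:8)`).
Functions 1–4 were adjusted on a 38-lesion cohort whose reference was the
expert-delineated lesion area on CT; functions 5–8 on a 27-lesion cohort
referenced to histological major axes of resected specimens. Within each
quartet: a power law on $T_{mean}/B_{min}$, a power law on
$T_{max}/B_{min}$, a linear $T_{max}$-from-$T_{mean}$ law, and the
composition of the last two, e.g. the validated CT-referenced function

$$\%T_{mean} = 136.09\left[1.64\,\frac{T_{mean}}{B_{min}} -
\frac{1634.8}{B_{min}}\right]^{-0.22}.$$

Composition matters because at segmentation time only $T_{mean}$ is updated
iteratively; routing it through the $T_{max}$ law exploits the tighter
$T_{max}$ correlation while keeping the iteration driven by the mean.
A composed model's fit quality is not inherited from its parents:
`composedRSquared()` measures $1 - SS_{res}/SS_{tot}$ of its predictions
against observed operating points (0.92 over the 27 bundled clinical
points).

## The segmentation loop

`segmentIterative()` is a fixed-point iteration:

1. measure $B_{min}$ once (fixed for all iterations); set
   $T_{mean} := T_{max}$ of the ROI;
2. evaluate the adjustment function at $(T_{mean}, B_{min})$, convert
   $\%T_{mean}$ to an absolute threshold (rounded to the nearest integer
   gray level, ties away from zero — PET intensities are integer counts);
3. extract the 8-connected component of pixels $\geq$ threshold containing
   the ROI's hottest pixel; re-measure $T_{mean}$;
4. repeat until the pixel set repeats.

State identity is the *pixel set*, not the floating-point $T_{mean}$: two
different means that extract the same region are the same state, which
avoids near-miss loops. An immediate repeat is a fixed point
(`converged = TRUE`); a revisit of an older state is a cycle, reported as
the last state with `converged = FALSE` rather than silently averaged —
cycles never occur on nested-region phantoms but the honest behaviour is to
flag them. When the computed threshold exceeds the achievable maximum
(possible for low $T_{mean}/B_{min}$, where the composed law exceeds 100%),
the region collapses to the single hottest pixel and the result is flagged
`degenerate`: this *is* the documented small-lesion failure mode, and
clamping it away would hide it. `maxIter` defaults to 100; on monotone
phantoms the loop provably stops within the number of unique ROI
intensities, and the clinical worked example converges in 3.

The inclusion rule is $\geq$ threshold, so the threshold equal to $T_{max}$
always yields a non-empty region; connectivity is 8-neighbour with the
anchor at the ROI maximum (row-major tie-break). Neither choice is forced
by the method's description; both are fixed here and exercised by the
oracle tests.

## Calibration

`calibrateToArea()` / `calibrateToAxis()` reproduce the reference-driven
threshold scan. The candidate ladder is *every unique pixel intensity in
the ROI*: since regions are nested as the threshold drops, this visits
every achievable region exactly once, and a coarser "several gray levels"
grid could only miss minimizers. All global minimizers of the absolute
discrepancy (region area vs CT area, or region major axis vs histological
axis) form the accepted set aTH; the retained Threshold is the midpoint of
its extremes, and $T_{mean}$, $T_{max}$, $\%T_{mean}$ are measured on the
region extracted at that Threshold (the alternative — averaging per-aTH
measurements — is ambiguous in the method's description; measuring at the
final Threshold matches how the function is later *applied*). For the axis
reference, the recorded PET area is the mean area over accepted thresholds.

`fitFamily()` fits the spreadsheet trend-line families — linear,
exponential, logarithmic, power, degree-2 polynomial — with power and
exponential fitted by ordinary least squares on the log response (the
spreadsheet convention) and every R² computed on the original response
scale, so families are comparable. `selectBestFamily()` retains the largest
R², breaking exact ties by the declared family order. The moving average of
the original six-family list is excluded: it has no closed-form predictor
and cannot serve as an adjustment function. The polynomial degree is fixed
at 2.

The major axis of a region is the maximum Euclidean distance between
member pixel centres. On a 4 mm grid this produces exactly the
characteristic published values (14.4, 17.9, 25.6, 28.8, ...), which is
the evidence that centre-to-centre distance is the measurement convention.
The uptake COV uses the population SD (divisor $n$), the convention under
which the published group SDs (±22.1, ±9.0, ±3.1, ±0.07) are reproduced
exactly at the printed precision; the sample SD is not compatible with
them. Pixel spacing is a required input defaulting to 4 x 4 mm² — a few
published areas (e.g. 244 mm²) are not multiples of 16 mm², so per-exam
spacing evidently varied and cannot be assumed.

## The phantom generator

`generatePhantom()` emulates the imaging chain, not a patient: a crisp
elliptical lesion (the ground truth, rendered at 1 mm CT resolution) inside
a circular low-activity lung field inside a warmer body, convolved with a
Gaussian PSF of 7 mm FWHM *at CT resolution*, then box-averaged to the 4 mm
PET grid (blur happens in the scanner before detector binning, so the order
matters), then additive Gaussian noise clipped at zero. All randomness
flows from the spec's single seed through a local RNG state; nothing leaks
into or depends on the caller's random stream.

`generateCohort()` draws specifications uniformly: lesion major axis
10–45 mm (the study's inclusion range), aspect ratio 0.6–1, lesion activity
3000–20000 against a lung background of 250–700, which reproduces the
clinical $T_{mean}/B_{min}$ range of roughly 5–60; noise SD defaults to 50
(about 10–20% of the lung background, keeping $B_{min}$ positive in fields
of a few thousand pixels) and body activity to 1000 (chest wall uptake
exceeds lung parenchyma, so the lung minimum stays inside the lungs).

What the phantoms *do* reproduce: partial-volume overestimation of small
lesions (at a half-maximum threshold, a 10–20 mm cohort shows a mean area
bias of about +19% while a 30–45 mm cohort is essentially unbiased), flux
conservation under blur, nested-region monotonicity, and a calibratable
$\%T_{mean}$-vs-contrast relationship: calibrating a power law on 30
phantoms and segmenting held-out 20–45 mm phantoms recovers truth areas to
a mean absolute dVs below 15%, with the small-lesion positive bias intact.
What they do *not* contain: respiratory motion, heterogeneous or necrotic
uptake, Poisson counting statistics (additive Gaussian noise is a
simplification), anatomy-dependent backgrounds, or 3D effects — the method
itself is strictly per-slice. Green phantom tests therefore validate the
algorithmic machinery, not clinical accuracy.

## Numerical choices and degenerate inputs

* Thresholds are rounded to integer gray levels, half away from zero.
* Published coefficients are stored exactly as printed; worked-example
  comparisons carry a ±0.5 percentage-point band because the printed
  %Tmean values were evidently produced with unrounded regression
  coefficients (e.g. the printed 52.88 versus 52.68 from printed
  coefficients).
* "Closest to the reference" means minimal absolute difference; *all*
  global minimizers (within 1e-9, absorbing float noise) enter aTH, and
  near-minimizers do not.
* Empty regions, dimension mismatches and out-of-domain model evaluations
  (non-positive $B_{min}$, non-positive power-law base) raise typed errors
  rather than returning sentinel values.
* A region whose mean is zero (possible only for an all-zero background
  mask) reports COV 0.
* Tie-breaks everywhere are deterministic: row-major anchor selection,
  first-in-order family selection, lowest-index slice selection.

## Problem sizes

The shipped tests run the oracle-equivalence check on 20 seeded phantoms
(48 x 48 PET grids) against an exhaustive threshold-sweep fixed-point
oracle, and the calibration round-trip on 30 calibration plus 20 held-out
phantoms; both complete in well under a minute. Larger cohorts change
nothing qualitatively: the estimators are deterministic given the seed and
the phantom grids are translation-invariant.

## Known limitations

* Small lesions (at or below ~3x the PSF FWHM) are intrinsically
  misestimated; the package reports the degenerate collapse rather than
  correcting for partial volume.
* The published functions' own patient-level R² values cannot be re-derived
  because the underlying calibration images are not available; the
  coefficients are carried verbatim and only printed-table arithmetic is
  reproducible.
* Calibration assumes a single connected lesion per ROI; multifocal uptake
  within one ROI is resolved in favour of the hottest component.
* No spatial registration is performed: PET, CT-derived lung masks and ROIs
  are assumed aligned on input.
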