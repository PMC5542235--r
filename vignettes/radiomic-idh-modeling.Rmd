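---
title: "Radiomic modeling of IDH mutation status: methods and design notes"
author: "idhrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic modeling of IDH mutation status: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idhrad)
```

## The problem

Glioblastomas split into two molecular subclasses by the mutation status of
the isocitrate dehydrogenase (IDH) gene, and the two subclasses differ in
prognosis and management. The mutation is normally established by
immunohistochemistry or sequencing of biopsy tissue; intratumoral
heterogeneity and inoperable lesions make a noninvasive image-based
surrogate attractive. `idhrad` implements a classical radiomic pipeline for
this question: quantitative features are extracted from a single 2-D tumor
region of interest (ROI) on a contrast-enhanced T1-weighted MR image, and a
binary logistic-regression classifier with wrapper feature selection maps
them to a mutation probability. The package covers the full chain -- image
and mask ingestion, intensity normalization, three feature families,
selection, leave-one-out validation, and the comparative statistics used to
judge one feature family against another -- plus a synthetic cohort
generator that provides a controlled end-to-end test bed.

The working unit is a `roi_image`: a grayscale pixel matrix and an aligned
binary tumor mask. Only single-slice 2-D input is supported, reflecting the
design in which a neuroradiologist picks the most representative axial
slice per tumor; 3-D volumes, registration and automatic segmentation are
out of scope.

## Preprocessing

Scanner units are arbitrary, so each image is linearly stretched over the
whole field of view to the full 8-bit range: `v -> round(255 (v - min) /
(max - min))`. Normalizing over the whole image (not just the ROI) mirrors
the clinical workflow in which the stretch is applied before the contour is
drawn, and keeps tumor-to-background contrast meaningful. Rounding is
half-away-from-zero so the discrete gray levels feeding the co-occurrence
matrix are platform-stable; strict min/max (not percentile) endpoints are
used, which makes the map idempotent and monotone but sensitive to single
extreme pixels -- acceptable for the synthetic data and documented here as
a deliberate simplification. A constant image has no contrast and is
rejected rather than silently mapped.

## Feature families

**Morphology** (`morph.*`): tumor area (pixel count), perimeter, their
combination into compactness `P^2 / (4 pi A)` (1 for an ideal disk, 4/pi
for a square), and the mean and population SD of the normalized radial
length (NRL) -- the distance from the mask centroid to each boundary pixel
divided by the maximum such distance. Boundary pixels are mask pixels with
at least one false 4-neighbour. The perimeter is measured on the Moore
(8-neighbour) contour. Two estimators are offered: the plain polygon
through boundary-pixel centers (axis step 1, diagonal `sqrt(2)`), which is
exactly hand-traceable on rectangles, and the default Vossepoel--Smeulders
corner-corrected chain length (weights 0.980 per axis step, 1.406 per
diagonal, -0.091 per direction change). The default was chosen because the
plain polygon carries a known ~5% systematic overestimate on smooth
digitized outlines, which squares to ~10% in compactness and does not
vanish with resolution: a digitized disk's compactness then plateaus near
1.10 at every radius. Under the corner-corrected estimator a disk of radius
20 gives compactness 0.974, converging toward 1 as the radius grows, which
is the behaviour a scale-free shape index should have.

**Intensity** (`int.*`): the ROI histogram over the 256 gray values (bin
width 1; masked pixels only) summarized by its first four moments -- mean,
variance, skewness (third standardized moment) and kurtosis. Kurtosis is
reported as excess (normal limit 0) by default since the index is usually
read against a Gaussian reference; the Pearson convention is a flag away.
A zero-variance ROI returns 0 for both shape moments instead of failing,
so degenerate inputs remain usable in controlled experiments.

**Texture** (`tex.*`): gray-level co-occurrence (GLCM) features. The
normalized image is first quantized to `G` levels (`floor(v G / 256)`,
default `G = 32` -- small enough that the `G x G` matrix is well populated
by a few thousand ROI pixels, large enough to retain contrast structure).
For distance `d = 1` and each direction 0, 45, 90, 135 degrees, ordered
level pairs whose two pixels both lie inside the mask are accumulated
symmetrically (each pair also counted reversed), giving a symmetric
probability matrix `p(i, j)`. Pairs crossing the ROI boundary are
discarded rather than padded. Fourteen descriptors are computed per
direction -- autocorrelation, contrast, correlation, cluster prominence,
cluster shading, dissimilarity, energy, entropy, homogeneity, difference
variance, difference entropy, information measure of correlation, inverse
difference normalized, and inverse difference moment -- and averaged over
the four directions by default (per-direction output is available, and a
90-degree image rotation permutes the directions exactly). All entropies
use natural logarithms with `0 log 0 = 0`.

A few conventions deserve explicit statement because published variants
differ:

* autocorrelation is `sum_ij i j p(i,j)`; it needs no marginal scaling.
* homogeneity is `sum_ij p(i,j) / (1 + |i-j|)` and inverse difference
  moment `sum_ij p(i,j) / (1 + (i-j)^2)`, so IDM <= homogeneity <= 1
  always.
* inverse difference normalized follows Clausi:
  `sum_ij p(i,j) / (1 + |i-j|/G)`.
* difference variance is implemented as the second raw moment of the
  `|i-j|` distribution, `sum_k k^2 p_(x-y)(k)`; under this definition it
  coincides with contrast, and it is retained as a separate named feature
  for interface completeness.
* the information measure of correlation is the canonical
  `(HXY - HXY1) / max(HX, HY)`.
* a constant ROI collapses the GLCM to one cell; correlation (and the
  information measure) are then defined as 0 and the feature vector is
  flagged degenerate, rather than erroring, so constant test images flow
  through the pipeline.

Gray levels are indexed 0..G-1 throughout; marginal means and SDs are
computed on that scale.

## Classification, selection, validation

Features are standardized (training mean/SD, stored in the model) before a
maximum-likelihood logistic fit, because GLCM features span orders of
magnitude. With only a handful of positives, quasi-complete separation is
likely; when it is detected the fit falls back to a weak ridge penalty
(1e-4 on standardized slopes, intercept free) and the model is flagged.

Feature selection is stepwise backward elimination with the leave-one-out
(LOOCV) error as the criterion: at each step the feature whose removal
gives the lowest LOOCV error is dropped, while the best removal does not
increase the current error; ties prefer removal (smaller subsets) and then
alphabetical order, so the procedure is fully deterministic. A
regression-style variant that removes by largest Wald p-value is available
behind `criterion = "wald"` for comparison.

Validation is leave-one-out: each case is predicted by a model fitted to
the other n-1 cases, with standardization re-estimated inside every fold.
The decision threshold on the mutation probability is 0.5. Two selection
placements are offered in `idh_model()`: `mode = "pooled"` (default)
selects once on all cases and cross-validates the chosen subset -- the
protocol classical radiomics studies report, which leaks the selection and
is optimistic -- and `mode = "nested"`, which re-runs elimination inside
every fold and is the leakage-free estimate. Both are kept because the
package's purpose includes reproducing the classical protocol faithfully
while making its optimism measurable.

Performance is summarized by accuracy, sensitivity and specificity
(positive class = IDH-mutant), Cohen's kappa
(`(Po - Pe) / (1 - Pe)` from the confusion marginals) with the usual
agreement bands (right-closed: slight <= 0.20 < fair <= 0.40 < moderate <=
0.60 < substantial <= 0.80 < almost perfect), and Pearson chi-squared
tests (df = 1, two-sided, no continuity correction) comparing
correct/incorrect counts between feature sets. The uncorrected test is the
deliberate choice: it is what mainstream statistical packages report as
the default Pearson statistic for these 2x2 comparisons, and it is the
variant under which the reference comparison p-values for this design
(0.0016, 0.0119, 0.0034, 0.0261, 0.2367) are recovered exactly from the
underlying correct/incorrect counts; Yates correction does not recover
them. For the reference texture confusion table (tp 6, fn 1, fp 5, tn 27)
the kappa formula gives 0.5730 (0.6 at one-decimal rounding); `idhrad`
always reports the full computed value.

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` produce a labeled two-class cohort
of image/mask PNG pairs emulating the study conditions the pipeline is
meant for: 32 wild-type and 7 mutant cases by default, a pronounced class
imbalance that exercises the separation fallback and the majority-rate
baseline of 32/39 = 0.82.

* **Shape**: star-convex masks with boundary radius
  `r(phi) = R (1 + sum_k a_k cos(k phi + phi_k))`, harmonics k = 2..6,
  total amplitude `shape_irregularity` (default 0.15) and random phases.
  Both classes share the same shape distribution, so morphology carries no
  label information by construction.
* **Interior texture**: Gaussian white noise smoothed with a Gaussian
  kernel of width equal to the class correlation length, rescaled to unit
  variance, scaled by the class amplitude and centered on the tumor base
  intensity. Defaults: correlation length 4 px (wild-type) vs 1.5 px
  (mutant), equal amplitudes 40. Equal amplitudes mean the classes match
  in marginal intensity distribution; only the *spatial* grain differs.
  A shorter correlation length produces more level changes between
  neighbouring pixels, which depresses the inverse difference moment and
  its relatives -- so the mutant class is the more heterogeneous one, the
  direction observed clinically, and texture is the only feature family
  that should separate the classes. The 1.5 vs 4 px contrast was fixed
  once as a clearly-resolvable effect at the 128 px image scale.
* **Background**: a darker noisy background (mean 60, SD 10, vs tumor mean
  150) so whole-image normalization is exercised realistically.
* **Reproducibility**: each case derives its RNG stream from
  `(seed, case index)`; regenerating a cohort with the same spec is
  byte-identical.

What the generator does *not* emulate: MRI physics (bias fields, Rician
noise, partial-volume edges), inter-scanner variation, correlated
shape/texture effects, or any real biological feature distribution. A
pipeline that passes the synthetic recovery tests is demonstrably able to
detect class-coded texture heterogeneity under class imbalance; passing
says nothing further about accuracy on clinical images.

## Numerical and degenerate-input choices

* Half-away-from-zero rounding in normalization; `floor` quantization
  clipped to `G - 1`.
* GLCM requires at least one valid pair; single-row masks at vertical
  directions raise a degenerate-input error rather than returning NaNs.
* A single-pixel mask has perimeter 1 by convention and no radial-length
  statistics (error), and empty masks are rejected at construction.
* LOOCV folds whose training half loses a class raise an error naming the
  held-out case; with at least 2 cases per class (enforced at table
  construction) this cannot happen silently.
* Elimination never empties the subset; with one feature left it stops.
* The ridge fallback strength 1e-4 is small enough to leave
  non-separable fits untouched (it only engages on detected separation)
  and large enough to keep coefficients finite.

## Problem sizes used in the test suite

The packaged tests run the full chain on cohorts of 39 cases at 128 px
(the reference configuration) and 15--21 cases at 48--64 px for the
faster property checks; the GLCM implementation is verified against an
independent brute-force double-loop evaluator on 100+ random masked
images up to 16 x 16 at up to 8 gray levels, at tolerance 1e-9. These
sizes were chosen so the whole suite completes in about a minute on a
single core while still exercising every code path at the reference
cohort scale.

## Known limitations

* Single 2-D slice only; no DICOM ingestion (PNG/TIFF/NIfTI readers are
  provided).
* The feature list is fixed to the three families above; run-length,
  wavelet and Laws families are out of scope.
* `mode = "pooled"` is knowingly optimistic; use `mode = "nested"` when an
  unbiased error estimate matters.
* Min/max normalization is outlier-sensitive; robust percentile stretching
  is not implemented.
* No ROC/AUC or confidence intervals on kappa; the evaluation mirrors the
  accuracy/sensitivity/specificity + kappa + chi-squared design it was
  built to reproduce.
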