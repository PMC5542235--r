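# idhrad

Radiomic prediction of IDH mutation status in glioblastoma from a single
2-D tumor ROI on contrast-enhanced T1-weighted MRI.

Glioblastomas with and without isocitrate dehydrogenase (IDH) mutations
differ in prognosis, but the mutation is normally established from biopsy
tissue. `idhrad` implements the classical radiomic alternative end to end,
for image-analysis researchers who want the whole chain as tested,
reusable R functions rather than a one-off script:

1. **Ingestion and normalization** — grayscale image + binary tumor mask
   (PNG/TIFF/NIfTI), whole-image intensity stretch to 0–255:
   `v ↦ round(255·(v − min)/(max − min))`.
2. **Feature extraction**, three families per ROI:
   * *morphology*: area `A`, perimeter `P` (corner-corrected contour
     length), compactness `P²/(4πA)`, mean and SD of the normalized
     radial length (centroid-to-boundary distances scaled by their
     maximum);
   * *intensity*: histogram moments — mean, variance, skewness, excess
     kurtosis — over masked pixels;
   * *texture*: 14 gray-level co-occurrence (Haralick) features from
     symmetric GLCMs `p(i,j | d=1, θ)` at θ ∈ {0°, 45°, 90°, 135°} after
     quantization to G = 32 levels, averaged over directions
     (autocorrelation, contrast, correlation, cluster prominence/shading,
     dissimilarity, energy, entropy, homogeneity, difference
     variance/entropy, information measure of correlation, inverse
     difference normalized, inverse difference moment).
3. **Classification** — binary logistic regression on standardized
   features with stepwise backward elimination selected by lowest
   leave-one-out error, leave-one-out validation (LOOCV), and a ridge
   fallback for quasi-separation.
4. **Evaluation** — accuracy/sensitivity/specificity, Cohen's κ with
   agreement bands, and uncorrected Pearson χ² comparisons of
   correct-classification counts between feature sets.
5. **Synthetic cohorts** — a generator of irregular star-convex tumor
   masks whose *interior texture grain* (Gaussian random field correlation
   length) differs by class while shape and intensity distributions do
   not, at a configurable 32:7 wild-type:mutant imbalance.

## Worked example

Generate the reference synthetic cohort (39 cases, 7 mutant; mutant
texture correlation length 1.5 px vs 4 px), extract all 23 features, and
run the three-way feature-set comparison:

```r
library(idhrad)

spec  <- cohort_spec(seed = 1)          # 32 WT : 7 mutant, 128 px images
man   <- generate_cohort(spec, file.path(tempdir(), "cohort"))
ft    <- extract_features(man)          # 39 x (5 morph + 4 int + 14 tex)
study <- run_study(ft, feature_sets = c("morphology", "intensity", "texture"))
print(study)
```

```
Radiomic feature-set study (loocv selection, pooled validation)

            morphology      intensity       texture
accuracy    "82% (32/39)"   "82% (32/39)"   "100% (39/39)"
sensitivity " 0% (0/7)"     " 0% (0/7)"     "100% (7/7)"
specificity "100% (32/32)"  "100% (32/32)"  "100% (32/32)"
kappa       "0.00 (slight)" "0.00 (slight)" "1.00 (almost perfect)"

morphology: selected morph.perimeter

intensity: selected int.mean

texture: selected tex.inverse_difference_normalized

Pairwise chi-squared comparisons:
      metric      set_a     set_b  chi2        p
    accuracy morphology intensity  0.00 1.000000
    accuracy morphology   texture  7.69 0.005550
    accuracy  intensity   texture  7.69 0.005550
 sensitivity morphology intensity    NA       NA
 sensitivity morphology   texture 14.00 0.000183
 sensitivity  intensity   texture 14.00 0.000183
 specificity morphology intensity    NA       NA
 specificity morphology   texture    NA       NA
 specificity  intensity   texture    NA       NA
```

Reading this: only texture carries the class signal by construction, and
the pipeline finds it — backward elimination keeps a single co-occurrence
homogeneity feature and LOOCV classifies all 39 cases, while morphology
and intensity models collapse to the majority class (32/39 = 82%
accuracy, κ = 0; their sensitivity is 0 because no mutant is ever
called). The χ² column quantifies the texture-vs-other gaps; `NA` marks
degenerate tables (e.g. both specificities perfect).

The central object is also available directly, in the usual R modeling
idiom:

```r
d <- as.data.frame(ft)[c("case_id", "label",
                         grep("^tex\\.", names(ft), value = TRUE))]
m <- idh_model(label ~ ., d, mode = "nested")   # leakage-free variant
summary(m)
coef(m); plot(m); head(m$predictions)
```

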