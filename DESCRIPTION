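Package: idhrad
Title: Radiomic Prediction of IDH Mutation Status in Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Radiomic analysis of 2-D tumor regions of interest on
    contrast-enhanced T1-weighted MRI for classifying glioblastomas by
    isocitrate dehydrogenase (IDH) mutation status. Extracts three feature
    families from a grayscale image plus binary tumor mask: morphology
    (area, perimeter, compactness, normalized radial length statistics),
    intensity-histogram moments (mean, variance, skewness, kurtosis), and
    fourteen gray-level co-occurrence matrix (Haralick) textures at
    distance 1 over four directions. Classifies with binary logistic
    regression under stepwise backward feature elimination selected by
    leave-one-out error, and evaluates with accuracy, sensitivity,
    specificity, Cohen's kappa and chi-squared comparisons between feature
    sets. Includes a synthetic two-class tumor-cohort generator with
    class-dependent interior texture heterogeneity for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    png,
    tiff,
    RNifti,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
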