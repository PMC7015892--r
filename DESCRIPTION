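Package: saqc
Title: Automated Quality Control for Short-Axis Cine Cardiac MR Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automated quality control for short-axis (SA) cine
    cardiac magnetic resonance stacks: heart coverage of the left
    ventricle (with basal/apical gap estimation), inter-slice
    misalignment caused by inconsistent breath-holds (overall and
    regional), and cardiac image contrast between the LV blood pool and
    myocardium normalised by the dynamic range. Includes world-space
    slice geometry derived from NIfTI affines, landmark fusion across
    long-axis views with sanity checks, threshold-based stack
    classification, a synthetic ellipsoidal LV phantom and cohort
    generator with full ground truth for validation, and the
    nonparametric cohort statistics battery (Wilcoxon rank-sum with
    Hodges-Lehmann confidence intervals, Kendall tau-b, Anderson-Darling
    normality testing, Bonferroni correction) used to relate image
    quality to acquisition details and subject phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    EBImage,
    nortest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
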