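Package: octmhri
Title: Macular Hole Reflectivity Indices from OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal pigment epithelium (RPE) reflectivity on
    spectral-domain OCT B-scans of full-thickness macular holes and evaluates
    the resulting indices as prognostic biomarkers. Implements straight-line
    brightness profiling on 8-bit greyscale images, the five reflectivity
    indices (CRI-Max, CRI-Mean, PCRI-Min, PCRI-Mean and the macular hole
    reflectivity index MHRI), minimum linear diameter measurement, synthetic
    B-scan phantoms with known ground truth, cohort simulation, and the full
    prognostic statistics toolkit: group comparisons, Spearman correlations,
    multiple linear regression with collinearity diagnostics, ROC analysis
    with Youden-index cutoffs, Bland-Altman limits of agreement and
    intraclass correlation coefficients.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    png,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    tiff,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
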