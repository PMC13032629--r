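# octmhri

Reflectivity-index analysis of full-thickness macular holes on SD-OCT
B-scans, for retina researchers evaluating preoperative prognostic
biomarkers of surgical and visual outcome.

Anatomical closure after macular hole surgery is common, but visual recovery
is not, and the state of the RPE–photoreceptor complex at the hole base is a
plausible determinant. On an 8-bit greyscale B-scan, the hole base shows a
central hyperreflective region flanked by two paracentral hyporeflective
regions along the RPE band. Writing `Cmax`/`Cmean` for the maximum/mean
brightness of the central line profile, `Pmin`/`Pmean` for the paracentral
profiles (aggregated across both sides) and `R̄` for the mean brightness of
unaffected ("normal") RPE, the package computes

    CRI-Max  = Cmax / R̄        CRI-Mean = Cmean / R̄
    PCRI-Min = Pmin / R̄        PCRI-Mean = Pmean / R̄
    MHRI     = Cmax / Pmin     (the macular hole reflectivity index)

plus the minimum linear diameter (MLD, µm) between the inner hole edges, and
runs the downstream prognostic statistics: group comparisons
(t / Mann-Whitney / Fisher with Shapiro-Wilk dispatch), Spearman
correlations with postoperative acuity, multiple linear regression with
VIF/tolerance collinearity diagnostics, ROC analysis with Youden-index
cutoffs (bootstrap or DeLong AUC intervals), and inter-rater agreement
(ICC(2,1) and Bland-Altman limits of agreement). Because clinical B-scans of
this kind are not publicly deposited, the package ships a phantom generator
(B-scans with known ground truth and optional multiplicative speckle) and a
cohort simulator with the published group-conditional index distributions,
so the whole pipeline is testable end to end.

## Worked example

```r
library(octmhri)

# a speckled phantom with known truth (MHRI 1.40, MLD 350 um)
ph <- generate_bscan(phantom_config(mld_um = 350, speckle_level = 0.05, seed = 42))
am <- auto_measure(ph$pixels, ph$lateral_scale_um)
am$indices
#> reflectivity indices: CRI-Max 1.047, CRI-Mean 1.034, PCRI-Min 0.729, PCRI-Mean 0.736, MHRI 1.436
am$mld_um
#> [1] 350

# a simulated 48-eye cohort and the full prognostic analysis
co  <- generate_cohort(cohort_config(seed = 7))
res <- analyze_cohort(co, seed = 7, boot_n = 2000)
res
#> cohort analysis: 48 eyes, 42 closed (87.5%)
#>   visual success (<= 0.3 logMAR): 20 of 42 closed (47.6%)
#>   anatomical ROC, MHRI: AUC 1.000, cutoff 1.82 (J = 1.00)
#>   visual ROC, MHRI: AUC 0.834, cutoff 1.45 (J = 0.67)
#>   inter-rater MHRI: ICC 0.988, Bland-Altman bias -0.005829
```

The measured MHRI (1.436) sits within 3% of the phantom's programmed 1.40
despite 5% multiplicative speckle; on a noise-free phantom the recovery is
exact. In the cohort analysis, the anatomical ROC uses all 48 eyes while the
visual-success ROC and the acuity regression are restricted to the 42
anatomically closed eyes; MHRI is a higher-in-failure score, so the reported
rule predicts success when the score falls *below* the cutoff.

A thin CLI wraps the same functions
(`system.file("cli", "octmhri", package = "octmhri")`):

```sh
octmhri simulate-images --n 5 --outdir phantoms --seed 1
octmhri simulate-cohort --out cohort.csv --seed 1
octmhri measure --images 'phantoms/*.png' --out indices.csv
octmhri analyze --cohort cohort.csv --outdir report --seed 1
```

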