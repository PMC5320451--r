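Package: metabpanel
Title: Circadian-Aligned Targeted Metabolomics Screening and Biomarker
    Panel Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of targeted plasma metabolomics panels
    sampled around the clock in a two-genotype cohort design. Implements
    LOD/LLOQ/ULOQ and QC2-repeatability exclusion rules with QC2-based
    between-plate normalization, circadian phase alignment to each
    animal's dim-light melatonin onset (25 percent threshold method),
    per-metabolite two-way sequential-sum-of-squares ANOVA screening
    with Benjamini-Hochberg false discovery rate control, urea- and
    nitric-oxide-cycle concentration ratios, and a biomarker panel
    builder that pre-filters markers by FDR, a subject-level permutation
    AUC test and relative concentration difference, then grows logistic
    panels by forward selection under leave-one-subject-out
    cross-validation with ROC operating-point reporting. A synthetic
    cohort generator with cosinor circadian structure and lognormal
    noise makes every stage testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
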