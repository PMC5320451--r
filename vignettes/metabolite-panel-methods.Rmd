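---
title: "Methods: circadian-aligned metabolomics screening and panel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian-aligned metabolomics screening and panel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabpanel)
```

## The problem this package addresses

Presymptomatic Huntington's disease is accompanied by metabolic
dysregulation long before motor signs appear. A targeted LC/MS plasma
panel (up to 183 metabolites across amino acids, biogenic amines,
acylcarnitines, glycerophospholipids and sphingolipids) measured in
around-the-clock samples from a transgenic sheep model gives a
repeated-measures, two-genotype design: 10 control and 14 HD rams, each
sampled every two hours over a 25 h window (15:00 to 15:00 the next
day, so the 15:00 clock time occurs twice). Because plasma metabolites
are strongly circadian, each animal's samples are phase-referenced to
its own dim-light melatonin onset (DLMO) rather than to clock time.

`metabpanel` implements that analysis end to end: assay-level QC
exclusion and between-plate normalization, DLMO estimation and phase
alignment, per-metabolite two-way ANOVA screening with
Benjamini-Hochberg FDR, urea-/NO-cycle concentration ratios, and a
biomarker-panel builder (marker pre-filtering followed by
forward-stepwise logistic modelling under leave-one-sheep-out
cross-validation, LOSOCV). A synthetic-cohort generator reproduces the
statistical structure of the design so that every stage is testable
without access to raw study data, which were never deposited.

## QC exclusion and QC2 normalization

A metabolite is excluded when more than 25% of its study measurements
are out of range — strictly below the LOD, at/above the LOD but below
the LLOQ, or strictly above the ULOQ, pooled into one fraction — or
when the coefficient of variation of its QC2 repeats exceeds 30%, or
when its mean blank-well value exceeds the LOD. Conventions worth
making explicit:

* Boundaries are strict, mirroring the assay's own notation
  (`< LOD`, `> ULOQ`); a value exactly at the LOD is treated as
  quantifiable-but-below-LLOQ.
* The 25% rule pools the three out-of-range categories. A per-category
  reading is also defensible; pooling is the stricter and simpler
  convention and is the one implemented.
* "Blank out of range" is not given a formula by kit software
  descriptions; we implement the conventional reading, mean blank
  value above the LOD.
* The out-of-range fraction is computed over study samples only — QC
  and blank wells are controls, not observations — and missing cells
  count toward neither numerator nor denominator.
* Rules are evaluated in a fixed order (out-of-range fraction, QC2 CV,
  blank) and the first violated rule is recorded as the reason.

Between-plate normalization uses the QC2 repeats (4 per plate, 5
plates): for each metabolite the global target is the **median** of
the per-plate QC2 means — robust to one aberrant plate — and every
measurement on a plate is scaled by `target / plate QC2 mean`. The
operation is idempotent and leaves missing cells missing.

## DLMO estimation and phase alignment

Melatonin onset is estimated by the 25%-threshold method: the
threshold is 25% of the animal's **own** observed nocturnal peak (not
a fixed pg/ml value, not a fitted curve), and DLMO is the first upward
crossing, located by linear interpolation between the bracketing
hourly samples. Missing assay points are skipped. Profiles that never
exceed the threshold, or begin above it with no preceding
sub-threshold sample, are reported as "onset not identifiable" rather
than guessed.

Alignment subtracts each animal's DLMO from its unwrapped sample times
(unwrapping adds 24 h at the midnight wrap so the repeated 15:00 time
point lands 24 h after the first). Cross-animal summaries snap offsets
to 2 h bins, matching the sampling grid.

## Per-metabolite screening

For each metabolite a linear model is fitted to genotype, time of day
(categorical, 13 levels) and animal, with the genotype-by-time
interaction, and the three terms are tested by two-way ANOVA with
sequential (type-I) sums of squares in the order genotype, time,
animal, genotype x time. Animal is a fixed factor nested in genotype;
its indicator columns span the genotype contrast, so genotype must be
entered first and the aliased animal columns are dropped. F statistics
use the residual mean square. Rows with missing concentrations are
dropped. P-values for each term are adjusted across the panel with
Benjamini-Hochberg FDR, and a metabolite is called significant at
FDR < 0.05 (strict).

**A limitation stated plainly:** this model — the standard fixed-effect
"animal as covariate" screen for this design — tests the sheep-level
genotype contrast against the *within*-animal residual. When real
between-animal variance is present, the expected genotype mean square
under the null is inflated by roughly `k * sigma_b^2` (k samples per
animal), so the screen over-states significance; on synthetic
null cohorts with a realistic between-animal variance share it flags
far more than 5% of metabolites. This is why panel construction does
**not** trust the screen alone: the marker pre-filter requires, in
addition, a sheep-level permutation AUC test, which is valid under
exactly the exchangeability the design gives (animals, not samples,
are the experimental units). A mixed model would be the alternative
screen, but is deliberately out of scope: the package reproduces the
published analysis pipeline, and documents its behaviour, rather than
substituting a different one.

Direction of change is read from the stored group means (24 h pooled
mean ± SEM per genotype). Exact ties at stored precision are counted
as ties, never silently assigned a direction — at two printed decimals
several low-abundance acylcarnitines tie even though finer precision
would break them. Whether SEMs should pool all samples or first
average within animal is not decidable from the published table;
pooled is the default and the sheep-level alternative is an option
(`group_means_sem(..., by = "sheep")`).

Urea-/NO-cycle activity is summarized by the concentration ratios
Cit/Arg (nitric oxide synthase), Cit/Orn (ornithine
carbamoylphosphate transferase) and Orn/Arg (arginase), computed per
sample and fed through the same ANOVA machinery as any metabolite.

## Panel building

Markers enter the candidate pool only if all three hold:

1. genotype FDR < 0.05 in the screen;
2. sheep-level permutation AUC p < 0.05: the observed statistic is the
   non-cross-validated single-marker AUC with orientation
   `max(AUC, 1 - AUC)`; the null permutes genotype labels over
   *animals* (all 13 samples of a sheep move together), with the
   add-one Monte-Carlo estimator `p = (1 + #{perm >= obs}) / (1 + B)`,
   B = 10,000 by default;
3. relative group-mean difference above 5%.

Sample-level permutation would be anti-conservative (within-animal
samples are not exchangeable across animals); sheep-level permutation
is the exchangeability the design actually supports.

Logistic panels are then grown forward: step 1 takes the candidate
with the highest pooled LOSOCV AUC; each later step adds the candidate
with the largest strictly positive LOSOCV AUC gain; the search stops
at no gain or at the size cap. Features are natural-log concentrations;
missing values are imputed with the per-marker mean of the *training*
fold (raw scale, before the log), and non-positive values are floored
at half the training fold's smallest positive value. Time never enters
the feature set, so a deployed panel needs a single sample at any
time of day. Ties in AUC gain are broken by smaller genotype FDR, then
alphabetically, making builds deterministic. The logistic fit is
iteratively reweighted least squares (convergence when the largest
coefficient change is below 1e-8, at most 100 iterations); on detected
separation the fit is repeated with a fixed ridge penalty of 1e-6 on
the non-intercept terms and flagged.

Reported operating points: ROC curve of the pooled cross-validated
predictions; maximum sensitivity among thresholds achieving at least
the target specificity (default 90%), without interpolation; AUC per
2 h phase bin (bins that lose a class report NA, never silently
disappear); and a sheep-level classification thresholding each
animal's median cross-validated probability.

**Pooled-LOSOCV pessimism.** Pooling predictions across
leave-one-animal-out folds makes the null distribution of the AUC sit
*below* 0.5: the training prevalence differs according to the held-out
animal's class (13/10 vs 14/9 here), shifting each fold's intercept
against the held-out class. With no signal this intercept gap
dominates and the pooled AUC averages ≈ 0.3 at this design size; with
strong signal the effect is small but still conservative. The
published single-marker cross-validated AUC for citrulline (0.664,
far below what its group separation implies) is consistent with the
same pessimism. We keep the estimator as described rather than
recentring folds, and note that it never flatters a null panel —
selection by this criterion is biased against, not toward,
overfitting.

**Forward selection recovers discrimination, not identity.** Once the
cross-validated AUC saturates, no candidate shows a strictly positive
gain and the search stops, so true-but-redundant markers are
interchangeable with each other (and occasionally with null
lookalikes that survive the permutation filter at rate alpha). On
synthetic cohorts seeded with the eight published panel markers the
builder reliably reaches cross-validated AUC above 0.9, but typically
recovers five to seven of the eight seeded identities, not all eight.
Users should read a selected panel as *one* maximiser of
cross-validated discrimination, not as the unique biological signal
set.

## The synthetic cohort generator

The generator emulates the study conditions: 10 control + 14 HD sheep,
13 two-hourly samples each (15:00–15:00), a 130-metabolite panel in 6
classes, per-sheep DLMO ~ Normal(21.0 h, 0.9 h), < 1.2% missingness,
LOD censoring (values below LOD reported at LOD/2), 5 plates with 4
QC2 wells and 2 blanks each, and multiplicative lognormal plate bias
(sigma 0.05). Each study value is

```
group_mean x sheep_factor x (1 + A cos(2 pi (t - DLMO - peak)/24))
           x residual x plate_bias
```

with lognormal sheep and residual factors of unit mean. Choices and
their reasons:

* **Lognormal multiplicative noise** — concentrations are positive and
  right-skewed, and the pipeline's own log transform implies
  multiplicative structure.
* **Totals calibrated to the published SEMs** — per-metabolite total CV
  is `sem x sqrt(130) / mean` under the pooled-sample reading
  (floor 0.05; metabolites whose SEM prints as 0.00 fall back to a
  typical 0.25).
* **Between/within split** — one eighth of the total variance is
  placed between animals (`cv_b = cv_tot / sqrt(8)`). The emulated
  protocol deliberately minimizes between-animal heterogeneity
  (same-age, same-sex, diet-matched flock under a constant dim-light
  routine), leaving circadian and assay variation within animals as
  the dominant components; the split also makes the weak published
  panel markers detectable at the sheep level, consistent with the
  fact that the published pipeline did detect them.
* **Rhythms** — metabolites with published time-of-day FDR < 0.05 get
  relative cosinor amplitude 0.15, others 0.02, with deterministically
  staggered peak offsets; amplitudes are phased to each animal's own
  DLMO, so phase alignment genuinely matters.
* **Effects** — the default preset seeds group-mean differences for
  the eight published panel markers only (taken from the published
  group means); `effects = "none"` gives a global-null cohort. Truth
  flags, true DLMOs and plate factors are returned so recovery can be
  scored without re-derivation.
* **Melatonin** — piecewise-linear onset positioned so the exact
  25%-of-peak crossing falls at the true DLMO, nocturnal plateau
  (~100 pg/ml, lognormal across animals), morning offset, 10%
  proportional assay noise by default and a 3.9 pg/ml detection floor.
  Noiseless profiles are recovered to < 0.1 h (interpolation error
  only); at 10% noise ≥ 95% of animals are recovered within 0.5 h.
* **AR(1) within-animal autocorrelation is not modelled** (the
  residuals are independent given the sheep factor and rhythm), and
  metabolites are conditionally independent given the shared sheep and
  plate factors — real panels have correlated families (e.g. SM
  species), so synthetic recovery rates likely overstate the
  independence of evidence across markers. Passing tests on this
  generator show the machinery is correct under its stated model, not
  that real data meet that model.

The kit fixture extends the panel to 183 candidates, 53 of which are
constructed to violate exactly one exclusion rule each (30 with > 25%
of study values below their LOD, enforced by placing each violator's
LOD just above its own 30th-percentile value; 18 with QC2 deviations
of ±80% around nominal, CV 0.8 with plate means untouched; 5 with
blank wells at three times the LOD), so default thresholds retain
exactly the 130-metabolite panel.

## Numerical conventions

* AUC is the midrank Mann-Whitney statistic (ties count half); the
  permutation null is computed from per-sheep rank sums, algebraically
  identical to the pairwise definition.
* BH adjustment is the step-up `q_(k) = min_{j>=k} p_(j) m / j`,
  capped at 1, via `stats::p.adjust`.
* Ward clustering of the heat-map profiles (per-genotype, per-bin
  means, z-scored per metabolite so shape rather than abundance
  drives the tree — absolute levels span four orders of magnitude
  across classes) uses Euclidean distance with `ward.D2` linkage;
  raw profiles are available behind `standardize = FALSE`.
* All simulation entry points take a mandatory integer seed and save
  and restore the caller's RNG state; identical seeds give
  bit-identical cohorts, pipelines and panels.

## Problem sizes used by the test suite

The suite checks oracle equivalence (AUC vs pair counting, BH vs the
literal step-up, ANOVA vs an SVD projection oracle) on 1,000 / 1,000 /
50 random cases at 1e-10; null calibration on 200 zero-effect cohorts;
panel behaviour on 50 seeded cohorts with 1,000 permutations in the
pre-filter; and DLMO recovery on 192 noisy profiles. These sizes give
Monte-Carlo error comfortably below the asserted margins while keeping
a full run to a few minutes.
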