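---
title: "Methods: lipidomic risk scoring for subclinical coronary artery disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipidomic risk scoring for subclinical coronary artery disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidcad)
library(dplyr)
```

## The problem

Plasma lipidomics quantifies hundreds of lipid species per person. The
question this package addresses is whether those species carry information
about *subclinical* coronary artery disease — calcified plaque burden
measured by CT before any clinical event — beyond what the traditional
Framingham risk factors already capture, and in whom. The pipeline goes
from a cohort with batch-structured lipid measurements to:

1. sCAD labels from coronary artery calcium (CAC),
2. batch-effect removal with RUV-III using pseudo-replicates, frozen and
   transferred to a validation cohort,
3. per-species logistic associations with FDR control,
4. a ridge-penalised lipid risk score (LRS) compared against a Framingham
   risk score (FRS) model,
5. per-sample classifiability and discovery of the covariate that modifies
   the lipidome–disease relationship,
6. paired ROC evaluation (DeLong) and per-individual model overlap.

Because real cohorts of this kind are privacy-restricted, the package
includes a first-class synthetic cohort generator with planted ground
truth; every stage is tested against that truth.

## Labels: calcium percentiles

Statin users are excluded (statins alter the lipidome). Among the
remainder, zero CAC defines sCAD−, and CAC at or above the 50th percentile
for the participant's sex and age decade defines sCAD+. The percentile
reference is the within-cohort empirical distribution of positive CAC among
non-statin participants; decade bins are the convention of CAC reference
tables. Participants with positive CAC below their stratum median are
excluded as intermediate — the arithmetic of the published cohort sizes
implies such a group, though the handling is our inference. The boundary is
inclusive (CAC equal to the median is sCAD+). A stratum with fewer than two
positive-CAC members falls back to the sex-only stratum with a warning.
Percentile labelling is invariant to monotone rescaling of CAC within
strata, which the tests assert.

The discovery/validation split follows recruitment order: the first
ceiling(fraction × n) analytical samples (default fraction 394/580) form
the discovery cohort. Note a consequence faithful to the real design:
because batches are storage blocks of consecutive recruits, the validation
cohort is concentrated in the late batches.

## Normalization: RUV-III with pseudo-replicates

True replicates are unavailable, so clinically homogeneous samples stand in
for them: study samples are clustered (Ward linkage, Euclidean distance on
standardized age, sex, BMI, hypertension, current smoking, diabetes,
hypercholesterolemia) into 80 groups, and each QC role (pooled QC,
technical QC, blank, NIST1950 reference plasma) forms one additional group.
Negative-control species are those associated with batch (one-way ANOVA,
BH-FDR < 0.05) but not with age or sex (raw p > 0.05 in both) — the
original analysis states the criteria without thresholds; these are ours.

With the column-centered matrix `Y`, replicate matrix `M` and controls `c`:

1. `Y0 = Y - group means` (the replicate-residual space),
2. `U` = top-k left singular vectors of `Y0`,
3. `alpha = U' Y` (k × p unwanted-variation coefficients),
4. `W = Y_c alpha_c' (alpha_c alpha_c')^{-1}` (per-sample scores from the
   controls),
5. adjusted data `= Y - W alpha + feature means`.

For a validation cohort the model is frozen: `alpha` and the control set
are fixed, only `W` is re-estimated from the new samples' control species.
The new cohort's own feature means are used for centering and restoration
(the alternative, discovery means, is available behind a flag); applying
the frozen model back to the discovery data reproduces the fit output
exactly, which the tests assert at 1e-8.

Two numerical properties worth knowing:

* at most `k` singular directions are removed, but because `W` is a
  regression estimate from the controls, a small amount of extra noise
  energy is removed too — on data with *no* batch structure the adjustment
  changes the matrix by a few percent in Frobenius norm, not zero;
* **choosing k matters.** `k` should approximate the true rank of the
  unwanted variation. For a simulated design with B batches that rank is
  B − 1. Setting k well above it makes the extra factors chase the largest
  remaining directions, and when a biological signal (for instance a
  concentrated class effect) rivals the noise floor of the replicate
  residuals, part of it is absorbed into the removed component. We measured
  roughly half the planted class contrast disappearing when k = 8 was
  applied to rank-2 batch structure. The pipeline default remains k = 8
  (the published analysis value, appropriate for real data whose technical
  variation is rich), but simulation studies in this package use k = B.

## Associations

Each species gets a maximum-likelihood logistic regression of sCAD class on
its log-concentration: univariate, and adjusted for BMI, hypertension,
current smoking, diabetes and hypercholesterolemia (age/sex adjustment is
available behind a flag; the published covariate list does not include
them). Combined discovery + validation data is the default input, as in
the source analysis. Odds ratios are per unit log-concentration with Wald
95% intervals — the standard for forest plots; profile-likelihood
intervals are deliberately not used. (Quasi-)separated fits are flagged,
their p-values set missing and excluded from the BH adjustment. The forest
export keeps species with adjusted-model BH-FDR < 0.05, ordered by
adjusted p.

## Risk models

The FRS is the published sex-specific general cardiovascular risk function
(log-transformed age, total and HDL cholesterol in mg/dL — converted from
mmol/L internally — and systolic blood pressure with separate treated
coefficients, plus smoking and diabetes). The cohort schema has no
blood-pressure-treatment column, so the hypertension flag stands in for
treatment. The FRS *model* is a one-covariate unpenalised logistic fit, so
its ROC is that of the raw score.

The LRS is ridge-penalised logistic regression over selected species,
solved by IRLS to a gradient max-norm of 1e-6, intercept unpenalised,
features standardized internally (the transform is stored). For p > n the
weighted normal equations are solved in the dual. At penalty → 0 the fit
matches the unpenalised MLE (tested at 1e-3 against `glm`, and
cross-checked against `glmnet` at matched penalty).

Hyperparameters and features come from a bootstrap on the discovery cohort
only (the interface refuses validation rows): per resample, full-species
ridge fits at each candidate penalty; species ranked by informativity =
mean absolute standardized coefficient across resamples (the source
analysis names the idea but not the formula; a univariate ranking would be
a reasonable alternative); each (penalty, n-features) grid point scored by
mean out-of-bag AUC of an in-bag refit on the top species. "alpha" in the
source's description is read as the L2 penalty strength (the model is named
ridge), tuned on a log grid 1e-3..1e3 by default. A fixed
penalty/n-features configuration is treated as a one-point grid, so the
bootstrap ranking is used either way. Binary calls use the Youden-optimal
threshold on training risk — the source never states its rule; a 0.5
threshold is available.

## Classifiability and the modifying variable

The individual classifiability score (ICS) of a sample is the proportion
of repeats of a stratified 5-fold cross-validation (default 50 repeats) in
which the ridge model fitted on the other folds classifies it correctly.
Scores are multiples of 1/r; fold draws are seeded per repeat and samples
are processed in canonical `sample_id` order, so the result is invariant
to row order. Inside the CV, calls use the training-fold Youden threshold
by default at the function level; the pipeline default is the posterior-0.5
rule, which is what the cross-validation tooling used by the source
analysis does natively. The choice matters in corner cases: heavy ridge
shrinkage compresses probabilities toward the class prevalence, which can
push every posterior below 0.5 and make the 0.5 rule call everything
negative even when the ranking is informative.

The modifying variable is found by one linear regression per candidate
(BMI, hypertension, hypercholesterolemia): `ics ~ candidate + age + sex`;
the candidate with the smallest coefficient p wins. The cohort is then
stratified at BMI 25 kg/m² (boundary inclusive to the high group), the
conventional overweight cut.

One calibration subtlety: under a completely uninformative lipidome the
expected ICS is the majority-class rate, not 0.5 — cross-validated accuracy
only centres on one half when the classes are balanced. Null-calibration
simulations in the test suite therefore balance the classes by
construction.

This scan is a deliberately simple instrument, and simulations show it has
modest power: the gradient lives mostly in the samples whose classification
actually changes between strata, and per-sample ICS is a noisy binomial
average. In the package's acceptance simulations a cohort of 1500
participants is used for this stage so that a strong planted
BMI-by-lipidome interaction is detected reliably.

## Evaluation

AUC is the Mann–Whitney concordance with half-credit for ties (midranks);
the O(n²) pair-counting definition is the test oracle. DeLong's test uses
midrank placement values and their covariance; identical scores give
z = 0, p = 1 by convention. Sub-cohort evaluation computes predictions once
on the full validation set, then partitions them by stratum; single-class
cells are flagged rather than computed. The model-overlap table restricts
to the truly sCAD+ validation samples and cross-tabulates which model
called them correctly, with percentages on the sCAD+ denominator.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
mass spectrometry. Defaults mirror a contemporary cardiology recruitment
cohort: 994 participants, age 61 (SD 12), 45% female, BMI 26.9 (SD 4.8),
hypertension 39%, diabetes 8.7%, hypercholesterolemia 59%, smoking 6.4%,
one third on statins; 683 species with baselines drawn once from
N(log 10, 1); additive per-batch offsets (SD 0.5 by default) on the log
scale, with batches assigned in contiguous recruitment blocks (their number
and size are free parameters — the source does not state them; default 3).
Residual noise SD is 0.3 per species, technical-replicate noise 0.05;
blanks sit 5 log-units below baseline. QC rows carry the batch offset plus
technical noise — required for batch correction to be observable in them.

Coronary calcium is zero-inflated log-normal. The zero mass shrinks with
age and is larger for females; the positive part grows with age and male
sex. Most covariate dependence flows through a standardized
traditional-risk-factor index whose strength is BMI-stratum-specific, so
how well Framingham covariates predict the resulting labels is a per-
stratum configuration choice (default link 0.6 in both strata, giving the
FRS a validation AUC around 0.7).

The class effect is planted on a sparse species set as a symmetric
conditional shift: within a BMI stratum, sCAD+ sits at +effect/2 and sCAD−
at −effect/2 noise-SDs, so the between-class contrast equals
effect × noise_sd and the log-odds recovered by a logistic fit on the
standardized species equals the configured effect. The BMI modification is
a two-level switch at 25 kg/m², which is exactly what the downstream
stratification is meant to detect; no continuous interaction is simulated.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: correlated lipid classes (species are
independent given the factors), skewed or heteroscedastic concentration
noise, batch effects that drift within a batch, missingness, or covariate
measurement error. Passing tests demonstrate the machinery is correct and
calibrated, not that real plasma lipidomes behave this way.

## Problem sizes used in the test-suite simulations

Unit tests run on cohorts of 40–500 participants and 8–400 species. The
acceptance simulations use: 600 participants × 683 species for the
batch-removal bound (k = 8, 80 clusters, 30 PCs); ~2000 analytical samples
× 200 species for association recovery; and twenty pipeline replicates of
1500 participants × 683 species for the direction check, with k = 3 (the
true unwanted rank of three simulated batches), a fixed penalty of 10 and
the top 200 species, 25 × 5 cross-validation, and 10 bootstrap resamples
for the informativity ranking. These sizes are the package's choice of a
desk-scale study; the published cohort constants (k = 8, 80 clusters, top
200, 50 × 5 CV, BMI 25, 5% FDR) remain the pipeline defaults.

## Known limitations

* The percentile reference for sCAD labels is internal to the cohort;
  external CAC charts are out of scope.
* The informativity ranking struggles when the class signal is
  concentrated in a small subgroup: single species rarely clear the
  max-of-nulls bar, and the score then relies on the signal being spread
  across many coefficients.
* The ICS-based modifier scan has modest power at a few hundred samples;
  treat its winner as a hypothesis, not a verdict.
* Ridge probabilities are not calibrated; binary calls depend on the
  threshold rule, and the model-overlap counts inherit that dependence.
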