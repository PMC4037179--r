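---
title: "Methods: biomarker panels and the Tclass ensemble workflow"
author: "MetaboPanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker panels and the Tclass ensemble workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboPanel)
```

## The analysis problem

A GC/MS metabonomics study of major depressive disorder (MDD) compares the
plasma metabolite profiles of three groups — healthy controls, MDD patients
with early-life-stress history (ELS/MDD) and MDD patients without it
(non-ELS/MDD) — and asks two questions: which metabolites differ between
groups, and how small a metabolite panel suffices to classify a new sample.
MetaboPanel implements the complete statistical workflow downstream of peak
alignment: normalization, multivariate profiling, panel construction, and
ensemble classification with a hierarchical subtype caller.

The central data object is a `MetaboCohort`, a `SummarizedExperiment`
holding a samples × metabolites matrix of relative peak areas (RPA) with
per-sample group labels. Two-group comparisons name a `(control, case)`
pair; `MDD_ALL` is accepted as a derived union of the two MDD subtypes and
is never stored as a sample label.

## Normalization

Raw peak intensities are converted to RPA per sample: every intensity is
divided by that sample's internal-standard (ribitol) peak intensity, which
is thereby set to 1, and the standard's column is dropped. Because each
sample is scaled by its own standard, the transform is equivariant under
per-sample rescaling — the property an internal standard exists to provide.
Upstream steps (signal-to-noise filtering, deconvolution, library matching,
retention alignment) are instrument-software territory and out of scope;
the pipeline assumes its input already passed them.

## PLS-DA, VIP and differential metabolites

For a two-group comparison the metabolite matrix is column-wise
mean-centered and unit-variance scaled (UV scaling is the metabonomics
default and makes VIP independent of measurement units), and the class
indicator (0/1, centered) is regressed on it by NIPALS partial least
squares with sequential deflation. Choices worth stating:

- **Components (A).** Default 2, configurable. Two components are what a
  2-D score plot displays, and with a univariate response additional
  components add little; the VIP definition aggregates over however many
  are fitted. When residuals are numerically exhausted the model returns
  fewer components with a `short_rank` flag and a warning.
- **Convergence.** With a single response column each NIPALS component is
  available in closed form; the iteration (initialized from the response,
  tolerance 1e-10 on the weight vector, cap 500) is retained for symmetry
  and determinism. There is no randomness anywhere in the fit.
- **Encoding.** A single binary response column, not a two-column dummy
  block — the workflow only ever compares two groups at a time; the four
  published comparisons are fit as four separate models.

Variable importance in projection is

$$\mathrm{VIP}_j = \sqrt{\,p \cdot \frac{\sum_a SSY_a\,(w_{ja}/\lVert w_a\rVert)^2}{\sum_a SSY_a}}$$

with $SSY_a$ the response sum of squares explained by component $a$, so
$\sum_j \mathrm{VIP}_j^2 = p$ always (a tested invariant). Metabolites with
VIP **strictly** above 1.0 are the differential metabolites; ties at the
threshold are excluded, matching the strict inequality of the selection
rule, and the panel is ordered by descending VIP.

## Differential panels: nested logistic models under ROC AUC

The VIP-ranked differential panel is evaluated as nested prefixes: for
k = 1…k_max (default 9) a logistic regression on the top-k metabolites is
fitted and scored by the ROC AUC of its linear predictor. Two numerical
choices:

- **Ridge penalty.** The published panels reach AUC 1, i.e. complete
  separation, where the unpenalized logistic MLE diverges. A small L2
  penalty (1e-4 on slopes, none on the intercept, IRLS with tolerance
  1e-8) keeps coefficients finite; since the penalty acts monotonically on
  the scores it cannot change their ranking, so the AUC is unaffected.
- **AUC convention.** AUC is the Mann–Whitney concordance probability with
  ties counted half, computed with the score direction fixed (higher score
  = case), so inverted predictors score below 0.5 rather than being
  auto-flipped. The implementation is cross-checked in the tests against an
  exhaustive pairwise-concordance oracle.

`bestPanel()` takes the highest AUC and, among ties, the smallest panel —
fewer assays at equal discrimination.

## The Tclass system

Base learners are deliberately simple two-class models:

- **Fisher linear discriminant classification functions.** Per-class affine
  scores $g_k(x) = \mu_k^\top \Sigma^{-1}x - \tfrac12 \mu_k^\top
  \Sigma^{-1}\mu_k + \ln \pi_k$ with pooled within-class covariance and
  equal priors (the groups are near-balanced by design; with equal priors
  the $\ln \pi_k$ terms cancel). The pooled covariance is ridge-stabilized
  as $\Sigma + \lambda\,\mathrm{tr}(\Sigma)/p\,I$ with $\lambda$ escalating
  from 1e-6 by decades to 1e-2 before erroring — forward selection can
  propose collinear panels, and a fold can leave a class with a single
  sample. This per-class-score form is exactly the printed classifier-pair
  shape (`LinearClassifierPair`), so the published example model is
  evaluable by the same code path.
- **Gaussian naive Bayes.** Per-class per-feature mean and variance with a
  variance floor of 1e-9 × the feature's pooled variance (absolute floor
  1e-12), equal priors, classification by the larger log-posterior.

All score ties resolve to the control label — conservative toward non-case
calls, consistent with the strictly-greater vote rule below.

**Forward selection** greedily adds the feature maximizing LOOCV accuracy of
the augmented panel (ties break toward the earlier catalog/column
position), stopping at `k_max` or when accuracy reaches 1; the chosen panel
is the smallest prefix attaining the traced maximum. Selection is evaluated
on the full data set — selection outside the cross-validation folds — which
is optimistically biased; the stability index below is precisely the
workflow's own resampling check of that optimism, and the two are always
reported together.

**Stability index.** The cohort is partitioned 1000 times into stratified
random 85% train / 15% test parts (per-class test size
max(1, round(0.15 n)); whether the original analysis stratified is
unstated, but stratification is the only way 15% test parts of 23-sample
classes reliably contain both classes). The index is the mean of the 1000
test accuracies. Splits are drawn on a canonical ordering of samples by id,
making the result invariant to row order, and the whole stream is governed
by one seed.

**Ensemble.** The 1000 classifiers trained on those same 1000 training sets
form the majority-vote ensemble — same seed, same splits, so the stability
index is exactly the resampling estimate of the ensemble members'
generalization. A sample's vote fraction P is the share of classifiers
voting for the case class; the case is called iff P > 0.5 strictly
(exactly 500 of 1000 votes is a control call).

**Hierarchical prediction.** A sample is first screened by the
healthy-vs-MDD ensemble. If positive, a subtype is called only when two
independent ensembles agree: ELS/MDD requires both healthy-vs-ELS and
ELS-vs-non-ELS to vote ELS; non-ELS/MDD symmetrically. Any other pattern
after a positive screen — including all-healthy component votes — is
reported as `INDETERMINATE` with all four vote fractions attached, rather
than forced into a subtype: the agreement rule defines the two positive
patterns and is silent on the rest, so the remainder is surfaced, not
resolved.

## The synthetic cohort generator

No per-sample data accompany the study, so the generator draws cohorts from
the published summary statistics: each metabolite is independent Gaussian
per group with the catalog's printed (mean, SD), at the study's group sizes
(25/23/23) by default. Three modes: `table2` (the study conditions), `null`
(all groups from the healthy parameters — a chance-level calibration
cohort) and `separated` (means planted 10 pooled SDs apart — a sanity-check
cohort where every stage should succeed).

- **Untruncated Gaussians by default.** Several metabolites have SD > mean
  (sorbitol in healthy controls: 0.0175 ± 0.0335); truncating at zero would
  bias the realized moments far from the printed ones, so the default
  draws faithfully reproduce mean and SD and occasionally go negative. The
  `nonneg` mode redraws negatives (rejection at 0) and documents the
  resulting upward moment bias; RPA data produced by actual normalization
  are non-negative by construction.
- **Independence.** Only marginal moments are published, so metabolites are
  generated independently. Real plasma metabolites are correlated
  (glucose/glucopyranose, the fatty acids); synthetic cohorts therefore
  overstate the information content of multi-metabolite panels relative to
  real data. Passing calibration tests shows the machinery is correct and
  well-calibrated, not that the published accuracies transfer to new
  patients.
- **The pooled-MDD column is never sampled.** `MDD_ALL` cohorts are formed
  by pooling generated ELS/MDD and non-ELS/MDD samples, keeping the
  three-group structure coherent; the printed MDD column stays in the
  catalog for reference.
- The mannose non-ELS entry (0.0414 ± 0.2214) has an SD about five times
  the other groups'; it is stored and used verbatim.

## Fixtures and name reconciliation

The packaged catalog transcribes the published 35-metabolite table:
retention times (aspartic acid's compound "16.233+17.767" label is kept as
display text with 16.233 as the sort key), per-group moments, and the VIP
annotations of the four comparisons (cardinalities 15/16/12/13, verified in
the tests). The published panel listing spells one member "glyceic acid";
the catalog's closest entry, glyceric acid, is the only candidate that
makes the printed nine-metabolite panel evaluable against the catalog, so
the name is canonicalized to "Glyceric acid" (likewise "6-deoxidation
mannopyrannose" → "6-deoxy-mannopyrannose"). The printed classifier pair is
introduced as the naive-Bayes winner but displayed as linear discriminant
functions; it is stored and evaluated in its displayed (affine-pair) form.

## Problem sizes and runtime choices

The test suite and acceptance checks run the study-sized design (25/23/23)
throughout. Forward selection in the end-to-end checks explores up to
k_max = 5 features — on synthetic cohorts LOOCV accuracy saturates at 1
within two or three steps, so deeper searches only re-confirm the stopping
rule. Stability analyses use the full 1000 splits wherever an index is
reported; smaller split counts (100–300) appear only in property tests
whose assertions are about invariance, not the index value. Moment-recovery
checks use 20 000 samples per group (4 standard errors across the 105
group × metabolite cells); the acceptance script uses 100 000 for the
single-column mean checks.

## Known limitations

- Marginal-moment simulation cannot reproduce the covariance structure of
  real plasma profiles; published headline accuracies (e.g. stability
  indices of the real feature panels) are not recoverable from summary
  statistics and are not claimed.
- PLS-DA component count, scaling, and the per-comparison model structure
  are unstated in the source analysis; the defaults here (A = 2, UV
  scaling, one model per comparison) are the field's conventions and are
  configurable.
- Forward selection inherits the optimism of selection-outside-the-folds;
  the stability index quantifies but does not remove it. No nested
  cross-validation variant is offered, deliberately — it would be a
  different procedure.
- Only Fisher and Gaussian naive Bayes base learners are provided; the
  learner interface accepts an injected training function, used in the
  tests and available for extension.
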