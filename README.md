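# MetaboPanel

Biomarker-panel discovery and ensemble diagnosis for GC/MS plasma
metabonomics.

Clinical diagnosis of major depressive disorder (MDD) — and of its subtypes
with and without early life stress (ELS) — still rests on symptom scales;
plasma metabolite profiles are a candidate laboratory readout. MetaboPanel
implements the full desk-side analysis that turns an aligned peak-intensity
table into diagnostic panels and prediction tools:

- **RPA normalization** — peak intensities divided by each sample's
  internal-standard (ribitol) intensity.
- **PLS-DA + VIP** — partial least squares discriminant analysis of a
  two-group comparison; metabolites with variable importance in projection
  VIP > 1 become *differential metabolites*. VIP is

  VIP_j = sqrt( p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a ),

  so the mean squared VIP is 1 and VIP > 1 marks above-average contributors.
- **Differential panels** — nested logistic-regression models over the
  VIP-ranked metabolites (top-1, top-2, …), each scored by ROC AUC
  (Mann–Whitney, ties half credit); the smallest panel with maximal AUC wins.
- **The Tclass system** — greedy forward feature selection with leave-one-out
  cross-validation (LOOCV) accuracy as the objective, over Fisher linear
  discriminant or Gaussian naive Bayes base learners; validation by the
  **stability index** (mean test accuracy over 1000 random stratified 85/15
  train/test splits); and a **majority-vote ensemble** of the 1000 per-split
  classifiers. A sample's vote fraction P (share of classifiers voting for
  the case class) calls the case iff P > 0.5 strictly.
- **Hierarchical prediction tool** — an MDD screen followed by a subtype call
  that requires two independent ensembles to agree (healthy-vs-subtype and
  ELS-vs-non-ELS); disagreement is surfaced as `INDETERMINATE`.
- **Reference fixtures** — the packaged 35-metabolite plasma catalog
  (retention times, per-group mean ± SD, VIP annotations for the four
  group comparisons), the eight published diagnostic panels, and the printed
  example classifier pair (per-class affine discriminant scores C/MDD).
- **Synthetic cohorts** — per-sample patient data were never deposited, so
  `generateCohort()` draws cohorts from the catalog's printed moments
  (modes: `table2`, `null`, `separated`), making every stage testable.

## Worked example

```r
library(MetaboPanel)

cohort <- generateCohort(seed = 1)       # 25 healthy / 23 ELS-MDD / 23 non-ELS-MDD
cmp <- c("HEALTHY", "NON_ELS_MDD")

## differential metabolites by PLS-DA VIP
fit <- fitPLSDA(cohort, cmp, n_components = 2)
panel <- selectDifferential(computeVIP(fit), cmp)
head(panelMetabolites(panel), 3)
#> [1] "Cholesterol"   "Linoleic acid" "Galactose"

## Tclass: forward selection + stability + ensemble
tc <- runTclass(cohort, cmp, learner = "naive_bayes", k_max = 5,
                n_splits = 1000, seed = 2)
tc$trace@steps
#>      metabolite k loocv_accuracy
#> 1   Cholesterol 1         0.9375
#> 2 Linoleic acid 2         1.0000
stabilityIndexValue(tc$stability)
#> [1] 0.986

## per-sample vote fractions
pr <- ensemblePredictTable(tc$ensemble, cohort)
tapply(pr$P, groupLabels(cohort)[pr$sample_id], mean)
#>     ELS_MDD     HEALTHY NON_ELS_MDD
#>   0.1489130   0.0014000   0.9956957
```

Cholesterol — the largest printed group difference — enters first and the
two-metabolite panel separates the synthetic groups completely in LOOCV;
the stability index (0.986) estimates out-of-sample accuracy, and the
ensemble's mean vote fraction is near 0 for healthy samples and near 1 for
the case group.

The printed example classifier can be evaluated directly:

```r
pm <- loadPrintedModel()
cat35 <- loadReferenceCatalog()
x <- setNames(cat35$healthy_mean[match(pm$classifier@feature_names, cat35$name)],
              pm$classifier@feature_names)
evaluateClassifierPair(pm$classifier, x)
#> $label
#> [1] "HEALTHY"
#> $control_score
#> [1] 192.9003
#> $case_score
#> [1] 185.4434
```

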