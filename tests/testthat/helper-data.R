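## Shared fixture builders (all data generated in code).

## Two-group cohort: one informative feature (means mu0/mu1, sd 1) plus
## `p_noise` standard-normal noise features.
makeTwoGroup <- function(n0 = 12, n1 = 12, mu0 = 0, mu1 = 0, sd = 1,
                         p_noise = 0, seed = 1,
                         groups = c("HEALTHY", "NON_ELS_MDD")) {
  withr::with_seed(seed, {
    x <- c(rnorm(n0, mu0, sd), rnorm(n1, mu1, sd))
    m <- cbind(M1 = x)
    if (p_noise > 0) {
      noise <- matrix(rnorm((n0 + n1) * p_noise), n0 + n1, p_noise)
      colnames(noise) <- paste0("N", seq_len(p_noise))
      m <- cbind(m, noise)
    }
    rownames(m) <- sprintf("s%02d", seq_len(n0 + n1))
    MetaboCohort(m, groups = rep(groups, c(n0, n1)))
  })
}

## Cohort from an explicit matrix, labels recycled over rows.
makeCohortFromMatrix <- function(m, groups) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("M", seq_len(ncol(m)))
  MetaboCohort(m, groups = groups)
}

## Independent AUC oracle: exhaustive pairwise concordance, ties half credit.
bruteForceAUC <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

## A degenerate one-feature "fisher" classifier that always votes `vote`.
constClassifier <- function(class_labels, vote, feature = "M1") {
  panel <- PanelDefinition(class_labels, "tclass", feature)
  delta <- if (vote == class_labels[2]) 1 else -1
  new("TrainedClassifier", learner = "fisher", class_labels = class_labels,
      panel = panel,
      parameters = new("LinearClassifierPair", class_labels = class_labels,
                       feature_names = feature,
                       control_intercept = 0, case_intercept = delta,
                       control_coefficients = 0, case_coefficients = 0))
}

## Ensemble casting a fixed number of case/control votes.
makeConstEnsemble <- function(comparison, n_case_votes, n_total = 10,
                              feature = "M1") {
  clfs <- c(replicate(n_case_votes,
                      constClassifier(comparison, comparison[2], feature),
                      simplify = FALSE),
            replicate(n_total - n_case_votes,
                      constClassifier(comparison, comparison[1], feature),
                      simplify = FALSE))
  new("EnsembleModel", classifiers = clfs,
      panel = PanelDefinition(comparison, "tclass", feature),
      class_labels = comparison, case_label = comparison[2],
      learner = "fisher", seed = 0L)
}

## Per-fold LOOCV oracle, independent of the package's internal loop: refits
## with the exported trainers on explicitly subset cohorts.
loocvOracle <- function(cohort, panel, comparison, learner) {
  m <- rpaMatrix(cohort)
  g <- groupLabels(cohort)
  keep <- g %in% c(comparison, if ("MDD_ALL" %in% comparison)
    c("ELS_MDD", "NON_ELS_MDD"))
  m <- m[keep, , drop = FALSE]; g <- g[keep]
  truth <- ifelse(g %in% c(comparison[2],
                           if (comparison[2] == "MDD_ALL")
                             c("ELS_MDD", "NON_ELS_MDD")),
                  comparison[2], comparison[1])
  train_fun <- if (learner == "fisher") trainFisher else trainNaiveBayes
  hits <- vapply(seq_len(nrow(m)), function(i) {
    sub <- MetaboCohort(m[-i, , drop = FALSE], groups = g[-i])
    clf <- train_fun(sub, panel, comparison)
    classifySample(clf, m[i, panelMetabolites(panel)])$label == truth[i]
  }, logical(1))
  mean(hits)
}
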