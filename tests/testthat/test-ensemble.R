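cmpHN <- c("HEALTHY", "NON_ELS_MDD")

test_that("stability index is the mean of its split accuracies", {
  co <- makeTwoGroup(n0 = 12, n1 = 12, mu0 = 0, mu1 = 1.5, seed = 2)
  panel <- PanelDefinition(cmpHN, "tclass", "M1")
  st <- stabilityIndex(co, panel, cmpHN, "fisher", n_splits = 50L, seed = 7L)
  expect_equal(stabilityIndexValue(st), mean(splitAccuracies(st)),
               tolerance = 1e-12)
  expect_length(splitAccuracies(st), 50L)
  expect_true(all(splitAccuracies(st) >= 0 & splitAccuracies(st) <= 1))
})

test_that("an injected always-correct learner scores index 1", {
  co <- makeTwoGroup(n0 = 10, n1 = 10, mu0 = 0, mu1 = 0, seed = 3)
  truth <- groupLabels(co)
  hook <- function(X, y01, class_labels) {
    function(newX) unname(truth[rownames(newX)])
  }
  panel <- PanelDefinition(cmpHN, "tclass", "M1")
  st <- stabilityIndex(co, panel, cmpHN, hook, n_splits = 40L, seed = 5L)
  expect_equal(stabilityIndexValue(st), 1.0)
})

test_that("stability is invariant to the row order of the table", {
  co <- makeTwoGroup(n0 = 10, n1 = 12, mu0 = 0, mu1 = 1, p_noise = 1,
                     seed = 4)
  panel <- PanelDefinition(cmpHN, "tclass", c("M1", "N1"))
  st1 <- stabilityIndex(co, panel, cmpHN, "fisher", n_splits = 60L,
                        seed = 11L)
  withr::with_seed(123, perm <- sample(22))
  co_perm <- MetaboCohort(rpaMatrix(co)[perm, ],
                          groups = unname(groupLabels(co)[perm]))
  st2 <- stabilityIndex(co_perm, panel, cmpHN, "fisher", n_splits = 60L,
                        seed = 11L)
  expect_equal(splitAccuracies(st2), splitAccuracies(st1))
})

test_that("stability errors when a class cannot be stratified", {
  m <- cbind(M1 = c(1, 2, 10, 11, 12, 13, 14, 15))
  co <- makeCohortFromMatrix(m, rep(cmpHN, c(2, 6)))
  panel <- PanelDefinition(cmpHN, "tclass", "M1")
  expect_error(stabilityIndex(co, panel, cmpHN, "fisher", n_splits = 5L),
               "too small")
})

test_that("null data sit at chance level; planted effects raise the index", {
  ## chance-level calibration: identical group distributions, n = 24/24
  co_null <- generateCohort("null",
                            n_per_group = c(HEALTHY = 24L, NON_ELS_MDD = 24L),
                            seed = 5L)
  panel <- PanelDefinition(cmpHN, "tclass",
                           c("Cholesterol", "Linoleic acid", "Glycine"))
  st <- stabilityIndex(co_null, panel, cmpHN, "fisher", n_splits = 300L,
                       seed = 5L)
  expect_gt(stabilityIndexValue(st), 0.35)
  expect_lt(stabilityIndexValue(st), 0.65)
  ## monotone calibration in effect size d over 20 seeds
  idx_by_d <- vapply(c(0, 1, 2, 4), function(d) {
    mean(vapply(1:20, function(seed) {
      co <- makeTwoGroup(n0 = 24, n1 = 24, mu0 = 0, mu1 = d, sd = 1,
                         seed = seed)
      stabilityIndexValue(
        stabilityIndex(co, PanelDefinition(cmpHN, "tclass", "M1"), cmpHN,
                       "fisher", n_splits = 100L, seed = seed))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(idx_by_d) >= 0))
  expect_lt(idx_by_d[1], 0.65)
  expect_gt(idx_by_d[4], 0.95)
})

test_that("ensembles reuse the stability split stream and are reproducible", {
  co <- makeTwoGroup(n0 = 12, n1 = 12, mu0 = 0, mu1 = 20, seed = 6)
  panel <- PanelDefinition(cmpHN, "tclass", "M1")
  ens1 <- buildEnsemble(co, panel, cmpHN, "fisher", n_splits = 10L,
                        seed = 21L)
  ens2 <- buildEnsemble(co, panel, cmpHN, "fisher", n_splits = 10L,
                        seed = 21L)
  expect_length(ens1@classifiers, 10L)
  expect_equal(ensembleToJSON(ens1), ensembleToJSON(ens2))
  ## every training sample of separated data is predicted with P = 1
  pr <- ensemblePredictTable(ens1, co)
  expect_equal(pr$P, as.numeric(groupLabels(co)[pr$sample_id] == cmpHN[2]))
})

test_that("the case call requires strictly more than half the votes", {
  ens <- makeConstEnsemble(cmpHN, n_case_votes = 600, n_total = 1000)
  pr <- ensemblePredict(ens, c(M1 = 0))
  expect_equal(voteFraction(pr), 0.6)
  expect_equal(predictedLabel(pr), "NON_ELS_MDD")
  ## exactly half: control (strict inequality)
  half <- ensemblePredict(makeConstEnsemble(cmpHN, 500, 1000), c(M1 = 0))
  expect_equal(voteFraction(half), 0.5)
  expect_equal(predictedLabel(half), "HEALTHY")
  none <- ensemblePredict(makeConstEnsemble(cmpHN, 0, 1000), c(M1 = 0))
  expect_equal(voteFraction(none), 0.0)
  expect_equal(predictedLabel(none), "HEALTHY")
})

test_that("prediction validates the feature vector against the panel", {
  ens <- makeConstEnsemble(cmpHN, 3, 10)
  expect_error(ensemblePredict(ens, c(Other = 1)), "missing feature")
  expect_error(ensemblePredict(ens, c(1, 2)), "length")
})

test_that("null-generator ensembles classify fresh samples at chance", {
  accs <- vapply(1:10, function(seed) {
    co <- generateCohort("null",
                         n_per_group = c(HEALTHY = 24L, NON_ELS_MDD = 24L),
                         seed = seed)
    panel <- PanelDefinition(cmpHN, "tclass",
                             c("Cholesterol", "Linoleic acid"))
    ens <- buildEnsemble(co, panel, cmpHN, "fisher", n_splits = 100L,
                         seed = seed)
    fresh <- generateCohort("null",
                            n_per_group = c(HEALTHY = 100L,
                                            NON_ELS_MDD = 100L),
                            seed = seed + 1000L)
    pr <- ensemblePredictTable(ens,
                               MetaboCohort(rpaMatrix(fresh)[, panelMetabolites(panel)]))
    mean(pr$predicted_label == groupLabels(fresh)[pr$sample_id])
  }, numeric(1))
  ## 95% binomial band around 0.5 for a fresh test set of 200
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})
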