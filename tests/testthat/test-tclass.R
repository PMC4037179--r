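cmpHN <- c("HEALTHY", "NON_ELS_MDD")

test_that("1-D Fisher discriminant puts the boundary midway between means", {
  m <- cbind(M1 = c(-1, 0, 1, 0, 9, 10, 11, 10))
  co <- makeCohortFromMatrix(m, rep(cmpHN, each = 4))
  panel <- PanelDefinition(cmpHN, "tclass", "M1")
  clf <- trainFisher(co, panel, cmpHN)
  at5 <- classifySample(clf, c(M1 = 5))
  expect_equal(unname(diff(at5$scores)), 0, tolerance = 1e-9)
  expect_equal(at5$label, "HEALTHY")         # exact tie goes to control
  expect_equal(classifySample(clf, c(M1 = 5 - 1e-6))$label, "HEALTHY")
  expect_equal(classifySample(clf, c(M1 = 5 + 1e-6))$label, "NON_ELS_MDD")
})

test_that("Fisher classification matches a shared-covariance Bayes oracle", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n0 <- 15; n1 <- 15; p <- 3
      m <- rbind(matrix(rnorm(n0 * p, 0), n0, p),
                 matrix(rnorm(n1 * p, 1.2), n1, p))
      colnames(m) <- paste0("M", 1:p)
      co <- makeCohortFromMatrix(m, rep(cmpHN, c(n0, n1)))
      panel <- PanelDefinition(cmpHN, "tclass", colnames(m))
      clf <- trainFisher(co, panel, cmpHN)
      ## oracle: equal-prior Gaussian Bayes rule with pooled covariance —
      ## assign to the class with smaller Mahalanobis distance
      mu0 <- colMeans(m[1:n0, ]); mu1 <- colMeans(m[-(1:n0), ])
      S <- (cov(m[1:n0, ]) * (n0 - 1) + cov(m[-(1:n0), ]) * (n1 - 1)) /
        (n0 + n1 - 2)
      Sinv <- solve(S)
      pts <- matrix(rnorm(30 * p, 0.6), 30, p, dimnames = list(NULL, colnames(m)))
      oracle <- apply(pts, 1, function(x) {
        d0 <- mahalanobis(x, mu0, Sinv, inverted = TRUE)
        d1 <- mahalanobis(x, mu1, Sinv, inverted = TRUE)
        if (d1 < d0) cmpHN[2] else cmpHN[1]
      })
      got <- apply(pts, 1, function(x) classifySample(clf, x)$label)
      expect_equal(unname(got), unname(oracle))
    })
  }
})

test_that("Fisher agrees with MASS::lda under equal priors", {
  skip_if_not_installed("MASS")
  withr::with_seed(31, {
    m <- rbind(matrix(rnorm(20 * 2, 0), 20, 2),
               matrix(rnorm(20 * 2, 1), 20, 2))
    colnames(m) <- c("M1", "M2")
    co <- makeCohortFromMatrix(m, rep(cmpHN, each = 20))
    clf <- trainFisher(co, PanelDefinition(cmpHN, "tclass", colnames(m)),
                       cmpHN)
    ld <- MASS::lda(m, grouping = rep(cmpHN, each = 20),
                    prior = c(0.5, 0.5))
    pts <- matrix(rnorm(40, 0.5), 20, 2, dimnames = list(NULL, colnames(m)))
    got <- apply(pts, 1, function(x) classifySample(clf, x)$label)
    expect_equal(unname(got),
                 as.character(predict(ld, pts)$class))
  })
})

test_that("identical class means give tied scores resolved to control", {
  m <- cbind(M1 = c(1, 2, 3, 1, 2, 3), M2 = c(0, 1, 0, 0, 1, 0))
  co <- makeCohortFromMatrix(m, rep(cmpHN, each = 3))
  panel <- PanelDefinition(cmpHN, "tclass", c("M1", "M2"))
  clf <- trainFisher(co, panel, cmpHN)
  for (x in list(c(M1 = 0, M2 = 0), c(M1 = 10, M2 = -3))) {
    r <- classifySample(clf, x)
    expect_equal(unname(diff(r$scores)), 0, tolerance = 1e-12)
    expect_equal(r$label, "HEALTHY")
  }
})

test_that("naive Bayes matches the factorized Gaussian log-density oracle", {
  withr::with_seed(8, {
    n <- 12
    m <- cbind(M1 = c(rnorm(n / 2, 0, 1), rnorm(n / 2, 2, 0.5)),
               M2 = c(rnorm(n / 2, 5, 2), rnorm(n / 2, 4, 1)))
    co <- makeCohortFromMatrix(m, rep(cmpHN, each = n / 2))
    panel <- PanelDefinition(cmpHN, "tclass", c("M1", "M2"))
    clf <- trainNaiveBayes(co, panel, cmpHN)
    ## oracle: per-class per-feature Gaussian log densities, equal priors
    stats0 <- list(mean = colMeans(m[1:6, ]), sd = apply(m[1:6, ], 2, sd))
    stats1 <- list(mean = colMeans(m[7:12, ]), sd = apply(m[7:12, ], 2, sd))
    pts <- matrix(rnorm(20, 1, 2), 10, 2, dimnames = list(NULL, c("M1", "M2")))
    oracle <- apply(pts, 1, function(x) {
      l0 <- sum(dnorm(x, stats0$mean, stats0$sd, log = TRUE))
      l1 <- sum(dnorm(x, stats1$mean, stats1$sd, log = TRUE))
      if (l1 > l0) cmpHN[2] else cmpHN[1]
    })
    got <- apply(pts, 1, function(x) classifySample(clf, x)$label)
    expect_equal(unname(got), unname(oracle))
  })
})

test_that("duplicating every feature k times preserves the naive Bayes call", {
  withr::with_seed(9, {
    m <- cbind(M1 = c(rnorm(6, 0), rnorm(6, 1.5)))
    co1 <- makeCohortFromMatrix(m, rep(cmpHN, each = 6))
    m3 <- cbind(M1 = m[, 1], M2 = m[, 1], M3 = m[, 1])
    co3 <- makeCohortFromMatrix(m3, rep(cmpHN, each = 6))
    clf1 <- trainNaiveBayes(co1, PanelDefinition(cmpHN, "tclass", "M1"), cmpHN)
    clf3 <- trainNaiveBayes(co3, PanelDefinition(cmpHN, "tclass",
                                                 c("M1", "M2", "M3")), cmpHN)
    for (x in seq(-1, 2.5, by = 0.5)) {
      r1 <- classifySample(clf1, c(M1 = x))
      r3 <- classifySample(clf3, c(M1 = x, M2 = x, M3 = x))
      expect_equal(r3$label, r1$label)
      ## log-posterior difference scales by the duplication factor
      expect_equal(unname(diff(r3$scores)), 3 * unname(diff(r1$scores)),
                   tolerance = 1e-9)
    }
  })
})

test_that("equal class-conditionals tie to the control label", {
  m <- cbind(M1 = rep(c(1, 2, 3), 2))
  co <- makeCohortFromMatrix(m, rep(cmpHN, each = 3))
  clf <- trainNaiveBayes(co, PanelDefinition(cmpHN, "tclass", "M1"), cmpHN)
  expect_equal(classifySample(clf, c(M1 = 7))$label, "HEALTHY")
})

test_that("the printed classifier pair labels the healthy mean profile", {
  pm <- loadPrintedModel()
  cat35 <- loadReferenceCatalog()
  feats <- pm$classifier@feature_names
  x <- setNames(cat35$healthy_mean[match(feats, cat35$name)], feats)
  ## oracle: evaluate both printed affine forms directly
  cs <- pm$classifier@control_intercept +
    sum(pm$classifier@control_coefficients * x)
  ks <- pm$classifier@case_intercept +
    sum(pm$classifier@case_coefficients * x)
  expect_equal(cs, 192.9003, tolerance = 1e-4)
  expect_equal(ks, 185.4434, tolerance = 1e-4)
  r <- evaluateClassifierPair(pm$classifier, x)
  expect_equal(r$label, if (ks > cs) "MDD_ALL" else "HEALTHY")
  expect_equal(r$label, "HEALTHY")           # frozen oracle outcome
})

test_that("LOOCV scores perfectly separated data at 1", {
  m <- cbind(M1 = c(1:5, 101:105))
  co <- makeCohortFromMatrix(m, rep(cmpHN, each = 5))
  panel <- PanelDefinition(cmpHN, "tclass", "M1")
  expect_equal(loocvAccuracy(co, panel, cmpHN, "fisher"), 1.0)
  expect_equal(loocvAccuracy(co, panel, cmpHN, "naive_bayes"), 1.0)
})

test_that("LOOCV equals the explicit fold-loop oracle on random data", {
  for (seed in 1:5) {
    co <- makeTwoGroup(n0 = 7, n1 = 7, mu0 = 0, mu1 = 1, p_noise = 2,
                       seed = seed)
    panel <- PanelDefinition(cmpHN, "tclass", c("M1", "N1", "N2"))
    for (learner in c("fisher", "naive_bayes")) {
      expect_equal(loocvAccuracy(co, panel, cmpHN, learner),
                   loocvOracle(co, panel, cmpHN, learner),
                   info = paste(learner, "seed", seed))
    }
  }
})

test_that("a contradictory duplicated pair caps LOOCV at 0.8", {
  ## 4 clean samples per class, plus one member of each class at the exact
  ## midpoint (identical features, opposite labels): held out, each is pulled
  ## to the wrong side, so exactly 2 of 10 folds fail.
  m <- cbind(M1 = c(-1, 0, 1, 0, 5, 9, 10, 11, 10, 5))
  co <- makeCohortFromMatrix(m, rep(cmpHN, each = 5))
  panel <- PanelDefinition(cmpHN, "tclass", "M1")
  expect_equal(loocvAccuracy(co, panel, cmpHN, "fisher"), 0.8)
})

test_that("forward selection finds the lone separating feature first", {
  withr::with_seed(6, {
    ind <- rep(c(0, 10), each = 6)
    m <- cbind(A = rnorm(12), B = ind + rnorm(12, sd = 0.1), C = rnorm(12))
    co <- makeCohortFromMatrix(m, rep(cmpHN, each = 6))
    ## exhaustive step-1 scan as the oracle
    accs <- vapply(colnames(m), function(f)
      loocvAccuracy(co, PanelDefinition(cmpHN, "tclass", f), cmpHN, "fisher"),
      numeric(1))
    expect_equal(names(which.max(accs)), "B")
    tr <- forwardSelect(co, cmpHN, "fisher", k_max = 3L)
    expect_equal(tr@steps$metabolite[1], "B")
    expect_equal(tr@steps$loocv_accuracy[1], unname(max(accs)))
    ## separation reached at step 1 stops the search
    expect_equal(nrow(tr@steps), 1L)
    expect_equal(panelMetabolites(tr@chosen), "B")
  })
})

test_that("forward selection respects k_max and emits a full trace", {
  co <- makeTwoGroup(n0 = 8, n1 = 8, mu0 = 0, mu1 = 0.5, p_noise = 3,
                     seed = 14)
  tr1 <- forwardSelect(co, cmpHN, "naive_bayes", k_max = 1L)
  expect_equal(nrow(tr1@steps), 1L)
  tr <- forwardSelect(co, cmpHN, "naive_bayes", k_max = 4L)
  expect_true(nrow(tr@steps) >= 1 && nrow(tr@steps) <= 4)
  expect_equal(tr@steps$k, seq_len(nrow(tr@steps)))
  ## chosen = smallest prefix attaining the traced maximum
  k_best <- which.max(tr@steps$loocv_accuracy)
  expect_equal(panelMetabolites(tr@chosen),
               tr@steps$metabolite[seq_len(k_best)])
  expect_error(forwardSelect(co, cmpHN, "fisher", k_max = 0L), "k_max")
})
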