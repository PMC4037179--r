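## Tclass base learners and selection machinery: Fisher linear discriminant
## classification functions, Gaussian naive Bayes, leave-one-out
## cross-validation and greedy forward feature selection.

## ---- internal trainers working on a plain (samples x features) matrix ----

## Pooled within-class covariance with escalating ridge. Classes contributing
## a single sample add no degrees of freedom; if no class has >= 2 samples the
## pooled estimate degenerates to the identity scale of the data.
.pooledCov <- function(X, y01) {
  p <- ncol(X)
  S <- matrix(0, p, p)
  df <- 0L
  for (cls in c(0L, 1L)) {
    Xi <- X[y01 == cls, , drop = FALSE]
    if (nrow(Xi) >= 2L) {
      S <- S + stats::cov(Xi) * (nrow(Xi) - 1L)
      df <- df + nrow(Xi) - 1L
    }
  }
  if (df > 0L) S / df else diag(p)
}

.fisherParams <- function(X, y01, class_labels, panel) {
  p <- ncol(X)
  mu0 <- colMeans(X[y01 == 0L, , drop = FALSE])
  mu1 <- colMeans(X[y01 == 1L, , drop = FALSE])
  S <- .pooledCov(X, y01)
  scale0 <- sum(diag(S)) / p
  if (scale0 <= 0) scale0 <- 1
  Sinv <- NULL
  for (lambda in 10^seq(-6, -2)) {
    Sr <- S + lambda * scale0 * diag(p)
    Sinv <- tryCatch(solve(Sr), error = function(e) NULL)
    if (!is.null(Sinv)) break
  }
  if (is.null(Sinv))
    stop("pooled covariance singular even after ridge stabilization")
  ## equal priors: the ln(pi_k) terms cancel and are omitted
  a0 <- as.numeric(Sinv %*% mu0); a1 <- as.numeric(Sinv %*% mu1)
  b0 <- -0.5 * sum(mu0 * a0); b1 <- -0.5 * sum(mu1 * a1)
  new("TrainedClassifier", learner = "fisher", class_labels = class_labels,
      panel = panel,
      parameters = new("LinearClassifierPair",
                       class_labels = class_labels,
                       feature_names = colnames(X),
                       control_intercept = b0, case_intercept = b1,
                       control_coefficients = a0, case_coefficients = a1))
}

.naiveBayesParams <- function(X, y01, class_labels, panel) {
  pooled_var <- apply(X, 2, stats::var)
  pooled_var[!is.finite(pooled_var)] <- 0
  floor_var <- pmax(1e-9 * pooled_var, 1e-12)
  cls_stats <- lapply(c(0L, 1L), function(cls) {
    Xi <- X[y01 == cls, , drop = FALSE]
    m <- colMeans(Xi)
    v <- if (nrow(Xi) >= 2L) apply(Xi, 2, stats::var) else rep(0, ncol(Xi))
    list(mean = m, var = pmax(v, floor_var))
  })
  if (all(vapply(cls_stats, function(s) all(s$var <= floor_var), logical(1))))
    warning("zero within-class variance on all features; variance floor applied")
  new("TrainedClassifier", learner = "naive_bayes",
      class_labels = class_labels, panel = panel,
      parameters = list(
        means = list(control = cls_stats[[1]]$mean, case = cls_stats[[2]]$mean),
        variances = list(control = cls_stats[[1]]$var, case = cls_stats[[2]]$var),
        priors = c(control = 0.5, case = 0.5)))
}

## learner: "fisher", "naive_bayes", or a function(X, y01, class_labels)
## returning a prediction function(newX) -> label vector (a test hook and
## extension point).
.trainLearner <- function(X, y01, class_labels, panel, learner) {
  if (is.function(learner)) return(learner(X, y01, class_labels))
  switch(learner,
         fisher = .fisherParams(X, y01, class_labels, panel),
         naive_bayes = .naiveBayesParams(X, y01, class_labels, panel),
         stop("unknown learner: ", learner))
}

## Per-class score matrix (n x 2: control, case) for a trained classifier.
.scoreMatrix <- function(clf, X) {
  if (clf@learner == "fisher") {
    lp <- clf@parameters
    cbind(X %*% lp@control_coefficients + lp@control_intercept,
          X %*% lp@case_coefficients + lp@case_intercept)
  } else {
    pars <- clf@parameters
    ll <- function(which) {
      m <- pars$means[[which]]; v <- pars$variances[[which]]
      ## row-wise sum of Gaussian log densities
      const <- -0.5 * sum(log(2 * pi * v))
      dev <- sweep(X, 2, m)
      const - 0.5 * as.numeric((dev^2) %*% (1 / v)) +
        log(pars$priors[[which]])
    }
    cbind(ll("control"), ll("case"))
  }
}

.predictLearner <- function(clf, X) {
  X <- as.matrix(X)
  if (is.function(clf)) return(clf(X))
  sc <- .scoreMatrix(clf, X)
  ## strict inequality: ties resolve to the control (first) label
  ifelse(sc[, 2L] > sc[, 1L], clf@class_labels[2L], clf@class_labels[1L])
}

## ---- exported surface ----

#' Train a Fisher linear discriminant classifier
#'
#' Per-class linear discriminant classification functions
#' g_k(x) = mu_k' S^-1 x - 1/2 mu_k' S^-1 mu_k + ln pi_k with pooled
#' within-class covariance S (ridge-stabilized: S + lambda tr(S)/p I with
#' lambda escalating from 1e-6 by decades to 1e-2 before erroring) and equal
#' priors. Classification is by the larger score; ties go to the control
#' label.
#'
#' @param cohort labeled \linkS4class{MetaboCohort}
#' @param panel a \linkS4class{PanelDefinition}
#' @param comparison character(2): (control, case).
#' @return a \linkS4class{TrainedClassifier}
#' @export
trainFisher <- function(cohort, panel, comparison) {
  cd <- .comparisonData(cohort, comparison, panelMetabolites(panel))
  .fisherParams(cd$X, cd$y, as.character(comparison), panel)
}

#' Train a Gaussian naive Bayes classifier
#'
#' Gaussian class-conditionals with per-class per-feature mean and variance
#' (variance floored at 1e-9 times the feature's pooled variance) and equal
#' priors; classification is by the higher log-posterior, ties to control.
#'
#' @inheritParams trainFisher
#' @return a \linkS4class{TrainedClassifier}
#' @export
trainNaiveBayes <- function(cohort, panel, comparison) {
  cd <- .comparisonData(cohort, comparison, panelMetabolites(panel))
  .naiveBayesParams(cd$X, cd$y, as.character(comparison), panel)
}

#' Classify a sample with a trained classifier
#'
#' @param model a \linkS4class{TrainedClassifier}
#' @param sample numeric vector in the panel's feature order (names, when
#'   present, are used to reorder).
#' @return list with \code{label} and \code{scores} (named per-class scores;
#'   the case label wins only on a strictly greater score).
#' @export
classifySample <- function(model, sample) {
  stopifnot(is(model, "TrainedClassifier"))
  feats <- panelMetabolites(model@panel)
  if (length(sample) != length(feats))
    stop("feature vector length ", length(sample), " != panel size ",
         length(feats))
  if (!is.null(names(sample))) {
    missing <- setdiff(feats, names(sample))
    if (length(missing))
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    sample <- sample[feats]
  }
  sc <- .scoreMatrix(model, matrix(sample, nrow = 1L,
                                   dimnames = list(NULL, feats)))
  list(label = if (sc[1, 2] > sc[1, 1]) model@class_labels[2L]
               else model@class_labels[1L],
       scores = stats::setNames(as.numeric(sc), model@class_labels))
}

## LOOCV on a plain matrix; used by both the exported function and forward
## selection (which re-evaluates many candidate panels on shared data).
.loocvMatrix <- function(X, y01, class_labels, panel, learner) {
  n <- nrow(X)
  correct <- 0L
  truth <- ifelse(y01 == 1L, class_labels[2L], class_labels[1L])
  for (i in seq_len(n)) {
    clf <- .trainLearner(X[-i, , drop = FALSE], y01[-i], class_labels,
                         panel, learner)
    pred <- .predictLearner(clf, X[i, , drop = FALSE])
    if (pred == truth[i]) correct <- correct + 1L
  }
  correct / n
}

#' Leave-one-out cross-validated accuracy of a panel
#'
#' Each sample is classified by a model trained on all other samples; the
#' returned value is the fraction classified correctly. Folds that leave a
#' class with fewer than 2 training samples still retrain through the
#' variance-floored / ridge path rather than being skipped.
#'
#' @inheritParams trainFisher
#' @param learner "fisher" or "naive_bayes" (or a training function hook,
#'   see \code{\link{stabilityIndex}}).
#' @return accuracy in [0, 1]
#' @export
loocvAccuracy <- function(cohort, panel, comparison, learner = "fisher") {
  cd <- .comparisonData(cohort, comparison, panelMetabolites(panel))
  if (nrow(cd$X) < 3L) stop("LOOCV needs at least 3 samples")
  .loocvMatrix(cd$X, cd$y, as.character(comparison), panel, learner)
}

#' Greedy forward feature selection under LOOCV
#'
#' At each step the candidate metabolite maximizing the LOOCV accuracy of
#' the augmented panel is added (ties broken toward the earlier catalog /
#' column position). Selection stops at \code{k_max} features or as soon as
#' accuracy reaches 1. The chosen panel is the smallest prefix attaining the
#' maximum traced accuracy.
#'
#' Selection is evaluated on the full data set (outside the LOOCV folds), so
#' the traced accuracies are optimistically biased; report them alongside a
#' \code{\link{stabilityIndex}}, which is the resampling check of that
#' optimism.
#'
#' @param cohort labeled \linkS4class{MetaboCohort}
#' @param comparison character(2): (control, case).
#' @param learner "fisher" or "naive_bayes".
#' @param k_max maximum panel size (>= 1).
#' @param candidates optional metabolite subset to search (default: every
#'   metabolite in the table, in column order).
#' @return a \linkS4class{SelectionTrace}
#' @export
forwardSelect <- function(cohort, comparison, learner = "fisher",
                          k_max = 9L, candidates = NULL) {
  if (k_max < 1L) stop("k_max must be >= 1")
  cd <- .comparisonData(cohort, comparison, candidates)
  X <- cd$X
  class_labels <- as.character(comparison)
  pool <- colnames(X)
  chosen <- character()
  steps <- data.frame(metabolite = character(), k = integer(),
                      loocv_accuracy = numeric())
  while (length(chosen) < min(k_max, ncol(X))) {
    accs <- vapply(pool, function(cand) {
      cols <- c(chosen, cand)
      .loocvMatrix(X[, cols, drop = FALSE], cd$y, class_labels,
                   PanelDefinition(comparison, "tclass", cols), learner)
    }, numeric(1))
    best <- which.max(accs)      # which.max takes the first (earlier column) on ties
    chosen <- c(chosen, pool[best])
    steps <- rbind(steps, data.frame(metabolite = pool[best],
                                     k = length(chosen),
                                     loocv_accuracy = accs[[best]]))
    pool <- pool[-best]
    if (accs[[best]] >= 1) break
  }
  k_best <- which.max(steps$loocv_accuracy)  # smallest panel at the max
  chosen_panel <- PanelDefinition(comparison, "tclass",
                                  steps$metabolite[seq_len(k_best)],
                                  learner = if (is.function(learner))
                                    NA_character_ else learner)
  rownames(steps) <- NULL
  new("SelectionTrace", steps = steps, chosen = chosen_panel)
}
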