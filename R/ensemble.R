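## Stability-index validation and the majority-vote ensemble: one classifier
## per random 85/15 training set, sharing a single seeded split stream so a
## stability analysis and the ensemble trained from it see identical splits.

#' Stability index over repeated random train/test splits
#'
#' The cohort is split at random into an 85\% training and 15\% test part
#' (stratified by class; per-class test size max(1, round(0.15 n_class)))
#' \code{n_splits} times; a classifier is trained on each training part and
#' scored on its test part. The stability index is the mean of the
#' \code{n_splits} test accuracies — a resampling estimate of how the panel
#' will perform on independent data.
#'
#' Splits are drawn on a canonical ordering of samples by id, so the result
#' is invariant to the row order of the input table.
#'
#' @param cohort labeled \linkS4class{MetaboCohort}
#' @param panel a \linkS4class{PanelDefinition}
#' @param comparison character(2): (control, case).
#' @param learner "fisher" or "naive_bayes"; alternatively a function
#'   \code{function(X, y01, class_labels)} returning a prediction function
#'   \code{function(newX) -> labels} (an injection hook for testing).
#' @param n_splits number of random partitions (default 1000).
#' @param train_fraction training fraction (default 0.85).
#' @param seed integer governing the split stream.
#' @return a \linkS4class{StabilityResult}
#' @export
stabilityIndex <- function(cohort, panel, comparison, learner = "fisher",
                           n_splits = 1000L, train_fraction = 0.85,
                           seed = 1L) {
  cd <- .comparisonData(cohort, comparison, panelMetabolites(panel))
  splits <- .drawSplits(cd$labels, cd$sample_ids, n_splits, train_fraction,
                        seed)
  class_labels <- as.character(comparison)
  truth <- ifelse(cd$y == 1L, class_labels[2L], class_labels[1L])
  acc <- vapply(splits, function(s) {
    clf <- .trainLearner(cd$X[s$train, , drop = FALSE], cd$y[s$train],
                         class_labels, panel, learner)
    mean(.predictLearner(clf, cd$X[s$test, , drop = FALSE]) == truth[s$test])
  }, numeric(1))
  new("StabilityResult", n_splits = as.integer(n_splits),
      train_fraction = train_fraction, split_accuracies = acc,
      stability_index = mean(acc), seed = as.integer(seed))
}

#' Build a majority-vote ensemble over the stability split stream
#'
#' Trains one classifier per random training part. Given the same seed,
#' cohort and parameters, the training sets are exactly the splits a
#' \code{\link{stabilityIndex}} call would score, so the ensemble is the
#' model whose generalization the stability index estimates.
#'
#' @inheritParams stabilityIndex
#' @return an \linkS4class{EnsembleModel} whose case label is
#'   \code{comparison[2]}
#' @export
buildEnsemble <- function(cohort, panel, comparison, learner = "fisher",
                          n_splits = 1000L, train_fraction = 0.85,
                          seed = 1L) {
  if (is.function(learner))
    stop("ensembles require a named learner ('fisher' or 'naive_bayes')")
  cd <- .comparisonData(cohort, comparison, panelMetabolites(panel))
  splits <- .drawSplits(cd$labels, cd$sample_ids, n_splits, train_fraction,
                        seed)
  class_labels <- as.character(comparison)
  clfs <- lapply(splits, function(s)
    .trainLearner(cd$X[s$train, , drop = FALSE], cd$y[s$train],
                  class_labels, panel, learner))
  new("EnsembleModel", classifiers = clfs, panel = panel,
      class_labels = class_labels, case_label = class_labels[2L],
      learner = learner, seed = as.integer(seed))
}

#' Ensemble vote fraction and call for one sample
#'
#' Every member classifier votes; P is the fraction voting for the case
#' label. The sample is called case iff P > 0.5 strictly (exactly half the
#' votes is a control call).
#'
#' @param model an \linkS4class{EnsembleModel}
#' @param sample named numeric vector covering the model's panel
#' @return an \linkS4class{EnsemblePrediction}
#' @export
ensemblePredict <- function(model, sample) {
  stopifnot(is(model, "EnsembleModel"))
  feats <- panelMetabolites(model@panel)
  if (!is.null(names(sample))) {
    missing <- setdiff(feats, names(sample))
    if (length(missing))
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    sample <- sample[feats]
  } else if (length(sample) != length(feats)) {
    stop("feature vector length ", length(sample), " != panel size ",
         length(feats))
  }
  X <- matrix(sample, nrow = 1L, dimnames = list(NULL, feats))
  votes <- vapply(model@classifiers,
                  function(clf) .predictLearner(clf, X), character(1))
  P <- mean(votes == model@case_label)
  new("EnsemblePrediction", vote_fraction = P,
      predicted_label = if (P > 0.5) model@case_label
                        else setdiff(model@class_labels, model@case_label))
}

#' Ensemble predictions for every sample of a table
#'
#' @param model an \linkS4class{EnsembleModel}
#' @param cohort a \linkS4class{MetaboCohort} containing the panel's
#'   metabolites
#' @return data.frame with columns \code{sample_id}, \code{P},
#'   \code{predicted_label}
#' @export
ensemblePredictTable <- function(model, cohort) {
  stopifnot(is(cohort, "MetaboCohort"))
  feats <- panelMetabolites(model@panel)
  missing <- setdiff(feats, metaboliteNames(cohort))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  X <- rpaMatrix(cohort)[, feats, drop = FALSE]
  ## vectorized over samples: each classifier votes on the whole matrix
  case_votes <- rowSums(vapply(model@classifiers, function(clf)
    .predictLearner(clf, X) == model@case_label,
    logical(nrow(X))))
  P <- case_votes / length(model@classifiers)
  data.frame(sample_id = rownames(X), P = P,
             predicted_label = ifelse(P > 0.5, model@case_label,
                                      setdiff(model@class_labels,
                                              model@case_label)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full Tclass workflow for one comparison
#'
#' Convenience wrapper: forward selection under LOOCV, stability analysis of
#' the chosen panel, and the majority-vote ensemble trained on the same
#' split stream.
#'
#' @inheritParams stabilityIndex
#' @param k_max maximum panel size explored by forward selection.
#' @param candidates optional metabolite subset to search.
#' @return list with \code{trace} (\linkS4class{SelectionTrace}),
#'   \code{stability} (\linkS4class{StabilityResult}) and \code{ensemble}
#'   (\linkS4class{EnsembleModel})
#' @export
runTclass <- function(cohort, comparison, learner = "fisher", k_max = 9L,
                      n_splits = 1000L, train_fraction = 0.85, seed = 1L,
                      candidates = NULL) {
  trace <- forwardSelect(cohort, comparison, learner, k_max, candidates)
  panel <- trace@chosen
  stab <- stabilityIndex(cohort, panel, comparison, learner, n_splits,
                         train_fraction, seed)
  ens <- buildEnsemble(cohort, panel, comparison, learner, n_splits,
                       train_fraction, seed)
  list(trace = trace, stability = stab, ensemble = ens)
}
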