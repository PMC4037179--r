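#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

## Group vocabulary. MDD_ALL is a derived union of the two MDD subtypes and is
## never stored as a per-sample label.
.GROUPS <- c("HEALTHY", "ELS_MDD", "NON_ELS_MDD")
.GROUPS_EXT <- c(.GROUPS, "MDD_ALL")

#' MetaboCohort: a sample-by-metabolite RPA table with group labels
#'
#' A thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' holding one assay \code{"rpa"} (metabolites in rows, samples in columns)
#' of relative peak areas, plus an optional per-sample \code{group} column in
#' \code{colData} drawn from \code{HEALTHY}, \code{ELS_MDD},
#' \code{NON_ELS_MDD}.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @export
setClass("MetaboCohort", contains = "SummarizedExperiment")

setValidity("MetaboCohort", function(object) {
  msg <- character()
  if (!("rpa" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'rpa' is required")
  else {
    m <- SummarizedExperiment::assay(object, "rpa")
    if (!is.numeric(m)) msg <- c(msg, "assay 'rpa' must be numeric")
    if (anyNA(m)) msg <- c(msg, "assay 'rpa' contains missing values")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "metabolite names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if ("group" %in% colnames(SummarizedExperiment::colData(object))) {
    g <- SummarizedExperiment::colData(object)$group
    bad <- setdiff(unique(as.character(g[!is.na(g)])), .GROUPS)
    if (length(bad))
      msg <- c(msg, paste0("unknown group label(s): ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MetaboCohort
#'
#' @param values numeric matrix, samples in rows, metabolites in columns
#'   (the orientation of a peak table as exported by alignment software).
#' @param sample_ids,metabolite_names character vectors; default to the
#'   dimnames of \code{values}.
#' @param groups optional character vector (length = number of samples) of
#'   group labels in \code{HEALTHY}, \code{ELS_MDD}, \code{NON_ELS_MDD}.
#' @return a \linkS4class{MetaboCohort}
#' @examples
#' m <- matrix(abs(rnorm(12)), 4, 3,
#'             dimnames = list(paste0("s", 1:4), c("Alanine", "Glycine", "Valine")))
#' MetaboCohort(m, groups = c("HEALTHY", "HEALTHY", "ELS_MDD", "NON_ELS_MDD"))
#' @export
MetaboCohort <- function(values, sample_ids = rownames(values),
                         metabolite_names = colnames(values), groups = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids) || is.null(metabolite_names))
    stop("sample ids and metabolite names are required")
  stopifnot(length(sample_ids) == nrow(values),
            length(metabolite_names) == ncol(values))
  assay <- t(values)
  dimnames(assay) <- list(metabolite_names, sample_ids)
  cd <- if (is.null(groups)) {
    S4Vectors::DataFrame(row.names = sample_ids)
  } else {
    stopifnot(length(groups) == length(sample_ids))
    S4Vectors::DataFrame(group = as.character(groups), row.names = sample_ids)
  }
  new("MetaboCohort",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(rpa = assay), colData = cd))
}

#' PanelDefinition: an ordered metabolite subset for one two-group comparison
#'
#' @slot comparison character(2), (control, case); each in HEALTHY, ELS_MDD,
#'   NON_ELS_MDD or the derived union MDD_ALL.
#' @slot method "differential" (VIP-selected) or "tclass" (forward-selected).
#' @slot metabolites ordered character vector, no duplicates.
#' @slot learner optional base learner ("fisher" or "naive_bayes"); NA when
#'   not applicable.
#' @export
setClass("PanelDefinition",
         representation(comparison = "character", method = "character",
                        metabolites = "character", learner = "character"),
         prototype(learner = NA_character_))

setValidity("PanelDefinition", function(object) {
  msg <- character()
  if (length(object@comparison) != 2L ||
      !all(object@comparison %in% .GROUPS_EXT))
    msg <- c(msg, "comparison must be two known group labels")
  if (!object@method %in% c("differential", "tclass"))
    msg <- c(msg, "method must be 'differential' or 'tclass'")
  if (length(object@metabolites) == 0L)
    msg <- c(msg, "panel must contain at least one metabolite")
  if (anyDuplicated(object@metabolites))
    msg <- c(msg, "panel metabolites must be unique")
  if (!is.na(object@learner) &&
      !object@learner %in% c("fisher", "naive_bayes"))
    msg <- c(msg, "learner must be 'fisher' or 'naive_bayes'")
  if (length(msg)) msg else TRUE
})

#' @rdname PanelDefinition-class
#' @param comparison,method,metabolites,learner see slots.
#' @export
PanelDefinition <- function(comparison, method, metabolites,
                            learner = NA_character_) {
  new("PanelDefinition", comparison = as.character(comparison),
      method = method, metabolites = as.character(metabolites),
      learner = as.character(learner))
}

#' LinearClassifierPair: per-class affine discriminant scores
#'
#' The printed form of a Fisher linear discriminant classifier: one affine
#' score per class; the class with the larger score wins.
#'
#' @slot class_labels character(2), (control, case).
#' @slot feature_names ordered features X1..Xp.
#' @slot control_intercept,case_intercept reals.
#' @slot control_coefficients,case_coefficients numeric length p.
#' @export
setClass("LinearClassifierPair",
         representation(class_labels = "character", feature_names = "character",
                        control_intercept = "numeric", case_intercept = "numeric",
                        control_coefficients = "numeric",
                        case_coefficients = "numeric"))

setValidity("LinearClassifierPair", function(object) {
  p <- length(object@feature_names)
  if (length(object@control_coefficients) != p ||
      length(object@case_coefficients) != p)
    "coefficient vectors must match the feature list length"
  else TRUE
})

#' PLSDAModel: a fitted two-group PLS-DA model
#'
#' @slot n_components number of extracted latent components A.
#' @slot x_weights p x A weight matrix (w).
#' @slot x_scores n x A score matrix (t), columns mutually orthogonal.
#' @slot x_loadings p x A loading matrix.
#' @slot y_loadings numeric(A) (q).
#' @slot y_ss_explained numeric(A): per-component explained sum of squares of
#'   the centered class indicator.
#' @slot center,scale numeric(p): column preprocessing applied before fitting.
#' @slot feature_names character(p).
#' @slot comparison character(2) (control, case).
#' @slot short_rank TRUE when fewer components than requested were
#'   extractable.
#' @export
setClass("PLSDAModel",
         representation(n_components = "integer", x_weights = "matrix",
                        x_scores = "matrix", x_loadings = "matrix",
                        y_loadings = "numeric", y_ss_explained = "numeric",
                        center = "numeric", scale = "numeric",
                        feature_names = "character", comparison = "character",
                        short_rank = "logical"))

#' VIPResult: variable importance in projection
#'
#' @slot metabolite_names character(p).
#' @slot vip numeric(p), non-negative; sum of squares equals p.
#' @export
setClass("VIPResult",
         representation(metabolite_names = "character", vip = "numeric"))

#' RocCurve: an ROC curve and its AUC
#'
#' @slot thresholds,sensitivities,specificities equal-length numeric vectors.
#' @slot auc area under the curve in [0, 1] (Mann-Whitney, ties half credit).
#' @export
setClass("RocCurve",
         representation(thresholds = "numeric", sensitivities = "numeric",
                        specificities = "numeric", auc = "numeric"))

#' PanelEvaluation: a fitted logistic panel and its ROC AUC
#'
#' @slot panel the evaluated \linkS4class{PanelDefinition}.
#' @slot k panel size.
#' @slot auc ROC AUC of the fitted linear predictor on the training samples.
#' @slot fitted_coefficients numeric(k + 1), intercept first.
#' @export
setClass("PanelEvaluation",
         representation(panel = "PanelDefinition", k = "integer",
                        auc = "numeric", fitted_coefficients = "numeric"))

#' TrainedClassifier: one fitted two-class base learner
#'
#' @slot learner "fisher" or "naive_bayes".
#' @slot class_labels character(2), (control, case).
#' @slot panel the \linkS4class{PanelDefinition} the classifier was trained on.
#' @slot parameters for "fisher" a \linkS4class{LinearClassifierPair}; for
#'   "naive_bayes" a list with per-class feature means, variances and priors.
#' @export
setClass("TrainedClassifier",
         representation(learner = "character", class_labels = "character",
                        panel = "PanelDefinition", parameters = "ANY"))

#' SelectionTrace: the path of greedy forward feature selection
#'
#' @slot steps data.frame with columns \code{metabolite} (the feature added),
#'   \code{k} (panel size after the step) and \code{loocv_accuracy}.
#' @slot chosen the smallest panel attaining the maximum traced accuracy.
#' @export
setClass("SelectionTrace",
         representation(steps = "data.frame", chosen = "PanelDefinition"))

#' StabilityResult: repeated random-split validation
#'
#' @slot n_splits number of random 85/15 partitions (default 1000).
#' @slot train_fraction training fraction (default 0.85).
#' @slot split_accuracies test-set accuracy of each split.
#' @slot stability_index arithmetic mean of the split accuracies.
#' @slot seed the RNG seed that generated the split stream.
#' @export
setClass("StabilityResult",
         representation(n_splits = "integer", train_fraction = "numeric",
                        split_accuracies = "numeric",
                        stability_index = "numeric", seed = "integer"))

setValidity("StabilityResult", function(object) {
  if (length(object@split_accuracies) != object@n_splits)
    return("split_accuracies length must equal n_splits")
  if (abs(object@stability_index - mean(object@split_accuracies)) > 1e-12)
    return("stability_index must equal the mean split accuracy")
  TRUE
})

#' EnsembleModel: a majority-vote ensemble of per-split classifiers
#'
#' One classifier per random training set of the stability split stream; a
#' sample's vote fraction P is the share of classifiers voting for the case
#' class, and P > 0.5 (strictly) calls the case.
#'
#' @slot classifiers list of \linkS4class{TrainedClassifier}, one per split.
#' @slot panel shared \linkS4class{PanelDefinition}.
#' @slot class_labels character(2) (control, case).
#' @slot case_label the label whose vote fraction defines P.
#' @slot learner shared base learner.
#' @slot seed the split-stream seed.
#' @export
setClass("EnsembleModel",
         representation(classifiers = "list", panel = "PanelDefinition",
                        class_labels = "character", case_label = "character",
                        learner = "character", seed = "integer"))

setValidity("EnsembleModel", function(object) {
  if (!object@case_label %in% object@class_labels)
    return("case_label must be one of class_labels")
  TRUE
})

#' EnsemblePrediction: vote fraction and call for one sample
#'
#' @slot vote_fraction P in [0, 1]: fraction of classifiers voting case.
#' @slot predicted_label case label iff P > 0.5 strictly, else control.
#' @export
setClass("EnsemblePrediction",
         representation(vote_fraction = "numeric",
                        predicted_label = "character"))

#' SubtypeCall: hierarchical MDD screen plus subtype agreement call
#'
#' @slot mdd_call "MDD" or "NOT_MDD".
#' @slot subtype "ELS_MDD", "NON_ELS_MDD", "INDETERMINATE", or
#'   "NOT_APPLICABLE" (iff the MDD screen is negative).
#' @slot component_votes named list of (P, label) per component model.
#' @export
setClass("SubtypeCall",
         representation(mdd_call = "character", subtype = "character",
                        component_votes = "list"))

setValidity("SubtypeCall", function(object) {
  if ((object@subtype == "NOT_APPLICABLE") != (object@mdd_call == "NOT_MDD"))
    return("subtype is NOT_APPLICABLE exactly when mdd_call is NOT_MDD")
  TRUE
})
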