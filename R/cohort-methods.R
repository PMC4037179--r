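#' @rdname MetaboCohort
#' @param x a \linkS4class{MetaboCohort}
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname MetaboCohort
#' @export
setMethod("sampleIds", "MetaboCohort", function(x) colnames(x))

#' @rdname MetaboCohort
#' @export
setGeneric("metaboliteNames", function(x) standardGeneric("metaboliteNames"))

#' @rdname MetaboCohort
#' @export
setMethod("metaboliteNames", "MetaboCohort", function(x) rownames(x))

#' @rdname MetaboCohort
#' @export
setGeneric("rpaMatrix", function(x) standardGeneric("rpaMatrix"))

#' Samples-by-metabolites RPA matrix
#' @rdname MetaboCohort
#' @export
setMethod("rpaMatrix", "MetaboCohort", function(x)
  t(SummarizedExperiment::assay(x, "rpa")))

#' @rdname MetaboCohort
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Named vector of group labels (NULL when unlabeled)
#' @rdname MetaboCohort
#' @export
setMethod("groupLabels", "MetaboCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"group" %in% colnames(cd)) return(NULL)
  stats::setNames(as.character(cd$group), rownames(cd))
})

setMethod("show", "MetaboCohort", function(object) {
  cat("MetaboCohort:", ncol(object), "samples x", nrow(object),
      "metabolites\n")
  g <- groupLabels(object)
  if (!is.null(g)) {
    tab <- table(g)
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else cat("  (unlabeled)\n")
})

setMethod("show", "PanelDefinition", function(object) {
  cat(sprintf("PanelDefinition (%s): %s vs %s, %d metabolite(s)\n",
              object@method, object@comparison[1], object@comparison[2],
              length(object@metabolites)))
  cat(" ", paste(object@metabolites, collapse = ", "), "\n")
  if (!is.na(object@learner)) cat("  learner:", object@learner, "\n")
})

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf("StabilityResult: %d splits (train fraction %.2f)\n",
              object@n_splits, object@train_fraction))
  cat(sprintf("  stability index = %.4f\n", object@stability_index))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %d %s classifiers, %s vs %s (case: %s)\n",
              length(object@classifiers), object@learner,
              object@class_labels[1], object@class_labels[2],
              object@case_label))
})

setMethod("show", "SubtypeCall", function(object) {
  cat("SubtypeCall:", object@mdd_call, "/", object@subtype, "\n")
  for (nm in names(object@component_votes)) {
    v <- object@component_votes[[nm]]
    cat(sprintf("  %s: P = %.3f -> %s\n", nm, v$P, v$label))
  }
})

#' Accessors for panels, stability results and ensembles
#'
#' @param x object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("panelMetabolites", function(x) standardGeneric("panelMetabolites"))

#' @rdname accessors
#' @export
setMethod("panelMetabolites", "PanelDefinition", function(x) x@metabolites)

#' @rdname accessors
#' @export
setGeneric("stabilityIndexValue",
           function(x) standardGeneric("stabilityIndexValue"))

#' @rdname accessors
#' @export
setMethod("stabilityIndexValue", "StabilityResult",
          function(x) x@stability_index)

#' @rdname accessors
#' @export
setGeneric("splitAccuracies", function(x) standardGeneric("splitAccuracies"))

#' @rdname accessors
#' @export
setMethod("splitAccuracies", "StabilityResult",
          function(x) x@split_accuracies)

#' @rdname accessors
#' @export
setGeneric("voteFraction", function(x) standardGeneric("voteFraction"))

#' @rdname accessors
#' @export
setMethod("voteFraction", "EnsemblePrediction", function(x) x@vote_fraction)

#' @rdname accessors
#' @export
setGeneric("predictedLabel", function(x) standardGeneric("predictedLabel"))

#' @rdname accessors
#' @export
setMethod("predictedLabel", "EnsemblePrediction",
          function(x) x@predicted_label)

#' @rdname accessors
#' @export
setGeneric("vipValues", function(x) standardGeneric("vipValues"))

#' @rdname accessors
#' @export
setMethod("vipValues", "VIPResult",
          function(x) stats::setNames(x@vip, x@metabolite_names))

#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname accessors
#' @export
setMethod("aucValue", "RocCurve", function(x) x@auc)

#' @rdname accessors
#' @export
setMethod("aucValue", "PanelEvaluation", function(x) x@auc)
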