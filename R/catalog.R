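## Packaged reference fixtures: the 35-metabolite plasma catalog (per-group
## means/SDs and VIP annotations), the published diagnostic panels, and the
## printed example classifier pair.

.catalogCache <- new.env(parent = emptyenv())

#' Load the packaged plasma-metabolite reference catalog
#'
#' Returns the 35-metabolite GC/MS plasma catalog: retention time, chemical
#' class, per-group RPA moments (mean, sd) for healthy controls, the pooled
#' MDD group and the two MDD subtypes (with and without early life stress),
#' and the VIP annotations from the four group-wise PLS-DA comparisons
#' (a: healthy vs MDD, b: healthy vs ELS/MDD, c: healthy vs non-ELS/MDD,
#' d: ELS/MDD vs non-ELS/MDD).
#'
#' Aspartic acid elutes as two peaks; its display label keeps the compound
#' retention time ("16.233+17.767") while its sort key is 16.233.
#'
#' @return a data.frame with one row per metabolite, ordered by retention
#'   time, with columns \code{index}, \code{retention_time},
#'   \code{retention_label}, \code{name}, \code{chemical_class},
#'   \code{{healthy,mdd,els,nonels}_{mean,sd}} and \code{vip_a..vip_d}
#'   (NA when the metabolite was not annotated in that comparison).
#' @examples
#' cat35 <- loadReferenceCatalog()
#' sum(!is.na(cat35$vip_a))   # 15 differential metabolites, healthy vs MDD
#' @export
loadReferenceCatalog <- function() {
  if (!is.null(.catalogCache$catalog)) return(.catalogCache$catalog)
  path <- system.file("extdata", "table2_catalog.tsv",
                      package = "MetaboPanel", mustWork = TRUE)
  cat35 <- utils::read.delim(path, sep = "\t", header = TRUE, fill = TRUE,
                             check.names = FALSE,
                             colClasses = c(rep(NA, 5), rep("numeric", 12)))
  stopifnot(nrow(cat35) == 35L, !anyDuplicated(cat35$name),
            !is.unsorted(cat35$retention_time),
            all(cat35$retention_time > 0),
            all(as.matrix(cat35[, grep("_mean$|_sd$", names(cat35))]) >= 0))
  .catalogCache$catalog <- cat35
  cat35
}

## (mean, sd) lookup for one group column set.
.catalogMoments <- function(group) {
  cat35 <- loadReferenceCatalog()
  prefix <- switch(group,
                   HEALTHY = "healthy", MDD_ALL = "mdd",
                   ELS_MDD = "els", NON_ELS_MDD = "nonels",
                   stop("unknown group: ", group))
  data.frame(name = cat35$name,
             mean = cat35[[paste0(prefix, "_mean")]],
             sd = cat35[[paste0(prefix, "_sd")]])
}

#' Load the printed example ensemble-member classifier
#'
#' The published example member of the healthy-control vs MDD ensemble: two
#' affine discriminant scores (one per class) over a nine-metabolite panel;
#' the class with the larger score wins.
#'
#' @return a list with elements \code{classifier}
#'   (\linkS4class{LinearClassifierPair}) and \code{panel}
#'   (\linkS4class{PanelDefinition}).
#' @examples
#' m <- loadPrintedModel()
#' m$classifier@control_coefficients[1]
#' @export
loadPrintedModel <- function() {
  path <- system.file("extdata", "printed_classifier.json",
                      package = "MetaboPanel", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  clf <- new("LinearClassifierPair",
             class_labels = j$class_labels,
             feature_names = j$feature_names,
             control_intercept = j$control_intercept,
             case_intercept = j$case_intercept,
             control_coefficients = j$control_coefficients,
             case_coefficients = j$case_coefficients)
  panel <- PanelDefinition(j$class_labels, "tclass", j$feature_names,
                           learner = "naive_bayes")
  list(classifier = clf, panel = panel)
}

#' Load the published diagnostic panels
#'
#' Eight panels: for each of the four two-group comparisons, the
#' VIP-ranked differential-metabolite panel (sizes 9/9/3/4) and the
#' forward-selected feature-combination panel (sizes 9/8/3/3).
#'
#' @return named list of \linkS4class{PanelDefinition}
#' @examples
#' panels <- loadReferencePanels()
#' lengths(lapply(panels, panelMetabolites))
#' @export
loadReferencePanels <- function() {
  path <- system.file("extdata", "reference_panels.json",
                      package = "MetaboPanel", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(j$panels, function(p)
    PanelDefinition(unlist(p$comparison), p$method, unlist(p$metabolites),
                    learner = if (is.null(p$learner)) NA_character_
                              else p$learner))
  names(out) <- vapply(j$panels, `[[`, "", "id")
  cat_names <- loadReferenceCatalog()$name
  for (p in out)
    stopifnot(all(panelMetabolites(p) %in% cat_names))
  out
}

#' Evaluate a linear classifier pair at a feature vector
#'
#' @param classifier a \linkS4class{LinearClassifierPair}
#' @param x numeric feature vector in the classifier's feature order (names,
#'   when present, are checked against the feature list).
#' @return list with \code{label}, \code{control_score}, \code{case_score};
#'   ties resolve to the control label.
#' @export
evaluateClassifierPair <- function(classifier, x) {
  stopifnot(is(classifier, "LinearClassifierPair"))
  p <- length(classifier@feature_names)
  if (length(x) != p)
    stop("feature vector length ", length(x), " != ", p)
  if (!is.null(names(x)) && !identical(names(x), classifier@feature_names))
    x <- x[classifier@feature_names]
  cs <- classifier@control_intercept + sum(classifier@control_coefficients * x)
  ks <- classifier@case_intercept + sum(classifier@case_coefficients * x)
  list(label = if (ks > cs) classifier@class_labels[2]
               else classifier@class_labels[1],
       control_score = cs, case_score = ks)
}
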