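#' Hierarchical diagnosis: MDD screen, then subtype by model agreement
#'
#' Stage 1 applies the healthy-vs-MDD ensemble: a negative screen returns
#' \code{NOT_MDD} with subtype \code{NOT_APPLICABLE}. Stage 2 calls a
#' subtype only when two independent ensembles agree: \code{ELS_MDD} iff
#' both the healthy-vs-ELS/MDD and the ELS-vs-non-ELS models vote ELS/MDD;
#' \code{NON_ELS_MDD} iff both the healthy-vs-non-ELS/MDD and the
#' ELS-vs-non-ELS models vote non-ELS/MDD. Any other vote pattern after a
#' positive screen is reported as \code{INDETERMINATE} rather than forced
#' into a subtype; all four component vote fractions are returned so
#' borderline calls can be audited.
#'
#' @param sample named numeric vector of RPAs covering every panel of the
#'   four models.
#' @param model_mdd ensemble for HEALTHY vs MDD (case: MDD_ALL).
#' @param model_hc_els ensemble for HEALTHY vs ELS_MDD (case: ELS_MDD).
#' @param model_hc_nonels ensemble for HEALTHY vs NON_ELS_MDD (case:
#'   NON_ELS_MDD).
#' @param model_els_nonels ensemble for ELS_MDD vs NON_ELS_MDD.
#' @return a \linkS4class{SubtypeCall}
#' @export
predictPatient <- function(sample, model_mdd, model_hc_els,
                           model_hc_nonels, model_els_nonels) {
  models <- list(mdd = model_mdd, hc_els = model_hc_els,
                 hc_nonels = model_hc_nonels, els_nonels = model_els_nonels)
  needed <- unique(unlist(lapply(models, function(m)
    panelMetabolites(m@panel))))
  if (is.null(names(sample)))
    stop("sample must be a named RPA vector")
  missing <- setdiff(needed, names(sample))
  if (length(missing))
    stop("missing required metabolite(s): ", paste(missing, collapse = ", "))
  votes <- lapply(models, function(m) {
    pr <- ensemblePredict(m, sample[panelMetabolites(m@panel)])
    list(P = voteFraction(pr), label = predictedLabel(pr))
  })
  if (votes$mdd$label != model_mdd@case_label)
    return(new("SubtypeCall", mdd_call = "NOT_MDD",
               subtype = "NOT_APPLICABLE", component_votes = votes))
  subtype <- if (votes$hc_els$label == "ELS_MDD" &&
                 votes$els_nonels$label == "ELS_MDD") {
    "ELS_MDD"
  } else if (votes$hc_nonels$label == "NON_ELS_MDD" &&
             votes$els_nonels$label == "NON_ELS_MDD") {
    "NON_ELS_MDD"
  } else "INDETERMINATE"
  new("SubtypeCall", mdd_call = "MDD", subtype = subtype,
      component_votes = votes)
}
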