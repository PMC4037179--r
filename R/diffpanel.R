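## Nested logistic-regression panels over VIP-ranked differential
## metabolites, scored by ROC AUC.

## Ridge-penalized logistic IRLS. The published panels reach AUC 1, i.e.
## complete separation, where the unpenalized MLE diverges; a small L2
## penalty on the slopes (none on the intercept) keeps the fit defined while
## leaving the score ranking — and hence the AUC — unchanged.
.ridgeLogit <- function(X, y, lambda = 1e-4, max_iter = 100L, tol = 1e-8) {
  n <- nrow(X); k <- ncol(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  pen <- diag(c(0, rep(lambda, k)), k + 1L)
  beta <- numeric(k + 1L)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    beta_new <- solve(XtW %*% Xd + pen, XtW %*% z)[, 1L]
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

#' Fit a penalized logistic model for a diagnostic panel
#'
#' Maximum penalized-likelihood linear logit of the case indicator on the
#' panel metabolites (ridge penalty 1e-4 on slopes, intercept unpenalized).
#' The returned score is the linear predictor; it is deterministic for fixed
#' input.
#'
#' @param cohort a labeled \linkS4class{MetaboCohort}
#' @param panel a \linkS4class{PanelDefinition}
#' @param comparison character(2): (control, case).
#' @return list with \code{coefficients} (intercept first), \code{score}
#'   (function mapping a samples-x-panel matrix to linear-predictor scores),
#'   \code{scores} (training-sample scores) and \code{y} (case indicator).
#' @export
fitLogistic <- function(cohort, panel, comparison) {
  stopifnot(is(panel, "PanelDefinition"))
  cd <- .comparisonData(cohort, comparison, panelMetabolites(panel))
  X <- cd$X
  const <- which(apply(X, 2, function(v) diff(range(v)) == 0))
  if (length(const))
    stop("zero-variance predictor(s): ",
         paste(colnames(X)[const], collapse = ", "))
  beta <- .ridgeLogit(X, cd$y)
  score <- function(newX) {
    newX <- as.matrix(newX)
    as.numeric(cbind(1, newX[, panelMetabolites(panel), drop = FALSE]) %*% beta)
  }
  list(coefficients = beta, score = score,
       scores = score(X), y = cd$y)
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random case outscores a random control,
#' with ties given half credit (the Mann-Whitney identity); equivalently the
#' trapezoidal area under the ROC curve. Computed via \pkg{pROC} with the
#' score direction fixed (higher score = case), so reversing the labels
#' yields 1 - AUC, not an auto-flipped value.
#'
#' @param scores numeric vector
#' @param labels binary vector (0/1, logical, or factor with the control
#'   level first)
#' @return a \linkS4class{RocCurve}
#' @export
rocAUC <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in labels")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  new("RocCurve", thresholds = r$thresholds,
      sensitivities = r$sensitivities, specificities = r$specificities,
      auc = as.numeric(r$auc))
}

#' Nested logistic panels over a VIP-ranked differential panel
#'
#' Fits one logistic model per k = 1..k_max on the top-k metabolites of the
#' (descending-VIP-ordered) differential panel and scores each by training
#' ROC AUC; the panels are nested prefixes.
#'
#' @param cohort labeled \linkS4class{MetaboCohort}
#' @param differential a \linkS4class{PanelDefinition} ordered by descending
#'   VIP (as produced by \code{\link{selectDifferential}}).
#' @param comparison character(2): (control, case).
#' @param k_max largest panel size, between 1 and the panel size.
#' @return list of \linkS4class{PanelEvaluation}, one per k
#' @export
buildNestedPanels <- function(cohort, differential, comparison,
                              k_max = min(9L, length(panelMetabolites(differential)))) {
  stopifnot(is(differential, "PanelDefinition"))
  mets <- panelMetabolites(differential)
  if (k_max < 1L || k_max > length(mets))
    stop("k_max must be between 1 and the panel size (", length(mets), ")")
  lapply(seq_len(k_max), function(k) {
    sub <- PanelDefinition(comparison, differential@method, mets[seq_len(k)])
    fit <- fitLogistic(cohort, sub, comparison)
    new("PanelEvaluation", panel = sub, k = as.integer(k),
        auc = aucValue(rocAUC(fit$scores, fit$y)),
        fitted_coefficients = fit$coefficients)
  })
}

#' Pick the best panel evaluation
#'
#' Highest AUC; among ties, the smallest panel (fewer metabolites make the
#' assay cheaper at equal discrimination).
#'
#' @param evaluations non-empty list of \linkS4class{PanelEvaluation}
#' @return the winning \linkS4class{PanelEvaluation}
#' @export
bestPanel <- function(evaluations) {
  if (!length(evaluations)) stop("no evaluations supplied")
  aucs <- vapply(evaluations, aucValue, numeric(1))
  ks <- vapply(evaluations, function(e) e@k, integer(1))
  best <- which(aucs == max(aucs))
  evaluations[[best[which.min(ks[best])]]]
}
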