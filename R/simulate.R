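#' Generate a synthetic three-group plasma cohort
#'
#' Draws sample-by-metabolite RPA tables with the statistical structure the
#' downstream analysis assumes, parameterized by the packaged reference
#' catalog, so every pipeline stage is exercisable without patient-level
#' data. Three modes:
#' \describe{
#'   \item{table2}{each metabolite is independent Gaussian per group with
#'     the catalog's (mean, sd) for that group: HEALTHY uses the healthy
#'     column, ELS_MDD and NON_ELS_MDD their subtype columns.}
#'   \item{null}{all groups are drawn from the HEALTHY parameters — a
#'     no-signal calibration cohort.}
#'   \item{separated}{group means are planted 10 pooled SDs apart on every
#'     metabolite (means 0, 10 s, 20 s with common sd s, the per-metabolite
#'     mean of the three catalog group SDs) — a fully separable cohort.}
#' }
#'
#' The default distribution is untruncated Gaussian so generated moments
#' match the catalog's printed mean/SD exactly; metabolites whose SD exceeds
#' their mean (e.g. sorbitol in healthy controls) then produce occasional
#' negative values, exactly as a Gaussian with those moments must.
#' \code{distribution = "nonneg"} instead redraws negative values (rejection
#' at zero), which biases the realized moments upward for those metabolites.
#'
#' @param mode "table2" (default), "null", or "separated".
#' @param n_per_group named integer vector; defaults to the study design
#'   c(HEALTHY = 25, ELS_MDD = 23, NON_ELS_MDD = 23).
#' @param seed integer; identical arguments and seed give an identical
#'   table.
#' @param distribution "gaussian" (default) or "nonneg".
#' @param metabolites optional subset of catalog metabolite names (default:
#'   all 35, in catalog order).
#' @return a labeled \linkS4class{MetaboCohort}
#' @examples
#' cohort <- generateCohort(seed = 1)
#' table(groupLabels(cohort))
#' @export
generateCohort <- function(mode = c("table2", "null", "separated"),
                           n_per_group = c(HEALTHY = 25L, ELS_MDD = 23L,
                                           NON_ELS_MDD = 23L),
                           seed = 1L,
                           distribution = c("gaussian", "nonneg"),
                           metabolites = NULL) {
  mode <- match.arg(mode)
  distribution <- match.arg(distribution)
  if (!all(names(n_per_group) %in% .GROUPS) || anyDuplicated(names(n_per_group)))
    stop("n_per_group must be named with groups among: ",
         paste(.GROUPS, collapse = ", "))
  if (any(n_per_group < 2L)) stop("need n >= 2 per group")
  cat35 <- loadReferenceCatalog()
  if (is.null(metabolites)) {
    metabolites <- cat35$name
  } else {
    unknown <- setdiff(metabolites, cat35$name)
    if (length(unknown))
      stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  }
  rows <- match(metabolites, cat35$name)
  group_sds <- cbind(cat35$healthy_sd, cat35$els_sd, cat35$nonels_sd)[rows, ,
                                                                     drop = FALSE]
  params <- lapply(stats::setNames(nm = names(n_per_group)), function(g) {
    switch(mode,
           table2 = {
             mm <- .catalogMoments(g)
             list(mean = mm$mean[rows], sd = mm$sd[rows])
           },
           null = {
             mm <- .catalogMoments("HEALTHY")
             list(mean = mm$mean[rows], sd = mm$sd[rows])
           },
           separated = {
             s <- rowMeans(group_sds)
             s[s <= 0] <- 1e-3
             shift <- 10 * s * (match(g, .GROUPS) - 1L)
             list(mean = shift, sd = s)
           })
  })
  .withSeed(seed, function() {
    blocks <- lapply(names(n_per_group), function(g) {
      n <- n_per_group[[g]]
      m <- vapply(seq_along(metabolites), function(j) {
        mu <- params[[g]]$mean[j]; s <- params[[g]]$sd[j]
        x <- stats::rnorm(n, mu, s)
        if (distribution == "nonneg") {
          while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mu, s)
        }
        x
      }, numeric(n))
      rownames(m) <- sprintf("%s_%03d", g, seq_len(n))
      m
    })
    values <- do.call(rbind, blocks)
    colnames(values) <- metabolites
    MetaboCohort(values,
                 groups = rep(names(n_per_group), n_per_group))
  })
}
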