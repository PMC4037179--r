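#' Internal-standard (relative peak area) normalization
#'
#' Converts raw peak intensities to relative peak areas (RPA): every
#' metabolite intensity in a sample is divided by that sample's
#' internal-standard peak intensity (the spiked-in standard, ribitol by
#' default, whose normalized intensity is thereby set to 1), and the
#' internal-standard column is dropped from the output.
#'
#' Normalization is per sample: each sample is scaled by its own standard, so
#' multiplying a whole sample (including the standard) by any c > 0 leaves
#' its RPA row unchanged.
#'
#' @param raw a \linkS4class{MetaboCohort} of raw (non-negative) peak
#'   intensities including the internal-standard column.
#' @param internal_standard name of the internal-standard metabolite column
#'   (default "Ribitol", matched case-insensitively).
#' @return a \linkS4class{MetaboCohort} of RPAs without the
#'   internal-standard column.
#' @examples
#' m <- matrix(c(3, 1.5, 6, 3), 2, 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("Alanine", "Ribitol")))
#' rpaMatrix(normalizeRPA(MetaboCohort(m)))   # both samples -> Alanine = 2
#' @export
normalizeRPA <- function(raw, internal_standard = "Ribitol") {
  stopifnot(is(raw, "MetaboCohort"))
  m <- rpaMatrix(raw)
  if (any(m < 0))
    stop("raw intensities must be non-negative")
  hit <- which(tolower(colnames(m)) == tolower(internal_standard))
  if (length(hit) != 1L)
    stop("internal-standard column '", internal_standard, "' not found")
  is_val <- m[, hit]
  bad <- which(is_val <= 0)
  if (length(bad))
    stop("internal-standard intensity <= 0 for sample(s): ",
         paste(rownames(m)[bad], collapse = ", "))
  out <- m[, -hit, drop = FALSE] / is_val
  MetaboCohort(out, groups = if (is.null(groupLabels(raw))) NULL
                             else unname(groupLabels(raw)[rownames(m)]))
}
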