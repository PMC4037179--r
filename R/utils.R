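## Internal helpers shared across modules.

## Evaluate fn() under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards.
.withSeed <- function(seed, fn) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

## Expand a (possibly derived) group label to its member stored labels.
.groupMembers <- function(group) {
  if (identical(group, "MDD_ALL")) c("ELS_MDD", "NON_ELS_MDD") else group
}

## Subset a labeled cohort to a two-group comparison; returns the feature
## matrix (samples x metabolites), a 0/1 case indicator and the sample labels
## mapped onto the comparison's (control, case) vocabulary.
.comparisonData <- function(cohort, comparison, metabolites = NULL) {
  stopifnot(is(cohort, "MetaboCohort"), length(comparison) == 2L)
  if (!all(comparison %in% .GROUPS_EXT))
    stop("unknown group in comparison: ",
         paste(setdiff(comparison, .GROUPS_EXT), collapse = ", "))
  g <- groupLabels(cohort)
  if (is.null(g)) stop("cohort has no group labels")
  lab <- rep(NA_character_, length(g))
  lab[g %in% .groupMembers(comparison[1L])] <- comparison[1L]
  lab[g %in% .groupMembers(comparison[2L])] <- comparison[2L]
  keep <- !is.na(lab)
  if (sum(lab[keep] == comparison[1L]) < 2L ||
      sum(lab[keep] == comparison[2L]) < 2L)
    stop("each comparison group needs at least 2 samples")
  X <- rpaMatrix(cohort)[keep, , drop = FALSE]
  if (!is.null(metabolites)) {
    missing <- setdiff(metabolites, colnames(X))
    if (length(missing))
      stop("metabolite(s) not in table: ", paste(missing, collapse = ", "))
    X <- X[, metabolites, drop = FALSE]
  }
  list(X = X, y = as.integer(lab[keep] == comparison[2L]),
       labels = lab[keep], sample_ids = rownames(X))
}

## Stratified random train/test splits on a canonical sample ordering.
## Returns a list of length n_splits; each element holds integer train/test
## indices into the canonical (sorted-by-id) ordering.
.drawSplits <- function(labels, sample_ids, n_splits, train_fraction, seed) {
  ord <- order(sample_ids)          # canonical ordering: sample-order invariance
  labels <- labels[ord]
  classes <- unique(labels)
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  n_test <- vapply(idx_by_class, function(ix)
    max(1L, as.integer(round((1 - train_fraction) * length(ix)))), integer(1))
  too_small <- vapply(seq_along(classes), function(i)
    length(idx_by_class[[i]]) - n_test[i] < 2L, logical(1))
  if (any(too_small))
    stop("class too small for stratified splitting: ",
         paste(classes[too_small], collapse = ", "))
  .withSeed(seed, function() {
    lapply(seq_len(n_splits), function(s) {
      test <- unlist(lapply(seq_along(classes), function(i)
        sample(idx_by_class[[i]], n_test[i])), use.names = FALSE)
      list(train = ord[setdiff(seq_along(labels), test)], test = ord[test])
    })
  })
}

## Canonical catalog ordering of a set of metabolite names (names absent from
## the catalog keep their incoming order, after catalog members).
.catalogOrder <- function(names) {
  cat_names <- loadReferenceCatalog()$name
  pos <- match(names, cat_names)
  pos[is.na(pos)] <- length(cat_names) + seq_len(sum(is.na(pos)))
  order(pos)
}
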