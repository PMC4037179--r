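## Tabular and JSON serialization. Sample tables are CSV/TSV with a header
## row: first column sample id, optional "group" column, remaining columns
## metabolite RPAs. Panels and ensemble models serialize to JSON with an
## explicit schema_version.

.sepForPath <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a sample-by-metabolite table
#'
#' @param path CSV (default) or TSV file; first column sample id, optional
#'   label column, one column per metabolite.
#' @param label_column name of the group-label column, or NULL for an
#'   unlabeled table. Default "group" (used only if present).
#' @return a \linkS4class{MetaboCohort}
#' @export
readSampleTable <- function(path, label_column = "group") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = .sepForPath(path), header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL, quote = "\"")
  if (ncol(df) < 2L) stop("table needs a sample-id column and at least one metabolite")
  hdr <- colnames(df)
  if (anyDuplicated(hdr))
    stop("duplicate column header(s): ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  groups <- NULL
  value_cols <- hdr[-1L]
  if (!is.null(label_column) && label_column %in% hdr) {
    groups <- df[[label_column]]
    bad <- setdiff(unique(groups), .GROUPS)
    if (length(bad))
      stop("unknown group label(s) in column '", label_column, "': ",
           paste(bad, collapse = ", "))
    value_cols <- setdiff(value_cols, label_column)
  }
  if (!length(value_cols)) stop("no metabolite columns found")
  vals <- matrix(NA_real_, nrow(df), length(value_cols),
                 dimnames = list(ids, value_cols))
  for (cn in value_cols) {
    raw <- df[[cn]]
    empty <- !nzchar(trimws(raw))
    if (any(empty))
      stop(sprintf("empty cell at row '%s', column '%s'",
                   ids[which(empty)[1L]], cn))
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   raw[which(is.na(v))[1L]], ids[which(is.na(v))[1L]], cn))
    vals[, cn] <- v
  }
  MetaboCohort(vals, groups = groups)
}

#' Write a sample table
#'
#' @param cohort a \linkS4class{MetaboCohort}
#' @param path output CSV/TSV path (separator chosen by extension).
#' @return \code{path}, invisibly
#' @export
writeSampleTable <- function(cohort, path) {
  stopifnot(is(cohort, "MetaboCohort"))
  m <- rpaMatrix(cohort)
  df <- data.frame(sample_id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  g <- groupLabels(cohort)
  if (!is.null(g)) df$group <- unname(g[rownames(m)])
  vals <- as.data.frame(m, check.names = FALSE)
  ## format() at full precision so read/write round-trips to < 1e-12
  vals[] <- lapply(vals, function(x) format(x, digits = 17, trim = TRUE,
                                            scientific = FALSE))
  df <- cbind(df, vals)
  utils::write.table(df, path, sep = .sepForPath(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a panel definition to JSON
#'
#' @param panel a \linkS4class{PanelDefinition}
#' @param path optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file)
#' @export
panelToJSON <- function(panel, path = NULL) {
  stopifnot(is(panel, "PanelDefinition"))
  obj <- list(schema_version = 1L,
              comparison = panel@comparison, method = panel@method,
              metabolites = panel@metabolites,
              learner = if (is.na(panel@learner)) NULL else panel@learner)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname panelToJSON
#' @param json JSON string or file path produced by \code{panelToJSON}
#' @export
panelFromJSON <- function(json) {
  j <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  PanelDefinition(j$comparison, j$method, j$metabolites,
                  learner = if (is.null(j$learner)) NA_character_ else j$learner)
}

.classifierToList <- function(clf) {
  stopifnot(is(clf, "TrainedClassifier"))
  if (clf@learner == "fisher") {
    lp <- clf@parameters
    list(control_intercept = lp@control_intercept,
         case_intercept = lp@case_intercept,
         control_coefficients = lp@control_coefficients,
         case_coefficients = lp@case_coefficients)
  } else {
    clf@parameters[c("means", "variances", "priors")]
  }
}

.classifierFromList <- function(x, learner, class_labels, panel) {
  params <- if (learner == "fisher") {
    new("LinearClassifierPair", class_labels = class_labels,
        feature_names = panel@metabolites,
        control_intercept = x$control_intercept,
        case_intercept = x$case_intercept,
        control_coefficients = as.numeric(x$control_coefficients),
        case_coefficients = as.numeric(x$case_coefficients))
  } else {
    nm <- function(l) {
      l <- lapply(l, function(v) unlist(v))
      names(l) <- c("control", "case")
      l
    }
    list(means = nm(x$means), variances = nm(x$variances),
         priors = stats::setNames(unlist(x$priors), c("control", "case")))
  }
  new("TrainedClassifier", learner = learner, class_labels = class_labels,
      panel = panel, parameters = params)
}

#' Serialize an ensemble model to JSON (all member coefficients included)
#'
#' @param model an \linkS4class{EnsembleModel}
#' @param path optional output path
#' @return JSON string, or \code{path} invisibly
#' @export
ensembleToJSON <- function(model, path = NULL) {
  stopifnot(is(model, "EnsembleModel"))
  obj <- list(schema_version = 1L,
              learner = model@learner,
              class_labels = model@class_labels,
              case_label = model@case_label,
              seed = model@seed,
              panel = list(comparison = model@panel@comparison,
                           method = model@panel@method,
                           metabolites = model@panel@metabolites),
              classifiers = lapply(model@classifiers, .classifierToList))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ensembleToJSON
#' @param json JSON string or file path produced by \code{ensembleToJSON}
#' @export
ensembleFromJSON <- function(json) {
  j <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  panel <- PanelDefinition(unlist(j$panel$comparison), j$panel$method,
                           unlist(j$panel$metabolites),
                           learner = j$learner)
  clfs <- lapply(j$classifiers, function(x) {
    x$control_coefficients <- unlist(x$control_coefficients)
    x$case_coefficients <- unlist(x$case_coefficients)
    .classifierFromList(x, j$learner, unlist(j$class_labels), panel)
  })
  new("EnsembleModel", classifiers = clfs, panel = panel,
      class_labels = unlist(j$class_labels), case_label = j$case_label,
      learner = j$learner, seed = as.integer(j$seed))
}
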