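# S4 containers for the two-view analysis. Subject and variable identity
# travel in dimnames; validity methods enforce the structural invariants so
# downstream code can assume them.

.checkIds <- function(ids, what) {
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    return(sprintf("%s must be non-empty and non-missing", what))
  if (anyDuplicated(ids))
    return(sprintf("duplicate %s", what))
  NULL
}

#' DataView: a subjects-by-variables numeric matrix
#'
#' The basic container for one "view" of the data: either the brain view
#' (subjects x connections) or the behaviour view (subjects x items).
#' Rows are subjects, columns are variables; both carry unique identifiers.
#' Missing entries (`NA`) are permitted only when `missingOk = TRUE`, the
#' convention used for the raw behaviour view before median imputation.
#'
#' @slot values numeric matrix with rownames (subject ids) and colnames
#'   (variable ids).
#' @slot missingOk logical scalar; whether `NA` entries are allowed.
#' @export
setClass("DataView",
         representation(values = "matrix", missingOk = "logical"),
         prototype(missingOk = FALSE))

setValidity("DataView", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  msg <- c(if (nrow(v)) .checkIds(rownames(v), "subject ids"),
           if (ncol(v)) .checkIds(colnames(v), "variable ids"))
  if (length(msg)) return(msg[1L])
  if (length(object@missingOk) != 1L || is.na(object@missingOk))
    return("missingOk must be TRUE or FALSE")
  bad <- if (object@missingOk) any(is.nan(v) | is.infinite(v))
         else any(!is.finite(v))
  if (bad) return("non-finite values (NA allowed only with missingOk = TRUE)")
  TRUE
})

#' Construct a DataView
#'
#' @param values numeric matrix (subjects in rows).
#' @param subjectIds,variableIds identifiers; default to the dimnames of
#'   `values`.
#' @param missingOk allow `NA` entries (behaviour view before imputation).
#' @return a \linkS4class{DataView}.
#' @examples
#' DataView(matrix(rnorm(6), 2, 3,
#'                 dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
#' @export
DataView <- function(values, subjectIds = rownames(values),
                     variableIds = colnames(values), missingOk = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(subjectIds), as.character(variableIds))
  new("DataView", values = values, missingOk = missingOk)
}

#' @describeIn DataView number of subjects (rows).
#' @param x a DataView.
#' @export
setMethod("nSubjects", "DataView", function(x) nrow(x@values))

#' @describeIn DataView number of variables (columns).
#' @export
setMethod("nVariables", "DataView", function(x) ncol(x@values))

#' @describeIn DataView subject identifiers.
#' @export
setMethod("subjectIds", "DataView", function(x) rownames(x@values))

#' @describeIn DataView variable identifiers.
#' @export
setMethod("variableIds", "DataView", function(x) colnames(x@values))

#' @describeIn DataView the underlying matrix.
#' @export
setMethod("viewValues", "DataView", function(x) x@values)

setMethod("show", "DataView", function(object) {
  cat(sprintf("DataView: %d subjects x %d variables%s\n",
              nrow(object@values), ncol(object@values),
              if (anyNA(object@values)) sprintf(" (%d missing entries)",
                                                sum(is.na(object@values)))
              else ""))
})

#' ConnectivityProfile: one subject's region-by-region correlation matrix
#'
#' A symmetric matrix of pairwise Pearson correlations between regional
#' time-series, unit diagonal, off-diagonal values in \[-1, 1\]. Asymmetry
#' beyond an absolute tolerance of 1e-8 is an error, never silently averaged.
#'
#' @slot matrix numeric r x r matrix with region ids as dimnames.
#' @export
setClass("ConnectivityProfile", representation(matrix = "matrix"))

setValidity("ConnectivityProfile", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || nrow(m) != ncol(m))
    return("matrix must be square and numeric")
  if (nrow(m) < 2L) return("need at least 2 regions")
  msg <- .checkIds(rownames(m), "region ids")
  if (!is.null(msg)) return(msg)
  if (!identical(rownames(m), colnames(m)))
    return("row and column region ids differ")
  if (any(!is.finite(m))) return("non-finite correlation values")
  if (max(abs(m - t(m))) > 1e-8)
    return("matrix is asymmetric beyond tolerance 1e-8")
  if (max(abs(diag(m) - 1)) > 1e-8) return("diagonal entries must equal 1")
  off <- m[upper.tri(m)]
  if (any(off < -1 - 1e-8 | off > 1 + 1e-8))
    return("off-diagonal correlations outside [-1, 1]")
  TRUE
})

#' Construct a ConnectivityProfile
#'
#' @param matrix symmetric correlation matrix.
#' @param regionIds region identifiers; default rownames of `matrix`.
#' @return a \linkS4class{ConnectivityProfile}.
#' @export
ConnectivityProfile <- function(matrix, regionIds = rownames(matrix)) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(regionIds)) regionIds <- sprintf("region-%03d", seq_len(nrow(matrix)))
  dimnames(matrix) <- list(as.character(regionIds), as.character(regionIds))
  new("ConnectivityProfile", matrix = matrix)
}

#' @describeIn ConnectivityProfile region identifiers.
#' @param x a ConnectivityProfile.
#' @export
setMethod("regionIds", "ConnectivityProfile", function(x) rownames(x@matrix))

setMethod("show", "ConnectivityProfile", function(object) {
  cat(sprintf("ConnectivityProfile: %d regions (%d unique connections)\n",
              nrow(object@matrix), nrow(object@matrix) * (nrow(object@matrix) - 1L) %/% 2L))
})

#' ConfoundTable: per-subject head motion and scanner site
#'
#' Mean and maximum framewise displacement (mm) summarize head motion during
#' the resting-state acquisition; `site` is the scanner-site label, later
#' expanded to one-hot columns for confound regression.
#'
#' @slot subjectIds character vector, unique.
#' @slot meanFd,maxFd non-negative numeric (mm), aligned with `subjectIds`.
#' @slot site character vector of site labels.
#' @export
setClass("ConfoundTable",
         representation(subjectIds = "character", meanFd = "numeric",
                        maxFd = "numeric", site = "character"))

setValidity("ConfoundTable", function(object) {
  n <- length(object@subjectIds)
  msg <- .checkIds(object@subjectIds, "subject ids")
  if (!is.null(msg)) return(msg)
  if (length(object@meanFd) != n || length(object@maxFd) != n ||
      length(object@site) != n)
    return("meanFd, maxFd and site must each have one entry per subject")
  if (any(object@meanFd < 0, na.rm = TRUE) || any(object@maxFd < 0, na.rm = TRUE))
    return("framewise displacement must be non-negative")
  TRUE
})

#' Construct a ConfoundTable
#'
#' @param subjectIds unique subject identifiers.
#' @param meanFd,maxFd per-subject mean / maximum framewise displacement (mm).
#' @param site per-subject scanner-site labels.
#' @return a \linkS4class{ConfoundTable}.
#' @export
ConfoundTable <- function(subjectIds, meanFd, maxFd, site) {
  new("ConfoundTable", subjectIds = as.character(subjectIds),
      meanFd = as.numeric(meanFd), maxFd = as.numeric(maxFd),
      site = as.character(site))
}

#' @describeIn ConfoundTable subject identifiers.
#' @param x a ConfoundTable.
#' @export
setMethod("subjectIds", "ConfoundTable", function(x) x@subjectIds)

#' @describeIn ConfoundTable number of subjects.
#' @export
setMethod("nSubjects", "ConfoundTable", function(x) length(x@subjectIds))

#' Coerce a ConfoundTable to data.frame
#' @param x a \linkS4class{ConfoundTable}.
#' @param ... ignored.
#' @return data.frame with columns subject_id, mean_fd, max_fd, site.
#' @export
as.data.frame.ConfoundTable <- function(x, ...) {
  data.frame(subject_id = x@subjectIds, mean_fd = x@meanFd,
             max_fd = x@maxFd, site = x@site, stringsAsFactors = FALSE)
}

setMethod("show", "ConfoundTable", function(object) {
  cat(sprintf("ConfoundTable: %d subjects, %d site(s) [%s]\n",
              length(object@subjectIds), length(unique(object@site)),
              paste(sort(unique(object@site)), collapse = ", ")))
})

#' DatasetBundle: aligned brain view, behaviour view and confounds
#'
#' The unit of analysis: both views and the confound table restricted to the
#' same subjects in the same order, so row i always refers to one subject.
#'
#' @slot brain \linkS4class{DataView} of connectivity variables.
#' @slot behaviour \linkS4class{DataView} of behavioural items.
#' @slot confounds \linkS4class{ConfoundTable}.
#' @export
setClass("DatasetBundle",
         representation(brain = "DataView", behaviour = "DataView",
                        confounds = "ConfoundTable"))

setValidity("DatasetBundle", function(object) {
  ids <- rownames(object@brain@values)
  if (!identical(ids, rownames(object@behaviour@values)))
    return("brain and behaviour views disagree on subjects or their order")
  if (!identical(ids, object@confounds@subjectIds))
    return("confounds disagree with the views on subjects or their order")
  TRUE
})

#' Construct a DatasetBundle
#'
#' Members must already share identical subject ids in identical order; use
#' [alignSubjects()] to intersect and reorder arbitrary inputs.
#'
#' @param brain,behaviour \linkS4class{DataView}s.
#' @param confounds a \linkS4class{ConfoundTable}.
#' @return a \linkS4class{DatasetBundle}.
#' @export
DatasetBundle <- function(brain, behaviour, confounds) {
  new("DatasetBundle", brain = brain, behaviour = behaviour,
      confounds = confounds)
}

#' @describeIn DatasetBundle subject identifiers (common order).
#' @param x a DatasetBundle.
#' @export
setMethod("subjectIds", "DatasetBundle", function(x) rownames(x@brain@values))

#' @describeIn DatasetBundle number of subjects.
#' @export
setMethod("nSubjects", "DatasetBundle", function(x) nrow(x@brain@values))

setMethod("show", "DatasetBundle", function(object) {
  cat(sprintf("DatasetBundle: %d subjects; brain %d variables, behaviour %d variables\n",
              nrow(object@brain@values), ncol(object@brain@values),
              ncol(object@behaviour@values)))
})

#' Restrict a bundle to a subset of subjects
#'
#' @param bundle a \linkS4class{DatasetBundle}.
#' @param ids subject ids to keep, in the desired order.
#' @return the restricted \linkS4class{DatasetBundle}.
#' @export
subsetSubjects <- function(bundle, ids) {
  stopifnot(is(bundle, "DatasetBundle"))
  ids <- as.character(ids)
  missing <- setdiff(ids, subjectIds(bundle))
  if (length(missing))
    stop("unknown subject ids: ", paste(missing, collapse = ", "))
  co <- bundle@confounds
  keep <- match(ids, co@subjectIds)
  DatasetBundle(
    brain = DataView(bundle@brain@values[ids, , drop = FALSE],
                     missingOk = bundle@brain@missingOk),
    behaviour = DataView(bundle@behaviour@values[ids, , drop = FALSE],
                         missingOk = bundle@behaviour@missingOk),
    confounds = ConfoundTable(ids, co@meanFd[keep], co@maxFd[keep],
                              co@site[keep]))
}

#' QcReport: machine-readable record of every exclusion and repair
#'
#' Accumulated across the preprocessing stages; every excluded subject carries
#' a reason code (`"max_fd"`, `"mean_fd"`), every removed variable the rule
#' that removed it.
#'
#' @slot excludedRegions character vector of region ids dropped by the
#'   low-signal filter.
#' @slot excludedSubjects data.frame with columns `subject_id`, `reason`.
#' @slot removedVariables character vector of behavioural items dropped by the
#'   near-constant filter.
#' @slot imputationCounts named integer vector: imputed entries per variable.
#' @slot notes character vector of free-text log lines.
#' @export
setClass("QcReport",
         representation(excludedRegions = "character",
                        excludedSubjects = "data.frame",
                        removedVariables = "character",
                        imputationCounts = "integer",
                        notes = "character"),
         prototype(excludedRegions = character(),
                   excludedSubjects = data.frame(subject_id = character(),
                                                 reason = character(),
                                                 stringsAsFactors = FALSE),
                   removedVariables = character(),
                   imputationCounts = integer(),
                   notes = character()))

setMethod("show", "QcReport", function(object) {
  cat("QcReport:\n")
  cat(sprintf("  excluded regions : %d\n", length(object@excludedRegions)))
  cat(sprintf("  excluded subjects: %d\n", nrow(object@excludedSubjects)))
  cat(sprintf("  removed variables: %d\n", length(object@removedVariables)))
  cat(sprintf("  imputed entries  : %d\n", sum(object@imputationCounts)))
  for (n in object@notes) cat("  note:", n, "\n")
})

#' Serialize a QcReport to JSON
#'
#' @param report a \linkS4class{QcReport}.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
writeQcReport <- function(report, path = NULL) {
  stopifnot(is(report, "QcReport"))
  x <- list(excluded_regions = report@excludedRegions,
            excluded_subjects = report@excludedSubjects,
            removed_variables = report@removedVariables,
            imputation_counts = as.list(report@imputationCounts),
            notes = report@notes)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

# merge two reports stage-wise
.mergeQc <- function(a, b) {
  new("QcReport",
      excludedRegions = c(a@excludedRegions, b@excludedRegions),
      excludedSubjects = rbind(a@excludedSubjects, b@excludedSubjects),
      removedVariables = c(a@removedVariables, b@removedVariables),
      imputationCounts = c(a@imputationCounts, b@imputationCounts),
      notes = c(a@notes, b@notes))
}
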