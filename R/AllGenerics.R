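#' @import methods
NULL

#' Subject identifiers
#'
#' @param x a \linkS4class{DataView}, \linkS4class{ConfoundTable} or
#'   \linkS4class{DatasetBundle}.
#' @return character vector of subject ids, in storage order.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Variable identifiers of a data view
#'
#' @param x a \linkS4class{DataView}.
#' @return character vector of variable ids.
#' @export
setGeneric("variableIds", function(x) standardGeneric("variableIds"))

#' Number of subjects
#' @param x an object holding per-subject rows.
#' @return integer count.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Number of variables
#' @param x a \linkS4class{DataView}.
#' @return integer count.
#' @export
setGeneric("nVariables", function(x) standardGeneric("nVariables"))

#' Numeric matrix held by a data view
#'
#' @param x a \linkS4class{DataView}.
#' @return the subjects-by-variables numeric matrix (with dimnames).
#' @export
setGeneric("viewValues", function(x) standardGeneric("viewValues"))

#' Region identifiers
#' @param x a \linkS4class{ConnectivityProfile}.
#' @return character vector of region ids.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' Canonical correlations of a fitted model
#'
#' @param x a \linkS4class{CcaModel} or \linkS4class{PermutationResult}.
#' @return numeric vector, one entry per mode, non-increasing.
#' @export
setGeneric("canonicalCorrelations",
           function(x) standardGeneric("canonicalCorrelations"))

#' Canonical variates (subject scores)
#'
#' @param x a \linkS4class{CcaModel}.
#' @param side `"x"` for the brain-view variates, `"y"` for behaviour.
#' @return n-by-d numeric matrix of subject scores.
#' @export
setGeneric("variates", function(x, side = c("x", "y")) standardGeneric("variates"))

#' Family-wise-error corrected p-values
#' @param x a \linkS4class{PermutationResult}.
#' @return numeric vector of per-mode FWE p-values.
#' @export
setGeneric("pFwe", function(x) standardGeneric("pFwe"))

#' Selected PCA dimensionality
#' @param x a \linkS4class{ModelSelectionResult}.
#' @return integer, or `NA` when no candidate reached significance.
#' @export
setGeneric("chosenDim", function(x) standardGeneric("chosenDim"))
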