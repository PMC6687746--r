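# Result containers for the statistical stages.

#' PcaModel: a fitted principal component reduction
#'
#' Basis vectors live in variable space and are orthonormal; component signs
#' are fixed so that each basis vector's largest-magnitude element is
#' positive, making the decomposition reproducible.
#'
#' @slot basis m x d orthonormal matrix of component directions.
#' @slot scores n x d matrix of component scores (projections).
#' @slot center length-m numeric: the column means removed before projection.
#' @slot explainedVariance length-d fractions of total variance, non-increasing.
#' @slot totalVariance total variance of the training data.
#' @slot d number of retained components.
#' @export
setClass("PcaModel",
         representation(basis = "matrix", scores = "matrix",
                        center = "numeric", explainedVariance = "numeric",
                        totalVariance = "numeric", d = "integer"))

setValidity("PcaModel", function(object) {
  d <- object@d
  if (ncol(object@basis) != d || ncol(object@scores) != d ||
      length(object@explainedVariance) != d)
    return("dimension mismatch between slots and d")
  g <- crossprod(object@basis)
  if (max(abs(g - diag(d))) > 1e-6) return("basis columns not orthonormal")
  ev <- object@explainedVariance
  if (any(ev < -1e-12 | ev > 1 + 1e-12)) return("explained fractions outside [0,1]")
  if (d > 1 && any(diff(ev) > 1e-12)) return("explained fractions must be non-increasing")
  if (sum(ev) > 1 + 1e-8) return("explained fractions sum above 1")
  TRUE
})

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d components over %d variables; cumulative variance %.1f%%\n",
              object@d, nrow(object@basis), 100 * sum(object@explainedVariance)))
})

#' CcaModel: a fitted canonical correlation analysis
#'
#' One CCA mode pairs a canonical basis vector per view with a pair of
#' canonical variates (per-subject scores). Variates are normalized to unit
#' sample variance; canonical correlations are non-increasing in \[0, 1\].
#' Mode signs are fixed so each mode's y-side weight vector has its
#' largest-magnitude element positive (u/P_X flipped jointly with v/P_Y).
#'
#' @slot d number of modes.
#' @slot xWeights,yWeights dx x d / dy x d canonical weight matrices applied
#'   to the centred reduced views.
#' @slot correlations length-d canonical correlations (the vector q).
#' @slot xVariates,yVariates n x d canonical variates (P_X, P_Y).
#' @slot xCenter,yCenter column means of the training reduced views, used to
#'   centre new data before projection.
#' @export
setClass("CcaModel",
         representation(d = "integer", xWeights = "matrix",
                        yWeights = "matrix", correlations = "numeric",
                        xVariates = "matrix", yVariates = "matrix",
                        xCenter = "numeric", yCenter = "numeric"))

setValidity("CcaModel", function(object) {
  d <- object@d
  q <- object@correlations
  if (length(q) != d || ncol(object@xVariates) != d || ncol(object@yVariates) != d)
    return("dimension mismatch between slots and d")
  if (any(q < -1e-8 | q > 1 + 1e-8)) return("canonical correlations outside [0,1]")
  if (d > 1 && any(diff(q) > 1e-8)) return("canonical correlations must be non-increasing")
  n <- nrow(object@xVariates)
  v <- apply(object@xVariates, 2, stats::var)
  if (max(abs(v - 1)) > 1e-6) return("x variates must have unit sample variance")
  v <- apply(object@yVariates, 2, stats::var)
  if (max(abs(v - 1)) > 1e-6) return("y variates must have unit sample variance")
  TRUE
})

#' @describeIn CcaModel the canonical correlations q.
#' @param x a CcaModel.
#' @export
setMethod("canonicalCorrelations", "CcaModel", function(x) x@correlations)

#' @describeIn CcaModel canonical variates of one side.
#' @param side `"x"` (brain) or `"y"` (behaviour).
#' @export
setMethod("variates", "CcaModel", function(x, side = c("x", "y")) {
  side <- match.arg(side)
  if (side == "x") x@xVariates else x@yVariates
})

setMethod("show", "CcaModel", function(object) {
  cat(sprintf("CcaModel: %d modes on %d subjects\n  q = %s\n",
              object@d, nrow(object@xVariates),
              paste(sprintf("%.3f", object@correlations), collapse = ", ")))
})

#' PermutationResult: max-statistic FWE inference for one PCA dimensionality
#'
#' Holds the true canonical correlations, the d x n_perm null matrix Q* of
#' ordered permuted correlations, and the per-mode family-wise-error p-values
#' obtained by comparing each true correlation with the null distribution of
#' the first (largest) permuted correlation.
#'
#' @slot d PCA dimensionality used.
#' @slot trueCorrelations length-d canonical correlations of the observed data.
#' @slot nullMatrix d x nPerm matrix; each column holds one permutation's
#'   ordered canonical correlations (non-increasing down the column).
#' @slot pFwe length-d p-values, non-decreasing across modes.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed; re-running with it reproduces the permutation sequence
#'   bit for bit.
#' @export
setClass("PermutationResult",
         representation(d = "integer", trueCorrelations = "numeric",
                        nullMatrix = "matrix", pFwe = "numeric",
                        nPerm = "integer", seed = "integer"))

setValidity("PermutationResult", function(object) {
  d <- object@d
  if (length(object@trueCorrelations) != d || length(object@pFwe) != d)
    return("dimension mismatch")
  if (nrow(object@nullMatrix) != d || ncol(object@nullMatrix) != object@nPerm)
    return("nullMatrix must be d x nPerm")
  p <- object@pFwe
  if (any(p < 0 | p > 1)) return("p-values outside [0,1]")
  if (d > 1 && any(diff(p) < -1e-12))
    return("FWE p-values must be non-decreasing across modes")
  if (d > 1 && any(apply(object@nullMatrix, 2, function(col) any(diff(col) > 1e-8))))
    return("null correlations must be ordered within each permutation")
  TRUE
})

#' @describeIn PermutationResult the per-mode FWE p-values.
#' @param x a PermutationResult.
#' @export
setMethod("pFwe", "PermutationResult", function(x) x@pFwe)

#' @describeIn PermutationResult the observed canonical correlations.
#' @export
setMethod("canonicalCorrelations", "PermutationResult",
          function(x) x@trueCorrelations)

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: d = %d, %d permutations (seed %d)\n",
              object@d, object@nPerm, object@seed))
  cat(sprintf("  q     = %s\n",
              paste(sprintf("%.3f", object@trueCorrelations), collapse = ", ")))
  cat(sprintf("  p_FWE = %s\n",
              paste(formatPermutationP(object@pFwe, object@nPerm), collapse = ", ")))
})

#' ModelSelectionResult: Bonferroni-corrected choice of PCA dimensionality
#'
#' One permutation test per candidate dimensionality; the first-mode p-value
#' of each candidate is Bonferroni-corrected over the grid and the optimal d
#' is the significant candidate with the lowest corrected p (ties broken by
#' the smaller d).
#'
#' @slot candidateDs integer grid of dimensionalities tested.
#' @slot firstModeP uncorrected first-mode p per candidate.
#' @slot correctedP Bonferroni-corrected p per candidate.
#' @slot alpha nominal family-wise level.
#' @slot bonferroniAlpha per-candidate threshold alpha / n_candidates.
#' @slot chosenD selected dimensionality; `NA` when no candidate is significant.
#' @slot results list of \linkS4class{PermutationResult}, one per candidate.
#' @export
setClass("ModelSelectionResult",
         representation(candidateDs = "integer", firstModeP = "numeric",
                        correctedP = "numeric", alpha = "numeric",
                        bonferroniAlpha = "numeric", chosenD = "integer",
                        results = "list"))

setValidity("ModelSelectionResult", function(object) {
  k <- length(object@candidateDs)
  if (length(object@firstModeP) != k || length(object@correctedP) != k ||
      length(object@results) != k)
    return("one entry per candidate required")
  if (!is.na(object@chosenD)) {
    i <- match(object@chosenD, object@candidateDs)
    if (is.na(i)) return("chosenD not among candidates")
    if (object@correctedP[i] > min(object@correctedP) + 1e-15)
      return("chosenD must attain the minimal corrected p")
  }
  TRUE
})

#' @describeIn ModelSelectionResult the selected dimensionality.
#' @param x a ModelSelectionResult.
#' @export
setMethod("chosenDim", "ModelSelectionResult", function(x) x@chosenD)

setMethod("show", "ModelSelectionResult", function(object) {
  cat(sprintf("ModelSelectionResult: %d candidates, alpha %.3g (per-candidate %.4g)\n",
              length(object@candidateDs), object@alpha, object@bonferroniAlpha))
  df <- data.frame(d = object@candidateDs, p = object@firstModeP,
                   p_corr = object@correctedP)
  print(df, row.names = FALSE)
  if (is.na(object@chosenD)) cat("  no significant candidate\n")
  else cat(sprintf("  chosen d = %d\n", object@chosenD))
})

#' SplitPlan: reproducible train/test partitions for hold-out validation
#'
#' @slot nSplits number of random splits.
#' @slot testFraction fraction of subjects held out per split, in (0, 0.5).
#' @slot seed RNG seed the plan was drawn with.
#' @slot splits list of `list(train =, test =)` character id vectors.
#' @export
setClass("SplitPlan",
         representation(nSplits = "integer", testFraction = "numeric",
                        seed = "integer", splits = "list"))

setValidity("SplitPlan", function(object) {
  if (length(object@splits) != object@nSplits) return("one entry per split required")
  for (s in object@splits) {
    if (length(intersect(s$train, s$test)))
      return("train and test sets overlap")
  }
  TRUE
})

setMethod("show", "SplitPlan", function(object) {
  nt <- if (object@nSplits) length(object@splits[[1]]$test) else 0L
  cat(sprintf("SplitPlan: %d splits, %d test subjects each (fraction %.2f, seed %d)\n",
              object@nSplits, nt, object@testFraction, object@seed))
})

#' HoldoutResult: multiple hold-out validation of the first CCA mode
#'
#' Per split: dimensionality used, in-sample (train) and out-of-sample (test)
#' first-mode canonical correlations, and a permutation p-value obtained by
#' shuffling the test subjects' behaviour rows. The omnibus decision is
#' Bonferroni over splits: significant iff any split's p falls below
#' alpha / n_splits.
#'
#' @slot splits data.frame with columns split, d, train_cor, test_cor, p.
#' @slot alpha nominal level of the omnibus test.
#' @slot omnibusP min over splits of p, Bonferroni-adjusted (capped at 1).
#' @slot significant logical omnibus decision.
#' @slot nPerm permutations per split.
#' @slot seed RNG seed of the run.
#' @export
setClass("HoldoutResult",
         representation(splits = "data.frame", alpha = "numeric",
                        omnibusP = "numeric", significant = "logical",
                        nPerm = "integer", seed = "integer"))

setValidity("HoldoutResult", function(object) {
  df <- object@splits
  need <- c("split", "d", "train_cor", "test_cor", "p")
  if (!all(need %in% names(df))) return("splits table lacks required columns")
  if (any(df$test_cor < -1 - 1e-8 | df$test_cor > 1 + 1e-8))
    return("test correlations outside [-1, 1]")
  k <- nrow(df)
  expect <- min(1, min(df$p) * k)
  if (abs(object@omnibusP - expect) > 1e-12)
    return("omnibus p inconsistent with the per-split p-values")
  if (!identical(object@significant, min(df$p) < object@alpha / k))
    return("omnibus decision inconsistent with the declared rule")
  TRUE
})

setMethod("show", "HoldoutResult", function(object) {
  cat(sprintf("HoldoutResult: %d splits, %d permutations each (seed %d)\n",
              nrow(object@splits), object@nPerm, object@seed))
  print(object@splits, row.names = FALSE, digits = 3)
  cat(sprintf("  omnibus p = %.4g -> %s at alpha %.2f\n", object@omnibusP,
              if (object@significant) "significant" else "not significant",
              object@alpha))
})
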