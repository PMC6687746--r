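# Multiple hold-out validation: repeated train/test splits in which every
# estimate — preprocessing parameters, PCA bases, canonical weights — comes
# from training subjects only, and significance is assessed on the projected
# test-subject correlation with an omnibus Bonferroni decision over splits.

#' Draw a reproducible train/test split plan
#'
#' @param subjectIds character vector of subject ids to split.
#' @param nSplits number of independent random splits (default 10).
#' @param testFraction fraction of subjects held out per split; must lie in
#'   (0, 0.5) so training always dominates (default 0.2).
#' @param seed integer RNG seed; the same seed reproduces the identical plan.
#' @return a \linkS4class{SplitPlan}.
#' @export
makeSplits <- function(subjectIds, nSplits = 10L, testFraction = 0.2,
                       seed = 1L) {
  subjectIds <- as.character(subjectIds)
  if (anyDuplicated(subjectIds)) stop("duplicate subject ids")
  if (!.isCount(nSplits)) stop("nSplits must be a positive integer")
  if (testFraction <= 0 || testFraction >= 0.5)
    stop("testFraction must lie in (0, 0.5)")
  n <- length(subjectIds)
  nTest <- as.integer(roundHalfAway(testFraction * n))
  if (nTest < 1L || n - nTest < 3L)
    stop("too few subjects for this test fraction")
  set.seed(as.integer(seed))
  splits <- lapply(seq_len(nSplits), function(s) {
    test <- sort(sample(subjectIds, nTest))
    list(train = setdiff(subjectIds, test), test = test)
  })
  new("SplitPlan", nSplits = as.integer(nSplits),
      testFraction = testFraction, seed = as.integer(seed), splits = splits)
}

#' Multiple hold-out validation of the first CCA mode
#'
#' Per split: the preprocessing pipeline is fitted on the training subjects
#' and replayed on the test subjects with training-derived parameters (no
#' test-set leakage); the PCA dimensionality is either the single value in
#' `candidateDs` or selected on training data only via
#' [selectPcaDimension()]; the CCA is fitted on training PCA scores and the
#' test subjects are projected through the trained model. The out-of-sample
#' statistic is the Pearson correlation of the first pair of test variates;
#' its permutation p-value shuffles the test subjects' behaviour rows
#' (one-sided, since training orients the pair toward a positive train
#' correlation). Omnibus rule: the effect replicates if any split's p falls
#' below `alpha / nSplits`.
#'
#' @param bundle an unpreprocessed \linkS4class{DatasetBundle}.
#' @param candidateDs PCA dimensionality (length 1) or candidate grid for
#'   training-side selection.
#' @param splitPlan a \linkS4class{SplitPlan}; defaults to 10 splits at test
#'   fraction 0.2 drawn with `seed`.
#' @param nPerm permutations per split (default 1000).
#' @param alpha omnibus level (default 0.05).
#' @param seed master seed for the permutations (and the default split plan).
#' @param config preprocessing settings, see [preprocessConfig()].
#' @param selectionPerm permutations used inside the training-side
#'   dimensionality selection when `candidateDs` has length > 1.
#' @return a \linkS4class{HoldoutResult}.
#' @export
holdoutRun <- function(bundle, candidateDs = 10L, splitPlan = NULL,
                       nPerm = 1000, alpha = 0.05, seed = 1L,
                       config = preprocessConfig(), selectionPerm = 200) {
  stopifnot(is(bundle, "DatasetBundle"))
  if (is.null(splitPlan))
    splitPlan <- makeSplits(subjectIds(bundle), seed = seed)
  stopifnot(is(splitPlan, "SplitPlan"))
  candidateDs <- as.integer(candidateDs)

  rows <- vector("list", splitPlan@nSplits)
  for (s in seq_len(splitPlan@nSplits)) {
    sp <- splitPlan@splits[[s]]
    train <- preprocessPipeline(subsetSubjects(bundle, sp$train), config)
    test <- preprocessApply(train$model, subsetSubjects(bundle, sp$test))

    d <- if (length(candidateDs) > 1L) {
      sel <- selectPcaDimension(train$bundle@brain, train$bundle@behaviour,
                                candidateDs = candidateDs,
                                nPerm = selectionPerm, alpha = alpha,
                                seed = deriveSeed(seed, 1000L + s))
      if (is.na(chosenDim(sel))) candidateDs[1L] else chosenDim(sel)
    } else candidateDs

    pcaX <- pcaReduce(train$bundle@brain, d)
    pcaY <- pcaReduce(train$bundle@behaviour, d)
    cca <- fitCca(pcaX@scores, pcaY@scores)
    proj <- projectCca(cca, pcaX, pcaY, test$bundle@brain,
                       test$bundle@behaviour)
    testCor <- stats::cor(proj$x[, 1L], proj$y[, 1L])

    nTest <- nrow(proj$x)
    set.seed(deriveSeed(seed, s))
    nullCor <- vapply(seq_len(nPerm), function(b)
      stats::cor(proj$x[, 1L], proj$y[sample.int(nTest), 1L]), 0)
    p <- (1 + sum(nullCor >= testCor)) / (1 + nPerm)

    rows[[s]] <- data.frame(split = s, d = d,
                            train_cor = cca@correlations[1L],
                            test_cor = testCor, p = p)
  }
  df <- do.call(rbind, rows)
  k <- nrow(df)
  new("HoldoutResult", splits = df, alpha = alpha,
      omnibusP = min(1, min(df$p) * k),
      significant = min(df$p) < alpha / k,
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}
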