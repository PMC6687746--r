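test_that("perfectly coupled views attain the minimal reportable p-value", {
  set.seed(5)
  x <- matrix(rnorm(100 * 6), 100, 6)
  res <- permutationPvalues(x, x, d = 3, nPerm = 99, seed = 2)
  expect_equal(res@trueCorrelations, rep(1, 3), tolerance = 1e-8)
  expect_equal(res@pFwe[1], 1 / 100)   # (1+0)/(1+99): no permutation reaches 1
  expect_equal(formatPermutationP(res@pFwe[1], 99), "< 0.01")
})

test_that("p-values are valid, monotone and bit-reproducible under a seed", {
  cfg <- syntheticConfig(n = 80, p = 15, q = 15, K = 1, aX = 1.2, aY = 1.2,
                         nNearConstant = 0, missingRate = 0, seed = 4)
  pp <- preprocessPipeline(generateDataset(cfg)$bundle)
  r1 <- permutationPvalues(pp$bundle@brain, pp$bundle@behaviour, d = 4,
                           nPerm = 199, seed = 7)
  r2 <- permutationPvalues(pp$bundle@brain, pp$bundle@behaviour, d = 4,
                           nPerm = 199, seed = 7)
  expect_identical(r1@nullMatrix, r2@nullMatrix)
  expect_identical(r1@pFwe, r2@pFwe)
  expect_true(all(diff(r1@pFwe) >= 0))
  expect_true(all(r1@pFwe >= 1 / 200 & r1@pFwe <= 1))
  # null columns are ordered (each permutation's correlations sorted)
  expect_true(all(apply(r1@nullMatrix, 2, function(cl) all(diff(cl) <= 1e-8))))
  # identity permutation would reproduce the true correlations
  qx <- ccamodes:::.qrView(pcaReduce(pp$bundle@brain, 4)@scores, "x")
  qy <- ccamodes:::.qrView(pcaReduce(pp$bundle@behaviour, 4)@scores, "y")
  expect_equal(ccamodes:::.canonicalCorrFromQ(qx$Q, qy$Q),
               r1@trueCorrelations, tolerance = 1e-10)
})

test_that("family-wise error is controlled under the global null", {
  cfg <- syntheticConfig(n = 60, p = 12, q = 12, K = 0, aX = numeric(),
                         aY = numeric(), nNearConstant = 0, missingRate = 0,
                         seed = 1)
  bundles <- generateNullSuite(cfg, nDatasets = 50, seed = 99L)
  hits <- vapply(seq_along(bundles), function(i) {
    pp <- preprocessPipeline(bundles[[i]])
    res <- permutationPvalues(pp$bundle@brain, pp$bundle@behaviour, d = 3,
                              nPerm = 99, seed = 100L + i)
    any(res@pFwe < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 50))
})

test_that("significant modes form a prefix selected by strict alpha", {
  res <- new("PermutationResult", d = 3L,
             trueCorrelations = c(0.62, 0.58, 0.30),
             nullMatrix = matrix(rep(c(0.3, 0.2, 0.1), 10), 3),
             pFwe = c(0.0001, 0.013, 0.4), nPerm = 10L, seed = 1L)
  expect_equal(significantModes(res), c(1L, 2L))
  expect_equal(significantModes(res, alpha = 0.01), 1L)
  expect_equal(significantModes(res, alpha = 1e-5), integer(0))
})

test_that("dimensionality selection applies Bonferroni and the tie-break", {
  cfg <- syntheticConfig(n = 100, p = 20, q = 20, K = 1, aX = 2, aY = 2,
                         nNearConstant = 0, missingRate = 0, seed = 6)
  pp <- preprocessPipeline(generateDataset(cfg)$bundle)
  sel <- selectPcaDimension(pp$bundle@brain, pp$bundle@behaviour,
                            candidateDs = c(2, 4, 8), nPerm = 199, seed = 3)
  expect_equal(sel@bonferroniAlpha, 0.05 / 3)
  expect_equal(sel@correctedP, pmin(1, sel@firstModeP * 3))
  # strong planted signal: every candidate attains the floor, smallest d wins
  expect_equal(sel@firstModeP, rep(1 / 200, 3))
  expect_equal(chosenDim(sel), 2L)

  # single candidate: threshold is alpha itself
  sel1 <- selectPcaDimension(pp$bundle@brain, pp$bundle@behaviour,
                             candidateDs = 4, nPerm = 99, seed = 3)
  expect_equal(sel1@bonferroniAlpha, 0.05)
  expect_equal(chosenDim(sel1), 4L)
})

test_that("null data yields a flagged no-significant-mode result, not an error", {
  set.seed(123)
  x <- matrix(rnorm(40 * 10), 40, 10)
  y <- matrix(rnorm(40 * 10), 40, 10)
  sel <- selectPcaDimension(x, y, candidateDs = c(2, 3), nPerm = 99, seed = 5)
  expect_true(is.na(chosenDim(sel)))
  expect_true(all(sel@firstModeP > sel@bonferroniAlpha))
})
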