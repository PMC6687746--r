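test_that("PCA fractions match a direct eigendecomposition oracle", {
  set.seed(21)
  x <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("v%02d", 1:10)))
  model <- pcaReduce(x, 10)
  ev <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(model@explainedVariance, ev / sum(ev), tolerance = 1e-10)
  expect_equal(model@totalVariance, sum(ev), tolerance = 1e-10)
  expect_equal(sum(pcaReduce(x, min(19, 10))@explainedVariance), 1,
               tolerance = 1e-10)

  # rank-1 signal dominates
  r1 <- outer(rnorm(30), rnorm(8)) + 1e-4 * matrix(rnorm(240), 30, 8)
  expect_gt(pcaReduce(r1, 2)@explainedVariance[1], 0.999)

  # scores equal projections onto the basis, signs deterministic
  expect_equal(model@scores, sweep(x, 2, colMeans(x)) %*% model@basis)
  expect_true(all(apply(model@basis, 2, function(b) b[which.max(abs(b))] > 0)))
  expect_error(pcaReduce(x, 20), "d must be")
})

test_that("PCA projection reproduces training scores and checks variables", {
  set.seed(3)
  x <- matrix(rnorm(15 * 6), 15, 6, dimnames = list(NULL, letters[1:6]))
  m <- pcaReduce(x, 3)
  expect_equal(pcaProject(m, x), m@scores)
  expect_error(pcaProject(m, x[, 1:5]), "variable count")
})

test_that("CCA matches the generalized-eigenvalue oracle and cancor", {
  set.seed(50)
  xd <- matrix(rnorm(50 * 3), 50, 3)
  yd <- 0.5 * xd %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(150), 50, 3)
  fit <- fitCca(xd, yd)
  expect_equal(fit@correlations, ccaOracleCorrelations(xd, yd), tolerance = 1e-8)
  expect_equal(fit@correlations, stats::cancor(xd, yd)$cor, tolerance = 1e-8)

  # structural invariants of the fit
  px <- fit@xVariates; py <- fit@yVariates
  expect_equal(unname(apply(px, 2, var)), rep(1, 3), tolerance = 1e-8)
  expect_lt(max(abs(cor(px)[upper.tri(diag(3))])), 1e-8)
  expect_lt(max(abs(cor(py)[upper.tri(diag(3))])), 1e-8)
  for (k in 1:3)
    expect_equal(cor(px[, k], py[, k]), fit@correlations[k], tolerance = 1e-8)
})

test_that("CCA degenerate and small cases behave as expected", {
  set.seed(8)
  xd <- matrix(rnorm(40 * 2), 40, 2)
  expect_equal(fitCca(xd, xd)@correlations, c(1, 1), tolerance = 1e-8)

  a <- rnorm(30); b <- 0.3 * a + rnorm(30)
  expect_equal(fitCca(cbind(a), cbind(b))@correlations,
               abs(cor(a, b)), tolerance = 1e-10)

  expect_error(fitCca(xd, matrix(rnorm(39 * 2), 39, 2)), "disagree")
  expect_error(fitCca(cbind(a, a), cbind(b, rnorm(30))), "rank-deficient")
  expect_error(fitCca(matrix(rnorm(4), 2, 2), matrix(rnorm(4), 2, 2)),
               "more subjects")
})

test_that("canonical correlations are invariant to invertible view transforms", {
  set.seed(60)
  xd <- matrix(rnorm(45 * 3), 45, 3)
  yd <- xd %*% diag(c(0.8, 0.4, 0.1)) + matrix(rnorm(135), 45, 3)
  base <- fitCca(xd, yd)@correlations
  for (i in 1:3) {
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    expect_equal(fitCca(xd %*% A, yd)@correlations, base, tolerance = 1e-7)
    expect_equal(fitCca(xd, sweep(yd %*% A, 2, rnorm(3)))@correlations, base,
                 tolerance = 1e-7)
  }
})

test_that("no random weight pair beats the first canonical correlation", {
  set.seed(70)
  xd <- matrix(rnorm(60 * 2), 60, 2)
  yd <- 0.6 * xd + matrix(rnorm(120), 60, 2)
  q1 <- fitCca(xd, yd)@correlations[1]
  best <- max(vapply(1:500, function(i) {
    wx <- rnorm(2); wy <- rnorm(2)
    abs(cor(xd %*% wx, yd %*% wy))
  }, 0))
  expect_lte(best, q1 + 1e-10)
})

test_that("out-of-sample projection uses training parameters only", {
  cfg <- syntheticConfig(n = 400, p = 20, q = 20, K = 1, aX = sqrt(1.5),
                         aY = sqrt(1.5), siteEffect = 0, motionEffect = 0,
                         missingRate = 0, nNearConstant = 0, seed = 13)
  ds <- generateDataset(cfg)
  pp <- preprocessPipeline(ds$bundle)
  ids <- subjectIds(pp$bundle)
  train <- ids[1:200]; test <- ids[201:length(ids)]
  xt <- viewValues(pp$bundle@brain)[train, ]; yt <- viewValues(pp$bundle@behaviour)[train, ]
  pcaX <- pcaReduce(xt, 4); pcaY <- pcaReduce(yt, 4)
  cca <- fitCca(pcaX@scores, pcaY@scores)

  # projecting the training data reproduces the training variates
  self <- projectCca(cca, pcaX, pcaY, xt, yt)
  expect_equal(self$x, cca@xVariates, tolerance = 1e-10)

  # permuted rows project to permuted values
  perm <- sample(nrow(xt))
  shuf <- projectCca(cca, pcaX, pcaY, xt[perm, ], yt[perm, ])
  expect_equal(unname(shuf$x), unname(cca@xVariates[perm, ]), tolerance = 1e-10)

  # held-out correlation near the planted population value (rho = 0.6);
  # a single split carries direction-estimation and sampling noise, so the
  # band is generous — the averaged recovery check lives in the acceptance suite
  oos <- projectCca(cca, pcaX, pcaY,
                    viewValues(pp$bundle@brain)[test, ],
                    viewValues(pp$bundle@behaviour)[test, ])
  expect_lt(abs(cor(oos$x[, 1], oos$y[, 1]) - 0.6), 0.2)
})

test_that("loadings equal per-variable Pearson correlations with the variates", {
  set.seed(31)
  n <- 200
  v <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, letters[1:5]))
  variate <- cbind(mode1 = v[, 1] * 2 + 1)   # proportional to variable 1
  L <- variableLoadings(v, variate)
  expect_equal(unname(L["a", 1]), 1, tolerance = 1e-12)
  for (j in 2:5) expect_equal(unname(L[letters[j], 1]), cor(v[, j], variate[, 1]))
  expect_lt(max(abs(L[2:5, 1])), 0.2)       # independent variables, large n
  expect_error(variableLoadings(cbind(k = rep(1, n)), variate), "zero-variance")
})

test_that("mode orientation makes the dominant behavioural loading positive", {
  set.seed(77)
  y <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(NULL, letters[1:4]))
  x <- y + 0.5 * matrix(rnorm(320), 80, 4)
  cca <- fitCca(pcaReduce(x, 3)@scores, pcaReduce(y, 3)@scores)
  flipped <- cca
  for (k in 1:3) {   # force the anti-convention, then re-orient
    flipped@xWeights[, k] <- -flipped@xWeights[, k]
    flipped@yWeights[, k] <- -flipped@yWeights[, k]
    flipped@xVariates[, k] <- -flipped@xVariates[, k]
    flipped@yVariates[, k] <- -flipped@yVariates[, k]
  }
  fixed <- orientModes(flipped, DataView(y, subjectIds = sprintf("s%d", 1:80)))
  L <- variableLoadings(y, fixed@yVariates)
  for (k in 1:3) expect_gt(L[which.max(abs(L[, k])), k], 0)
  expect_equal(fixed@correlations, cca@correlations)
  expect_equal(abs(cor(fixed@xVariates[, 1], fixed@yVariates[, 1])),
               cca@correlations[1], tolerance = 1e-10)
})
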