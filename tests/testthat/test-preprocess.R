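test_that("connectivity from time-series matches a per-pair Pearson oracle", {
  set.seed(42)
  ts <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, sprintf("R%d", 1:5)))
  prof <- computeConnectivity(ts)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(prof@matrix[i, j], cor(ts[, i], ts[, j]), tolerance = 1e-12)

  same <- cbind(a = ts[, 1], b = ts[, 1], c = -ts[, 1], d = ts[, 2])
  prof2 <- computeConnectivity(same)
  expect_equal(prof2@matrix["a", "b"], 1)
  expect_equal(prof2@matrix["a", "c"], -1)
  expect_error(computeConnectivity(cbind(flat = rep(1, 10), x = rnorm(10))),
               "flat")
  expect_error(computeConnectivity(ts[1:2, ]), "3 time points")
})

test_that("low-signal regions are excluded per within-subject z-score", {
  # single subject [10,10,10,10,10,0]: region 6 has z = -2.041 (sample SD)
  sig <- matrix(c(10, 10, 10, 10, 10, 0), 1,
                dimnames = list("s1", sprintf("R%d", 1:6)))
  res <- excludeLowSignalRegions(sig)
  expect_equal(unname(res$keep), c(rep(TRUE, 5), FALSE))
  expect_equal(res$report@excludedRegions, "R6")

  # all equal: zero variance, no exclusions, logged
  flat <- matrix(5, 2, 4, dimnames = list(c("a", "b"), sprintf("R%d", 1:4)))
  res2 <- excludeLowSignalRegions(flat)
  expect_true(all(res2$keep))
  expect_match(res2$report@notes, "zero signal variance")

  # threshold is strict: z exactly at the cut is retained
  x <- c(1, 1, 1, 1, 0)
  z5 <- (0 - mean(x)) / sd(x)
  res3 <- excludeLowSignalRegions(matrix(x, 1), zCut = z5)
  expect_true(all(res3$keep))
})

test_that("motion exclusion applies strict mm thresholds with reasons", {
  cf <- ConfoundTable(c("a", "b", "c", "d"),
                      meanFd = c(0.10, 0.10, 0.31, 0.30),
                      maxFd = c(1.40, 1.30, 0.50, 1.30),
                      site = rep("X", 4))
  res <- excludeHighMotionSubjects(cf)
  expect_equal(unname(res$keep), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(res$report@excludedSubjects$reason, c("max_fd", "mean_fd"))

  cf2 <- ConfoundTable("a", meanFd = NA_real_, maxFd = 1, site = "X")
  expect_error(excludeHighMotionSubjects(cf2), "missing")
})

test_that("near-constant filter uses strict modal share over observed values", {
  n <- 100
  v <- cbind(ok = c(rep(1, 95), 2:6),              # share exactly 0.95: keep
             gone = c(rep(1, 96), 2:5),            # share 0.96: drop
             const = rep(7, n),                    # share 1: drop
             cont = rnorm(n))
  rownames(v) <- sprintf("s%03d", 1:n)
  res <- filterNearConstant(DataView(v, missingOk = TRUE))
  expect_setequal(res$report@removedVariables, c("gone", "const"))
  expect_equal(variableIds(res$view), c("ok", "cont"))

  # missing entries are excluded from the share denominator
  w <- cbind(x = c(rep(1, 96), NA, NA, NA, 2))  # 96/97 observed > 0.95: drop
  rownames(w) <- sprintf("s%03d", 1:n)
  expect_equal(filterNearConstant(DataView(w, missingOk = TRUE))$report@removedVariables,
               "x")
})

test_that("median imputation fills gaps with the per-variable median", {
  v <- cbind(a = c(1, 2, NA, 4), b = c(1, 2, 3, 4), c = c(NA, 1, 2, NA))
  rownames(v) <- sprintf("s%d", 1:4)
  res <- imputeMedian(DataView(v, missingOk = TRUE))
  expect_equal(unname(viewValues(res$view)[3, "a"]), 2)   # median {1,2,4}
  expect_equal(unname(viewValues(res$view)[, "b"]), c(1, 2, 3, 4))
  expect_equal(unname(viewValues(res$view)[1, "c"]), 1.5) # mean of middle two
  expect_equal(res$report@imputationCounts, c(a = 1L, c = 2L))
  expect_equal(unname(res$medians["b"]), 2.5)             # even-count convention

  allNA <- DataView(cbind(x = c(NA_real_, NA_real_)),
                    subjectIds = c("a", "b"), missingOk = TRUE)
  expect_error(imputeMedian(allNA), "fully missing")
})

test_that("one-hot site coding follows the declared label order", {
  cf <- ConfoundTable(c("a", "b", "c"), meanFd = rep(0.1, 3),
                      maxFd = rep(0.5, 3), site = c("London", "CBU", "London"))
  oh <- oneHotSite(cf, labelOrder = c("CBU", "WBIC", "London"))
  expect_equal(unname(oh["a", ]), c(0, 0, 1))
  expect_equal(unname(rowSums(oh)), rep(1, 3))
  expect_error(oneHotSite(cf, labelOrder = c("CBU", "WBIC")), "London")
})

test_that("confound regression yields residuals orthogonal to the design", {
  set.seed(11)
  n <- 50
  cf <- ConfoundTable(sprintf("s%02d", 1:n), meanFd = runif(n, 0, 0.3),
                      maxFd = runif(n, 0, 1), site = sample(c("A", "B", "C"), n, TRUE))
  design <- buildConfoundDesign(cf)
  expect_equal(colnames(design), c("mean_fd", "A", "B"))

  v <- matrix(rnorm(n * 4), n, 4, dimnames = list(subjectIds(cf), letters[1:4]))
  v[, 1] <- 3 * cf@meanFd - 1                      # exactly linear in FD
  res <- regressConfounds(DataView(v), design)
  rv <- viewValues(res$view)
  expect_lt(max(abs(rv[, 1])), 1e-10)
  expect_lt(max(abs(crossprod(rv, cbind(1, design)))), 1e-8)
  # orthogonal also to the dropped one-hot column (a combination of the rest)
  expect_lt(max(abs(crossprod(rv, oneHotSite(cf)[, "C"]))), 1e-8)

  bad <- cbind(design, again = design[, "mean_fd"])
  expect_error(regressConfounds(DataView(v), bad), "rank-deficient")
})

test_that("standardization gives exact moments and is idempotent", {
  v <- matrix(c(1, 2, 3, 5, 5, 8), 3, 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  s1 <- standardizeView(DataView(v))
  expect_equal(unname(colMeans(viewValues(s1$view))), c(0, 0))
  expect_equal(unname(apply(viewValues(s1$view), 2, sd)), c(1, 1))
  s2 <- standardizeView(s1$view)
  expect_equal(viewValues(s2$view), viewValues(s1$view), tolerance = 1e-12)
  expect_error(standardizeView(DataView(cbind(k = rep(2, 3)),
                                        subjectIds = c("a", "b", "c"))),
               "zero-variance")
})

test_that("pipeline removes planted artefacts and meets the moment invariants", {
  cfg <- syntheticConfig(n = 150, p = 30, q = 40, K = 1, aX = 1, aY = 1,
                         nNearConstant = 4, missingRate = 0.05, seed = 9)
  ds <- generateDataset(cfg)
  pp <- preprocessPipeline(ds$bundle)

  expect_setequal(pp$report@removedVariables, ds$truth$nearConstant)
  for (side in list(pp$bundle@brain, pp$bundle@behaviour)) {
    v <- viewValues(side)
    expect_false(anyNA(v))
    expect_lt(max(abs(colMeans(v))), 1e-8)
    expect_lt(max(abs(apply(v, 2, sd) - 1)), 1e-6)
    conf <- cbind(pp$bundle@confounds@meanFd, oneHotSite(pp$bundle@confounds))
    expect_lt(max(abs(cor(v, conf))), 1e-8)
  }

  # re-running on its own output is a no-op up to standardization tolerance
  pp2 <- preprocessPipeline(pp$bundle)
  expect_equal(nrow(pp2$report@excludedSubjects), 0)
  expect_length(pp2$report@removedVariables, 0)
  expect_equal(viewValues(pp2$bundle@brain), viewValues(pp$bundle@brain),
               tolerance = 1e-6)
})

test_that("single-site, constant-motion confounds degrade gracefully", {
  b <- toyBundle(n = 25, seed = 7, sites = "only")
  cf <- ConfoundTable(subjectIds(b), meanFd = rep(0.1, 25),
                      maxFd = rep(0.5, 25), site = rep("only", 25))
  bundle <- DatasetBundle(b@brain, b@behaviour, cf)
  pp <- preprocessPipeline(bundle)
  v <- viewValues(pp$bundle@brain)
  expect_lt(max(abs(colMeans(v))), 1e-8)
  expect_lt(max(abs(apply(v, 2, sd) - 1)), 1e-6)
})

test_that("cohort accounting subtracts printed exclusion tallies", {
  res <- accountExclusions(list(
    one = list(initial = 10, excluded = c(reasonA = 2, reasonB = 1)),
    two = list(initial = 5, excluded = c(reasonA = 1))))
  expect_equal(res$perCohort$retained, c(7, 4))
  expect_equal(res$total, 11)
  expect_error(accountExclusions(list(x = list(initial = 2, excluded = c(a = 3)))),
               "more exclusions")
})
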