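test_that("the closed-form population correlation matches a large-n CCA oracle", {
  # a_x = a_y = 1, sigma_x = sigma_y = 1 -> rho = 0.5 exactly
  cfg <- syntheticConfig(n = 100000L, p = 8, q = 8, K = 1, aX = 1, aY = 1,
                         siteEffect = 0, motionEffect = 0, missingRate = 0,
                         nNearConstant = 0, seed = 314)
  expect_equal(populationCanonicalCorrelation(cfg, 1), 0.5)
  ds <- generateDataset(cfg)
  fit <- fitCca(viewValues(ds$bundle@brain), viewValues(ds$bundle@behaviour))
  expect_equal(fit@correlations[1], 0.5, tolerance = 0.01)

  # degenerate limits of the closed form
  cfg0 <- syntheticConfig(n = 10, p = 4, q = 4, K = 1, aX = 0, aY = 0,
                          nNearConstant = 0, missingRate = 0, seed = 1)
  expect_equal(populationCanonicalCorrelation(cfg0, 1), 0)
  cfg1 <- syntheticConfig(n = 10, p = 4, q = 4, K = 1, aX = 2, aY = 3,
                          sigmaX = 0, sigmaY = 0, nNearConstant = 0,
                          missingRate = 0, seed = 1)
  expect_equal(populationCanonicalCorrelation(cfg1, 1), 1)
  expect_error(populationCanonicalCorrelation(cfg1, 2), "out of range")
})

test_that("the noiseless planted mode yields a sample correlation of 1", {
  cfg <- syntheticConfig(n = 50, p = 10, q = 10, K = 1, aX = 1, aY = 1,
                         sigmaX = 0, sigmaY = 0, siteEffect = 0,
                         motionEffect = 0, missingRate = 0, nNearConstant = 0,
                         seed = 6)
  ds <- generateDataset(cfg)
  # noiseless single-mode data is exactly rank one, so reduce to d = 1
  fit <- fitCca(pcaReduce(viewValues(ds$bundle@brain), 1)@scores,
                pcaReduce(viewValues(ds$bundle@behaviour), 1)@scores)
  expect_equal(fit@correlations[1], 1, tolerance = 1e-6)
})

test_that("generation is seed-deterministic and honours the config contract", {
  cfg <- syntheticConfig(n = 60, p = 12, q = 20, K = 2, aX = c(1.5, 1),
                         aY = c(1.5, 1), nNearConstant = 3, missingRate = 0.05,
                         seed = 99)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(viewValues(a$bundle@brain), viewValues(b$bundle@brain))
  expect_identical(viewValues(a$bundle@behaviour), viewValues(b$bundle@behaviour))
  expect_identical(a$truth$z, b$truth$z)

  expect_equal(dim(viewValues(a$bundle@brain)), c(60, 12))
  expect_equal(dim(viewValues(a$bundle@behaviour)), c(60, 20))
  expect_length(a$truth$nearConstant, 3)
  expect_true(anyNA(viewValues(a$bundle@behaviour)))
  expect_false(anyNA(viewValues(a$bundle@brain)))
  # orthonormal loading directions, non-increasing population correlations
  expect_equal(crossprod(a$truth$wX), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(a$truth$rho) <= 0))
  expect_true(all(a$truth$rho >= 0 & a$truth$rho <= 1))

  expect_error(syntheticConfig(n = 10, p = 3, q = 4, K = 5), "K exceeds")
  expect_error(syntheticConfig(missingRate = 1), "missingRate")
})

test_that("confound regression removes the planted site and motion effects", {
  cfg <- syntheticConfig(n = 120, p = 25, q = 25, K = 1, aX = 1, aY = 1,
                         siteEffect = 1, motionEffect = 1, nNearConstant = 0,
                         missingRate = 0, seed = 8)
  ds <- generateDataset(cfg)
  # planted site effects are visible before regression (motion effects scale
  # with the small FD variance, so site is the sensitive probe)...
  rawCor <- abs(cor(viewValues(ds$bundle@brain),
                    oneHotSite(ds$bundle@confounds)))
  expect_gt(max(rawCor), 0.3)
  # ...and exactly orthogonal after
  pp <- preprocessPipeline(ds$bundle)
  conf <- cbind(pp$bundle@confounds@meanFd, oneHotSite(pp$bundle@confounds))
  expect_lt(max(abs(cor(viewValues(pp$bundle@brain), conf))), 1e-8)
  expect_lt(max(abs(cor(viewValues(pp$bundle@behaviour), conf))), 1e-8)
})

test_that("null suites are reproducible, distinct, valid bundles", {
  cfg <- syntheticConfig(n = 30, p = 8, q = 10, K = 0, aX = numeric(),
                         aY = numeric(), nNearConstant = 1, missingRate = 0.02,
                         seed = 1)
  suite <- generateNullSuite(cfg, nDatasets = 5, seed = 11L)
  suite2 <- generateNullSuite(cfg, nDatasets = 5, seed = 11L)
  expect_length(suite, 5)
  for (i in 1:5) {
    expect_true(validObject(suite[[i]], test = TRUE))
    expect_identical(viewValues(suite[[i]]@brain), viewValues(suite2[[i]]@brain))
  }
  expect_false(identical(viewValues(suite[[1]]@brain),
                         viewValues(suite[[2]]@brain)))
  expect_error(generateNullSuite(syntheticConfig(K = 1, aX = 1, aY = 1), 2),
               "K = 0")
})

test_that("synthetic datasets round-trip through the text formats", {
  cfg <- syntheticConfig(n = 20, p = 6, q = 8, K = 1, aX = 1, aY = 1,
                         nNearConstant = 0, missingRate = 0.05, seed = 2)
  ds <- generateDataset(cfg)
  dir <- withr::local_tempdir()
  writeSyntheticDataset(ds, dir)
  brain <- readDataMatrix(file.path(dir, "brain.tsv"))
  behav <- readDataMatrix(file.path(dir, "behaviour.tsv"), missingOk = TRUE)
  conf <- readConfoundTable(file.path(dir, "confounds.tsv"))
  al <- alignSubjects(brain, behav, conf)
  expect_length(al$dropped, 0)
  expect_equal(viewValues(al$bundle@brain), viewValues(ds$bundle@brain),
               tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$rho, ds$truth$rho, tolerance = 1e-12)
})
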