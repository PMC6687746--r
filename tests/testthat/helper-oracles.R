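# Fixture builders and independent oracles shared across the suite.

# symmetric correlation-like matrix with unit diagonal
randomProfile <- function(r, seed = 1) {
  set.seed(seed)
  m <- stats::cor(matrix(rnorm((r + 5) * r), r + 5, r))
  dimnames(m) <- list(sprintf("R%02d", 1:r), sprintf("R%02d", 1:r))
  ConnectivityProfile(m)
}

# small aligned bundle with independent views and benign confounds
toyBundle <- function(n = 30, p = 6, q = 5, seed = 1, sites = c("A", "B", "C")) {
  set.seed(seed)
  ids <- sprintf("s%03d", 1:n)
  brain <- DataView(matrix(rnorm(n * p), n, p,
                           dimnames = list(ids, sprintf("b%02d", 1:p))))
  behav <- DataView(matrix(rnorm(n * q), n, q,
                           dimnames = list(ids, sprintf("y%02d", 1:q))),
                    missingOk = TRUE)
  conf <- ConfoundTable(ids, meanFd = runif(n, 0.05, 0.2),
                        maxFd = runif(n, 0.3, 1.0),
                        site = sample(sites, n, replace = TRUE))
  DatasetBundle(brain, behav, conf)
}

# independent CCA oracle: canonical correlations via the classical
# generalized-eigenvalue problem Sxx^-1 Sxy Syy^-1 Syx, solved directly
ccaOracleCorrelations <- function(x, y) {
  Sxx <- stats::cov(x); Syy <- stats::cov(y); Sxy <- stats::cov(x, y)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmin(pmax(ev[seq_len(min(ncol(x), ncol(y)))], 0), 1))
}

# caches the null-suite permutation results used by the FWE and
# monotonicity acceptance checks, so the suite is computed once
.nullSuiteCache <- new.env(parent = emptyenv())
nullSuitePermResults <- function() {
  if (!is.null(.nullSuiteCache$results)) return(.nullSuiteCache$results)
  cfg <- syntheticConfig(n = 120, p = 40, q = 40, K = 0, aX = numeric(),
                         aY = numeric(), nNearConstant = 2, missingRate = 0.02,
                         seed = 2024L)
  bundles <- generateNullSuite(cfg, nDatasets = 200, seed = 2024L)
  .nullSuiteCache$results <- lapply(seq_along(bundles), function(i) {
    pp <- preprocessPipeline(bundles[[i]])
    permutationPvalues(pp$bundle@brain, pp$bundle@behaviour, d = 5,
                       nPerm = 200, seed = 5000L + i)
  })
  .nullSuiteCache$results
}
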