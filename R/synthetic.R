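# Two-view latent-factor simulator with planted modes of covariation,
# additive confound effects, missingness and near-constant items — the
# ground-truth source for every downstream validation.
#
# Model, per subject i:
#   x_i = sum_k a_xk w_xk z_ik + B_site' s_i + b_mot fd_i + sigma_x e_i
# and analogously for the behaviour view, with z_ik ~ N(0,1) shared latent
# scores, orthonormal loading directions w (QR of a Gaussian matrix), s_i a
# one-hot 3-level site, fd_i a log-normal motion scalar and isotropic
# Gaussian noise. Under this model the population canonical correlation of
# mode k has the closed form a_xk a_yk / sqrt((a_xk^2 + sigma_x^2)
# (a_yk^2 + sigma_y^2)).

#' Configuration of the two-view simulator
#'
#' Defaults mirror the shape of the motivating cohort where the analysis
#' pipeline defines it: 306 subjects; a behaviour view of 372 items of which
#' 8 are near-constant (leaving 364 after filtering); three scanner sites;
#' log-normal motion around 0.1 mm. The brain view defaults to 300
#' connectivity variables — a scale at which the sampling behaviour of the
#' pipeline is faithful while simulations stay fast; signal strengths
#' a = (1.5, 1.0) against unit noise give population canonical correlations
#' of about 0.69 and 0.5 for the two planted modes.
#'
#' @param n subjects.
#' @param p brain variables.
#' @param q behaviour variables (including the near-constant ones).
#' @param K number of planted modes (0 = global null).
#' @param aX,aY length-K per-mode signal strengths (>= 0, non-increasing
#'   products keep the population correlations sorted).
#' @param sigmaX,sigmaY isotropic noise scales.
#' @param siteEffect,motionEffect scales of the per-variable confound
#'   coefficients (0 disables).
#' @param siteProbs length-3 site assignment probabilities.
#' @param missingRate completely-at-random missingness rate of the behaviour
#'   view, in \[0, 1).
#' @param nNearConstant behavioural columns made near-constant (modal share
#'   ~0.97, above the 0.95 filter threshold).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return validated configuration list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(n = 306L, p = 300L, q = 372L, K = 2L,
                            aX = c(1.5, 1.0)[seq_len(K)],
                            aY = c(1.5, 1.0)[seq_len(K)],
                            sigmaX = 1, sigmaY = 1,
                            siteEffect = 0.3, motionEffect = 0.3,
                            siteProbs = c(0.4, 0.3, 0.3),
                            missingRate = 0.02, nNearConstant = 8L,
                            seed = 1L) {
  cfg <- list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
              K = as.integer(K), aX = as.numeric(aX), aY = as.numeric(aY),
              sigmaX = sigmaX, sigmaY = sigmaY, siteEffect = siteEffect,
              motionEffect = motionEffect, siteProbs = siteProbs,
              missingRate = missingRate,
              nNearConstant = as.integer(nNearConstant),
              seed = as.integer(seed))
  if (cfg$K > min(cfg$p, cfg$q - cfg$nNearConstant))
    stop("K exceeds min(p, q - nNearConstant)")
  if (length(cfg$aX) != cfg$K || length(cfg$aY) != cfg$K)
    stop("aX and aY must have one entry per mode")
  if (any(c(cfg$aX, cfg$aY) < 0) || cfg$sigmaX < 0 || cfg$sigmaY < 0 ||
      cfg$siteEffect < 0 || cfg$motionEffect < 0)
    stop("scales must be non-negative")
  if (cfg$missingRate < 0 || cfg$missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  if (length(cfg$siteProbs) != 3L || any(cfg$siteProbs <= 0))
    stop("siteProbs must be 3 positive probabilities")
  class(cfg) <- "SyntheticConfig"
  cfg
}

# orthonormal m x K directions (QR of a Gaussian matrix), deterministic sign
.randomDirections <- function(m, K) {
  if (K == 0L) return(matrix(0, m, 0L))
  Q <- qr.Q(qr(matrix(stats::rnorm(m * K), m, K)))
  for (k in seq_len(K)) if (Q[which.max(abs(Q[, k])), k] < 0) Q[, k] <- -Q[, k]
  Q
}

#' Generate a synthetic two-view dataset with known ground truth
#'
#' Draws shared latent scores, builds both views from the latent-factor
#' model, adds site and motion confound effects to both, then injects
#' near-constant columns and completely-at-random missing entries into the
#' behaviour view only. The near-constant columns carry no latent signal, so
#' the variables removed by [filterNearConstant()] at the default threshold
#' are exactly the injected ones.
#'
#' @param config a [syntheticConfig()].
#' @return list with `bundle` (a \linkS4class{DatasetBundle}; behaviour view
#'   has `missingOk = TRUE`) and `truth` (latent scores `z`, loading
#'   directions `wX`/`wY`, population canonical correlations `rho`, the site
#'   labels, motion values, and the injected near-constant/missing
#'   positions).
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$n; p <- config$p; K <- config$K
  qCore <- config$q - config$nNearConstant
  ids <- sprintf("sub-%04d", seq_len(n))

  z <- matrix(stats::rnorm(n * K), n, K)
  wX <- .randomDirections(p, K)
  wY <- .randomDirections(qCore, K)

  sites <- c("CBU", "WBIC", "UCL")
  site <- sample(sites, n, replace = TRUE, prob = config$siteProbs)
  meanFd <- stats::rlnorm(n, meanlog = log(0.1), sdlog = 0.4)
  maxFd <- meanFd * stats::runif(n, 2.5, 4)
  confounds <- ConfoundTable(ids, meanFd, maxFd, site)

  siteDesign <- outer(site, sites, `==`) + 0
  addConfounds <- function(M) {
    m <- ncol(M)
    if (config$siteEffect > 0)
      M <- M + siteDesign %*% matrix(stats::rnorm(3 * m, sd = config$siteEffect), 3, m)
    if (config$motionEffect > 0)
      M <- M + outer(meanFd, stats::rnorm(m, sd = config$motionEffect))
    M
  }

  X <- matrix(stats::rnorm(n * p, sd = config$sigmaX), n, p)
  if (K > 0) X <- X + z %*% (t(wX) * config$aX)
  X <- addConfounds(X)
  dimnames(X) <- list(ids, sprintf("conn-%04d", seq_len(p)))

  Y <- matrix(stats::rnorm(n * qCore, sd = config$sigmaY), n, qCore)
  if (K > 0) Y <- Y + z %*% (t(wY) * config$aY)
  Y <- addConfounds(Y)

  nearConstIds <- character()
  if (config$nNearConstant > 0L) {
    # ceiling keeps the modal share >= 0.97 > 0.95; for n <= 20 no non-degenerate
    # column can exceed 0.95, so the injected columns degrade to constants
    nOdd <- as.integer(n - ceiling(0.97 * n))
    NC <- vapply(seq_len(config$nNearConstant), function(j) {
      col <- rep(0, n); col[sample.int(n, nOdd)] <- 1; col
    }, numeric(n))
    Y <- cbind(Y, NC)
    nearConstIds <- sprintf("item-%04d", qCore + seq_len(config$nNearConstant))
  }
  dimnames(Y) <- list(ids, sprintf("item-%04d", seq_len(ncol(Y))))

  missingIdx <- matrix(integer(), 0L, 2L)
  if (config$missingRate > 0 && qCore > 0) {
    mask <- matrix(stats::runif(n * qCore) < config$missingRate, n, qCore)
    # keep every variable observable at least once
    full <- colSums(mask) == n
    mask[1L, full] <- FALSE
    Y[, seq_len(qCore)][mask] <- NA_real_
    missingIdx <- which(mask, arr.ind = TRUE)
  }

  rownames(wX) <- colnames(X)
  rownames(wY) <- colnames(Y)[seq_len(qCore)]
  rho <- vapply(seq_len(K), function(k)
    populationCanonicalCorrelation(config, k), 0)

  list(bundle = DatasetBundle(
         brain = DataView(X),
         behaviour = DataView(Y, missingOk = TRUE),
         confounds = confounds),
       truth = list(z = z, wX = wX, wY = wY, rho = rho, site = site,
                    meanFd = meanFd, nearConstant = nearConstIds,
                    missing = missingIdx, config = config))
}

#' Population canonical correlation of a planted mode
#'
#' Closed form for the isotropic single-direction latent model with
#' orthonormal loading directions:
#' rho_k = a_xk a_yk / sqrt((a_xk^2 + sigma_x^2)(a_yk^2 + sigma_y^2)).
#' Validated against an empirical large-n CCA oracle in the test suite.
#'
#' @param config a [syntheticConfig()].
#' @param k mode index, 1 <= k <= K.
#' @return the population canonical correlation in \[0, 1\].
#' @export
populationCanonicalCorrelation <- function(config, k) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!.isCount(k) || k > config$K) stop("mode index out of range")
  (config$aX[k] * config$aY[k]) /
    sqrt((config$aX[k]^2 + config$sigmaX^2) * (config$aY[k]^2 + config$sigmaY^2))
}

#' Generate a suite of independent null datasets
#'
#' Replicates of a K = 0 configuration under derived seeds; the workhorse of
#' the family-wise-error calibration checks.
#'
#' @param config a [syntheticConfig()] with `K = 0`.
#' @param nDatasets number of replicates.
#' @param seed master seed; replicate i uses a seed derived from it.
#' @return list of \linkS4class{DatasetBundle}s.
#' @export
generateNullSuite <- function(config, nDatasets, seed = 1L) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (config$K != 0L) stop("null suite requires K = 0")
  lapply(seq_len(nDatasets), function(i) {
    cfg <- config
    cfg$seed <- deriveSeed(seed, i)
    generateDataset(cfg)$bundle
  })
}

#' Write a synthetic dataset to delimited files
#'
#' Emits the bundle in the package's text formats (`brain.tsv`,
#' `behaviour.tsv`, `confounds.tsv`) plus the ground truth as
#' `truth.json`.
#'
#' @param dataset the list returned by [generateDataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, `dir`.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeDataMatrix(dataset$bundle@brain, file.path(dir, "brain.tsv"))
  writeDataMatrix(dataset$bundle@behaviour, file.path(dir, "behaviour.tsv"))
  data.table::fwrite(as.data.frame(dataset$bundle@confounds),
                     file.path(dir, "confounds.tsv"), sep = "\t")
  tr <- dataset$truth
  jsonlite::write_json(
    list(rho = tr$rho, near_constant = tr$nearConstant,
         n_missing = nrow(tr$missing),
         config = unclass(tr$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
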