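# Small shared helpers.

# round half away from zero (base round() rounds half to even); used for
# fraction-of-edges selections where 0.005 * 60378 = 301.89 -> 302
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# derive a stream-specific seed from a master seed, kept inside 32-bit range
deriveSeed <- function(seed, stream) {
  as.integer((as.double(seed) + 104729 * as.double(stream)) %% 2147483587 + 1)
}

#' Display convention for permutation p-values
#'
#' With the add-one convention p = (1 + b) / (1 + N), the smallest reportable
#' p-value is 1 / (N + 1); a zero-exceedance result is displayed as
#' `"< 0.0001"` at N = 10000 rather than as an exact value.
#'
#' @param p numeric p-values from a permutation test.
#' @param nPerm number of permutations N.
#' @return character vector for display.
#' @export
formatPermutationP <- function(p, nPerm) {
  floor_p <- 1 / (nPerm + 1)
  ifelse(p <= floor_p + 1e-15, sprintf("< %.4g", floor_p), sprintf("%.4g", p))
}

.isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 1

# ordinary least squares: X (with intercept prepended) against each column of Y;
# errors on rank deficiency. Returns list(beta, residuals, qr)
.olsFit <- function(design, Y) {
  X <- cbind(`(intercept)` = 1, design)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("confound design is rank-deficient after adding an intercept; ",
         "drop a redundant column (e.g. the last one-hot site column)")
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  list(beta = beta, residuals = res, columns = colnames(X))
}
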