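# PCA reduction, the CCA fit, out-of-sample projection, and loadings.
#
# The CCA solver works on the QR-orthonormalized centred views: with
# Xc = Qx Rx and Yc = Qy Ry, Qx'Qy is the whitened cross-covariance and its
# singular values are the canonical correlations; weights are recovered by
# back-solving through R. This is the numerically stable formulation of the
# classical generalized-eigenvalue problem.

#' Reduce a view with principal component analysis
#'
#' SVD-based PCA on the column-centred matrix. Component signs are fixed so
#' each basis vector's largest-magnitude element is positive. The explained
#' variance fractions are reported against the total variance of the input
#' (in the motivating analysis, d = 25 components explained 53% / 56% of the
#' behaviour / connectivity variance).
#'
#' @param view a \linkS4class{DataView} (preprocessed: no missing values) or
#'   numeric matrix.
#' @param d number of components; must satisfy d <= min(n - 1, m).
#' @return a \linkS4class{PcaModel}.
#' @export
pcaReduce <- function(view, d) {
  x <- if (is(view, "DataView")) viewValues(view) else as.matrix(view)
  n <- nrow(x); m <- ncol(x)
  if (!.isCount(d) || d > min(n - 1L, m))
    stop(sprintf("d must be a positive integer <= min(n-1, m) = %d", min(n - 1L, m)))
  d <- as.integer(d)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = d)
  basis <- sv$v
  # sign convention: largest-|.| element of each direction positive
  for (k in seq_len(d)) {
    j <- which.max(abs(basis[, k]))
    if (basis[j, k] < 0) basis[, k] <- -basis[, k]
  }
  rownames(basis) <- colnames(x)
  colnames(basis) <- sprintf("PC%d", seq_len(d))
  scores <- xc %*% basis
  rownames(scores) <- rownames(x)
  totvar <- sum(sv$d^2) / (n - 1)
  new("PcaModel", basis = basis, scores = scores, center = ctr,
      explainedVariance = (sv$d[seq_len(d)]^2 / (n - 1)) / totvar,
      totalVariance = totvar, d = d)
}

#' Project new subjects onto a fitted PCA basis
#'
#' @param model a \linkS4class{PcaModel}.
#' @param view new data over the same variables (\linkS4class{DataView} or
#'   matrix).
#' @return n x d matrix of component scores.
#' @export
pcaProject <- function(model, view) {
  stopifnot(is(model, "PcaModel"))
  x <- if (is(view, "DataView")) viewValues(view) else as.matrix(view)
  if (ncol(x) != nrow(model@basis))
    stop("variable count does not match the training PCA")
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), rownames(model@basis)))
    stop("variables (or their order) do not match the training PCA")
  sweep(x, 2, model@center) %*% model@basis
}

# canonical correlations from orthonormalized views; the hot inner loop of
# the permutation test
.canonicalCorrFromQ <- function(Qx, Qy) {
  s <- svd(crossprod(Qx, Qy), nu = 0, nv = 0)$d
  pmin(pmax(s, 0), 1)
}

# centre + thin QR of one view; errors on rank deficiency
.qrView <- function(x, what) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  qx <- qr(xc)
  if (qx$rank < ncol(x))
    stop(sprintf("%s view is rank-deficient (rank %d < %d columns)",
                 what, qx$rank, ncol(x)))
  list(Q = qr.Q(qx), qr = qx, center = colMeans(x))
}

#' Fit a canonical correlation analysis
#'
#' Finds, mode by mode, the pair of linear combinations of the two (reduced)
#' views with maximal Pearson correlation, each new pair uncorrelated with
#' the preceding ones within its view. Returns min(dx, dy) modes with
#' correlations sorted non-increasing; variates are scaled to unit sample
#' variance and mode signs follow the convention documented in
#' \linkS4class{CcaModel}.
#'
#' @param xd,yd n x dx / n x dy numeric matrices (typically PCA scores), full
#'   column rank, n > max(dx, dy).
#' @return a \linkS4class{CcaModel}.
#' @export
fitCca <- function(xd, yd) {
  xd <- as.matrix(xd); yd <- as.matrix(yd)
  n <- nrow(xd)
  if (nrow(yd) != n) stop("views disagree on the number of subjects")
  if (n <= max(ncol(xd), ncol(yd)))
    stop("need more subjects than reduced dimensions")
  qx <- .qrView(xd, "x"); qy <- .qrView(yd, "y")
  sv <- svd(crossprod(qx$Q, qy$Q))
  d <- min(ncol(xd), ncol(yd))
  q <- pmin(pmax(sv$d[seq_len(d)], 0), 1)
  # weights in the original (reduced-view) coordinates: back-solve through R,
  # scaled so the variates have unit sample variance
  wx <- backsolve(qr.R(qx$qr), sv$u[, seq_len(d), drop = FALSE]) * sqrt(n - 1)
  wy <- backsolve(qr.R(qy$qr), sv$v[, seq_len(d), drop = FALSE]) * sqrt(n - 1)
  # undo any column pivoting applied by qr()
  wx[qx$qr$pivot, ] <- wx; wy[qy$qr$pivot, ] <- wy
  for (k in seq_len(d)) {     # joint sign fix keeps cor(Px_k, Py_k) = +q_k
    j <- which.max(abs(wy[, k]))
    if (wy[j, k] < 0) { wy[, k] <- -wy[, k]; wx[, k] <- -wx[, k] }
  }
  px <- sweep(xd, 2, qx$center) %*% wx
  py <- sweep(yd, 2, qy$center) %*% wy
  modes <- sprintf("mode%d", seq_len(d))
  colnames(wx) <- colnames(wy) <- colnames(px) <- colnames(py) <- modes
  rownames(px) <- rownames(py) <- rownames(xd)
  new("CcaModel", d = as.integer(d), xWeights = wx, yWeights = wy,
      correlations = q, xVariates = px, yVariates = py,
      xCenter = qx$center, yCenter = qy$center)
}

#' Out-of-sample canonical variates
#'
#' Projects new, already-preprocessed subjects through the training PCA bases
#' and then the training canonical weights; nothing is refit. Projecting the
#' training data itself reproduces the training variates.
#'
#' @param cca a \linkS4class{CcaModel} fitted on the training PCA scores.
#' @param pcaX,pcaY the training \linkS4class{PcaModel}s of the two views.
#' @param xNew,yNew new-data views (\linkS4class{DataView} or matrix) over
#'   the training variables, preprocessed with training-derived parameters.
#' @return list with matrices `x` and `y` (n_new x d variates).
#' @export
projectCca <- function(cca, pcaX, pcaY, xNew, yNew) {
  stopifnot(is(cca, "CcaModel"))
  xd <- pcaProject(pcaX, xNew)
  yd <- pcaProject(pcaY, yNew)
  list(x = sweep(xd, 2, cca@xCenter) %*% cca@xWeights,
       y = sweep(yd, 2, cca@yCenter) %*% cca@yWeights)
}

#' Loadings: correlations of original variables with the canonical variates
#'
#' For each variable of the (preprocessed) view and each mode, the Pearson
#' correlation between the variable and the corresponding canonical variate
#' — brain variables against P_X, behavioural variables against P_Y. These
#' structure coefficients are the basis for ranking and "top k" selections.
#'
#' @param view the preprocessed \linkS4class{DataView} whose variables to
#'   correlate.
#' @param variates n x d matrix of canonical variates for the same subjects
#'   in the same order (see [variates()]).
#' @return m x d numeric matrix of loadings in \[-1, 1\] (rownames = variable
#'   ids, colnames = modes).
#' @export
variableLoadings <- function(view, variates) {
  v <- if (is(view, "DataView")) viewValues(view) else as.matrix(view)
  variates <- as.matrix(variates)
  if (nrow(v) != nrow(variates))
    stop("view and variates disagree on subjects")
  sds <- apply(v, 2, stats::sd)
  if (any(sds < 1e-12))
    stop("zero-variance variable(s): ", paste(colnames(v)[sds < 1e-12],
                                              collapse = ", "))
  L <- stats::cor(v, variates)
  colnames(L) <- colnames(variates) %||% sprintf("mode%d", seq_len(ncol(variates)))
  L
}

#' Flip mode signs toward interpretable behavioural loadings
#'
#' CCA mode signs are arbitrary; for reporting, each mode is oriented so the
#' behavioural variable with the largest absolute loading has a positive
#' loading. u and P_X are flipped jointly with v and P_Y, preserving all
#' correlations.
#'
#' @param cca a \linkS4class{CcaModel}.
#' @param behaviourView the preprocessed behaviour \linkS4class{DataView}
#'   (training subjects).
#' @return the re-oriented \linkS4class{CcaModel}.
#' @export
orientModes <- function(cca, behaviourView) {
  stopifnot(is(cca, "CcaModel"))
  L <- variableLoadings(behaviourView, cca@yVariates)
  for (k in seq_len(cca@d)) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) {
      cca@xWeights[, k] <- -cca@xWeights[, k]
      cca@yWeights[, k] <- -cca@yWeights[, k]
      cca@xVariates[, k] <- -cca@xVariates[, k]
      cca@yVariates[, k] <- -cca@yVariates[, k]
    }
  }
  cca
}
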