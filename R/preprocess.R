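# Quality control and preprocessing. Each stated rule is implemented as a
# pure function of its inputs; preprocessPipeline() composes them in the
# declared order (motion exclusion -> near-constant filter -> median
# imputation -> confound regression -> standardization) and records every
# exclusion in a QcReport. preprocessApply() replays a fitted pipeline on new
# subjects (hold-out test sets) without re-estimating anything.

#' Pearson connectivity from regional time-series
#'
#' Computes the full pairwise Pearson correlation between the time-series of
#' every pair of regions.
#'
#' @param timeseries T x r numeric matrix, one column per region (colnames
#'   are region ids); T >= 3 time points.
#' @return a \linkS4class{ConnectivityProfile}.
#' @export
computeConnectivity <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 3L) stop("need at least 3 time points")
  if (is.null(colnames(timeseries)))
    colnames(timeseries) <- sprintf("region-%03d", seq_len(ncol(timeseries)))
  sds <- apply(timeseries, 2, stats::sd)
  if (any(sds == 0))
    stop("constant time-series (undefined correlation) for region(s): ",
         paste(colnames(timeseries)[sds == 0], collapse = ", "))
  m <- stats::cor(timeseries)
  diag(m) <- 1
  m[m > 1] <- 1
  m[m < -1] <- -1
  m <- (m + t(m)) / 2
  ConnectivityProfile(m)
}

#' Exclude regions with low mean signal in any subject
#'
#' For each subject, regional mean signals are z-scored across regions
#' (sample standard deviation); a region is excluded when its z-score falls
#' strictly below `zCut` in at least one subject. A subject whose signals
#' have zero variance across regions contributes no exclusions (logged).
#' In the motivating connectome this rule removed 28 of 376 regions,
#' retaining 348.
#'
#' @param meanSignals subjects x regions numeric matrix of regional mean
#'   signals (colnames are region ids).
#' @param zCut z-score threshold, default -1.96.
#' @return list with `keep` (named logical vector over regions) and `report`
#'   (\linkS4class{QcReport}).
#' @export
excludeLowSignalRegions <- function(meanSignals, zCut = -1.96) {
  meanSignals <- as.matrix(meanSignals)
  if (ncol(meanSignals) < 2L) stop("need at least 2 regions")
  if (is.null(colnames(meanSignals)))
    colnames(meanSignals) <- sprintf("region-%03d", seq_len(ncol(meanSignals)))
  flagged <- rep(FALSE, ncol(meanSignals))
  degenerate <- character()
  for (s in seq_len(nrow(meanSignals))) {
    x <- meanSignals[s, ]
    sdx <- stats::sd(x)
    if (is.na(sdx) || sdx == 0) {
      degenerate <- c(degenerate, rownames(meanSignals)[s] %||% as.character(s))
      next
    }
    flagged <- flagged | ((x - mean(x)) / sdx < zCut)
  }
  keep <- !flagged
  names(keep) <- colnames(meanSignals)
  notes <- if (length(degenerate))
    sprintf("low-signal filter: subject(s) with zero signal variance skipped: %s",
            paste(degenerate, collapse = ", ")) else character()
  report <- new("QcReport", excludedRegions = colnames(meanSignals)[flagged],
                notes = notes)
  list(keep = keep, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exclude subjects with excessive head motion
#'
#' A subject is excluded when their maximum framewise displacement is
#' strictly larger than `maxCut` (default 1.3 mm) or their mean framewise
#' displacement strictly larger than `meanCut` (default 0.3 mm). Subjects at
#' exactly the threshold are retained. Missing FD values are an error.
#'
#' @param confounds a \linkS4class{ConfoundTable}.
#' @param maxCut,meanCut thresholds in mm.
#' @return list with `keep` (named logical over subjects) and `report`
#'   (\linkS4class{QcReport} with per-subject reason codes).
#' @export
excludeHighMotionSubjects <- function(confounds, maxCut = 1.3, meanCut = 0.3) {
  stopifnot(is(confounds, "ConfoundTable"))
  if (anyNA(confounds@meanFd) || anyNA(confounds@maxFd))
    stop("missing framewise-displacement value(s); cannot apply motion QC")
  byMax <- confounds@maxFd > maxCut
  byMean <- confounds@meanFd > meanCut
  keep <- !(byMax | byMean)
  names(keep) <- confounds@subjectIds
  reason <- ifelse(byMax, "max_fd", "mean_fd")[!keep]
  report <- new("QcReport",
                excludedSubjects = data.frame(
                  subject_id = confounds@subjectIds[!keep],
                  reason = reason, stringsAsFactors = FALSE))
  list(keep = keep, report = report)
}

#' Remove near-constant variables
#'
#' Drops every variable whose modal value accounts for strictly more than
#' `shareCut` (default 95%) of the non-missing entries; a column with exactly
#' 95 of 100 identical values is retained. In the motivating behavioural
#' table this removed 8 of 372 items, leaving 364.
#'
#' @param view a \linkS4class{DataView} (missing entries allowed).
#' @param shareCut modal-share threshold in (0, 1\].
#' @return list with `view` (filtered \linkS4class{DataView}) and `report`.
#' @export
filterNearConstant <- function(view, shareCut = 0.95) {
  stopifnot(is(view, "DataView"))
  if (nSubjects(view) < 2L) stop("need at least 2 subjects")
  v <- viewValues(view)
  share <- apply(v, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(1)
    max(tabulate(match(col, unique(col)))) / length(col)
  })
  drop <- share > shareCut
  report <- new("QcReport", removedVariables = colnames(v)[drop])
  list(view = DataView(v[, !drop, drop = FALSE], missingOk = view@missingOk),
       report = report)
}

#' Median-impute missing entries
#'
#' Replaces each missing entry by the median of the observed values of its
#' variable (even counts: mean of the two middle values). A variable with no
#' observed value is an error.
#'
#' @param view a \linkS4class{DataView} with `missingOk = TRUE`.
#' @return list with `view` (complete \linkS4class{DataView}, `missingOk`
#'   FALSE) and `report` carrying per-variable imputation counts.
#' @export
imputeMedian <- function(view) {
  stopifnot(is(view, "DataView"))
  v <- viewValues(view)
  counts <- colSums(is.na(v))
  if (any(counts == nrow(v)))
    stop("variable(s) fully missing: ",
         paste(colnames(v)[counts == nrow(v)], collapse = ", "))
  medians <- apply(v, 2, stats::median, na.rm = TRUE)
  for (j in which(counts > 0)) v[is.na(v[, j]), j] <- medians[j]
  imputed <- counts[counts > 0]
  report <- new("QcReport",
                imputationCounts = stats::setNames(as.integer(imputed),
                                                   names(imputed)))
  list(view = DataView(v, missingOk = FALSE), report = report,
       medians = medians)
}

#' One-hot encoding of scanner site
#'
#' One binary column per site label in the declared order; each subject's row
#' sums to 1 (e.g. `[0 0 1]` for the third site). A label outside
#' `labelOrder` is an error.
#'
#' @param confounds a \linkS4class{ConfoundTable}.
#' @param labelOrder site labels in column order; defaults to the sorted
#'   unique labels present.
#' @return n x length(labelOrder) 0/1 matrix with label colnames.
#' @export
oneHotSite <- function(confounds, labelOrder = sort(unique(confounds@site))) {
  stopifnot(is(confounds, "ConfoundTable"))
  unseen <- setdiff(unique(confounds@site), labelOrder)
  if (length(unseen))
    stop("site label(s) not in labelOrder: ", paste(unseen, collapse = ", "))
  m <- outer(confounds@site, labelOrder, `==`) + 0
  dimnames(m) <- list(confounds@subjectIds, labelOrder)
  m
}

#' Build the confound regression design
#'
#' Mean framewise displacement plus one-hot site columns. With an intercept
#' in the regression the full one-hot set is collinear, so the last site
#' column is dropped by default to keep the design full-rank.
#'
#' @param confounds a \linkS4class{ConfoundTable}.
#' @param labelOrder site label order for the one-hot block.
#' @param dropLast drop the last one-hot column (default TRUE).
#' @return n x k numeric design matrix (no intercept column).
#' @export
buildConfoundDesign <- function(confounds,
                                labelOrder = sort(unique(confounds@site)),
                                dropLast = TRUE) {
  oh <- oneHotSite(confounds, labelOrder)
  if (dropLast && ncol(oh) > 1L) oh <- oh[, -ncol(oh), drop = FALSE]
  cbind(mean_fd = confounds@meanFd, oh)
}

#' Regress confounds out of a data view
#'
#' Per-variable ordinary least squares on the confound design (an intercept
#' is always added); returns the residuals, which are exactly orthogonal to
#' the intercept and to every confound column. A rank-deficient design is an
#' error.
#'
#' @param view a complete \linkS4class{DataView}.
#' @param design confound matrix from [buildConfoundDesign()] (rows aligned
#'   with the view's subjects).
#' @return list with `view` (residual \linkS4class{DataView}) and `beta`
#'   (the (1+k) x m coefficient matrix, reusable on new subjects).
#' @export
regressConfounds <- function(view, design) {
  stopifnot(is(view, "DataView"))
  v <- viewValues(view)
  if (anyNA(v)) stop("missing values; impute before confound regression")
  design <- as.matrix(design)
  if (nrow(design) != nrow(v)) stop("design rows do not match subjects")
  fit <- .olsFit(design, v)
  list(view = DataView(fit$residuals), beta = fit$beta)
}

# apply previously fitted confound coefficients to new subjects
.applyConfoundBeta <- function(view, design, beta) {
  v <- viewValues(view)
  X <- cbind(1, as.matrix(design))
  DataView(v - X %*% beta)
}

#' Standardize every variable to mean 0, SD 1
#'
#' Column-wise centring and scaling with the sample standard deviation. A
#' zero-variance column is an error: it should be impossible after the
#' near-constant filter and is never silently zeroed.
#'
#' @param view a complete \linkS4class{DataView}.
#' @return list with `view` (standardized), `center` and `scale` (named
#'   numeric vectors reusable on new subjects).
#' @export
standardizeView <- function(view) {
  stopifnot(is(view, "DataView"))
  v <- viewValues(view)
  if (anyNA(v)) stop("missing values; impute before standardizing")
  ctr <- colMeans(v)
  sc <- apply(v, 2, stats::sd)
  if (any(sc < 1e-12))
    stop("zero-variance variable(s): ",
         paste(colnames(v)[sc < 1e-12], collapse = ", "))
  list(view = DataView(scale(v, center = ctr, scale = sc)[, , drop = FALSE]),
       center = ctr, scale = sc)
}

#' Default preprocessing configuration
#'
#' All thresholds default to the motivating study's values: motion cuts
#' 1.3 mm (max FD) and 0.3 mm (mean FD), near-constant modal share 0.95.
#'
#' @param maxFdCut,meanFdCut motion-exclusion thresholds (mm).
#' @param shareCut near-constant modal-share threshold.
#' @param siteLevels site label order for one-hot coding; `NULL` = sorted
#'   unique labels of the data.
#' @return named list of settings for [preprocessPipeline()].
#' @export
preprocessConfig <- function(maxFdCut = 1.3, meanFdCut = 0.3, shareCut = 0.95,
                             siteLevels = NULL) {
  list(maxFdCut = maxFdCut, meanFdCut = meanFdCut, shareCut = shareCut,
       siteLevels = siteLevels)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: motion-based subject exclusion (both views and
#' confounds restricted consistently); near-constant filtering of the
#' behaviour view (modal share over observed values); median imputation of
#' the behaviour view; confound regression of both views on mean FD and
#' one-hot site; standardization of both views. Returns the processed bundle,
#' the accumulated \linkS4class{QcReport}, and a fitted-parameter model for
#' replaying the pipeline on new subjects.
#'
#' @param bundle a \linkS4class{DatasetBundle}.
#' @param config settings from [preprocessConfig()].
#' @return list with `bundle` (processed), `report`
#'   (\linkS4class{QcReport}) and `model` (parameters for
#'   [preprocessApply()]).
#' @export
preprocessPipeline <- function(bundle, config = preprocessConfig()) {
  stopifnot(is(bundle, "DatasetBundle"))
  motion <- excludeHighMotionSubjects(bundle@confounds,
                                      maxCut = config$maxFdCut,
                                      meanCut = config$meanFdCut)
  keep_ids <- names(motion$keep)[motion$keep]
  if (!length(keep_ids)) stop("motion QC excluded every subject")
  bundle <- subsetSubjects(bundle, keep_ids)
  report <- motion$report

  nc <- filterNearConstant(bundle@behaviour, shareCut = config$shareCut)
  report <- .mergeQc(report, nc$report)
  imp <- imputeMedian(nc$view)
  report <- .mergeQc(report, imp$report)

  siteLevels <- config$siteLevels %||% sort(unique(bundle@confounds@site))
  design <- buildConfoundDesign(bundle@confounds, labelOrder = siteLevels)
  # a degenerate confound column (single site, zero FD variance) is constant
  # and already captured by the intercept: drop it rather than erroring
  keepCols <- apply(design, 2, stats::sd) > 0
  if (any(!keepCols))
    report@notes <- c(report@notes,
                      sprintf("constant confound column(s) dropped: %s",
                              paste(colnames(design)[!keepCols], collapse = ", ")))
  design <- design[, keepCols, drop = FALSE]
  rb <- regressConfounds(bundle@brain, design)
  ry <- regressConfounds(imp$view, design)
  sb <- standardizeView(rb$view)
  sy <- standardizeView(ry$view)

  out <- DatasetBundle(brain = sb$view, behaviour = sy$view,
                       confounds = bundle@confounds)
  model <- list(config = config, siteLevels = siteLevels,
                confoundCols = colnames(design),
                keptBehaviourVars = variableIds(nc$view),
                medians = imp$medians,
                brainBeta = rb$beta, behaviourBeta = ry$beta,
                brainCenter = sb$center, brainScale = sb$scale,
                behaviourCenter = sy$center, behaviourScale = sy$scale)
  list(bundle = out, report = report, model = model)
}

#' Replay a fitted preprocessing pipeline on new subjects
#'
#' Applies training-derived parameters only: the same motion thresholds, the
#' training variable set, training medians for imputation, training confound
#' coefficients and training centring/scaling. Nothing is re-estimated, so
#' hold-out test subjects never leak into the training-side fit.
#'
#' @param model the `model` element returned by [preprocessPipeline()].
#' @param bundle a \linkS4class{DatasetBundle} of new subjects.
#' @return list with `bundle` (processed) and `report`.
#' @export
preprocessApply <- function(model, bundle) {
  stopifnot(is(bundle, "DatasetBundle"))
  cfg <- model$config
  motion <- excludeHighMotionSubjects(bundle@confounds, maxCut = cfg$maxFdCut,
                                      meanCut = cfg$meanFdCut)
  keep_ids <- names(motion$keep)[motion$keep]
  if (!length(keep_ids)) stop("motion QC excluded every test subject")
  bundle <- subsetSubjects(bundle, keep_ids)

  y <- viewValues(bundle@behaviour)[, model$keptBehaviourVars, drop = FALSE]
  for (j in seq_len(ncol(y)))
    y[is.na(y[, j]), j] <- model$medians[[colnames(y)[j]]]
  design <- buildConfoundDesign(bundle@confounds,
                                labelOrder = model$siteLevels)[
    , model$confoundCols, drop = FALSE]
  xb <- .applyConfoundBeta(bundle@brain, design, model$brainBeta)
  yb <- .applyConfoundBeta(DataView(y), design, model$behaviourBeta)
  xs <- DataView(scale(viewValues(xb), center = model$brainCenter,
                       scale = model$brainScale)[, , drop = FALSE])
  ys <- DataView(scale(viewValues(yb), center = model$behaviourCenter,
                       scale = model$behaviourScale)[, , drop = FALSE])
  list(bundle = DatasetBundle(brain = xs, behaviour = ys,
                              confounds = bundle@confounds),
       report = motion$report)
}

#' Cohort accounting from exclusion counts
#'
#' Bookkeeping helper for stated per-cohort exclusion tallies: subtracts each
#' cohort's exclusions from its initial size and totals the retained
#' subjects.
#'
#' @param cohorts named list; each element is
#'   `list(initial = <int>, excluded = <named integer vector of counts>)`.
#' @return list with `perCohort` (data.frame: cohort, initial, excluded,
#'   retained) and `total` (integer sum of retained).
#' @export
accountExclusions <- function(cohorts) {
  rows <- lapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    excl <- sum(co$excluded)
    if (excl > co$initial) stop("more exclusions than subjects in ", nm)
    data.frame(cohort = nm, initial = co$initial, excluded = excl,
               retained = co$initial - excl, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(perCohort = per, total = sum(per$retained))
}
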