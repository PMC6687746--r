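# End-to-end orchestration: preprocess -> dimensionality selection by
# permutation -> final CCA at the chosen d -> loadings and report tables,
# with every output written to a run directory alongside the verbatim
# configuration for provenance.

#' Configuration of a full analysis run
#'
#' @param candidateDs candidate PCA grid (default [defaultCandidateDims()]).
#' @param nPerm permutations per candidate (the motivating analysis used
#'   10000).
#' @param alpha nominal FWE level before Bonferroni correction over the grid.
#' @param topK variables per sign in the report tables.
#' @param seed master seed.
#' @param preprocess settings from [preprocessConfig()].
#' @return named list of class `RunConfig`.
#' @export
runConfig <- function(candidateDs = defaultCandidateDims(), nPerm = 10000,
                      alpha = 0.05, topK = 20L, seed = 1L,
                      preprocess = preprocessConfig()) {
  cfg <- list(candidateDs = as.integer(candidateDs), nPerm = as.integer(nPerm),
              alpha = alpha, topK = as.integer(topK), seed = as.integer(seed),
              preprocess = preprocess)
  class(cfg) <- "RunConfig"
  cfg
}

.writeTsv <- function(df, path) data.table::fwrite(df, path, sep = "\t")

#' Run the full analysis and write a reproducible run directory
#'
#' Stages: preprocessing with QC (motion exclusion, near-constant filter,
#' imputation, confound regression, standardization); permutation-based
#' selection of the PCA dimensionality over the candidate grid; at the chosen
#' d, per-mode FWE p-values and the final CCA (modes oriented so the
#' strongest behavioural loading of each mode is positive); loadings of both
#' views and top-`topK` tables for every significant mode. All numeric
#' outputs are deterministic given the configuration: re-running with the
#' same config yields byte-identical files (`run.log` carries timestamps and
#' is the one exception).
#'
#' Written files: `run_config.json` (verbatim configuration), `qc.json`,
#' `selection.json` (per-candidate p-values, chosen d), `pvalues.json`
#' (per-mode q and p_FWE at the chosen d), `loadings_brain.tsv`,
#' `loadings_behaviour.tsv`, `top_behaviour_modeK.tsv` /
#' `top_brain_modeK.tsv` per significant mode, `variates.tsv`, `run.log`.
#'
#' @param bundle a raw \linkS4class{DatasetBundle}.
#' @param outDir output directory, created if needed.
#' @param config a [runConfig()].
#' @return invisibly, a list with `selection`
#'   (\linkS4class{ModelSelectionResult}), `permutation`
#'   (\linkS4class{PermutationResult} at the chosen d or `NULL`), `cca`,
#'   `loadings` and `qc`.
#' @export
runFullAnalysis <- function(bundle, outDir, config = runConfig()) {
  stopifnot(is(bundle, "DatasetBundle"), inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  logLine <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   sprintf(...))
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    message(msg)
  }
  jsonlite::write_json(list(candidate_ds = config$candidateDs,
                            n_perm = config$nPerm, alpha = config$alpha,
                            top_k = config$topK, seed = config$seed,
                            preprocess = config$preprocess),
                       file.path(outDir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logLine("run started; %d subjects", nSubjects(bundle))

  pp <- preprocessPipeline(bundle, config$preprocess)
  writeQcReport(pp$report, file.path(outDir, "qc.json"))
  logLine("preprocessing done: %d subjects retained, brain %d x behaviour %d",
          nSubjects(pp$bundle), nVariables(pp$bundle@brain),
          nVariables(pp$bundle@behaviour))

  sel <- selectPcaDimension(pp$bundle@brain, pp$bundle@behaviour,
                            candidateDs = config$candidateDs,
                            nPerm = config$nPerm, alpha = config$alpha,
                            seed = config$seed)
  jsonlite::write_json(
    list(candidate_ds = sel@candidateDs, first_mode_p = sel@firstModeP,
         corrected_p = sel@correctedP, bonferroni_alpha = sel@bonferroniAlpha,
         chosen_d = if (is.na(sel@chosenD)) NULL else sel@chosenD,
         no_significant_mode = is.na(sel@chosenD)),
    file.path(outDir, "selection.json"), auto_unbox = TRUE, digits = NA,
    null = "null")

  if (is.na(sel@chosenD)) {
    logLine("no candidate dimensionality reached significance; stopping")
    return(invisible(list(selection = sel, permutation = NULL, cca = NULL,
                          loadings = NULL, qc = pp$report)))
  }
  d <- sel@chosenD
  perm <- sel@results[[match(d, sel@candidateDs)]]
  sig <- significantModes(perm, alpha = config$alpha)
  logLine("chosen d = %d; %d significant mode(s)", d, length(sig))
  jsonlite::write_json(
    list(d = d, q = perm@trueCorrelations, p_fwe = perm@pFwe,
         p_display = formatPermutationP(perm@pFwe, perm@nPerm),
         n_perm = perm@nPerm, significant_modes = sig),
    file.path(outDir, "pvalues.json"), auto_unbox = TRUE, digits = NA)

  pcaX <- pcaReduce(pp$bundle@brain, d)
  pcaY <- pcaReduce(pp$bundle@behaviour, d)
  cca <- orientModes(fitCca(pcaX@scores, pcaY@scores), pp$bundle@behaviour)
  lb <- variableLoadings(pp$bundle@brain, variates(cca, "x"))
  ly <- variableLoadings(pp$bundle@behaviour, variates(cca, "y"))
  .writeTsv(data.frame(variable = rownames(lb), lb, check.names = FALSE),
            file.path(outDir, "loadings_brain.tsv"))
  .writeTsv(data.frame(variable = rownames(ly), ly, check.names = FALSE),
            file.path(outDir, "loadings_behaviour.tsv"))
  .writeTsv(data.frame(subject_id = rownames(variates(cca, "x")),
                       brain = variates(cca, "x"),
                       behaviour = variates(cca, "y"), check.names = FALSE),
            file.path(outDir, "variates.tsv"))
  for (k in sig) {
    .writeTsv(selectTop(ly, mode = k, k = min(config$topK, nrow(ly))),
              file.path(outDir, sprintf("top_behaviour_mode%d.tsv", k)))
    .writeTsv(selectTop(lb, mode = k, k = min(config$topK, nrow(lb))),
              file.path(outDir, sprintf("top_brain_mode%d.tsv", k)))
  }
  logLine("run finished")
  invisible(list(selection = sel, permutation = perm, cca = cca,
                 loadings = list(brain = lb, behaviour = ly), qc = pp$report))
}
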