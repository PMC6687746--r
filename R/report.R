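# Interpretation tables: ranked loadings, signed top-k / top-fraction
# selections, per-node summaries of selected edges, and network labelling.

#' Rank a mode's loadings
#'
#' Descending by loading value; ties broken lexicographically by variable id
#' so the order is stable.
#'
#' @param loadings m x d loading matrix from [variableLoadings()].
#' @param mode mode index (column) to rank.
#' @return data.frame with columns `variable`, `loading`, sorted.
#' @export
rankLoadings <- function(loadings, mode = 1L) {
  loadings <- as.matrix(loadings)
  if (mode < 1L || mode > ncol(loadings)) stop("mode out of range")
  v <- loadings[, mode]
  ord <- order(-v, rownames(loadings))
  data.frame(variable = rownames(loadings)[ord], loading = unname(v[ord]),
             stringsAsFactors = FALSE)
}

#' Select the most positively and most negatively loaded variables
#'
#' Count rule: exactly `k` variables per sign (the motivating figures use
#' k = 20). Fraction rule: `round(f * m)` per sign with half rounded away
#' from zero, so 0.5% of 60378 edges selects 302 per sign and 5% matches the
#' supplementary overlap analyses. Positive and negative tails are kept
#' separate.
#'
#' @param loadings m x d loading matrix.
#' @param mode mode index.
#' @param k variables per sign (exclusive with `fraction`).
#' @param fraction fraction of all variables per sign.
#' @return data.frame with columns `variable`, `loading`, `sign`
#'   (`"positive"`/`"negative"`), `mode`; positive tail sorted descending,
#'   negative tail ascending (most negative first).
#' @export
selectTop <- function(loadings, mode = 1L, k = NULL, fraction = NULL) {
  if (is.null(k) == is.null(fraction))
    stop("supply exactly one of k or fraction")
  loadings <- as.matrix(loadings)
  m <- nrow(loadings)
  if (!is.null(fraction)) {
    if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
    k <- as.integer(roundHalfAway(fraction * m))
  }
  if (!.isCount(k) || k > m)
    stop("k must be a positive integer no larger than the variable count")
  ranked <- rankLoadings(loadings, mode)
  pos <- ranked[seq_len(k), ]
  neg <- ranked[m - seq_len(k) + 1L, ]   # ascending: most negative first
  out <- rbind(cbind(pos, sign = "positive"), cbind(neg, sign = "negative"))
  out$mode <- as.integer(mode)
  rownames(out) <- NULL
  out
}

#' Summarize selected edges by node
#'
#' For every region incident to at least one selected edge, the mean of the
#' absolute loadings over its incident selected edges (the quantity the
#' motivating figures size nodes by). Regions on no selected edge are absent
#' from the output.
#'
#' @param selection a [selectTop()] data.frame whose variables are edge ids.
#' @param index the [edgeIndex()] the edge ids come from.
#' @return data.frame with columns `region`, `n_edges`, `mean_abs_loading`,
#'   sorted by decreasing mean absolute loading.
#' @export
summarizeByNode <- function(selection, index) {
  pos <- match(selection$variable, index$edge_id)
  if (anyNA(pos))
    stop("unknown edge id(s): ",
         paste(selection$variable[is.na(pos)], collapse = ", "))
  ends <- data.frame(region = c(index$region_i[pos], index$region_j[pos]),
                     loading = rep(selection$loading, 2L),
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(abs(ends$loading), by = list(region = ends$region),
                          FUN = function(z) c(mean(z), length(z)))
  out <- data.frame(region = agg$region,
                    n_edges = as.integer(agg$x[, 2L]),
                    mean_abs_loading = agg$x[, 1L],
                    stringsAsFactors = FALSE)
  out[order(-out$mean_abs_loading, out$region), , drop = FALSE]
}

#' Attach resting-state network labels to a node summary
#'
#' Labels every summarized region with its network (seven cortical networks
#' plus subcortex in the motivating parcellation) and counts selected-edge
#' endpoints per network; the counts sum to twice the number of selected
#' edges. A region without a label is an error listing the offending ids.
#'
#' @param nodeSummary a [summarizeByNode()] data.frame.
#' @param networkMap named character vector `region -> network label`, or a
#'   [readRegionMetadata()] data.frame.
#' @param selection optionally, the [selectTop()] selection and `index` used
#'   for the summary, to count endpoints over all selected edges (defaults
#'   to counting via the node summary's `n_edges`).
#' @return list with `nodes` (labelled summary) and `networkCounts` (named
#'   integer vector of selected-edge endpoints per network).
#' @export
attachNetworks <- function(nodeSummary, networkMap) {
  if (is.data.frame(networkMap))
    networkMap <- stats::setNames(networkMap$network_label,
                                  networkMap$region_id)
  lab <- networkMap[nodeSummary$region]
  if (anyNA(lab) || any(!nzchar(lab)))
    stop("unlabelled region(s): ",
         paste(nodeSummary$region[is.na(lab) | !nzchar(lab)], collapse = ", "))
  nodes <- cbind(nodeSummary, network = unname(lab), stringsAsFactors = FALSE)
  counts <- tapply(nodes$n_edges, nodes$network, sum)
  list(nodes = nodes,
       networkCounts = stats::setNames(as.integer(counts), names(counts)))
}
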