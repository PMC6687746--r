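# Loading, aligning and converting the two views, confounds and region
# metadata; the canonical edge vectorization of symmetric connectivity
# matrices lives here because every downstream edge id depends on it.

#' Canonical edge index of an r-region connectivity matrix
#'
#' Fixes the bijection between unordered region pairs and edge-vector
#' positions: row-major upper triangle with i < j, i.e. pairs
#' (1,2), (1,3), ..., (1,r), (2,3), ..., (r-1,r). An r-region matrix yields
#' r(r-1)/2 edges; the 348-region connectome of the motivating analysis
#' yields 60378.
#'
#' @param regionIds character vector of r (>= 2) region identifiers.
#' @return data.frame with columns `edge_id` (`"<region_i>--<region_j>"`),
#'   `region_i`, `region_j`; one row per edge in canonical order.
#' @examples
#' edgeIndex(c("A", "B", "C"))
#' @export
edgeIndex <- function(regionIds) {
  regionIds <- as.character(regionIds)
  r <- length(regionIds)
  if (r < 2L) stop("need at least 2 regions")
  if (anyDuplicated(regionIds)) stop("duplicate region ids")
  i <- rep.int(seq_len(r - 1L), (r - 1L):1L)
  j <- sequence((r - 1L):1L, from = 2L:r)
  data.frame(edge_id = paste(regionIds[i], regionIds[j], sep = "--"),
             region_i = regionIds[i], region_j = regionIds[j],
             stringsAsFactors = FALSE)
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the upper triangle of a \linkS4class{ConnectivityProfile} in the
#' canonical [edgeIndex()] order, producing one connectivity value per
#' unordered region pair.
#'
#' @param profile a \linkS4class{ConnectivityProfile}.
#' @return list with `values` (named numeric vector of length r(r-1)/2, names
#'   are edge ids) and `index` (the [edgeIndex()] data.frame).
#' @export
vectorizeConnectivity <- function(profile) {
  stopifnot(is(profile, "ConnectivityProfile"))
  validObject(profile)
  m <- profile@matrix
  idx <- edgeIndex(rownames(m))
  # t(m)[lower.tri] walks the upper triangle row by row, matching edgeIndex
  v <- t(m)[lower.tri(m)]
  names(v) <- idx$edge_id
  list(values = v, index = idx)
}

#' Rebuild a connectivity matrix from an edge vector
#'
#' Inverse of [vectorizeConnectivity()]: places each edge value at its region
#' pair (symmetrically) and restores the unit diagonal. The round trip
#' vectorize-then-devectorize is exact.
#'
#' @param values numeric edge vector.
#' @param index an [edgeIndex()] data.frame matching `values` in length.
#' @return a \linkS4class{ConnectivityProfile}.
#' @export
devectorizeConnectivity <- function(values, index) {
  if (length(values) != nrow(index))
    stop(sprintf("edge vector length %d does not match index length %d",
                 length(values), nrow(index)))
  regions <- unique(c(index$region_i, index$region_j))
  r <- length(regions)
  m <- diag(1, r)
  dimnames(m) <- list(regions, regions)
  ii <- match(index$region_i, regions)
  jj <- match(index$region_j, regions)
  m[cbind(ii, jj)] <- values
  m[cbind(jj, ii)] <- values
  ConnectivityProfile(m)
}

#' Stack per-subject connectivity profiles into a brain DataView
#'
#' Vectorizes each subject's profile with the shared canonical edge order and
#' binds them into a subjects x edges \linkS4class{DataView}. All profiles
#' must cover identical regions.
#'
#' @param profiles named list of \linkS4class{ConnectivityProfile}s (names are
#'   subject ids).
#' @return list with `view` (the \linkS4class{DataView}) and `index` (the
#'   shared [edgeIndex()]).
#' @export
stackConnectivity <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    stop("profiles must be uniquely named by subject id")
  ref <- regionIds(profiles[[1]])
  rows <- lapply(profiles, function(p) {
    if (!identical(regionIds(p), ref))
      stop("profiles disagree on regions or their order")
    vectorizeConnectivity(p)$values
  })
  list(view = DataView(do.call(rbind, rows)), index = edgeIndex(ref))
}

#' Align two views and the confounds on their common subjects
#'
#' Restricts brain view, behaviour view and confound table to the
#' intersection of their subject ids, all reordered to the brain view's order
#' restricted to that intersection. Dropped subjects are reported via a
#' message and returned.
#'
#' @param brain,behaviour \linkS4class{DataView}s.
#' @param confounds a \linkS4class{ConfoundTable}.
#' @return list with `bundle` (a \linkS4class{DatasetBundle}) and `dropped`
#'   (character vector of subject ids absent from at least one input).
#' @export
alignSubjects <- function(brain, behaviour, confounds) {
  stopifnot(is(brain, "DataView"), is(behaviour, "DataView"),
            is(confounds, "ConfoundTable"))
  common <- intersect(intersect(subjectIds(brain), subjectIds(behaviour)),
                      subjectIds(confounds))
  if (!length(common)) stop("no subjects shared by all three inputs")
  order_ids <- subjectIds(brain)[subjectIds(brain) %in% common]
  dropped <- setdiff(unique(c(subjectIds(brain), subjectIds(behaviour),
                              subjectIds(confounds))), common)
  if (length(dropped))
    message(sprintf("alignSubjects: dropped %d subject(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  keep <- match(order_ids, subjectIds(confounds))
  bundle <- DatasetBundle(
    brain = DataView(viewValues(brain)[order_ids, , drop = FALSE],
                     missingOk = brain@missingOk),
    behaviour = DataView(viewValues(behaviour)[order_ids, , drop = FALSE],
                         missingOk = behaviour@missingOk),
    confounds = ConfoundTable(order_ids, confounds@meanFd[keep],
                              confounds@maxFd[keep], confounds@site[keep]))
  list(bundle = bundle, dropped = dropped)
}

#' Read a subjects-by-variables matrix from delimited text
#'
#' Expects a header row of variable ids and a first column of subject ids
#' (any delimiter `data.table::fread` can sniff; CSV and TSV both work).
#'
#' @param path file path.
#' @param missingOk allow missing entries (behaviour tables).
#' @return a \linkS4class{DataView}.
#' @export
readDataMatrix <- function(path, missingOk = FALSE) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  DataView(m, missingOk = missingOk)
}

#' Write a DataView to delimited text
#'
#' @param view a \linkS4class{DataView}.
#' @param path destination file; the delimiter follows the file extension
#'   (`.csv` comma, otherwise tab).
#' @return invisibly, `path`.
#' @export
writeDataMatrix <- function(view, path) {
  stopifnot(is(view, "DataView"))
  df <- data.frame(subject_id = subjectIds(view), viewValues(view),
                   check.names = FALSE, stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Read a confound table from delimited text
#'
#' Requires columns `subject_id`, `mean_fd`, `max_fd`, `site`.
#'
#' @param path file path.
#' @return a \linkS4class{ConfoundTable}.
#' @export
readConfoundTable <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("subject_id", "mean_fd", "max_fd", "site")
  if (!all(need %in% names(dt)))
    stop("confound table must have columns: ", paste(need, collapse = ", "))
  ConfoundTable(dt$subject_id, dt$mean_fd, dt$max_fd, dt$site)
}

#' Read region metadata
#'
#' TSV with columns `region_id`, `network_label` and optional coordinates
#' `x`, `y`, `z`; the network labels feed [attachNetworks()].
#'
#' @param path file path.
#' @return data.frame of region metadata.
#' @export
readRegionMetadata <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("region_id", "network_label") %in% names(dt)))
    stop("region metadata must have columns region_id and network_label")
  dt
}
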