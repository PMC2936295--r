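# Edge selection from the z-score matrix: at a target precision against a
# reference network, at a fixed threshold, or as a fixed count.

#' Reference interaction network
#'
#' A set of known regulator -> target interactions (RegulonDB-style extract)
#' used both to annotate inferred edges and to calibrate thresholds via
#' precision on the reduced graph.
#'
#' @param edges data.frame with columns `regulator` and `target`.
#' @return object of class `ReferenceNetwork` with fields `known_edges`,
#'   `regulators_with_targets`, `targets_with_regulators`.
#' @export
reference_network <- function(edges) {
  if (!all(c("regulator", "target") %in% names(edges)))
    stop("reference edges need columns 'regulator' and 'target'")
  edges <- unique(edges[, c("regulator", "target")])
  structure(list(known_edges = edges,
                 regulators_with_targets = unique(edges$regulator),
                 targets_with_regulators = unique(edges$target),
                 key = paste(edges$regulator, edges$target, sep = "\r")),
            class = "ReferenceNetwork")
}

#' @export
print.ReferenceNetwork <- function(x, ...) {
  cat("ReferenceNetwork:", nrow(x$known_edges), "known edges,",
      length(x$regulators_with_targets), "regulators,",
      length(x$targets_with_regulators), "targets\n")
  invisible(x)
}

.annotate_known <- function(edges, reference) {
  if (is.null(reference)) {
    edges$known <- rep(NA, nrow(edges))
  } else {
    edges$known <- paste(edges$regulator, edges$target, sep = "\r") %in%
      reference$key
  }
  edges
}

.zmat_edges <- function(zmat) {
  stopifnot(inherits(zmat, "ZScoreMatrix"))
  idx <- which(!is.na(zmat$z), arr.ind = TRUE)
  data.frame(regulator = zmat$regulator_ids[idx[, 1L]],
             target = zmat$target_ids[idx[, 2L]],
             z = zmat$z[idx],
             stringsAsFactors = FALSE)
}

#' Reduce an edge set to the calibratable subgraph
#'
#' Precision can only be judged where the reference has something to say:
#' an edge (r, t) is kept iff r has at least one known target and t has at
#' least one known regulator.
#'
#' @param edges data.frame of interactions (`regulator`, `target`, ...).
#' @param reference a [reference_network()].
#' @return the subset of `edges` in the reduced graph.
#' @export
reduced_graph <- function(edges, reference) {
  stopifnot(inherits(reference, "ReferenceNetwork"))
  edges[edges$regulator %in% reference$regulators_with_targets &
          edges$target %in% reference$targets_with_regulators, , drop = FALSE]
}

#' Precision of an edge set on the reduced graph
#'
#' Fraction of known interactions among the inferred interactions, evaluated
#' on the reduced graph only.
#'
#' @inheritParams reduced_graph
#' @return fraction in [0, 1].
#' @export
precision <- function(edges, reference) {
  red <- reduced_graph(edges, reference)
  if (nrow(red) == 0L)
    stop("precision undefined: reduced graph is empty")
  red <- .annotate_known(red, reference)
  mean(red$known)
}

#' All edges at or above a z threshold
#'
#' @param zmat a [clr_zscores()] result.
#' @param tau z-score threshold.
#' @param reference optional [reference_network()] for known/unknown flags.
#' @return data.frame with columns `regulator`, `target`, `z`, `known`,
#'   ordered by decreasing z (ties: regulator then target).
#' @export
edges_at_threshold <- function(zmat, tau, reference = NULL) {
  e <- .zmat_edges(zmat)
  e <- e[e$z >= tau, , drop = FALSE]
  e <- e[order(-e$z, e$regulator, e$target), , drop = FALSE]
  rownames(e) <- NULL
  .annotate_known(e, reference)
}

#' Top-k edges by z-score
#'
#' Ties at the boundary are broken deterministically by (regulator, target)
#' lexicographic order.
#'
#' @inheritParams edges_at_threshold
#' @param k number of edges to return.
#' @return data.frame as in [edges_at_threshold()].
#' @export
edges_top_k <- function(zmat, k, reference = NULL) {
  e <- .zmat_edges(zmat)
  e <- e[order(-e$z, e$regulator, e$target), , drop = FALSE]
  e <- utils::head(e, k)
  rownames(e) <- NULL
  .annotate_known(e, reference)
}

#' Calibrate the z threshold at a target precision
#'
#' Scans the observed z values and returns the smallest threshold tau whose
#' edge set reaches the target precision on the reduced graph -- i.e. the
#' largest network satisfying the precision constraint. The returned edge
#' set is the full (non-reduced) set at tau; precision is nonetheless
#' guaranteed >= target on its reduced subgraph by construction.
#'
#' @inheritParams edges_at_threshold
#' @param reference a [reference_network()] (required).
#' @param target_precision fraction in (0, 1].
#' @return list with `threshold`, `edges` (as [edges_at_threshold()]) and
#'   `achieved_precision` on the reduced graph.
#' @export
threshold_at_precision <- function(zmat, reference, target_precision) {
  stopifnot(inherits(reference, "ReferenceNetwork"))
  if (!(target_precision > 0 && target_precision <= 1))
    stop("target_precision must be in (0, 1]")
  e <- .zmat_edges(zmat)
  e <- .annotate_known(e, reference)
  in_red <- e$regulator %in% reference$regulators_with_targets &
    e$target %in% reference$targets_with_regulators
  # descending walk: at candidate tau = each distinct observed z, the reduced
  # set is the cumulative reduced edges with z >= tau
  o <- order(-e$z)
  zs <- e$z[o]
  cum_red <- cumsum(in_red[o])
  cum_known <- cumsum(in_red[o] & e$known[o])
  last_of_tie <- c(zs[-1L] < zs[-length(zs)], TRUE)
  cand <- which(last_of_tie & cum_red > 0)
  prec <- cum_known[cand] / cum_red[cand]
  ok <- which(prec >= target_precision)
  if (length(ok) == 0L)
    stop("no threshold reaches precision ", target_precision,
         " on the reduced graph")
  pick <- max(ok)  # largest network, i.e. smallest tau
  tau <- zs[cand[pick]]
  list(threshold = tau,
       edges = edges_at_threshold(zmat, tau, reference),
       achieved_precision = prec[pick])
}
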