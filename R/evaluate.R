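#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples under
#' the permutation model; 1 means identical partitions (up to label names).
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  if (length(labels_a) < 2L) stop("need at least 2 samples")
  as.numeric(mclust::adjustedRandIndex(labels_a, labels_b))
}

#' Kruskal-Wallis rank test of a variable across groups
#'
#' Non-parametric one-way analysis: rank-based H statistic with tie
#' correction, p-value from the chi-square approximation with
#' (number of groups - 1) degrees of freedom.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 non-empty groups).
#' @return list with `H` and `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) stop("values and groups must align")
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, p_value = 1))  # all ranks tied: no rank variation
  res <- stats::kruskal.test(values, g)
  p <- res$p.value
  if (p == 0) p <- .Machine$double.xmin  # report the underflow bound, not 0
  list(H = unname(res$statistic), p_value = p)
}

lcc_mean_degree <- function(edges_i, edges_j, ...) {
  if (!length(edges_i)) return(0)
  g <- igraph::graph_from_edgelist(cbind(edges_i, edges_j), directed = FALSE)
  comp <- igraph::components(g)
  members <- which(comp$membership == which.max(comp$csize))
  mean(igraph::degree(g, v = members))
}

#' Graph filtration curve of an ISN
#'
#' For each threshold t, keeps the edges with weight strictly greater than t
#' and records the mean node degree of the largest connected component of the
#' surviving subgraph (0 if no edge survives). Converts a weighted network
#' into a 1-D curve comparable across samples when a shared threshold grid is
#' used (see [filtration_thresholds()]).
#'
#' @param isn_edges numeric edge-weight vector (length k).
#' @param edge_index data.frame with integer columns `i`, `j` (as in an
#'   `isn_collection`).
#' @param thresholds strictly increasing numeric vector.
#' @return A `filtration_curve`: list with `thresholds` and `values`.
#' @export
filtration_curve <- function(isn_edges, edge_index, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  values <- vapply(thresholds, function(t) {
    keep <- isn_edges > t
    lcc_mean_degree(edge_index$i[keep], edge_index$j[keep])
  }, numeric(1L))
  structure(list(thresholds = thresholds, values = values),
            class = "filtration_curve")
}

#' Shared threshold grid for filtration curves
#'
#' Evenly spaced quantiles of the pooled edge-weight distribution across all
#' ISNs, so that curves are comparable between samples.
#'
#' @param isns an `isn_collection`.
#' @param n_thresholds number of grid points (default 100).
#' @return Strictly increasing numeric vector.
#' @export
filtration_thresholds <- function(isns, n_thresholds = 100L) {
  q <- stats::quantile(isns$W, probs = seq(0, 1, length.out = n_thresholds),
                       names = FALSE)
  unique(q)
}

#' Per-cluster mean-ISN largest connected components
#'
#' For every cluster, averages the member ISN edge vectors, binarizes the mean
#' network at the `1 - top_fraction` quantile of its edge weights (strictly
#' greater retained, ties at the quantile excluded) and returns the node ids
#' of the largest connected component of the resulting simple graph.
#'
#' @param isns an `isn_collection`.
#' @param labels a `cluster_labels` object or integer vector.
#' @param top_fraction fraction of edges retained (default 0.01, the top 1%).
#' @return Named list (one entry per cluster) of character vectors of node
#'   ids.
#' @export
cluster_mean_isn_lcc <- function(isns, labels, top_fraction = 0.01) {
  stopifnot(inherits(isns, "isn_collection"))
  if (inherits(labels, "cluster_labels")) labels <- labels$labels
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must lie in (0, 1)")
  if (length(labels) != nrow(isns$W)) stop("labels must align with samples")
  out <- list()
  for (cl in sort(unique(labels))) {
    rows <- which(labels == cl)
    if (!length(rows)) stop("empty cluster ", cl)
    mw <- colMeans(isns$W[rows, , drop = FALSE])
    thr <- stats::quantile(mw, 1 - top_fraction, names = FALSE)
    keep <- mw > thr
    if (!any(keep)) { out[[as.character(cl)]] <- character(0); next }
    g <- igraph::graph_from_edgelist(
      cbind(isns$edge_index$i[keep], isns$edge_index$j[keep]),
      directed = FALSE)
    comp <- igraph::components(g)
    members <- which(comp$membership == which.max(comp$csize))
    out[[as.character(cl)]] <- isns$global$node_ids[members]
  }
  out
}
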