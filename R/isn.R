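#' Build the phenotype-augmented global correlation network
#'
#' Nodes are the selected features (X block then Y block). The weight of edge
#' (i, j) is the sum of three Pearson correlations computed over all samples:
#' `corr(Vi, Vj) + corr(Vi, Z) + corr(Vj, Z)`, so each edge lies in
#' `[-3, 3]`. The diagonal is set to 0.
#'
#' @param data a [multiview_dataset()].
#' @param idx_x,idx_y selected column indices into X resp. Y
#'   (e.g. from [selected_features()]).
#' @return A `global_network`: list with `node_ids`, `edges` (r x r symmetric
#'   matrix, zero diagonal) and `corr_z` (r-vector of feature-phenotype
#'   correlations).
#' @export
build_global_network <- function(data, idx_x, idx_y) {
  stopifnot(inherits(data, "multiview_dataset"))
  V <- cbind(data$X[, idx_x, drop = FALSE], data$Y[, idx_y, drop = FALSE])
  r <- ncol(V)
  if (r < 2L) stop("need at least 2 selected features")
  if (nrow(V) < 4L) stop("need at least 4 samples")
  sds <- apply(V, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance selected feature: ", colnames(V)[which(sds == 0)[1L]])
  cz <- as.numeric(stats::cor(V, data$Z))
  E <- stats::cor(V) + outer(cz, cz, "+")
  diag(E) <- 0
  E <- (E + t(E)) / 2  # enforce exact symmetry
  node_ids <- c(data$feature_ids_x[idx_x], data$feature_ids_y[idx_y])
  dimnames(E) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, edges = E, corr_z = cz),
            class = "global_network")
}

# Fixed lexicographic upper-triangle edge order (i < j), X-block first.
edge_index_pairs <- function(node_ids) {
  r <- length(node_ids)
  i <- sequence(seq_len(r - 1L))                 # 1; 1 2; 1 2 3; ...
  j <- rep(2:r, 1:(r - 1L))
  ord <- order(i, j)
  data.frame(i = i[ord], j = j[ord],
             feature_i = node_ids[i[ord]], feature_j = node_ids[j[ord]],
             stringsAsFactors = FALSE)
}

# lower.tri() column-major extraction of a symmetric matrix enumerates pairs
# (1,2),(1,3),...,(1,r),(2,3),... i.e. exactly the lexicographic (i,j) order.
lower_tri_vec <- function(M) M[lower.tri(M)]

#' Build individual-specific networks by leave-one-out perturbation
#'
#' For every sample s, the network is recomputed on the remaining n - 1
#' samples and the ISN edge weight is the absolute difference
#' `|e(all) - e(without s)|` for every feature pair i < j. The pairwise
#' feature correlations are genuinely recomputed on each leave-one-out subset
#' (with that subset's own means and standard deviations); the two
#' phenotype-correlation terms of the edge weight are cohort-level quantities
#' estimated once on all samples and enter the global and the leave-one-out
#' network alike, so they cancel in the absolute difference and the ISN edge
#' reduces to the perturbation of the feature-feature correlation. (Were they
#' recomputed per subset, every edge of sample s would inherit a shared
#' noise term driven by that sample's phenotype value, which swamps the
#' between-sample correlation signal; see the methods vignette.) A
#' moment-downdating fast path (compiled, O(n r^2) total) produces results
#' identical to naive full recomputation.
#'
#' @param data a [multiview_dataset()].
#' @param idx_x,idx_y selected column indices into X resp. Y.
#' @return An `isn_collection`: list with `sample_ids`, `edge_index`
#'   (data.frame of pairs in fixed lexicographic order), `W` (n x k matrix of
#'   non-negative edge weights) and the `global` network.
#' @export
build_isns <- function(data, idx_x, idx_y) {
  stopifnot(inherits(data, "multiview_dataset"))
  n <- length(data$Z)
  if (n < 4L) stop("leave-one-out ISNs need at least 4 samples")
  glob <- build_global_network(data, idx_x, idx_y)
  V <- cbind(data$X[, idx_x, drop = FALSE], data$Y[, idx_y, drop = FALSE])
  W <- cpp_build_isns(V, lower_tri_vec(stats::cor(V)))
  ei <- edge_index_pairs(glob$node_ids)
  rownames(W) <- data$sample_ids
  structure(list(sample_ids = data$sample_ids, edge_index = ei, W = W,
                 global = glob),
            class = "isn_collection")
}

#' @export
print.isn_collection <- function(x, ...) {
  cat("isn_collection: ", nrow(x$W), " samples x ", ncol(x$W),
      " edges over ", length(x$global$node_ids), " nodes\n", sep = "")
  invisible(x)
}

#' Pairwise Euclidean distances between ISN edge vectors
#'
#' @param isns an `isn_collection`.
#' @return n x n symmetric matrix of unsquared Euclidean distances, zero
#'   diagonal.
#' @export
isn_distance_matrix <- function(isns) {
  stopifnot(inherits(isns, "isn_collection"))
  W <- isns$W
  rs <- rowSums(W^2)
  D2 <- outer(rs, rs, "+") - 2 * tcrossprod(W)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(isns$sample_ids, isns$sample_ids)
  D
}

#' ISN distances without materializing the edge matrix
#'
#' Computes the same n x n Euclidean distance matrix as
#' `isn_distance_matrix(build_isns(...))` but processes the edges in chunks
#' (each edge computed exactly once) and accumulates the sample Gram matrix
#' chunk by chunk, so memory stays at O(n x chunk + n^2) instead of
#' O(n x k). Used by [run_netmug()] when the full edge matrix would be very
#' large.
#'
#' @param data a [multiview_dataset()].
#' @param idx_x,idx_y selected column indices into X resp. Y.
#' @param chunk_edges edges per chunk (default sized to ~600 MB per chunk).
#' @return n x n symmetric distance matrix with sample ids as dimnames.
#' @export
isn_distances_lowmem <- function(data, idx_x, idx_y, chunk_edges = NULL) {
  stopifnot(inherits(data, "multiview_dataset"))
  n <- length(data$Z)
  if (n < 4L) stop("leave-one-out ISNs need at least 4 samples")
  build_global_network(data, idx_x, idx_y)  # runs the variance/Z checks
  V <- cbind(data$X[, idx_x, drop = FALSE], data$Y[, idx_y, drop = FALSE])
  k <- ncol(V) * (ncol(V) - 1) / 2
  if (is.null(chunk_edges))
    chunk_edges <- max(1000, min(k, as.integer(600e6 / (8 * n))))
  D <- cpp_isn_distances(V, lower_tri_vec(stats::cor(V)), chunk_edges)
  dimnames(D) <- list(data$sample_ids, data$sample_ids)
  D
}

#' Write ISNs as a long-format edge table
#'
#' @param isns an `isn_collection`.
#' @param path output TSV path (columns sample_id, feature_i, feature_j,
#'   weight).
#' @return Invisibly, `path`.
#' @export
write_isn_table <- function(isns, path) {
  k <- nrow(isns$edge_index)
  df <- data.frame(
    sample_id = rep(isns$sample_ids, each = k),
    feature_i = rep(isns$edge_index$feature_i, times = nrow(isns$W)),
    feature_j = rep(isns$edge_index$feature_j, times = nrow(isns$W)),
    weight = as.vector(t(isns$W)))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
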