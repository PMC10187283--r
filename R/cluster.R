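#' Ward.D2 agglomerative tree from a distance matrix
#'
#' Agglomerative clustering under the Ward minimum-variance criterion with the
#' squared-distance ("ward.D2") Lance-Williams update, appropriate when the
#' input distances are unsquared Euclidean.
#'
#' @param D symmetric distance matrix (or `dist` object), zero diagonal,
#'   non-negative.
#' @return An `hclust` tree (`merge`, `height`, `order`, `labels`).
#' @export
ward_d2_tree <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
      stop("D must be a symmetric square matrix")
    if (any(D < 0)) stop("distances must be non-negative")
    if (any(abs(diag(D)) > 1e-12)) stop("distance diagonal must be zero")
    D <- stats::as.dist(D)
  }
  if (attr(D, "Size") < 2L) stop("need at least 2 samples to build a tree")
  stats::hclust(D, method = "ward.D2")
}

# deepSplit in 0..4 maps to (maxCoreScatter, minGap) as in the dynamic hybrid
# branch-detection literature: more aggressive splitting tolerates a larger
# relative core scatter and requires a smaller gap.
deep_split_params <- function(deep_split) {
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  max_core_scatter <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1L]
  list(max_core_scatter = max_core_scatter,
       min_gap = (1 - max_core_scatter) * 3 / 4)
}

core_size <- function(branch_size, min_cluster_size) {
  base <- min_cluster_size / 2 + 1
  if (base >= branch_size) return(branch_size)
  as.integer(base + sqrt(branch_size - base))
}

# scatter of the branch core: mean of the lowest (coreSize - 1) internal merge
# heights, i.e. how tightly the tightest part of the branch is knit.
branch_core_scatter <- function(heights, size, min_cluster_size) {
  if (!length(heights)) return(0)
  cs <- core_size(size, min_cluster_size)
  hs <- sort(heights)
  mean(hs[seq_len(max(cs - 1L, 1L))])
}

#' Dynamic hybrid tree cut
#'
#' Adaptive extraction of clusters from a dendrogram: candidate branches are
#' detected bottom-up along the merge sequence and accepted as clusters when
#' they are large enough (`min_cluster_size`), internally tight (core scatter
#' below a threshold) and separated from their surroundings by a height gap;
#' the `deep_split` level (0..4, default 1: fewer but larger clusters)
#' controls how permissive the scatter/gap thresholds are. Leaves not falling
#' in any accepted branch are attached to the cluster with the smallest mean
#' distance (using `D`), so every sample receives a label. Labels are
#' 1..K by decreasing cluster size (ties by smallest member index).
#'
#' @param tree an `hclust` tree (e.g. from [ward_d2_tree()]).
#' @param D the distance matrix the tree was built from (used for the
#'   assignment stage).
#' @param deep_split integer 0..4; default 1.
#' @param min_cluster_size minimum branch size to qualify as a cluster;
#'   default 20.
#' @param cut_height maximum joining height considered part of any cluster;
#'   default 99% of the merge-height range above the minimum.
#' @return A `cluster_labels` object: list with `labels` (integer vector,
#'   one per leaf) and `K`. Degenerate trees yield K = 1.
#' @export
dynamic_tree_cut <- function(tree, D, deep_split = 1L, min_cluster_size = 20L,
                             cut_height = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  D <- as.matrix(D)
  h <- tree$height
  if (is.null(cut_height))
    cut_height <- min(h) + 0.99 * (max(h) - min(h))
  par <- deep_split_params(deep_split)
  ref_height <- stats::quantile(h, 0.05, names = FALSE)
  max_abs_scatter <- ref_height + par$max_core_scatter * (cut_height - ref_height)
  min_abs_gap <- par$min_gap * (cut_height - ref_height)

  # branch bookkeeping; entity per processed merge node
  new_branch <- function(members, heights)
    list(members = members, heights = heights, composite = FALSE,
         clusters = list(), unassigned = integer(0))
  singleton <- function(leaf) new_branch(leaf, numeric(0))

  qualifies <- function(br, join_height) {
    size <- length(br$members)
    if (size < min_cluster_size) return(FALSE)
    scatter <- branch_core_scatter(br$heights, size, min_cluster_size)
    top <- if (length(br$heights)) max(br$heights) else 0
    gap <- join_height - top
    scatter <= max_abs_scatter && gap >= min_abs_gap
  }
  # finalize a still-open branch (at the root or severed above cut_height)
  finalize <- function(br) {
    if (br$composite) {
      br$unassigned <- setdiff(br$members, unlist(br$clusters))
      return(br)
    }
    if (qualifies(br, cut_height)) br$clusters <- list(br$members)
    else br$unassigned <- br$members
    br$composite <- TRUE
    br
  }

  entities <- vector("list", nrow(tree$merge))
  get_entity <- function(ref)
    if (ref < 0) singleton(-ref) else entities[[ref]]

  for (t in seq_len(nrow(tree$merge))) {
    b1 <- get_entity(tree$merge[t, 1L])
    b2 <- get_entity(tree$merge[t, 2L])
    ht <- h[t]
    if (ht > cut_height) {
      b1 <- finalize(b1); b2 <- finalize(b2)
      entities[[t]] <- list(members = c(b1$members, b2$members),
                            heights = numeric(0), composite = TRUE,
                            clusters = c(b1$clusters, b2$clusters),
                            unassigned = c(b1$unassigned, b2$unassigned))
      next
    }
    if (!b1$composite && !b2$composite) {
      q1 <- qualifies(b1, ht); q2 <- qualifies(b2, ht)
      if (q1 && q2) {
        entities[[t]] <- list(members = c(b1$members, b2$members),
                              heights = c(b1$heights, b2$heights, ht),
                              composite = TRUE,
                              clusters = list(b1$members, b2$members),
                              unassigned = integer(0))
      } else {
        entities[[t]] <- new_branch(c(b1$members, b2$members),
                                    c(b1$heights, b2$heights, ht))
      }
    } else {
      # at least one side already carries locked clusters
      comp <- list(members = c(b1$members, b2$members), heights = numeric(0),
                   composite = TRUE, clusters = list(), unassigned = integer(0))
      for (br in list(b1, b2)) {
        if (br$composite) {
          comp$clusters <- c(comp$clusters, br$clusters)
          comp$unassigned <- c(comp$unassigned, br$unassigned)
        } else if (qualifies(br, ht)) {
          comp$clusters <- c(comp$clusters, list(br$members))
        } else {
          comp$unassigned <- c(comp$unassigned, br$members)
        }
      }
      entities[[t]] <- comp
    }
  }
  root <- finalize(entities[[nrow(tree$merge)]])
  clusters <- root$clusters
  unassigned <- root$unassigned

  labels <- integer(n)
  if (!length(clusters)) {
    labels[] <- 1L
  } else {
    for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
    if (length(unassigned)) {
      for (s in unassigned) {
        md <- vapply(clusters, function(m) mean(D[s, m]), numeric(1L))
        labels[s] <- which.min(md)
      }
    }
    # relabel by decreasing size, ties by smallest member index
    sizes <- tabulate(labels)
    first <- vapply(seq_along(sizes), function(ci) min(which(labels == ci)), integer(1L))
    ord <- order(-sizes, first)
    labels <- match(labels, ord)
  }
  if (!is.null(tree$labels)) names(labels) <- tree$labels
  structure(list(labels = labels, K = max(labels)), class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat("cluster_labels: K = ", x$K, "; sizes: ",
      paste(tabulate(x$labels), collapse = ", "), "\n", sep = "")
  invisible(x)
}
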