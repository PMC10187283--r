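# Independent oracles used across the test suite. These deliberately avoid
# the package's computational paths: correlations via stats::cor on rebuilt
# subsets, agglomeration from scratch at every merge, contingency-table ARI,
# breadth-first search for components.

# lexicographic (i < j) upper-triangle vector of a symmetric matrix
ltv <- function(M) M[lower.tri(M)]

rand_dataset <- function(n, p, q, seed) {
  set.seed(seed)
  multiview_dataset(matrix(rnorm(n * p), n, p),
                    matrix(rnorm(n * q), n, q),
                    rnorm(n))
}

# naive leave-one-out ISNs: rebuild the (n-1)-sample dataset from scratch for
# every s and recompute the pairwise feature correlations with stats::cor;
# the phenotype-correlation terms are cohort-level and common to both
# networks, so the ISN edge is the absolute correlation perturbation.
naive_isns <- function(data, idx_x, idx_y) {
  V <- cbind(data$X[, idx_x, drop = FALSE], data$Y[, idx_y, drop = FALSE])
  c_full <- ltv(stats::cor(V))
  t(vapply(seq_len(nrow(V)), function(s) {
    abs(c_full - ltv(stats::cor(V[-s, , drop = FALSE])))
  }, numeric(length(c_full))))
}

# closed-form Ward.D2 merge cost from raw coordinates:
# sqrt(2 |A| |B| / (|A| + |B|)) * ||centroid_A - centroid_B||_2.
# Recomputes every pairwise cost from scratch after each merge.
naive_ward_d2 <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)            # hclust convention: negatives are leaves
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      a <- length(clusters[[i]]); b <- length(clusters[[j]])
      mu_a <- colMeans(X[clusters[[i]], , drop = FALSE])
      mu_b <- colMeans(X[clusters[[j]], , drop = FALSE])
      cost <- sqrt(2 * a * b / (a + b)) * sqrt(sum((mu_a - mu_b)^2))
      if (cost < best[1]) best <- c(cost, i, j)
    }
    i <- best[2]; j <- best[3]
    merges[step, ] <- c(ids[i], ids[j])
    heights[step] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- step
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merges, height = heights)
}

# naive complete-linkage agglomeration on a distance matrix, recomputing the
# full between-cluster maxima at every step; returns the partition obtained
# by merging while the minimal complete-linkage distance is <= cut_height.
naive_complete_partition <- function(D, cut_height) {
  m <- nrow(D)
  clusters <- lapply(seq_len(m), identity)
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    if (best[1] > cut_height) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  labels <- integer(m)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  labels
}

# adjusted Rand index from the contingency table: (Index - E) / (Max - E)
ari_contingency <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  idx <- sum(ch2(tab))
  ra <- sum(ch2(rowSums(tab))); cb <- sum(ch2(colSums(tab)))
  expd <- ra * cb / ch2(sum(tab))
  (idx - expd) / ((ra + cb) / 2 - expd)
}

same_partition <- function(a, b) ari_contingency(a, b) == 1

# mean degree of the largest connected component, via adjacency-list BFS
bfs_lcc_mean_degree <- function(ei, ej, n_nodes) {
  if (!length(ei)) return(0)
  adj <- vector("list", n_nodes)
  for (e in seq_along(ei)) {
    adj[[ei[e]]] <- c(adj[[ei[e]]], ej[e])
    adj[[ej[e]]] <- c(adj[[ej[e]]], ei[e])
  }
  seen <- logical(n_nodes)
  best <- integer(0)
  for (v in seq_len(n_nodes)) {
    if (seen[v] || !length(adj[[v]])) next
    comp <- integer(0); queue <- v; seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    if (length(comp) > length(best)) best <- comp
  }
  mean(vapply(best, function(v) length(adj[[v]]), numeric(1)))
}

# random-search oracle for the supervised sparse CCA objective: draws random
# unit-vector pairs, rejects those violating the l1 bounds, maximizes the
# objective over the accepted pairs.
random_search_smcca <- function(C, u, v, c1, c2, n_draws, seed) {
  set.seed(seed)
  p <- nrow(C); q <- ncol(C)
  A <- matrix(rnorm(n_draws * p), n_draws, p)
  A <- A / sqrt(rowSums(A^2))
  B <- matrix(rnorm(n_draws * q), n_draws, q)
  B <- B / sqrt(rowSums(B^2))
  ok <- rowSums(abs(A)) <= c1 & rowSums(abs(B)) <= c2
  if (!any(ok)) return(-Inf)
  A <- A[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
  max(rowSums((A %*% C) * B) + as.numeric(A %*% u) + as.numeric(B %*% v))
}
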