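#' Detect multi-view feature modules from a similarity matrix
#'
#' Complete-linkage hierarchical clustering on the distance matrix `1 - S`
#' (diagonal ignored, distances clipped to `[0, 1]`), cut at `cut_height`;
#' clusters with fewer than 2 features or with features from a single view are
#' discarded, leaving multi-view modules only.
#'
#' @param S a `similarity_matrix` (symmetric, entries in `[0, 1]`).
#' @param cut_height cut height on the distance dendrogram, in (0, 1];
#'   default 0.999 (very close to 1, so that any recurrent nonzero similarity
#'   joins a module).
#' @return A `feature_module_set`: list with `modules` (list of integer index
#'   vectors into the concatenated feature list), `feature_ids`, `view_of`,
#'   `cut_height`, and the full `hclust` tree.
#' @export
detect_modules <- function(S, cut_height = 0.999) {
  stopifnot(inherits(S, "similarity_matrix"))
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must lie in (0, 1]")
  M <- S$S
  if (max(abs(M - t(M))) > 1e-12) stop("similarity matrix must be symmetric")
  D <- 1 - M
  D[D < 0] <- 0; D[D > 1] <- 1
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  labels <- stats::cutree(hc, h = cut_height)
  groups <- split(seq_along(labels), labels)
  keep <- vapply(groups, function(g)
    length(g) >= 2L && length(unique(S$view_of[g])) == 2L, logical(1L))
  modules <- unname(groups[keep])
  if (!length(modules))
    message("detect_modules: no multi-view module at cut height ", cut_height)
  structure(list(modules = modules, feature_ids = S$feature_ids,
                 view_of = S$view_of, cut_height = cut_height, tree = hc),
            class = "feature_module_set")
}

#' @export
print.feature_module_set <- function(x, ...) {
  cat("feature_module_set: ", length(x$modules), " multi-view module(s), ",
      length(unlist(x$modules)), " features (cut height ", x$cut_height, ")\n",
      sep = "")
  invisible(x)
}

#' Selected features from a module set
#'
#' Union of all retained modules, split by view, as sorted per-view column
#' indices.
#'
#' @param mods a `feature_module_set` from [detect_modules()].
#' @return list with `idx_x`, `idx_y` (sorted integer vectors of column
#'   indices into X resp. Y).
#' @export
selected_features <- function(mods) {
  stopifnot(inherits(mods, "feature_module_set"))
  if (!length(mods$modules))
    stop("no multi-view modules retained: lower the module cut stringency ",
         "or revisit the sparsity bounds c1/c2")
  all_idx <- sort(unique(unlist(mods$modules)))
  p <- sum(mods$view_of == "X")
  list(idx_x = all_idx[all_idx <= p],
       idx_y = all_idx[all_idx > p] - p)
}
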