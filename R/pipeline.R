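#' Full workflow configuration
#'
#' Collects every hyperparameter of the end-to-end workflow. One global
#' `seed` fans out deterministically to per-stage seeds (cross-validation,
#' subsampling), so a rerun with the same config and inputs reproduces the
#' same labels bit for bit.
#'
#' @param smcca an [smcca_config()].
#' @param cut_height module-detection cut height on the 1 - similarity
#'   dendrogram (default 0.999).
#' @param deep_split,min_cluster_size dynamic tree cut settings (defaults 1
#'   and 20).
#' @param cv_folds,cv_grid_size cross-validation settings used when `c1`/`c2`
#'   are not fixed in `smcca`.
#' @param n_thresholds filtration-curve grid size.
#' @param seed global integer seed.
#' @return A list of class `netmug_config`.
#' @export
netmug_config <- function(smcca = smcca_config(), cut_height = 0.999,
                          deep_split = 1L, min_cluster_size = 20L,
                          cv_folds = 5L, cv_grid_size = 8L,
                          n_thresholds = 100L, seed = 1L) {
  structure(list(smcca = smcca, cut_height = cut_height,
                 deep_split = as.integer(deep_split),
                 min_cluster_size = as.integer(min_cluster_size),
                 cv_folds = as.integer(cv_folds),
                 cv_grid_size = as.integer(cv_grid_size),
                 n_thresholds = as.integer(n_thresholds),
                 seed = as.integer(seed)),
            class = "netmug_config")
}

stage_seed <- function(config, offset) (config$seed * 97L + offset) %% 2147483647L

#' Run the full network-guided multi-view clustering workflow
#'
#' Three stages: (1) phenotype-supervised sparse multiple CCA with feature
#' subsampling selects cross-view feature modules; (2) individual-specific
#' networks are built on the selected features by leave-one-out perturbation
#' of the phenotype-augmented correlation network; (3) samples are clustered
#' on ISN edge vectors with Ward.D2 linkage and a dynamic hybrid tree cut.
#'
#' @param data a [multiview_dataset()] (or pass file paths to [load_views()]
#'   first).
#' @param config a [netmug_config()].
#' @param out_dir optional directory: writes `selected_features.tsv`,
#'   `labels.tsv`, `dendrogram.tsv`, `metrics.json` and the echoed config.
#' @param true_labels optional ground-truth labels; if given, the adjusted
#'   Rand index is included in the metrics.
#' @param keep_isns keep the (potentially large) ISN edge-weight matrix in
#'   the returned object (default TRUE). When the edge matrix would exceed
#'   ~1 GB the pipeline switches to a blocked distance computation
#'   ([isn_distances_lowmem()]) and `isns` is not retained regardless.
#' @param verbose print stage progress messages (default TRUE).
#' @return A `netmug_fit`: list with `labels` (a `cluster_labels`), `cv`
#'   (sparsity selection, if run), `similarity`, `modules`, `selected`,
#'   `isns`, `tree`, `metrics`, `config`.
#' @export
run_netmug <- function(data, config = netmug_config(), out_dir = NULL,
                       true_labels = NULL, keep_isns = TRUE, verbose = TRUE) {
  stopifnot(inherits(data, "multiview_dataset"), inherits(config, "netmug_config"))
  say <- function(...) if (verbose) message("netmug: ", ...)
  data_s <- standardize(data)
  sm <- config$smcca
  cv <- NULL
  if (is.null(sm$c1) || is.null(sm$c2)) {
    say("selecting sparsity bounds by ", config$cv_folds, "-fold CV")
    cv <- select_sparsity_cv(data_s, n_folds = config$cv_folds,
                             seed = stage_seed(config, 1L), config = sm,
                             n_grid = config$cv_grid_size)
    sm$c1 <- cv$c1; sm$c2 <- cv$c2
    say("chose c1 = ", format(sm$c1, digits = 4), ", c2 = ",
        format(sm$c2, digits = 4))
  }
  sm$seed <- stage_seed(config, 2L)
  say("ensemble similarity over ", sm$n_subsamples, " subsampling runs")
  S <- ensemble_similarity(data_s, sm)
  mods <- detect_modules(S, config$cut_height)
  sel <- selected_features(mods)
  say(length(mods$modules), " module(s); ", length(sel$idx_x), " + ",
      length(sel$idx_y), " features selected")
  say("building individual-specific networks")
  r <- length(sel$idx_x) + length(sel$idx_y)
  k <- r * (r - 1) / 2
  n <- length(data$sample_ids)
  if (n * k * 8 > 1e9) {
    # the edge matrix would be very large: blocked distance computation
    say("large edge set (", r, " nodes, ", k,
        " edges): using blocked ISN distances")
    isns <- NULL
    D <- isn_distances_lowmem(data, sel$idx_x, sel$idx_y)
  } else {
    isns <- build_isns(data, sel$idx_x, sel$idx_y)
    D <- isn_distance_matrix(isns)
  }
  say("clustering ISN edge vectors")
  tree <- ward_d2_tree(D)
  labels <- dynamic_tree_cut(tree, D, deep_split = config$deep_split,
                             min_cluster_size = config$min_cluster_size)
  metrics <- list(
    n_samples = length(data$sample_ids),
    n_selected_x = length(sel$idx_x), n_selected_y = length(sel$idx_y),
    n_modules = length(mods$modules), K = labels$K,
    c1 = sm$c1, c2 = sm$c2)
  if (labels$K >= 2L) {
    kw <- kruskal_wallis(data$Z, labels$labels)
    metrics$kruskal_H <- kw$H
    metrics$kruskal_p <- kw$p_value
  }
  if (!is.null(true_labels))
    metrics$ari <- adjusted_rand_index(labels$labels, true_labels)
  fit <- structure(list(labels = labels, cv = cv, similarity = S,
                        modules = mods, selected = sel,
                        isns = if (keep_isns && !is.null(isns)) isns else NULL,
                        tree = tree, metrics = metrics, config = config),
                   class = "netmug_fit")
  if (!is.null(out_dir)) write_fit(fit, data, out_dir)
  fit
}

#' @export
print.netmug_fit <- function(x, ...) {
  m <- x$metrics
  cat("netmug_fit: ", m$n_samples, " samples -> ", m$K, " cluster(s); ",
      m$n_selected_x + m$n_selected_y, " selected features (",
      m$n_selected_x, " X + ", m$n_selected_y, " Y) in ", m$n_modules,
      " module(s)\n", sep = "")
  if (!is.null(m$ari)) cat("  ARI vs ground truth: ", format(m$ari), "\n", sep = "")
  if (!is.null(m$kruskal_H))
    cat("  Kruskal-Wallis of Z across clusters: H = ",
        format(m$kruskal_H, digits = 6), ", p = ",
        format(m$kruskal_p, digits = 3), "\n", sep = "")
  invisible(x)
}

write_fit <- function(fit, data, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  sel_ids <- c(data$feature_ids_x[fit$selected$idx_x],
               data$feature_ids_y[fit$selected$idx_y])
  view <- rep(c("X", "Y"), c(length(fit$selected$idx_x), length(fit$selected$idx_y)))
  p <- sum(fit$modules$view_of == "X")
  cat_idx <- c(fit$selected$idx_x, fit$selected$idx_y + p)
  module_of <- integer(length(cat_idx))
  for (mi in seq_along(fit$modules$modules))
    module_of[cat_idx %in% fit$modules$modules[[mi]]] <- mi
  data.table::fwrite(data.frame(feature_id = sel_ids, view = view,
                                module_id = module_of),
                     file.path(out_dir, "selected_features.tsv"), sep = "\t")
  data.table::fwrite(data.frame(sample_id = data$sample_ids,
                                cluster = fit$labels$labels),
                     file.path(out_dir, "labels.tsv"), sep = "\t")
  data.table::fwrite(data.frame(left = fit$tree$merge[, 1L],
                                right = fit$tree$merge[, 2L],
                                height = fmt(fit$tree$height)),
                     file.path(out_dir, "dendrogram.tsv"), sep = "\t")
  jsonlite::write_json(fit$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- fit$config
  cfg$smcca <- unclass(cfg$smcca)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
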