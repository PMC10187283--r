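#' SmCCA configuration
#'
#' Hyperparameters for phenotype-supervised sparse multiple CCA and its
#' subsampling ensemble. `c1`, `c2` are the l1 bounds on the canonical weight
#' vectors (any value >= 1 accepted; since the weights are unit l2 norm, values
#' above sqrt(p) resp. sqrt(q) are non-binding). The three correlation weights
#' default to 1, the workflow's convention.
#'
#' @param c1,c2 l1 sparsity bounds (>= 1), or `NULL` to select by
#'   cross-validation in [run_netmug()].
#' @param w1,w2,w3 weights of the X-Y, X-Z and Y-Z correlation terms.
#' @param subsample_prop_x,subsample_prop_y fraction of features of each view
#'   drawn per subsampling run, in (0, 1].
#' @param n_subsamples number of subsampling runs in the ensemble.
#' @param max_iter,tol alternating-maximization iteration cap and convergence
#'   tolerance on the weight-vector sup-norm change.
#' @param seed integer seed controlling the subsampling draws.
#' @return A list of class `smcca_config`.
#' @export
smcca_config <- function(c1 = NULL, c2 = NULL, w1 = 1, w2 = 1, w3 = 1,
                         subsample_prop_x = 0.5, subsample_prop_y = 0.5,
                         n_subsamples = 100L, max_iter = 200L, tol = 1e-6,
                         seed = 1L) {
  if (!is.null(c1) && c1 < 1) stop("c1 must be >= 1")
  if (!is.null(c2) && c2 < 1) stop("c2 must be >= 1")
  if (subsample_prop_x <= 0 || subsample_prop_x > 1 ||
      subsample_prop_y <= 0 || subsample_prop_y > 1)
    stop("subsample proportions must lie in (0, 1]")
  if (n_subsamples < 1L) stop("n_subsamples must be >= 1")
  structure(list(c1 = c1, c2 = c2, w1 = w1, w2 = w2, w3 = w3,
                 subsample_prop_x = subsample_prop_x,
                 subsample_prop_y = subsample_prop_y,
                 n_subsamples = as.integer(n_subsamples),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "smcca_config")
}

# Projection onto {v : ||v||_2 = 1, ||v||_1 <= c} maximizing <v, x>:
# soft-threshold then l2-normalize, with the threshold found by bisection.
l1l2_project <- function(x, c, n_bisect = 50L) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) return(x)
  v <- x / nrm
  if (sum(abs(v)) <= c) return(v)
  lo <- 0; hi <- max(abs(x))
  for (i in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    s <- sign(x) * pmax(abs(x) - mid, 0)
    ns <- sqrt(sum(s^2))
    l1 <- if (ns == 0) 0 else sum(abs(s)) / ns
    if (l1 > c) lo <- mid else hi <- mid
  }
  s <- sign(x) * pmax(abs(x) - hi, 0)
  ns <- sqrt(sum(s^2))
  if (ns == 0) {
    # keep only the largest-magnitude entry: the c -> 1 limit
    s <- numeric(length(x))
    s[which.max(abs(x))] <- sign(x[which.max(abs(x))])
    ns <- 1
  }
  s / ns
}

# Leading left singular vector of M by power iteration on M M^T;
# deterministic start from the (abs) row-sum vector.
leading_left_sv <- function(M, iter = 40L, tol = 1e-9) {
  x <- rowSums(abs(M))
  if (all(x == 0)) x <- rep(1, nrow(M))
  x <- x / sqrt(sum(x^2))
  for (i in seq_len(iter)) {
    y <- as.numeric(M %*% crossprod(M, x))
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(x)
    y <- y / ny
    if (max(abs(y - x)) < tol) return(y)
    x <- y
  }
  x
}

# Core alternating maximization on precomputed Pearson-scale cross-products:
# C = t(X) %*% Y / (n-1), u = t(X) %*% Z / (n-1), v = t(Y) %*% Z / (n-1).
smcca_core <- function(C, u, v, c1, c2, w = c(1, 1, 1),
                       max_iter = 200L, tol = 1e-6, init = NULL,
                       multi_start = TRUE) {
  obj <- function(a, b)
    w[1] * as.numeric(crossprod(a, C %*% b)) + w[2] * sum(a * u) + w[3] * sum(b * v)
  climb <- function(a0) {
    a <- l1l2_project(a0, c1)
    b <- l1l2_project(as.numeric(w[1] * crossprod(C, a)) + w[3] * v, c2)
    if (all(b == 0)) b <- l1l2_project(as.numeric(colSums(abs(C))) + abs(v), c2)
    objs <- obj(a, b)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      a_new <- l1l2_project(as.numeric(w[1] * (C %*% b)) + w[2] * u, c1)
      if (all(a_new == 0)) a_new <- a
      b_new <- l1l2_project(as.numeric(w[1] * crossprod(C, a_new)) + w[3] * v, c2)
      if (all(b_new == 0)) b_new <- b
      delta <- max(max(abs(a_new - a)), max(abs(b_new - b)))
      a <- a_new; b <- b_new
      objs <- c(objs, obj(a, b))
      if (delta < tol) { converged <- TRUE; break }
    }
    list(a = a, b = b, objs = objs, converged = converged)
  }
  if (is.null(init)) init <- leading_left_sv(cbind(w[1] * C, w[2] * u))
  # the supervised objective is not invariant under (a, b) -> (-a, -b), and
  # alternating ascent is only locally optimal: hedge with deterministic
  # restarts (both signs of the SVD start, plus a phenotype-aligned start)
  starts <- list(init, -init)
  if (multi_start && any(u != 0)) starts <- c(starts, list(w[2] * u))
  if (!multi_start) starts <- starts[1]
  best <- NULL
  for (s in starts) {
    cand <- climb(s)
    if (is.null(best) ||
        cand$objs[length(cand$objs)] > best$objs[length(best$objs)] + 1e-12)
      best <- cand
  }
  a <- best$a; b <- best$b
  if (all(a == 0) || all(b == 0))
    stop("SmCCA update collapsed to an all-zero weight vector (degenerate)")
  # final sign: prefer the orientation with the larger objective; on an
  # exact tie (sign-invariant case) make the largest-magnitude entry of
  # c(a, b) positive for reproducibility
  o1 <- obj(a, b); o2 <- obj(-a, -b)
  if (o2 > o1 + 1e-12) { a <- -a; b <- -b }
  else if (abs(o2 - o1) <= 1e-12) {
    ab <- c(a, b)
    if (ab[which.max(abs(ab))] < 0) { a <- -a; b <- -b }
  }
  structure(list(a = a, b = b, objective = obj(a, b),
                 objective_trace = best$objs, converged = best$converged,
                 iterations = length(best$objs) - 1L),
            class = "canonical_pair")
}

#' @export
print.canonical_pair <- function(x, ...) {
  cat("canonical_pair: ", sum(x$a != 0), "/", length(x$a), " nonzero in a, ",
      sum(x$b != 0), "/", length(x$b), " nonzero in b; objective = ",
      format(x$objective, digits = 6),
      if (!x$converged) " (not converged)" else "", "\n", sep = "")
  invisible(x)
}

cross_products <- function(data) {
  n <- length(data$Z)
  list(C = crossprod(data$X, data$Y) / (n - 1),
       u = as.numeric(crossprod(data$X, data$Z)) / (n - 1),
       v = as.numeric(crossprod(data$Y, data$Z)) / (n - 1))
}

#' Solve phenotype-supervised sparse multiple CCA
#'
#' Finds sparse unit-norm weight vectors (a, b) approximately maximizing
#' \deqn{w_1 a' X' Y b + w_2 a' X' Z + w_3 b' Y' Z}
#' subject to \eqn{\|a\|_2 = \|b\|_2 = 1}, \eqn{\|a\|_1 \le c_1},
#' \eqn{\|b\|_1 \le c_2}, by alternating maximization with soft-thresholding
#' (each half-update solves its subproblem exactly, so the objective is
#' monotone non-decreasing). Cross-products are computed on standardized data
#' and divided by (n - 1), so each term is a sum of Pearson-scale
#' correlations and the default weights w1 = w2 = w3 = 1 are comparable.
#'
#' @param data a [multiview_dataset()] (standardized internally if needed).
#' @param config an [smcca_config()]; `c1`, `c2` must be set.
#' @return A `canonical_pair`: list with `a`, `b`, `objective`,
#'   `objective_trace`, `converged`.
#' @export
solve_smcca <- function(data, config) {
  stopifnot(inherits(data, "multiview_dataset"), inherits(config, "smcca_config"))
  if (is.null(config$c1) || is.null(config$c2))
    stop("c1 and c2 must be set (use select_sparsity_cv to choose them)")
  if (length(data$Z) < 4L) stop("SmCCA needs at least 4 samples")
  if (!is_standardized(data)) data <- standardize(data)
  cp <- cross_products(data)
  fit <- smcca_core(cp$C, cp$u, cp$v, config$c1, config$c2,
                    w = c(config$w1, config$w2, config$w3),
                    max_iter = config$max_iter, tol = config$tol)
  if (!fit$converged)
    warning("SmCCA did not converge within ", config$max_iter,
            " iterations; returning best iterate")
  names(fit$a) <- data$feature_ids_x
  names(fit$b) <- data$feature_ids_y
  fit
}

#' Choose the l1 sparsity bounds by k-fold cross-validation
#'
#' For every (c1, c2) grid point, fits SmCCA on the training folds and scores
#' the held-out fold (standardized with training-fold moments) by the
#' weighted sum of the three canonical correlations,
#' `w1 cor(Xa, Yb) + w2 cor(Xa, Z) + w3 cor(Yb, Z)`. Unlike the raw
#' cross-product objective — which grows roughly linearly with the number of
#' weighted features and therefore always prefers the densest feasible model
#' — this correlation score is scale-free and comparable across sparsity
#' levels, so cross-validation can actually trade signal against dilution.
#' Returns the point maximizing the mean held-out score, ties broken toward
#' larger c1 + c2.
#'
#' @param data a [multiview_dataset()].
#' @param grid_c1,grid_c2 candidate values (default: `n_grid` log-spaced values
#'   in `[1, sqrt(p)]` resp. `[1, sqrt(q)]`).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param config an [smcca_config()] providing weights and solver settings.
#' @param n_grid grid size when `grid_c1`/`grid_c2` are `NULL`.
#' @return A list with `c1`, `c2`, and the grid of mean held-out objectives
#'   (`cv_table`, a data.frame).
#' @export
select_sparsity_cv <- function(data, grid_c1 = NULL, grid_c2 = NULL,
                               n_folds = 5L, seed = 1L,
                               config = smcca_config(), n_grid = 8L) {
  stopifnot(inherits(data, "multiview_dataset"))
  p <- ncol(data$X); q <- ncol(data$Y); n <- length(data$Z)
  if (is.null(grid_c1)) grid_c1 <- exp(seq(0, log(max(sqrt(p), 1 + 1e-9)), length.out = n_grid))
  if (is.null(grid_c2)) grid_c2 <- exp(seq(0, log(max(sqrt(q), 1 + 1e-9)), length.out = n_grid))
  if (!length(grid_c1) || !length(grid_c2)) stop("empty sparsity grid")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n - ceiling(n / n_folds) < 4L) stop("every fold must leave >= 4 training samples")
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  grid <- expand.grid(c1 = grid_c1, c2 = grid_c2, KEEP.OUT.ATTRS = FALSE)
  score <- matrix(NA_real_, nrow(grid), n_folds)
  w <- c(config$w1, config$w2, config$w3)
  for (f in seq_len(n_folds)) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    tr_raw <- subset_samples(data, tr_idx)
    tr <- standardize(tr_raw)
    cp <- cross_products(tr)
    # held-out matrices standardized with training-fold moments
    mx <- colMeans(tr_raw$X); sx <- apply(tr_raw$X, 2L, stats::sd)
    my <- colMeans(tr_raw$Y); sy <- apply(tr_raw$Y, 2L, stats::sd)
    Xte <- sweep(sweep(data$X[te_idx, , drop = FALSE], 2L, mx, "-"), 2L, sx, "/")
    Yte <- sweep(sweep(data$Y[te_idx, , drop = FALSE], 2L, my, "-"), 2L, sy, "/")
    Zte <- (data$Z[te_idx] - mean(tr_raw$Z)) / stats::sd(tr_raw$Z)
    init <- leading_left_sv(cbind(w[1] * cp$C, w[2] * cp$u))
    # ranking grid points needs less precision than a final fit
    tol_cv <- max(config$tol, 1e-4)
    iter_cv <- min(config$max_iter, 50L)
    for (g in seq_len(nrow(grid))) {
      fit <- smcca_core(cp$C, cp$u, cp$v, grid$c1[g], grid$c2[g], w = w,
                        max_iter = iter_cv, tol = tol_cv,
                        init = init)
      xa <- as.numeric(Xte %*% fit$a)
      yb <- as.numeric(Yte %*% fit$b)
      score[g, f] <- if (stats::sd(xa) == 0 || stats::sd(yb) == 0) -Inf else
        w[1] * stats::cor(xa, yb) + w[2] * stats::cor(xa, Zte) +
        w[3] * stats::cor(yb, Zte)
    }
  }
  mean_score <- rowMeans(score)
  best <- which(mean_score == max(mean_score))
  if (length(best) > 1L) best <- best[which.max(grid$c1[best] + grid$c2[best])]
  list(c1 = grid$c1[best], c2 = grid$c2[best],
       cv_table = data.frame(grid, mean_heldout_objective = mean_score))
}

#' Feature similarity matrix from canonical weights
#'
#' With `c = c(a, b)`, returns the (p+q) x (p+q) matrix
#' `S[i, j] = |c_i| * |c_j|` (the elementwise absolute value of the outer
#' product of the concatenated weight vector with itself). Un-rescaled.
#'
#' @param a,b canonical weight vectors for views X and Y.
#' @param feature_ids optional character vector of length p+q.
#' @return A `similarity_matrix`: list with `S`, `feature_ids`, `view_of`.
#' @export
similarity_from_weights <- function(a, b, feature_ids = NULL) {
  ab <- abs(c(a, b))
  S <- tcrossprod(ab)
  if (is.null(feature_ids))
    feature_ids <- c(if (!is.null(names(a))) names(a) else paste0("x", seq_along(a)),
                     if (!is.null(names(b))) names(b) else paste0("y", seq_along(b)))
  dimnames(S) <- list(feature_ids, feature_ids)
  structure(list(S = S, feature_ids = feature_ids,
                 view_of = rep(c("X", "Y"), c(length(a), length(b)))),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix: ", nrow(x$S), " features (",
      sum(x$view_of == "X"), " X + ", sum(x$view_of == "Y"), " Y); max = ",
      format(max(x$S), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Ensemble-averaged feature similarity via feature subsampling
#'
#' Runs SmCCA `n_subsamples` times, each on a random feature subset
#' (`ceiling(prop_x * p)` features of X, `ceiling(prop_y * q)` of Y, drawn
#' without replacement), embeds each run's `|c c'|` similarity into the full
#' (p+q)^2 frame with zeros for unsampled features, averages over runs and
#' rescales by the global maximum.
#'
#' @param data a [multiview_dataset()].
#' @param config an [smcca_config()] with `c1`, `c2` set.
#' @return A `similarity_matrix` with maximum entry 1.
#' @export
ensemble_similarity <- function(data, config) {
  stopifnot(inherits(data, "multiview_dataset"), inherits(config, "smcca_config"))
  if (is.null(config$c1) || is.null(config$c2)) stop("c1 and c2 must be set")
  if (!is_standardized(data)) data <- standardize(data)
  p <- ncol(data$X); q <- ncol(data$Y); n <- length(data$Z)
  px <- ceiling(config$subsample_prop_x * p)
  qy <- ceiling(config$subsample_prop_y * q)
  S <- matrix(0, p + q, p + q)
  w <- c(config$w1, config$w2, config$w3)
  set.seed(config$seed)
  for (r in seq_len(config$n_subsamples)) {
    ix <- sort(sample.int(p, px))
    iy <- sort(sample.int(q, qy))
    Xs <- data$X[, ix, drop = FALSE]; Ys <- data$Y[, iy, drop = FALSE]
    C <- crossprod(Xs, Ys) / (n - 1)
    u <- as.numeric(crossprod(Xs, data$Z)) / (n - 1)
    v <- as.numeric(crossprod(Ys, data$Z)) / (n - 1)
    fit <- smcca_core(C, u, v, config$c1, config$c2, w = w,
                      max_iter = config$max_iter, tol = config$tol)
    ab <- abs(c(fit$a, fit$b))
    idx <- c(ix, p + iy)
    S[idx, idx] <- S[idx, idx] + tcrossprod(ab)
  }
  S <- S / config$n_subsamples
  mx <- max(S)
  if (mx == 0) stop("ensemble similarity matrix is all zero: no signal detected")
  S <- S / mx
  ids <- c(data$feature_ids_x, data$feature_ids_y)
  dimnames(S) <- list(ids, ids)
  structure(list(S = S, feature_ids = ids,
                 view_of = rep(c("X", "Y"), c(p, q))),
            class = "similarity_matrix")
}
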