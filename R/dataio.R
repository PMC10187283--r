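#' Construct a multi-view dataset
#'
#' Bundles two sample-by-feature matrices and a scalar phenotype into the
#' aligned container used throughout the pipeline. All three components must
#' describe the same samples in the same order.
#'
#' @param X numeric matrix, n samples x p features (view 1).
#' @param Y numeric matrix, n samples x q features (view 2).
#' @param Z numeric vector of length n, the extraneous phenotype.
#' @param sample_ids character vector of sample identifiers (defaults to
#'   rownames of `X` or `s1..sn`).
#' @param feature_ids_x,feature_ids_y character vectors of feature names
#'   (default to colnames or `x1..`, `y1..`).
#' @return An object of class `multiview_dataset`: a list with elements
#'   `X`, `Y`, `Z`, `sample_ids`, `feature_ids_x`, `feature_ids_y`.
#' @export
multiview_dataset <- function(X, Y, Z, sample_ids = NULL,
                              feature_ids_x = NULL, feature_ids_y = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y); Z <- as.numeric(Z)
  n <- nrow(X)
  if (nrow(Y) != n || length(Z) != n)
    stop("X, Y and Z must describe the same number of samples (got ",
         n, ", ", nrow(Y), ", ", length(Z), ")")
  if (anyNA(X) || anyNA(Y) || anyNA(Z))
    stop("multi-view data must not contain missing values")
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (is.null(feature_ids_x)) feature_ids_x <- colnames(X)
  if (is.null(feature_ids_x)) feature_ids_x <- paste0("x", seq_len(ncol(X)))
  if (is.null(feature_ids_y)) feature_ids_y <- colnames(Y)
  if (is.null(feature_ids_y)) feature_ids_y <- paste0("y", seq_len(ncol(Y)))
  dimnames(X) <- list(sample_ids, feature_ids_x)
  dimnames(Y) <- list(sample_ids, feature_ids_y)
  names(Z) <- sample_ids
  structure(list(X = X, Y = Y, Z = Z, sample_ids = as.character(sample_ids),
                 feature_ids_x = as.character(feature_ids_x),
                 feature_ids_y = as.character(feature_ids_y)),
            class = "multiview_dataset")
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat("multiview_dataset: ", length(x$sample_ids), " samples; view X: ",
      ncol(x$X), " features; view Y: ", ncol(x$Y), " features\n", sep = "")
  invisible(x)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_view <- function(path, what = "matrix") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = delim_for(path), header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2L) stop("file ", path, " needs a sample-id column plus at least one value column")
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample id '", ids[duplicated(ids)][1L], "' in ", path)
  m <- dt[, -1L, drop = FALSE]
  for (j in seq_along(m)) {
    col <- m[[j]]
    if (is.character(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric cell in ", path, " at row ", bad[1L],
             " (sample '", ids[bad[1L]], "'), column '", names(m)[j], "'")
      col <- num
    }
    na <- which(is.na(col))
    if (length(na))
      stop("missing value in ", path, " at row ", na[1L],
           " (sample '", ids[na[1L]], "'), column '", names(m)[j], "'")
    m[[j]] <- col
  }
  m <- as.matrix(m)
  rownames(m) <- ids
  m
}

#' Load a multi-view dataset from delimited text files
#'
#' Each file must have a header row of feature names and a first column of
#' sample identifiers; the phenotype file carries exactly one value column.
#' The delimiter is taken from the extension (`.csv` comma, otherwise tab).
#' Samples are intersected across the three files and returned in the order of
#' the X file; dropped samples are reported with a message.
#'
#' @param path_x,path_y,path_z paths to the view-1, view-2 and phenotype files.
#' @return A [multiview_dataset()].
#' @export
load_views <- function(path_x, path_y, path_z) {
  X <- read_view(path_x)
  Y <- read_view(path_y)
  Zm <- read_view(path_z)
  if (ncol(Zm) != 1L)
    stop("phenotype file ", path_z, " must have exactly one value column, found ", ncol(Zm))
  shared <- intersect(intersect(rownames(X), rownames(Y)), rownames(Zm))
  keep <- rownames(X)[rownames(X) %in% shared]
  if (length(keep) < 4L)
    stop("fewer than 4 samples shared across the three files (found ", length(keep), ")")
  dropped <- setdiff(unique(c(rownames(X), rownames(Y), rownames(Zm))), keep)
  if (length(dropped))
    message("load_views: dropped ", length(dropped),
            " sample(s) not present in all files: ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  multiview_dataset(X[keep, , drop = FALSE], Y[keep, , drop = FALSE],
                    Zm[keep, 1L], sample_ids = keep)
}

#' Write a multi-view dataset to delimited text files
#'
#' Inverse of [load_views()]; values are written with full double precision so
#' a write/load round trip is numerically faithful.
#'
#' @param data a [multiview_dataset()].
#' @param path_x,path_y,path_z output paths (`.csv` comma, otherwise tab).
#' @return Invisibly, the three paths.
#' @export
write_views <- function(data, path_x, path_y, path_z) {
  wr <- function(m, ids, path) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    data.table::fwrite(df, path, sep = delim_for(path))
  }
  old <- options(digits = 17); on.exit(options(old))
  wr(data$X, data$sample_ids, path_x)
  wr(data$Y, data$sample_ids, path_y)
  zm <- matrix(data$Z, ncol = 1L, dimnames = list(data$sample_ids, "Z"))
  wr(zm, data$sample_ids, path_z)
  invisible(c(path_x, path_y, path_z))
}

standardize_matrix <- function(m, label) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  zero <- which(sd == 0)
  if (length(zero))
    stop("zero-variance ", label, " feature: ", colnames(m)[zero[1L]])
  sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
}

#' Standardize a multi-view dataset
#'
#' Centers every column of X and Y (and the phenotype Z) to mean 0 and scales
#' to sample standard deviation 1 (n - 1 denominator, the same convention as
#' the Pearson correlations used downstream). Idempotent.
#'
#' @param data a [multiview_dataset()].
#' @return A standardized [multiview_dataset()].
#' @export
standardize <- function(data) {
  stopifnot(inherits(data, "multiview_dataset"))
  X <- standardize_matrix(data$X, "X")
  Y <- standardize_matrix(data$Y, "Y")
  sz <- stats::sd(data$Z)
  if (sz == 0) stop("zero-variance phenotype Z")
  Z <- (data$Z - mean(data$Z)) / sz
  multiview_dataset(X, Y, Z, data$sample_ids, data$feature_ids_x, data$feature_ids_y)
}

is_standardized <- function(data, tol = 1e-8) {
  all(abs(colMeans(data$X)) < tol) && all(abs(colMeans(data$Y)) < tol) &&
    abs(mean(data$Z)) < tol &&
    all(abs(apply(data$X, 2L, stats::sd) - 1) < tol) &&
    all(abs(apply(data$Y, 2L, stats::sd) - 1) < tol) &&
    abs(stats::sd(data$Z) - 1) < tol
}

subset_samples <- function(data, idx) {
  multiview_dataset(data$X[idx, , drop = FALSE], data$Y[idx, , drop = FALSE],
                    data$Z[idx], data$sample_ids[idx],
                    data$feature_ids_x, data$feature_ids_y)
}
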