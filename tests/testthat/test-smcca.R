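test_that("perfectly aligned single features attain objective 3", {
  set.seed(1)
  v <- rnorm(20)
  v <- (v - mean(v)) / sd(v)
  d <- multiview_dataset(matrix(v), matrix(v), v)
  fit <- solve_smcca(d, smcca_config(c1 = 1, c2 = 1))
  expect_equal(fit$a, c(x1 = 1))
  expect_equal(fit$b, c(y1 = 1))
  # three unit Pearson correlations with unit weights
  expect_equal(fit$objective, 3, tolerance = 1e-10)
})

test_that("similarity matrix is the absolute outer product of c(a, b)", {
  s <- similarity_from_weights(a = c(1, -0.5), b = 0)
  expect_equal(unname(s$S),
               rbind(c(1, 0.5, 0), c(0.5, 0.25, 0), c(0, 0, 0)))
  expect_equal(unname(similarity_from_weights(c(0, 0), c(0, 0))$S),
               matrix(0, 4, 4))
  # random vector vs element-by-element double loop
  set.seed(3)
  a <- rnorm(4); b <- rnorm(3)
  s <- similarity_from_weights(a, b)
  cc <- c(a, b)
  for (i in 1:7) for (j in 1:7)
    expect_equal(s$S[i, j], abs(cc[i]) * abs(cc[j]), tolerance = 1e-14)
})

test_that("alternating maximization is monotone and respects the constraints", {
  for (seed in 1:5) {
    d <- standardize(rand_dataset(30, 4, 5, seed = seed))
    cfg <- smcca_config(c1 = 1.5, c2 = 1.7)
    fit <- solve_smcca(d, cfg)
    expect_true(all(diff(fit$objective_trace) > -1e-10))
    expect_equal(sqrt(sum(fit$a^2)), 1, tolerance = 1e-8)
    expect_equal(sqrt(sum(fit$b^2)), 1, tolerance = 1e-8)
    expect_lte(sum(abs(fit$a)), 1.5 + 1e-8)
    expect_lte(sum(abs(fit$b)), 1.7 + 1e-8)
    # orientation: the returned sign attains the better objective
    cp <- netmug:::cross_products(d)
    obj <- function(a, b) as.numeric(crossprod(a, cp$C %*% b)) +
      sum(a * cp$u) + sum(b * cp$v)
    expect_gte(obj(fit$a, fit$b), obj(-fit$a, -fit$b) - 1e-12)
  }
})

test_that("with inactive l1 bounds and no supervision the solution is the leading SVD pair", {
  for (seed in 1:3) {
    d <- standardize(rand_dataset(25, 3, 3, seed = 100 + seed))
    cfg <- smcca_config(c1 = sqrt(3), c2 = sqrt(3), w2 = 0, w3 = 0, tol = 1e-10)
    fit <- solve_smcca(d, cfg)
    sv <- svd(crossprod(d$X, d$Y) / 24)
    a <- sv$u[, 1]; b <- sv$v[, 1]
    if (sum(a * fit$a) < 0) { a <- -a; b <- -b }
    expect_equal(unname(fit$a), a, tolerance = 1e-6)
    expect_equal(unname(fit$b), b, tolerance = 1e-6)
    expect_equal(fit$objective, sv$d[1], tolerance = 1e-8)
  }
})

test_that("solver attains the random-search oracle objective on small instances", {
  # quick version; the acceptance suite runs the full 20-instance 1e6-draw check
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:40, 1); p <- sample(2:3, 1); q <- sample(2:3, 1)
    d <- standardize(rand_dataset(n, p, q, seed = 200 + seed))
    c1 <- runif(1, 1.05, sqrt(p)); c2 <- runif(1, 1.05, sqrt(q))
    cp <- netmug:::cross_products(d)
    fit <- netmug:::smcca_core(cp$C, cp$u, cp$v, c1, c2)
    oracle <- random_search_smcca(cp$C, cp$u, cp$v, c1, c2,
                                  n_draws = 2e5, seed = 300 + seed)
    expect_gte(fit$objective, 0.99 * oracle)
  }
})

test_that("an ensemble of one run equals the rescaled single-fit similarity", {
  d <- standardize(rand_dataset(30, 5, 4, seed = 11))
  cfg <- smcca_config(c1 = 1.6, c2 = 1.6, subsample_prop_x = 1,
                      subsample_prop_y = 1, n_subsamples = 1, seed = 5)
  S <- ensemble_similarity(d, cfg)
  fit <- solve_smcca(d, cfg)
  S1 <- similarity_from_weights(fit$a, fit$b)$S
  expect_equal(S$S, S1 / max(S1), tolerance = 1e-12)
  expect_equal(max(S$S), 1)
  expect_true(isSymmetric(S$S))
})

test_that("ensemble averaging embeds zero-padded run similarities and rescales", {
  d <- standardize(rand_dataset(40, 6, 5, seed = 21))
  cfg <- smcca_config(c1 = 1.4, c2 = 1.4, subsample_prop_x = 0.5,
                      subsample_prop_y = 0.6, n_subsamples = 2, seed = 99)
  S <- ensemble_similarity(d, cfg)
  # replay the sampling sequence (the solver itself consumes no RNG)
  p <- 6; q <- 5
  px <- ceiling(0.5 * p); qy <- ceiling(0.6 * q)
  set.seed(99)
  draws <- lapply(1:2, function(r)
    list(ix = sort(sample.int(p, px)), iy = sort(sample.int(q, qy))))
  acc <- matrix(0, p + q, p + q)
  for (dr in draws) {
    sub <- multiview_dataset(d$X[, dr$ix, drop = FALSE],
                             d$Y[, dr$iy, drop = FALSE], d$Z)
    fit <- solve_smcca(sub, smcca_config(c1 = 1.4, c2 = 1.4))
    ab <- abs(c(fit$a, fit$b))
    idx <- c(dr$ix, p + dr$iy)
    acc[idx, idx] <- acc[idx, idx] + tcrossprod(ab)
  }
  acc <- acc / 2
  expect_equal(unname(S$S), acc / max(acc), tolerance = 1e-10)
})

test_that("cross-validation picks a near-optimal grid point under independent rescoring", {
  # only (x1, y1) carry signal (rho = 0.9), plus 9 noise features per view
  set.seed(31)
  n <- 60
  x1 <- rnorm(n)
  y1 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  d <- multiview_dataset(cbind(x1, matrix(rnorm(n * 9), n)),
                         cbind(y1, matrix(rnorm(n * 9), n)),
                         rnorm(n))
  grid1 <- c(1, 1.5, 2.2, 3.2)
  grid2 <- c(1, 1.5, 2.2, 3.2)
  sel <- select_sparsity_cv(d, grid1, grid2, n_folds = 5, seed = 4)
  # independent rescoring: same folds, public solver, held-out sum of the
  # three canonical correlations
  rescore <- function(c1, c2) {
    set.seed(4)
    fold <- sample(rep(1:5, length.out = n))
    mean(sapply(1:5, function(f) {
      tr <- netmug:::subset_samples(d, which(fold != f))
      fit <- solve_smcca(standardize(tr), smcca_config(c1 = c1, c2 = c2))
      mx <- colMeans(tr$X); sx <- apply(tr$X, 2, sd)
      my <- colMeans(tr$Y); sy <- apply(tr$Y, 2, sd)
      te <- which(fold == f)
      Xte <- sweep(sweep(d$X[te, ], 2, mx), 2, sx, "/")
      Yte <- sweep(sweep(d$Y[te, ], 2, my), 2, sy, "/")
      Zte <- (d$Z[te] - mean(tr$Z)) / sd(tr$Z)
      xa <- as.numeric(Xte %*% fit$a); yb <- as.numeric(Yte %*% fit$b)
      cor(xa, yb) + cor(xa, Zte) + cor(yb, Zte)
    }))
  }
  scores <- outer(grid1, grid2, Vectorize(rescore))
  expect_gte(rescore(sel$c1, sel$c2), 0.95 * max(scores))
  # single-point grid is returned as-is
  one <- select_sparsity_cv(d, 1.3, 1.7, n_folds = 5, seed = 4)
  expect_equal(c(one$c1, one$c2), c(1.3, 1.7))
  expect_error(select_sparsity_cv(d, numeric(0), 1.5), "empty")
})

test_that("ensemble similarity is invariant to the order of subsample runs", {
  # averaging is commutative; verify by accumulating the replayed runs in
  # reverse order
  d <- standardize(rand_dataset(30, 5, 5, seed = 41))
  cfg <- smcca_config(c1 = 1.5, c2 = 1.5, subsample_prop_x = 0.6,
                      subsample_prop_y = 0.6, n_subsamples = 3, seed = 8)
  S <- ensemble_similarity(d, cfg)
  p <- 5; q <- 5; px <- ceiling(0.6 * 5); qy <- px
  set.seed(8)
  draws <- lapply(1:3, function(r)
    list(ix = sort(sample.int(p, px)), iy = sort(sample.int(q, qy))))
  acc <- matrix(0, p + q, p + q)
  for (dr in rev(draws)) {
    sub <- multiview_dataset(d$X[, dr$ix, drop = FALSE],
                             d$Y[, dr$iy, drop = FALSE], d$Z)
    fit <- solve_smcca(sub, smcca_config(c1 = 1.5, c2 = 1.5))
    ab <- abs(c(fit$a, fit$b))
    idx <- c(dr$ix, p + dr$iy)
    acc[idx, idx] <- acc[idx, idx] + tcrossprod(ab)
  }
  acc <- acc / 3
  expect_equal(unname(S$S), acc / max(acc), tolerance = 1e-10)
})
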