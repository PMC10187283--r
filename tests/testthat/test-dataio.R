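write_fixture_files <- function(dir, X, Y, Z, ids, ext = "tsv") {
  sep <- if (ext == "csv") "," else "\t"
  px <- file.path(dir, paste0("X.", ext))
  py <- file.path(dir, paste0("Y.", ext))
  pz <- file.path(dir, paste0("Z.", ext))
  wr <- function(m, path) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  rownames(X) <- ids; rownames(Y) <- ids
  wr(X, px); wr(Y, py)
  wr(matrix(Z, ncol = 1, dimnames = list(ids, "Z")), pz)
  list(x = px, y = py, z = pz)
}

test_that("three consistent files load into an aligned dataset", {
  dir <- withr::local_tempdir()
  set.seed(1)
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  Y <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("f1", "f2")))
  Z <- rnorm(5)
  ids <- paste0("s", 1:5)
  p <- write_fixture_files(dir, X, Y, Z, ids)
  d <- load_views(p$x, p$y, p$z)
  expect_s3_class(d, "multiview_dataset")
  expect_identical(d$sample_ids, ids)
  expect_equal(unname(d$X), unname(X), tolerance = 1e-12)
  expect_identical(d$feature_ids_x, c("g1", "g2", "g3"))
  expect_equal(unname(d$Z), unname(Z), tolerance = 1e-12)
})

test_that("samples are intersected in X-file order and drops are reported", {
  dir <- withr::local_tempdir()
  set.seed(2)
  X <- matrix(rnorm(25), 5, 5); Y <- matrix(rnorm(25), 5, 5); Z <- rnorm(5)
  rownames(X) <- paste0("s", 1:5)
  rownames(Y) <- paste0("s", 2:6)
  idsz <- paste0("s", 1:5)
  sep <- "\t"
  px <- file.path(dir, "X.tsv"); py <- file.path(dir, "Y.tsv"); pz <- file.path(dir, "Z.tsv")
  wr <- function(m, path) utils::write.table(
    data.frame(sample_id = rownames(m), m, check.names = FALSE), path,
    sep = sep, row.names = FALSE, quote = FALSE)
  wr(X, px); wr(Y, py)
  wr(matrix(Z, ncol = 1, dimnames = list(idsz, "Z")), pz)
  expect_message(d <- load_views(px, py, pz), "dropped")
  expect_identical(d$sample_ids, paste0("s", 2:5))  # X-file order, 4 shared
  expect_equal(unname(d$X), unname(X[2:5, ]), tolerance = 1e-12)
  expect_equal(unname(d$Y), unname(Y[1:4, ]), tolerance = 1e-12)
})

test_that("validation failures name the offending file and location", {
  dir <- withr::local_tempdir()
  ids <- paste0("s", 1:5)
  X <- matrix(rnorm(10), 5, 2); Y <- matrix(rnorm(10), 5, 2); Z <- rnorm(5)
  p <- write_fixture_files(dir, X, Y, Z, ids)
  # empty cell
  lines <- readLines(p$x)
  lines[3] <- sub("\t[^\t]*$", "\t", lines[3])
  writeLines(lines, p$x)
  expect_error(load_views(p$x, p$y, p$z), "missing value.*row 2", ignore.case = TRUE)
  # non-numeric cell
  p2 <- write_fixture_files(dir, X, Y, Z, ids, ext = "csv")
  lines <- readLines(p2$y)
  lines[2] <- sub(",[^,]*$", ",abc", lines[2])
  writeLines(lines, p2$y)
  expect_error(load_views(p2$x, p2$y, p2$z), "non-numeric")
  # duplicate sample id
  p3 <- write_fixture_files(dir, X, Y, Z, c("s1", "s1", "s3", "s4", "s5"))
  expect_error(load_views(p3$x, p3$y, p3$z), "duplicate")
  # too few shared samples: X carries only 3 of the ids present in Y and Z
  dir_a <- file.path(dir, "a"); dir_b <- file.path(dir, "b")
  dir.create(dir_a); dir.create(dir_b)
  p4 <- write_fixture_files(dir_a, X, Y, Z, ids)
  pb <- write_fixture_files(dir_b, X, Y, Z, c("s1", "s2", "s3", "t4", "t5"))
  expect_error(load_views(pb$x, p4$y, p4$z), "fewer than 4")
})

test_that("standardize centers and scales with the n-1 convention", {
  d <- multiview_dataset(matrix(c(1, 2, 3, 4, 5, 9), 3, 2),
                         matrix(rnorm(6), 3, 2), c(0, 1, 4))
  s <- standardize(d)
  expect_equal(unname(s$X[, 1]), c(-1, 0, 1))  # sd of (1,2,3) is 1 with n-1
  expect_true(all(abs(colMeans(s$X)) < 1e-12))
  expect_true(all(abs(apply(s$Y, 2, sd) - 1) < 1e-12))
  expect_true(abs(mean(s$Z)) < 1e-12 && abs(sd(s$Z) - 1) < 1e-12)
  # zero-variance column errors with the feature named
  dbad <- multiview_dataset(matrix(c(2, 2, 2, 1, 2, 3), 3, 2,
                                   dimnames = list(NULL, c("const", "ok"))),
                            matrix(rnorm(6), 3, 2), c(0, 1, 4))
  expect_error(standardize(dbad), "const")
})

test_that("standardize recovers exact moments on random data and is idempotent", {
  d <- rand_dataset(5, 3, 2, seed = 42)
  s <- standardize(d)
  expect_true(all(abs(colMeans(s$X)) < 1e-12))
  expect_true(all(abs(apply(s$X, 2, sd) - 1) < 1e-12))
  s2 <- standardize(s)
  expect_equal(s2$X, s$X, tolerance = 1e-10)
  expect_equal(s2$Z, s$Z, tolerance = 1e-10)
})

test_that("write/load round-trips values to high precision", {
  d <- rand_dataset(6, 4, 3, seed = 7)
  dir <- withr::local_tempdir()
  write_views(d, file.path(dir, "X.tsv"), file.path(dir, "Y.csv"),
              file.path(dir, "Z.tsv"))
  d2 <- load_views(file.path(dir, "X.tsv"), file.path(dir, "Y.csv"),
                   file.path(dir, "Z.tsv"))
  expect_equal(d2$X, d$X, tolerance = 1e-12)
  expect_equal(d2$Y, d$Y, tolerance = 1e-12)
  expect_equal(d2$Z, d$Z, tolerance = 1e-12)
})
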