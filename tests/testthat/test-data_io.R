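write_edge_file <- function(rows, path = tempfile(fileext = ".tsv"),
                            header = TRUE, sep = "\t") {
  lines <- vapply(rows, function(r) paste(r, collapse = sep), "")
  if (header) {
    lines <- c(paste(c("microbe", "disease", "evidence")[seq_along(rows[[1]])],
                     collapse = sep), lines)
  }
  writeLines(lines, path)
  path
}

test_that("multi-evidence rows collapse to one association", {
  p <- write_edge_file(list(c("m1", "d1", "PMID:1"),
                            c("m1", "d1", "PMID:2"),
                            c("m2", "d1", "PMID:3")))
  ds <- read_association_table(p)
  expect_equal(dim(ds$A), c(2L, 1L))
  expect_equal(sum(ds$A), 2)
  expect_true(all(ds$A == 1))
})

test_that("single-row table yields a 1x1 matrix", {
  p <- write_edge_file(list(c("m1", "d1", "PMID:1")))
  ds <- read_association_table(p)
  expect_equal(unname(ds$A), matrix(1, 1, 1))
})

test_that("duplicate collapse agrees with a set-of-tuples oracle", {
  set.seed(31)
  base <- data.frame(m = paste0("m", sample(1:5, 7, replace = TRUE)),
                     d = paste0("d", sample(1:3, 7, replace = TRUE)))
  base <- unique(base)[1:min(7, nrow(unique(base))), ]
  rows <- rbind(base, base[c(1, 2, 3), ])  # 3 exact duplicates
  rows <- rows[sample(nrow(rows)), ]
  p <- write_edge_file(Map(function(m, d) c(m, d, "ev"), rows$m, rows$d))
  ds <- read_association_table(p)
  oracle <- length(unique(paste(base$m, base$d)))
  expect_equal(sum(ds$A), oracle)
})

test_that("reader handles CSV, two-column edge lists, and trims names", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("microbe,disease", " m2 ,d1", "m1,d2"), p)
  ds <- read_association_table(p)
  expect_equal(ds$microbe_names, c("m1", "m2"))
  expect_equal(ds$A["m2", "d1"], 1)

  p2 <- tempfile()
  writeLines(c("mA\tdA", "mB\tdA"), p2)  # headerless minimal dialect
  ds2 <- read_association_table(p2)
  expect_equal(dim(ds2$A), c(2L, 1L))
})

test_that("reader errors are informative", {
  expect_error(read_association_table(tempfile()), "not found")
  p <- tempfile()
  writeLines(c("a\tb\tc", "x\ty\tz"), p)
  expect_error(read_association_table(p, microbe_col = "bug",
                                      disease_col = "host"), "not found")
  # a file with a header but only whitespace names is empty after parsing
  p3 <- tempfile()
  writeLines(c("microbe\tdisease", " \t "), p3)
  expect_error(read_association_table(p3), "no usable rows")
})

test_that("dataset round-trips through the MTX directory format bit-exactly", {
  ds <- toy_dataset()
  dir <- tempfile()
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_identical(ds2$A, ds$A)
  expect_identical(ds2$microbe_names, ds$microbe_names)
  expect_identical(ds2$disease_names, ds$disease_names)
})

test_that("cv folds partition the positives evenly", {
  # a dataset with exactly 450 positives, the scale of a curated database
  set.seed(5)
  A <- matrix(0, 292, 39)
  A[sample(length(A), 450)] <- 1
  ds <- association_dataset(A, paste0("m", 1:292), paste0("d", 1:39))
  splits <- make_cv_splits(ds, k = 5, repetitions = 1, base_seed = 2)
  sizes <- vapply(splits, function(s) nrow(s$test_pos), 0L)
  expect_equal(sizes, rep(90L, 5))
  all_test <- do.call(rbind, lapply(splits, `[[`, "test_pos"))
  expect_equal(nrow(all_test), 450L)
  expect_equal(nrow(unique(as.data.frame(all_test))), 450L)  # disjoint folds
})

test_that("split invariants hold across repetitions", {
  ds <- toy_dataset()
  splits <- make_cv_splits(ds, k = 4, repetitions = 3, base_seed = 9)
  npos <- sum(ds$A)
  key <- function(p) paste(p[, 1], p[, 2])
  for (r in 1:3) {
    reps <- Filter(function(s) s$rep == r, splits)
    test_union <- unlist(lapply(reps, function(s) key(s$test_pos)))
    expect_setequal(test_union, key(which(ds$A == 1, arr.ind = TRUE)))
    expect_equal(anyDuplicated(test_union), 0L)
  }
  for (s in splits) {
    expect_equal(nrow(s$train_neg), nrow(s$train_pos))
    expect_equal(nrow(s$test_neg), nrow(s$test_pos))
    expect_true(all(ds$A[s$train_neg] == 0))
    expect_true(all(ds$A[s$test_neg] == 0))
    expect_equal(length(intersect(key(s$train_neg), key(s$test_neg))), 0L)
    expect_equal(length(intersect(key(s$train_pos), key(s$test_pos))), 0L)
  }
})

test_that("splits are deterministic given the base seed", {
  ds <- toy_dataset()
  s1 <- make_cv_splits(ds, k = 3, repetitions = 2, base_seed = 11)
  s2 <- make_cv_splits(ds, k = 3, repetitions = 2, base_seed = 11)
  expect_identical(s1, s2)
})

test_that("leave-one-out splits have singleton test sets", {
  A <- matrix(0, 4, 3)
  A[cbind(1:4, c(1, 2, 3, 1))] <- 1
  ds <- association_dataset(A, paste0("m", 1:4), paste0("d", 1:3))
  splits <- make_cv_splits(ds, k = 4, repetitions = 1, base_seed = 1)
  expect_true(all(vapply(splits, function(s) nrow(s$test_pos), 0L) == 1L))
})

test_that("split construction validates its preconditions", {
  A <- matrix(0, 3, 3)
  A[1, 1] <- 1
  ds <- association_dataset(A, paste0("m", 1:3), paste0("d", 1:3))
  expect_error(make_cv_splits(ds, k = 5), "fewer positives")
  dense <- association_dataset(matrix(1, 3, 3) - diag(3) * 0,
                               paste0("m", 1:3), paste0("d", 1:3))
  expect_error(make_cv_splits(dense, k = 3), "zero cells")
})

test_that("training matrix zeroes exactly the held-out cells", {
  ds <- association_dataset(matrix(c(1, 0, 1, 1), 2, 2),
                            c("m1", "m2"), c("d1", "d2"))
  sp <- gcatmd:::new_edge_split(
    train_pos = matrix(c(1, 2, 1, 2), 2, 2),
    train_neg = matrix(c(2, 1), 1, 2),
    test_pos = matrix(c(1, 2), 1, 2),
    test_neg = matrix(integer(0), 0, 2), seed = 1
  )
  expect_equal(unname(training_matrix(ds, sp)), matrix(c(1, 0, 0, 1), 2, 2))

  # empty test set leaves the matrix untouched
  sp0 <- gcatmd:::new_edge_split(which(ds$A == 1, arr.ind = TRUE),
                                 matrix(c(2, 1), 1, 2),
                                 matrix(integer(0), 0, 2),
                                 matrix(integer(0), 0, 2), seed = 1)
  expect_equal(training_matrix(ds, sp0), ds$A)
})

test_that("training matrix differs from A in exactly the held-out cells", {
  set.seed(13)
  A <- matrix(rbinom(200, 1, 0.4), 20, 10)
  ds <- association_dataset(A, paste0("m", 1:20), paste0("d", 1:10))
  pos <- which(A == 1, arr.ind = TRUE)
  test <- pos[sample(nrow(pos), 5), ]
  sp <- gcatmd:::new_edge_split(pos, which(A == 0, arr.ind = TRUE)[1:nrow(pos), ],
                                test, matrix(integer(0), 0, 2), seed = 1)
  M <- training_matrix(ds, sp)
  expect_equal(sum(M != ds$A), 5)
  expect_true(all(M[test] == 0))
})

test_that("splits export to a tidy TSV", {
  ds <- toy_dataset()
  splits <- make_cv_splits(ds, k = 2, repetitions = 1, base_seed = 3)
  p <- tempfile(fileext = ".tsv")
  write_splits(splits, ds, p)
  tab <- read.delim(p)
  expect_setequal(unique(tab$role),
                  c("train_pos", "train_neg", "test_pos", "test_neg"))
  expect_equal(sum(tab$role == "test_pos"), sum(ds$A) )
})
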