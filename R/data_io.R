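#' Construct a microbe-disease association dataset
#'
#' Wraps a binary association matrix together with its microbe (row) and
#' disease (column) name indexes. `A[i, j] = 1` records a known association
#' between microbe `i` and disease `j`; `A[i, j] = 0` means the pair is
#' *unlabeled* (absence of evidence, not evidence of absence), so zero cells
#' may later be sampled as putative negatives.
#'
#' @param A numeric matrix of 0/1 indicators, microbes in rows, diseases in
#'   columns.
#' @param microbe_names,disease_names unique character vectors naming the
#'   rows and columns; default to `dimnames(A)`.
#' @return An object of class `association_dataset`: a list with elements
#'   `microbe_names`, `disease_names` and the binary matrix `A` (with
#'   dimnames set).
#' @export
association_dataset <- function(A, microbe_names = rownames(A),
                                disease_names = colnames(A)) {
  A <- as.matrix(A)
  if (is.null(microbe_names) || is.null(disease_names)) {
    stop("microbe and disease names are required", call. = FALSE)
  }
  if (!all(A %in% c(0, 1))) {
    stop("association matrix must contain only 0/1", call. = FALSE)
  }
  if (length(microbe_names) != nrow(A) || length(disease_names) != ncol(A)) {
    stop("name lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(microbe_names) || anyDuplicated(disease_names)) {
    stop("names must be unique within each axis", call. = FALSE)
  }
  storage.mode(A) <- "double"
  dimnames(A) <- list(microbe_names, disease_names)
  structure(
    list(microbe_names = as.character(microbe_names),
         disease_names = as.character(disease_names),
         A = A),
    class = "association_dataset"
  )
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf(
    "association_dataset: %d microbes x %d diseases, %d known associations\n",
    nrow(x$A), ncol(x$A), sum(x$A)
  ))
  invisible(x)
}

#' Read an HMDAD-style association edge list
#'
#' Reads a delimiter-separated table of (microbe, disease) records, collapses
#' duplicate pairs reported by multiple evidence entries into a single
#' association, and builds the indexed binary association matrix. Names are
#' whitespace-trimmed but case is preserved (taxonomy is case-bearing), and
#' rows/columns are ordered lexicographically (radix order, locale-stable) so
#' that indices are reproducible across machines.
#'
#' @param path path to a TSV/CSV file. A header line is expected when column
#'   names are used; a headerless two-column file is accepted as a minimal
#'   edge list.
#' @param microbe_col,disease_col names of the microbe and disease columns.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the first line.
#' @return An [association_dataset()].
#' @export
read_association_table <- function(path, microbe_col = "microbe",
                                   disease_col = "disease", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty association table: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  header_fields <- trimws(strsplit(first, sep, fixed = TRUE)[[1]])
  has_header <- all(c(microbe_col, disease_col) %in% header_fields)
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           quote = "\"", stringsAsFactors = FALSE,
                           comment.char = "", check.names = FALSE)
  if (has_header) {
    mic <- tab[[microbe_col]]
    dis <- tab[[disease_col]]
  } else if (ncol(tab) == 2L) {
    # minimal two-column edge-list dialect
    mic <- tab[[1L]]
    dis <- tab[[2L]]
  } else {
    stop("columns '", microbe_col, "'/'", disease_col,
         "' not found and file is not a two-column edge list", call. = FALSE)
  }
  mic <- trimws(as.character(mic))
  dis <- trimws(as.character(dis))
  keep <- !is.na(mic) & !is.na(dis) & nzchar(mic) & nzchar(dis)
  mic <- mic[keep]
  dis <- dis[keep]
  if (length(mic) == 0L) stop("no usable rows after parsing", call. = FALSE)
  pairs <- unique(data.frame(microbe = mic, disease = dis,
                             stringsAsFactors = FALSE))
  microbes <- sort(unique(pairs$microbe), method = "radix")
  diseases <- sort(unique(pairs$disease), method = "radix")
  A <- matrix(0, length(microbes), length(diseases),
              dimnames = list(microbes, diseases))
  A[cbind(match(pairs$microbe, microbes), match(pairs$disease, diseases))] <- 1
  association_dataset(A, microbes, diseases)
}

#' Save / load an association dataset
#'
#' The on-disk format is a directory holding the sparse matrix in
#' MatrixMarket format (`association.mtx`) plus two plain-text name indexes
#' (`microbes.txt`, `diseases.txt`, one name per line, in matrix order).
#' Round-tripping reproduces the matrix bit-exactly.
#'
#' @param ds an [association_dataset()].
#' @param dir directory to write to / read from (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns
#'   the reconstructed [association_dataset()].
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "association_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(ds$A, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "association.mtx"))
  writeLines(ds$microbe_names, file.path(dir, "microbes.txt"))
  writeLines(ds$disease_names, file.path(dir, "diseases.txt"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  A <- as.matrix(Matrix::readMM(file.path(dir, "association.mtx")))
  microbes <- readLines(file.path(dir, "microbes.txt"))
  diseases <- readLines(file.path(dir, "diseases.txt"))
  association_dataset(A, microbes, diseases)
}

new_edge_split <- function(train_pos, train_neg, test_pos, test_neg,
                           seed, rep = NA_integer_, fold = NA_integer_) {
  as_pairs <- function(x) {
    x <- matrix(as.integer(x), ncol = 2,
                dimnames = list(NULL, c("microbe", "disease")))
    x
  }
  structure(
    list(train_pos = as_pairs(train_pos), train_neg = as_pairs(train_neg),
         test_pos = as_pairs(test_pos), test_neg = as_pairs(test_neg),
         seed = as.integer(seed), rep = as.integer(rep), fold = as.integer(fold)),
    class = "edge_split"
  )
}

#' Repeated k-fold cross-validation splits with balanced negative sampling
#'
#' Per repetition, the known positive cells of `A` are shuffled (with seed
#' `base_seed + repetition`) and partitioned into `k` folds; each fold in
#' turn is held out as `test_pos`. For every split an equal number of
#' negatives is sampled uniformly without replacement from the zero cells
#' (`|train_neg| = |train_pos|`, `|test_neg| = |test_pos|`), with train and
#' test negatives disjoint and never overlapping any positive. Negatives are
#' drawn once per split and stay fixed across training epochs.
#'
#' @param ds an [association_dataset()].
#' @param k number of folds (>= 2).
#' @param repetitions number of independent repetitions.
#' @param base_seed integer; the whole set of splits is deterministic given
#'   this seed.
#' @return A list of `edge_split` objects (length `k * repetitions`), each
#'   carrying its `rep` and `fold` indices.
#' @export
make_cv_splits <- function(ds, k = 5, repetitions = 10, base_seed = 1) {
  stopifnot(inherits(ds, "association_dataset"))
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  pos <- which(ds$A == 1, arr.ind = TRUE)
  zeros <- which(ds$A == 0, arr.ind = TRUE)
  npos <- nrow(pos)
  if (npos < k) stop("fewer positives (", npos, ") than folds (", k, ")",
                     call. = FALSE)
  if (nrow(zeros) < npos) {
    stop("not enough zero cells to sample balanced negatives", call. = FALSE)
  }
  splits <- list()
  for (r in seq_len(repetitions)) {
    seed_r <- as.integer(base_seed + r)
    set.seed(seed_r)
    perm <- sample.int(npos)
    fold_id <- rep(seq_len(k), length.out = npos)
    for (f in seq_len(k)) {
      test_idx <- perm[fold_id == f]
      train_idx <- perm[fold_id != f]
      neg_idx <- sample.int(nrow(zeros), npos)
      n_train <- length(train_idx)
      splits[[length(splits) + 1L]] <- new_edge_split(
        train_pos = pos[train_idx, , drop = FALSE],
        train_neg = zeros[neg_idx[seq_len(n_train)], , drop = FALSE],
        test_pos = pos[test_idx, , drop = FALSE],
        test_neg = zeros[neg_idx[n_train + seq_along(test_idx)], , drop = FALSE],
        seed = seed_r, rep = r, fold = f
      )
    }
  }
  splits
}

#' Training-fold association matrix
#'
#' Returns `A` with the held-out positive cells zeroed. This matrix is the
#' *only* association input used downstream of a split: both the GIP
#' similarity networks and the message-passing association graph are rebuilt
#' from it, so held-out links can never leak into the model being evaluated.
#'
#' @param ds an [association_dataset()].
#' @param split an `edge_split` derived from `ds`.
#' @return A binary matrix of the same shape as `ds$A`.
#' @export
training_matrix <- function(ds, split) {
  stopifnot(inherits(ds, "association_dataset"), inherits(split, "edge_split"))
  A <- ds$A
  check_pairs_in <- function(p) {
    if (nrow(p) > 0 &&
        (max(p[, 1]) > nrow(A) || max(p[, 2]) > ncol(A) || min(p) < 1)) {
      stop("split indices out of range for this dataset", call. = FALSE)
    }
  }
  check_pairs_in(split$test_pos)
  check_pairs_in(split$train_pos)
  if (nrow(split$test_pos) > 0) A[split$test_pos] <- 0
  A
}

#' Save cross-validation splits as TSV
#'
#' One row per edge: repetition, fold, role (`train_pos`, `train_neg`,
#' `test_pos`, `test_neg`), microbe name, disease name.
#'
#' @param splits list of `edge_split` objects from [make_cv_splits()].
#' @param ds the [association_dataset()] the splits refer to.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_splits <- function(splits, ds, path) {
  rows <- lapply(splits, function(sp) {
    do.call(rbind, lapply(c("train_pos", "train_neg", "test_pos", "test_neg"),
      function(role) {
        p <- sp[[role]]
        if (nrow(p) == 0) return(NULL)
        data.frame(rep = sp$rep, fold = sp$fold, role = role,
                   microbe = ds$microbe_names[p[, 1]],
                   disease = ds$disease_names[p[, 2]],
                   stringsAsFactors = FALSE)
      }))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
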