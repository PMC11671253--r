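#' Classification metrics for a set of scored pairs
#'
#' AUC is the probability that a uniformly chosen positive outranks a
#' uniformly chosen negative, with ties counted one half (the rank / Mann-
#' Whitney form, exact for any input). AUPR is the step-wise integral of
#' the precision-recall curve (average precision). Precision, recall and F1
#' are evaluated at the score `threshold` (default 0.5).
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector of the same length; both classes must be
#'   present.
#' @param threshold classification cutoff for precision/recall/F1.
#' @return An object of class `metrics_report`: `auc`, `aupr`, `precision`,
#'   `recall`, `f1`, `n_test_pos`, `n_test_neg`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop("AUC/AUPR undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)

  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / np
  aupr <- sum(diff(c(0, rec)) * prec)

  pred <- scores >= threshold
  tp_c <- sum(pred & labels == 1)
  precision <- if (sum(pred) == 0) 0 else tp_c / sum(pred)
  recall <- tp_c / np
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    list(auc = auc, aupr = aupr, precision = precision, recall = recall,
         f1 = f1, n_test_pos = np, n_test_neg = nn),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f  AUPR %.3f  Precision %.3f  Recall %.3f  F1 %.3f  (%d+/%d-)\n",
    x$auc, x$aupr, x$precision, x$recall, x$f1, x$n_test_pos, x$n_test_neg
  ))
  invisible(x)
}

# "0.908 (0.020)" style report formatting.
format_mean_sd <- function(m, s) sprintf("%.3f (%.3f)", m, s)

score_split <- function(fit, split) {
  cells <- rbind(split$test_pos, split$test_neg)
  labels <- c(rep(1, nrow(split$test_pos)), rep(0, nrow(split$test_neg)))
  list(scores = fit$scores[cells], labels = labels)
}

#' Repeated k-fold cross-validation of the full pipeline
#'
#' For every split: rebuild the similarity networks and association graph
#' from the training fold only, train the model, score the held-out
#' positive and sampled negative pairs, and compute the metrics. Summaries
#' are the mean and standard deviation over all `k * repetitions` folds.
#' Fully deterministic given `base_seed` (which drives the splits) and
#' `cfg$seed` (which, combined with repetition and fold indices, drives
#' initialisation).
#'
#' @param ds an [association_dataset()].
#' @param cfg a [model_config()].
#' @param k folds per repetition.
#' @param repetitions number of repetitions.
#' @param base_seed split seed.
#' @return A list with `folds` (one metrics row per split), `summary`
#'   (mean, sd and `"mean (sd)"`-formatted string per metric).
#' @export
run_repeated_cv <- function(ds, cfg = model_config(), k = 5,
                            repetitions = 10, base_seed = 1) {
  splits <- make_cv_splits(ds, k = k, repetitions = repetitions,
                           base_seed = base_seed)
  rows <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    cfg_i <- cfg
    cfg_i$seed <- as.integer(cfg$seed + 1009L * sp$rep + 101L * sp$fold)
    fit <- tryCatch(
      train_model(ds, sp, cfg_i),
      error = function(e) {
        stop("fold failure at (rep=", sp$rep, ", fold=", sp$fold, "): ",
             conditionMessage(e), call. = FALSE)
      }
    )
    sc <- score_split(fit, sp)
    m <- compute_metrics(sc$scores, sc$labels)
    rows[[i]] <- data.frame(rep = sp$rep, fold = sp$fold, auc = m$auc,
                            aupr = m$aupr, precision = m$precision,
                            recall = m$recall, f1 = m$f1)
  }
  folds <- do.call(rbind, rows)
  metric_names <- c("auc", "aupr", "precision", "recall", "f1")
  summary <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(mn) mean(folds[[mn]]), 0),
    sd = vapply(metric_names, function(mn) stats::sd(folds[[mn]]), 0)
  )
  summary$formatted <- format_mean_sd(summary$mean, summary$sd)
  rownames(summary) <- NULL
  list(folds = folds, summary = summary, k = k, repetitions = repetitions,
       base_seed = base_seed)
}

#' Rank candidate microbes for a disease
#'
#' Using a model trained on all known associations (see
#' [fit_full_model()]), returns the top-k *unknown* microbe partners of a
#' disease, sorted by decreasing predicted score, ties broken by microbe
#' index (stable). Known positives never appear.
#'
#' @param fit a `gcatmd_fit` trained on the full dataset.
#' @param ds the [association_dataset()] the fit was trained on.
#' @param disease disease name.
#' @param k number of candidates to return (default 20, truncated with a
#'   warning if fewer unknown pairs exist).
#' @return A data.frame with columns `rank`, `microbe`, `score`; attribute
#'   `disease` carries the query.
#' @export
rank_candidates <- function(fit, ds, disease, k = 20) {
  j <- match(disease, ds$disease_names)
  if (is.na(j)) stop("unknown disease: ", disease, call. = FALSE)
  unknown <- which(ds$A[, j] == 0)
  if (length(unknown) < k) {
    warning("only ", length(unknown), " unknown pairs for '", disease,
            "'; returning all")
    k <- length(unknown)
  }
  sc <- fit$scores[unknown, j]
  ord <- order(-sc, unknown)
  top <- head(ord, k)
  out <- data.frame(rank = seq_len(k),
                    microbe = ds$microbe_names[unknown[top]],
                    score = sc[top], stringsAsFactors = FALSE)
  attr(out, "disease") <- disease
  out
}

#' Grid sweep over key hyperparameters
#'
#' Runs [run_repeated_cv()] once per grid row (columns among `t`, `F_dim`,
#' `L`, `heads`); failed grid points are reported in the `error` column and
#' the sweep continues.
#'
#' @param ds an [association_dataset()].
#' @param grid data.frame of settings, one row per configuration.
#' @param cfg base [model_config()] supplying every unswept parameter.
#' @param k,repetitions,base_seed CV settings.
#' @return A data.frame: the grid columns plus mean/sd AUC and AUPR and an
#'   `error` column (`NA` on success).
#' @export
parameter_sweep <- function(ds, grid, cfg = model_config(), k = 5,
                            repetitions = 2, base_seed = 1) {
  allowed <- c("t", "F_dim", "L", "heads")
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) stop("unknown sweep parameters: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_i <- cfg
    for (nm in names(grid)) cfg_i[[nm]] <- grid[[nm]][i]
    res <- tryCatch(
      run_repeated_cv(ds, cfg_i, k = k, repetitions = repetitions,
                      base_seed = base_seed),
      error = function(e) e
    )
    row <- grid[i, , drop = FALSE]
    if (inherits(res, "error")) {
      row$auc_mean <- NA_real_; row$auc_sd <- NA_real_
      row$aupr_mean <- NA_real_; row$aupr_sd <- NA_real_
      row$error <- conditionMessage(res)
    } else {
      s <- res$summary
      row$auc_mean <- s$mean[s$metric == "auc"]
      row$auc_sd <- s$sd[s$metric == "auc"]
      row$aupr_mean <- s$mean[s$metric == "aupr"]
      row$aupr_sd <- s$sd[s$metric == "aupr"]
      row$error <- NA_character_
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export ROC and PR curve points
#'
#' Curve coordinates for plotting: one row per distinct score cutoff, with
#' false/true positive rates and precision/recall.
#'
#' @param scores,labels as in [compute_metrics()].
#' @return A data.frame with columns `cutoff`, `fpr`, `tpr`, `recall`,
#'   `precision`.
#' @export
roc_pr_points <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each tied block
  data.frame(cutoff = s[keep], fpr = fp[keep] / nn, tpr = tp[keep] / np,
             recall = tp[keep] / np, precision = tp[keep] / seq_along(y)[keep])
}
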