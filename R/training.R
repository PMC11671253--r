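# Loss + gradients of one full forward/backward pass (internal).
# Labels come from the split roles (train_pos -> 1, train_neg -> 0); the
# dataset matrix itself is never read here, so held-out cells cannot leak.
model_loss_grads <- function(graphs, params, cfg, cells, labels) {
  sw <- config_switches(cfg)
  fwd <- model_forward_cache(graphs, params, cfg)
  n_m <- graphs$n_m; n_d <- graphs$n_d
  Fdim <- cfg$F_dim

  q <- fwd$logits[cells]
  p <- sigmoid(q)
  pc <- pmin(pmax(p, cfg$eps), 1 - cfg$eps)
  classify <- -mean(labels * log(pc) + (1 - labels) * log(1 - pc))

  dQ <- matrix(0, n_m, n_d)
  dQ[cells] <- (p - labels) / length(labels)
  dZ_m <- dQ %*% fwd$Z_d
  dZ_d <- crossprod(dQ, fwd$Z_m)

  dviews <- list(
    ZA_m = dZ_m[, seq_len(Fdim), drop = FALSE],
    ZS_m = dZ_m[, Fdim + seq_len(Fdim), drop = FALSE],
    ZA_d = dZ_d[, seq_len(Fdim), drop = FALSE],
    ZS_d = dZ_d[, Fdim + seq_len(Fdim), drop = FALSE]
  )

  contrast <- 0
  if (sw$lam > 0) {
    cg <- contrastive_total_grad(fwd$views, cfg$tau, cfg$eps)
    contrast <- cg$loss
    dviews$ZA_m <- dviews$ZA_m + sw$lam * cg$dZA_m
    dviews$ZS_m <- dviews$ZS_m + sw$lam * cg$dZS_m
    dviews$ZA_d <- dviews$ZA_d + sw$lam * cg$dZA_d
    dviews$ZS_d <- dviews$ZS_d + sw$lam * cg$dZS_d
  }

  grads <- list()
  if (sw$use_assoc && sw$use_sim) {
    grads$assoc <- encoder_backward(fwd$caches$assoc, params$assoc,
                                    rbind(dviews$ZA_m, dviews$ZA_d),
                                    sw$settings)
    grads$micro <- encoder_backward(fwd$caches$micro, params$micro,
                                    dviews$ZS_m, sw$settings)
    grads$dis <- encoder_backward(fwd$caches$dis, params$dis,
                                  dviews$ZS_d, sw$settings)
  } else if (sw$use_sim) {
    # ZA is an alias of ZS: both view gradients flow into the similarity
    # encoders
    grads$micro <- encoder_backward(fwd$caches$micro, params$micro,
                                    dviews$ZA_m + dviews$ZS_m, sw$settings)
    grads$dis <- encoder_backward(fwd$caches$dis, params$dis,
                                  dviews$ZA_d + dviews$ZS_d, sw$settings)
  } else {
    grads$assoc <- encoder_backward(
      fwd$caches$assoc, params$assoc,
      rbind(dviews$ZA_m + dviews$ZS_m, dviews$ZA_d + dviews$ZS_d),
      sw$settings
    )
  }

  list(classify = classify, contrast = contrast,
       total = classify + sw$lam * contrast,
       grads = grads, forward = fwd)
}

#' Train the model on one split
#'
#' Full-batch Adam on the total loss (BCE over the balanced training edges
#' plus `lam` times the cross-view contrastive loss over all nodes) for a
#' fixed number of epochs. The similarity networks and the message-passing
#' graph are built once from the training fold and stay fixed; no held-out
#' cell ever contributes to the loss or the graphs.
#'
#' @param ds an [association_dataset()].
#' @param split an `edge_split` from [make_cv_splits()] or
#'   [full_data_split()].
#' @param cfg a [model_config()].
#' @return An object of class `gcatmd_fit`: `params` (trained weights),
#'   `log` (data.frame epoch/classify/contrast/total), final `scores`
#'   matrix, `views`, plus the `cfg` and dataset names.
#' @export
train_model <- function(ds, split, cfg = model_config()) {
  stopifnot(inherits(ds, "association_dataset"), inherits(split, "edge_split"))
  if (nrow(split$train_pos) == 0) stop("no training positives", call. = FALSE)
  graphs <- build_graphs(ds, split, cfg)
  params <- init_params(graphs, cfg)
  state <- adam_init(params)
  cells <- rbind(split$train_pos, split$train_neg)
  labels <- c(rep(1, nrow(split$train_pos)), rep(0, nrow(split$train_neg)))
  log_rows <- vector("list", cfg$epochs)
  last <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    res <- model_loss_grads(graphs, params, cfg, cells, labels)
    if (!is.finite(res$total)) {
      stop("non-finite loss at epoch ", epoch, call. = FALSE)
    }
    upd <- adam_step(params, res$grads, state, lr = cfg$lr, wd = cfg$wd)
    params <- upd$params
    state <- upd$state
    log_rows[[epoch]] <- data.frame(epoch = epoch, classify = res$classify,
                                    contrast = res$contrast, total = res$total)
    last <- res
  }
  final <- model_forward_cache(graphs, params, cfg)
  structure(
    list(params = params, cfg = cfg,
         log = do.call(rbind, log_rows),
         scores = final$scores, views = final$views,
         microbe_names = ds$microbe_names, disease_names = ds$disease_names,
         split = split),
    class = "gcatmd_fit"
  )
}

#' @export
print.gcatmd_fit <- function(x, ...) {
  cat(sprintf(
    "gcatmd_fit: variant=%s, %d epochs, final total loss %.4f\n",
    x$cfg$variant, nrow(x$log), x$log$total[nrow(x$log)]
  ))
  invisible(x)
}

#' Split that trains on every known association
#'
#' For candidate ranking the model is trained on all known associations
#' (nothing held out); an equal number of negatives is sampled from the
#' zero cells with the given seed.
#'
#' @param ds an [association_dataset()].
#' @param seed integer seed for negative sampling.
#' @return An `edge_split` with empty test sets.
#' @export
full_data_split <- function(ds, seed = 1) {
  pos <- which(ds$A == 1, arr.ind = TRUE)
  zeros <- which(ds$A == 0, arr.ind = TRUE)
  if (nrow(pos) == 0) stop("dataset has no positives", call. = FALSE)
  if (nrow(zeros) < nrow(pos)) {
    stop("not enough zero cells for balanced negatives", call. = FALSE)
  }
  set.seed(seed)
  neg <- zeros[sample.int(nrow(zeros), nrow(pos)), , drop = FALSE]
  new_edge_split(pos, neg,
                 matrix(integer(0), 0, 2), matrix(integer(0), 0, 2),
                 seed = seed)
}

#' Train on all known associations
#'
#' Convenience wrapper combining [full_data_split()] and [train_model()],
#' the protocol used before ranking candidate microbes for a disease.
#'
#' @param ds an [association_dataset()].
#' @param cfg a [model_config()]; its seed drives both negative sampling
#'   and weight initialisation.
#' @return A `gcatmd_fit`.
#' @export
fit_full_model <- function(ds, cfg = model_config()) {
  train_model(ds, full_data_split(ds, seed = cfg$seed), cfg)
}

#' Save / read the per-epoch training log
#'
#' @param fit a `gcatmd_fit`.
#' @param path TSV path.
#' @return `path` invisibly.
#' @export
write_training_log <- function(fit, path) {
  utils::write.table(fit$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
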