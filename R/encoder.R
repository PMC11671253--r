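#' Symmetrically normalized adjacency with self-loops
#'
#' Computes `D^(-1/2) (G + I) D^(-1/2)` where `D` is the degree matrix of
#' `G + I`. Rows/columns of isolated nodes reduce to a pure self-loop of
#' weight 1, so propagation is well defined on any graph.
#'
#' @param adjacency square symmetric binary matrix with zero diagonal.
#' @return The dense normalized adjacency matrix.
#' @export
normalized_adjacency <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency) || max(abs(adjacency - t(adjacency))) > 0) {
    stop("adjacency must be square and symmetric", call. = FALSE)
  }
  Gt <- adjacency
  diag(Gt) <- diag(Gt) + 1
  dinv <- 1 / sqrt(rowSums(Gt))
  Gt * (dinv %o% dinv)
}

#' One step of graph-convolutional propagation
#'
#' `H_out = sigma(norm_adj %*% H %*% W)`: features are mixed with their
#' neighbors' under symmetric degree normalization, linearly transformed,
#' then passed through the activation.
#'
#' @param norm_adj normalized adjacency from [normalized_adjacency()].
#' @param H node feature matrix (n x d).
#' @param W weight matrix (d x F).
#' @param activation activation name (`"relu"`, `"elu"`, `"identity"`,
#'   `"leaky_relu"`).
#' @return The propagated feature matrix (n x F).
#' @export
gcn_propagate <- function(norm_adj, H, W, activation = "relu") {
  out <- act_fun(activation)(norm_adj %*% H %*% W)
  stopifnot_finite(out, "gcn_propagate output")
  out
}

#' Graph-attention coefficients
#'
#' For each node `i`, a softmax over its attention neighborhood
#' `N_i union {i}` of the LeakyReLU-activated scores
#' `a . [W_att h_i || W_att h_j]`. Including the node itself follows
#' standard GAT practice and guarantees a non-empty softmax even for
#' isolated nodes. Attention is computed on the *binary* adjacency.
#'
#' @param adjacency square symmetric binary matrix, zero diagonal.
#' @param H node features (n x d).
#' @param W_att attention projection (d x F).
#' @param a attention vector of length `2F` (first half scores the target
#'   node, second half the neighbor).
#' @param slope negative slope of the LeakyReLU, default 0.2.
#' @return A dense n x n matrix `alpha`; each row sums to 1 over its
#'   support and is zero elsewhere.
#' @export
attention_coefficients <- function(adjacency, H, W_att, a, slope = 0.2) {
  HW <- as.matrix(H) %*% W_att
  Fdim <- ncol(HW)
  if (length(a) != 2 * Fdim) stop("attention vector must have length 2F",
                                  call. = FALSE)
  mask <- (as.matrix(adjacency) != 0) * 1
  diag(mask) <- 1
  s <- drop(HW %*% a[seq_len(Fdim)])
  tt <- drop(HW %*% a[Fdim + seq_len(Fdim)])
  E <- outer(s, tt, "+")
  E <- E * ((E > 0) + slope * (E <= 0))  # LeakyReLU
  logit <- E
  logit[mask == 0] <- -Inf
  mx <- apply(logit, 1, max)
  num <- exp(logit - mx) * mask
  num / rowSums(num)
}

#' Multi-head graph-attention aggregation
#'
#' Each head computes attention coefficients and a weighted sum of its
#' linearly transformed neighborhood; the head outputs are averaged and
#' passed through the activation:
#' `z_i = sigma((1/K) * sum_k sum_j alpha_ij^k W_att^k h_j)`.
#'
#' @param adjacency,H as in [attention_coefficients()].
#' @param heads list of heads, each a list with elements `W` (d x F) and `a`
#'   (length 2F).
#' @param activation activation name, default `"elu"`.
#' @param slope LeakyReLU slope inside the attention scores.
#' @return Aggregated feature matrix (n x F).
#' @export
gat_aggregate <- function(adjacency, H, heads, activation = "elu",
                          slope = 0.2) {
  if (length(heads) < 1) stop("need at least one attention head", call. = FALSE)
  H <- as.matrix(H)
  acc <- 0
  for (hd in heads) {
    alpha <- attention_coefficients(adjacency, H, hd$W, hd$a, slope)
    acc <- acc + alpha %*% (H %*% hd$W)
  }
  out <- act_fun(activation)(acc / length(heads))
  stopifnot_finite(out, "gat_aggregate output")
  out
}

#' Dual feature fusion of per-layer encoder outputs
#'
#' Combines the outputs of all attention layers by concatenation (which
#' preserves per-layer information) and elementwise product (which
#' emphasises features the layers agree on):
#' `Z = [Z1 || ... || ZL] W_a + (Z1 * ... * ZL) W_b`.
#'
#' @param Z_list list of L feature matrices, all n x F.
#' @param W_a fusion weight, (L*F) x F.
#' @param W_b fusion weight, F x F.
#' @return Fused feature matrix n x F.
#' @export
dual_fuse <- function(Z_list, W_a, W_b) {
  Fdim <- ncol(Z_list[[1]])
  if (!all(vapply(Z_list, function(z) all(dim(z) == dim(Z_list[[1]])), TRUE))) {
    stop("all per-layer outputs must share a shape", call. = FALSE)
  }
  if (nrow(W_a) != length(Z_list) * Fdim || ncol(W_a) != Fdim ||
      !all(dim(W_b) == c(Fdim, Fdim))) {
    stop("fusion weight shapes inconsistent with Z_list", call. = FALSE)
  }
  do.call(cbind, Z_list) %*% W_a + Reduce(`*`, Z_list) %*% W_b
}

# Per-encoder hyperparameter bundle (internal).
encoder_settings <- function(fusion = "dual", use_gcn = TRUE, use_gat = TRUE,
                             act_gcn = "relu", act_att = "elu", slope = 0.2) {
  comp <- if (identical(fusion, "dual")) c("C", "H") else {
    strsplit(toupper(fusion), "")[[1]]
  }
  if (!all(comp %in% c("C", "S", "H")) || length(comp) == 0) {
    stop("fusion must be 'dual' or a combination of C, S, H", call. = FALSE)
  }
  list(fusion = unique(comp), use_gcn = use_gcn, use_gat = use_gat,
       act_gcn = act_gcn, act_att = act_att, slope = slope)
}

#' Initialize trainable weights for one GCAT encoder
#'
#' Glorot-uniform initialisation of the input projection, per-layer GCN
#' weights, per-layer/per-head attention weights and vectors, and the
#' fusion weights. Only the weights the configuration actually uses are
#' created (e.g. no attention weights when the attention stage is ablated).
#'
#' @param d_in input feature dimension.
#' @param F_dim embedding dimension F.
#' @param L number of GCAT layers.
#' @param K number of attention heads per layer.
#' @param settings internal list from `encoder_settings()`; controls which
#'   stages/fusion components need weights.
#' @return A named list (parameter tree) of matrices/vectors.
#' @export
encoder_params <- function(d_in, F_dim, L = 3, K = 2,
                           settings = encoder_settings()) {
  p <- list(W_proj = glorot_matrix(d_in, F_dim))
  if (settings$use_gcn) {
    p$W_gcn <- lapply(seq_len(L), function(l) glorot_matrix(F_dim, F_dim))
  }
  if (settings$use_gat) {
    p$W_att <- lapply(seq_len(L), function(l) {
      lapply(seq_len(K), function(k) glorot_matrix(F_dim, F_dim))
    })
    p$a_att <- lapply(seq_len(L), function(l) {
      lapply(seq_len(K), function(k) glorot_vector(2 * F_dim))
    })
  }
  if ("C" %in% settings$fusion) p$W_a <- glorot_matrix(L * F_dim, F_dim)
  if ("H" %in% settings$fusion) p$W_b <- glorot_matrix(F_dim, F_dim)
  if ("S" %in% settings$fusion) p$W_s <- glorot_matrix(F_dim, F_dim)
  p
}

# Forward pass of one encoder keeping every intermediate needed for
# backpropagation. Layer semantics: one GCAT layer is GCN propagation
# followed by multi-head GAT aggregation; the GAT output feeds the next
# layer's GCN; the L per-layer outputs enter the fusion module.
encode_cache <- function(adjacency, features, params, settings) {
  adjacency <- as.matrix(adjacency)
  features <- as.matrix(features)
  n <- nrow(adjacency)
  L <- encoder_depth(params, settings)
  fg <- act_fun(settings$act_gcn)
  fa <- act_fun(settings$act_att)
  slope <- settings$slope
  mask <- (adjacency != 0) * 1
  diag(mask) <- 1
  Anorm <- if (settings$use_gcn) normalized_adjacency(adjacency) else NULL
  H0 <- features %*% params$W_proj
  layers <- vector("list", L)
  Hprev <- H0
  for (l in seq_len(L)) {
    lay <- list(Hin = Hprev)
    if (settings$use_gcn) {
      lay$AH <- Anorm %*% Hprev
      lay$Pg <- lay$AH %*% params$W_gcn[[l]]
      lay$Hg <- fg(lay$Pg)
    } else {
      lay$Hg <- Hprev
    }
    if (settings$use_gat) {
      K <- length(params$W_att[[l]])
      Fdim <- ncol(lay$Hg)
      acc <- 0
      hds <- vector("list", K)
      for (k in seq_len(K)) {
        W <- params$W_att[[l]][[k]]
        a <- params$a_att[[l]][[k]]
        HW <- lay$Hg %*% W
        s <- drop(HW %*% a[seq_len(Fdim)])
        tt <- drop(HW %*% a[Fdim + seq_len(Fdim)])
        Eraw <- outer(s, tt, "+")
        E <- Eraw * ((Eraw > 0) + slope * (Eraw <= 0))
        logit <- E
        logit[mask == 0] <- -Inf
        mx <- apply(logit, 1, max)
        num <- exp(logit - mx) * mask
        alpha <- num / rowSums(num)
        hds[[k]] <- list(HW = HW, Eraw = Eraw, alpha = alpha)
        acc <- acc + alpha %*% HW
      }
      lay$heads <- hds
      lay$Spre <- acc / K
      lay$Z <- fa(lay$Spre)
    } else {
      lay$Z <- lay$Hg
    }
    if (!all(is.finite(lay$Z))) {
      stop("non-finite encoder output at layer ", l, call. = FALSE)
    }
    layers[[l]] <- lay
    Hprev <- lay$Z
  }
  Z_list <- lapply(layers, `[[`, "Z")
  Zf <- fuse_forward(Z_list, params, settings)
  list(features = features, mask = mask, Anorm = Anorm, H0 = H0,
       layers = layers, Z_list = Z_list, Z_fused = Zf)
}

encoder_depth <- function(params, settings) {
  if (settings$use_gcn) return(length(params$W_gcn))
  if (settings$use_gat) return(length(params$W_att))
  if (!is.null(params$W_a)) return(nrow(params$W_a) / ncol(params$W_proj))
  1L
}

fuse_forward <- function(Z_list, params, settings) {
  Z <- 0
  if ("C" %in% settings$fusion) Z <- Z + do.call(cbind, Z_list) %*% params$W_a
  if ("H" %in% settings$fusion) Z <- Z + Reduce(`*`, Z_list) %*% params$W_b
  if ("S" %in% settings$fusion) Z <- Z + Reduce(`+`, Z_list) %*% params$W_s
  Z
}

#' Run one GCAT encoder
#'
#' Projects the input features to dimension F, applies L layers of GCN
#' propagation followed by multi-head GAT aggregation, and fuses the
#' per-layer outputs.
#'
#' @param graph list with elements `adjacency` (binary, symmetric, zero
#'   diagonal) and `features` (n x d_in).
#' @param params parameter tree from [encoder_params()].
#' @param settings internal settings list; defaults to the full model
#'   (GCN + GAT, dual fusion, ReLU/ELU activations, LeakyReLU slope 0.2).
#' @return A list with `Z_list` (the L per-layer outputs) and `Z_fused`.
#' @export
encode <- function(graph, params, settings = encoder_settings()) {
  cache <- encode_cache(graph$adjacency, graph$features, params, settings)
  list(Z_list = cache$Z_list, Z_fused = cache$Z_fused)
}

# Reverse-mode gradients of one encoder given the gradient of the loss with
# respect to the fused output. Returns a gradient tree matching `params`.
encoder_backward <- function(cache, params, dZf, settings) {
  L <- length(cache$layers)
  ga <- act_grad(settings$act_att)
  gg <- act_grad(settings$act_gcn)
  slope <- settings$slope
  grads <- tree_zeros_like(params)
  Z_list <- cache$Z_list
  Fdim <- ncol(Z_list[[1]])

  # fusion backward
  dZ <- lapply(Z_list, function(z) z * 0)
  if ("C" %in% settings$fusion) {
    Cc <- do.call(cbind, Z_list)
    grads$W_a <- crossprod(Cc, dZf)
    dC <- dZf %*% t(params$W_a)
    for (l in seq_len(L)) {
      dZ[[l]] <- dZ[[l]] + dC[, (l - 1) * Fdim + seq_len(Fdim), drop = FALSE]
    }
  }
  if ("H" %in% settings$fusion) {
    Hd <- Reduce(`*`, Z_list)
    grads$W_b <- crossprod(Hd, dZf)
    dHd <- dZf %*% t(params$W_b)
    for (l in seq_len(L)) {
      others <- if (L == 1) 1 else Reduce(`*`, Z_list[-l])
      dZ[[l]] <- dZ[[l]] + dHd * others
    }
  }
  if ("S" %in% settings$fusion) {
    Ss <- Reduce(`+`, Z_list)
    grads$W_s <- crossprod(Ss, dZf)
    dS <- dZf %*% t(params$W_s)
    for (l in seq_len(L)) dZ[[l]] <- dZ[[l]] + dS
  }

  dHnext <- 0
  for (l in rev(seq_len(L))) {
    lay <- cache$layers[[l]]
    dZl <- dZ[[l]] + dHnext
    if (settings$use_gat) {
      K <- length(lay$heads)
      dSpre <- dZl * ga(lay$Spre)
      dHg <- 0
      for (k in seq_len(K)) {
        hd <- lay$heads[[k]]
        dOk <- dSpre / K
        dalpha <- dOk %*% t(hd$HW)
        dHW <- crossprod(hd$alpha, dOk)
        rs <- rowSums(hd$alpha * dalpha)
        dE <- hd$alpha * (dalpha - rs)
        dEraw <- dE * ((hd$Eraw > 0) + slope * (hd$Eraw <= 0))
        ds <- rowSums(dEraw)
        dt <- colSums(dEraw)
        a <- params$a_att[[l]][[k]]
        a1 <- a[seq_len(Fdim)]
        a2 <- a[Fdim + seq_len(Fdim)]
        dHW <- dHW + ds %o% a1 + dt %o% a2
        grads$a_att[[l]][[k]] <- c(drop(crossprod(hd$HW, ds)),
                                   drop(crossprod(hd$HW, dt)))
        grads$W_att[[l]][[k]] <- crossprod(lay$Hg, dHW)
        dHg <- dHg + dHW %*% t(params$W_att[[l]][[k]])
      }
    } else {
      dHg <- dZl
    }
    if (settings$use_gcn) {
      dPg <- dHg * gg(lay$Pg)
      grads$W_gcn[[l]] <- crossprod(lay$AH, dPg)
      dHin <- cache$Anorm %*% (dPg %*% t(params$W_gcn[[l]]))
    } else {
      dHin <- dHg
    }
    dHnext <- dHin
  }
  grads$W_proj <- crossprod(cache$features, dHnext)
  grads
}
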