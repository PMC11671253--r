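# Independent straight-line reference implementations used as oracles.
# Everything here is written with explicit loops and no reuse of package
# internals, so agreement is evidence of correctness, not of shared code.

ref_normalized_adjacency <- function(G) {
  n <- nrow(G)
  Gt <- G + diag(n)
  out <- matrix(0, n, n)
  deg <- rowSums(Gt)
  for (i in 1:n) for (j in 1:n) {
    out[i, j] <- Gt[i, j] / sqrt(deg[i] * deg[j])
  }
  out
}

ref_gcn <- function(G, H, W, act = function(x) pmax(x, 0)) {
  act(ref_normalized_adjacency(G) %*% H %*% W)
}

ref_lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# attention coefficients by explicit per-node softmax over N_i U {i}
ref_attention <- function(G, H, W, a, slope = 0.2) {
  n <- nrow(G)
  Fdim <- ncol(W)
  HW <- H %*% W
  alpha <- matrix(0, n, n)
  for (i in 1:n) {
    nb <- sort(unique(c(i, which(G[i, ] != 0))))
    logits <- sapply(nb, function(j) {
      ref_lrelu(sum(a * c(HW[i, ], HW[j, ])), slope)
    })
    e <- exp(logits - max(logits))
    alpha[i, nb] <- e / sum(e)
  }
  alpha
}

ref_gat <- function(G, H, heads, act = function(x) ifelse(x > 0, x, exp(x) - 1),
                    slope = 0.2) {
  n <- nrow(G)
  acc <- matrix(0, n, ncol(heads[[1]]$W))
  for (hd in heads) {
    alpha <- ref_attention(G, H, hd$W, hd$a, slope)
    acc <- acc + alpha %*% (H %*% hd$W)
  }
  act(acc / length(heads))
}

ref_dual_fuse <- function(Z_list, W_a, W_b) {
  C <- do.call(cbind, Z_list)
  Hd <- Z_list[[1]]
  if (length(Z_list) > 1) {
    for (l in 2:length(Z_list)) Hd <- Hd * Z_list[[l]]
  }
  C %*% W_a + Hd %*% W_b
}

# whole encoder by composing the reference pieces (full model semantics:
# GCN then GAT per layer, GAT output feeds the next GCN, dual fusion)
ref_encode <- function(G, X, params, slope = 0.2) {
  relu <- function(x) pmax(x, 0)
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  H <- X %*% params$W_proj
  L <- length(params$W_gcn)
  Z_list <- vector("list", L)
  for (l in 1:L) {
    Hg <- ref_gcn(G, H, params$W_gcn[[l]], relu)
    heads <- lapply(seq_along(params$W_att[[l]]), function(k) {
      list(W = params$W_att[[l]][[k]], a = params$a_att[[l]][[k]])
    })
    H <- ref_gat(G, Hg, heads, elu, slope)
    Z_list[[l]] <- H
  }
  list(Z_list = Z_list, Z_fused = ref_dual_fuse(Z_list, params$W_a, params$W_b))
}

# GIP kernel by explicit double loop
ref_gip_kernel <- function(P, gamma) {
  n <- nrow(P)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    K[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  }
  K
}

# AUC by brute-force pair counting (ties one half)
ref_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# one-sided contrastive loss by explicit per-node evaluation
ref_contrastive_one_side <- function(ZX, ZY, tau) {
  cosv <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  n <- nrow(ZX)
  tot <- 0
  for (i in 1:n) {
    num <- exp(cosv(ZX[i, ], ZY[i, ]) / tau)
    den <- num
    for (k in seq_len(n)[-i]) {
      den <- den + exp(cosv(ZX[i, ], ZX[k, ]) / tau) +
        exp(cosv(ZX[i, ], ZY[k, ]) / tau)
    }
    tot <- tot + log(num / den)
  }
  -tot / n
}

# small random symmetric binary graph with zero diagonal
random_graph <- function(n, p = 0.4) {
  G <- matrix(rbinom(n * n, 1, p), n, n)
  G <- 1 * ((G + t(G)) > 0)
  diag(G) <- 0
  G
}

random_encoder_params <- function(d_in, Fdim, L, K) {
  rn <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.5), nr, nc)
  list(
    W_proj = rn(d_in, Fdim),
    W_gcn = lapply(1:L, function(l) rn(Fdim, Fdim)),
    W_att = lapply(1:L, function(l) lapply(1:K, function(k) rn(Fdim, Fdim))),
    a_att = lapply(1:L, function(l) lapply(1:K, function(k) {
      rnorm(2 * Fdim, sd = 0.5)
    })),
    W_a = rn(L * Fdim, Fdim),
    W_b = rn(Fdim, Fdim)
  )
}

# a small planted-block dataset plus one split, shared by several tests
toy_dataset <- function(seed = 7, n_m = 20, n_d = 8) {
  generate_synthetic(synthetic_config(n_m = n_m, n_d = n_d, n_blocks = 2,
                                      p_in = 0.6, p_out = 0.1, seed = seed))
}

tiny_config <- function(...) {
  args <- list(F_dim = 4, L = 2, heads = 2, epochs = 3, lr = 1e-3, seed = 3)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}
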