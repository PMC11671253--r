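#' Model configuration
#'
#' Bundles every tunable of the pipeline with the defaults used throughout:
#' similarity threshold `t = 0.4`, embedding dimension `F = 128`, `L = 3`
#' GCAT layers, `heads = 2` attention heads, temperature `tau = 1`,
#' contrastive weight `lam = 0.2`, Adam learning rate `lr = 1e-5`, weight
#' decay `wd = 1e-3` and `epochs = 100`.
#'
#' @param t similarity threshold in (0, 1).
#' @param F_dim embedding dimension F.
#' @param L number of GCAT layers.
#' @param heads number of attention heads K.
#' @param tau contrastive temperature (> 0).
#' @param lam contrastive loss weight (>= 0).
#' @param lr,wd,epochs Adam learning rate, weight decay and iteration count.
#' @param seed integer seed for weight initialisation (and negative sampling
#'   in [fit_full_model()]).
#' @param variant ablation variant: `"full"` (default), `"sim_only"`
#'   (similarity-network encoders only), `"asso_only"` (association-network
#'   encoder only), `"no_gcn"` (attention directly on projected features),
#'   `"no_gat"` (GCN outputs only), `"no_cl"` (contrastive weight forced to
#'   0), or `"fusion_X"` with `X` one of `C`, `S`, `H`, `CS`, `CH`, `SH`,
#'   `CSH` selecting which fusion components (concatenation, sum, Hadamard
#'   product) are combined; the default dual fusion equals `fusion_CH`.
#' @param act_gcn,act_att activation names for the GCN and attention stages.
#' @param slope LeakyReLU slope inside attention scores.
#' @param eps numeric clipping constant for logs and norms.
#' @param gamma_prime raw GIP bandwidth.
#' @return An object of class `model_config`.
#' @export
model_config <- function(t = 0.4, F_dim = 128, L = 3, heads = 2,
                         tau = 1, lam = 0.2, lr = 1e-5, wd = 1e-3,
                         epochs = 100, seed = 1, variant = "full",
                         act_gcn = "relu", act_att = "elu", slope = 0.2,
                         eps = 1e-7, gamma_prime = 1) {
  known <- c("full", "sim_only", "asso_only", "no_gcn", "no_gat", "no_cl",
             paste0("fusion_", c("C", "S", "H", "CS", "CH", "SH", "CSH",
                                 "dual")))
  if (!variant %in% known) {
    stop("unknown variant '", variant, "'", call. = FALSE)
  }
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (lam < 0) stop("lam must be >= 0", call. = FALSE)
  structure(
    list(t = t, F_dim = as.integer(F_dim), L = as.integer(L),
         heads = as.integer(heads), tau = tau, lam = lam, lr = lr, wd = wd,
         epochs = as.integer(epochs), seed = as.integer(seed),
         variant = variant, act_gcn = act_gcn, act_att = act_att,
         slope = slope, eps = eps, gamma_prime = gamma_prime),
    class = "model_config"
  )
}

# Effective switches implied by the ablation variant.
config_switches <- function(cfg) {
  fusion <- "dual"
  if (startsWith(cfg$variant, "fusion_")) {
    fusion <- sub("fusion_", "", cfg$variant)
  }
  list(
    use_assoc = cfg$variant != "sim_only",
    use_sim = cfg$variant != "asso_only",
    use_gcn = cfg$variant != "no_gcn",
    use_gat = cfg$variant != "no_gat",
    lam = if (cfg$variant == "no_cl") 0 else cfg$lam,
    settings = encoder_settings(fusion = fusion,
                                use_gcn = cfg$variant != "no_gcn",
                                use_gat = cfg$variant != "no_gat",
                                act_gcn = cfg$act_gcn, act_att = cfg$act_att,
                                slope = cfg$slope)
  )
}

#' Assemble the three encoder input graphs for one split
#'
#' From the training-fold association matrix only: the GIP similarity
#' networks for microbes and diseases, the bipartite association graph
#' `G = [0 A; A' 0]` over `n_m + n_d` nodes, and the initial features
#' `H0 = blockdiag(KM, KD)` (each similarity graph uses its own kernel rows
#' as features).
#'
#' @param ds an [association_dataset()].
#' @param split an `edge_split` (use a full-data split to train on all
#'   associations).
#' @param cfg a [model_config()].
#' @return A list with `assoc`, `micro`, `dis` graphs (each
#'   `list(adjacency, features)`), the two `similarity_network` objects and
#'   the dimensions `n_m`, `n_d`.
#' @export
build_graphs <- function(ds, split, cfg = model_config()) {
  A_tr <- training_matrix(ds, split)
  n_m <- nrow(A_tr); n_d <- ncol(A_tr)
  sim_m <- similarity_network(A_tr, "microbe", t = cfg$t,
                              gamma_prime = cfg$gamma_prime)
  sim_d <- similarity_network(A_tr, "disease", t = cfg$t,
                              gamma_prime = cfg$gamma_prime)
  G <- rbind(cbind(matrix(0, n_m, n_m), A_tr),
             cbind(t(A_tr), matrix(0, n_d, n_d)))
  H0 <- rbind(cbind(sim_m$kernel, matrix(0, n_m, n_d)),
              cbind(matrix(0, n_d, n_m), sim_d$kernel))
  dimnames(G) <- NULL; dimnames(H0) <- NULL
  list(
    assoc = list(adjacency = G, features = H0),
    micro = list(adjacency = unname(sim_m$adjacency), features = sim_m$kernel),
    dis = list(adjacency = unname(sim_d$adjacency), features = sim_d$kernel),
    sim_m = sim_m, sim_d = sim_d, n_m = n_m, n_d = n_d
  )
}

#' Initialize all trainable weights of the model
#'
#' One independent parameter tree per encoder in use (association,
#' microbe-similarity, disease-similarity); no weight sharing.
#'
#' @param graphs output of [build_graphs()].
#' @param cfg a [model_config()]; `cfg$seed` makes initialisation
#'   deterministic.
#' @return A named parameter tree.
#' @export
init_params <- function(graphs, cfg = model_config()) {
  sw <- config_switches(cfg)
  set.seed(cfg$seed)
  params <- list()
  if (sw$use_assoc) {
    params$assoc <- encoder_params(ncol(graphs$assoc$features), cfg$F_dim,
                                   cfg$L, cfg$heads, sw$settings)
  }
  if (sw$use_sim) {
    params$micro <- encoder_params(ncol(graphs$micro$features), cfg$F_dim,
                                   cfg$L, cfg$heads, sw$settings)
    params$dis <- encoder_params(ncol(graphs$dis$features), cfg$F_dim,
                                 cfg$L, cfg$heads, sw$settings)
  }
  params
}

#' Inner-product decoder
#'
#' `A' = sigmoid(Z_m %*% t(Z_d))`: the association score of (microbe i,
#' disease j) is the sigmoid of the dot product of their final concatenated
#' embeddings, so every score lies strictly in (0, 1).
#'
#' @param Z_m microbe embeddings (n_m x 2F).
#' @param Z_d disease embeddings (n_d x 2F).
#' @return The n_m x n_d score matrix.
#' @export
decode <- function(Z_m, Z_d) {
  if (ncol(Z_m) != ncol(Z_d)) stop("embedding dimensions differ", call. = FALSE)
  sigmoid(tcrossprod(as.matrix(Z_m), as.matrix(Z_d)))
}

# Forward pass keeping caches for backprop (internal).
model_forward_cache <- function(graphs, params, cfg) {
  sw <- config_switches(cfg)
  n_m <- graphs$n_m; n_d <- graphs$n_d
  caches <- list()
  if (sw$use_assoc) {
    caches$assoc <- encode_cache(graphs$assoc$adjacency,
                                 graphs$assoc$features,
                                 params$assoc, sw$settings)
  }
  if (sw$use_sim) {
    caches$micro <- encode_cache(graphs$micro$adjacency,
                                 graphs$micro$features,
                                 params$micro, sw$settings)
    caches$dis <- encode_cache(graphs$dis$adjacency, graphs$dis$features,
                               params$dis, sw$settings)
  }
  if (sw$use_assoc) {
    ZA_m <- caches$assoc$Z_fused[seq_len(n_m), , drop = FALSE]
    ZA_d <- caches$assoc$Z_fused[n_m + seq_len(n_d), , drop = FALSE]
  }
  if (sw$use_sim) {
    ZS_m <- caches$micro$Z_fused
    ZS_d <- caches$dis$Z_fused
  }
  if (!sw$use_assoc) { ZA_m <- ZS_m; ZA_d <- ZS_d }
  if (!sw$use_sim) { ZS_m <- ZA_m; ZS_d <- ZA_d }
  views <- list(ZA_m = ZA_m, ZS_m = ZS_m, ZA_d = ZA_d, ZS_d = ZS_d)
  Z_m <- cbind(ZA_m, ZS_m)
  Z_d <- cbind(ZA_d, ZS_d)
  logits <- tcrossprod(Z_m, Z_d)
  list(caches = caches, views = views, Z_m = Z_m, Z_d = Z_d,
       logits = logits, scores = sigmoid(logits))
}

#' Full forward pass of the model on one split
#'
#' Rebuilds the three graphs from the training fold, runs the encoders in
#' use for the configured variant, assembles the cross-view embeddings and
#' decodes the association score matrix. Deterministic given `params`.
#'
#' @param ds an [association_dataset()].
#' @param split an `edge_split`.
#' @param cfg a [model_config()].
#' @param params parameter tree from [init_params()] (or a trained fit's
#'   `$params`).
#' @return A list with the `scores` matrix (n_m x n_d, entries in (0, 1))
#'   and the embedding `views` (`ZA_m`, `ZS_m`, `ZA_d`, `ZS_d`).
#' @export
model_forward <- function(ds, split, cfg, params) {
  graphs <- build_graphs(ds, split, cfg)
  fwd <- model_forward_cache(graphs, params, cfg)
  list(scores = fwd$scores, views = fwd$views)
}
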