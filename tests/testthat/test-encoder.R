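test_that("normalized adjacency handles the closed-form cases", {
  expect_equal(normalized_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))

  two <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalized_adjacency(two), matrix(0.5, 2, 2))

  edgeless <- matrix(0, 5, 5)
  expect_equal(normalized_adjacency(edgeless), diag(5))

  asym <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(normalized_adjacency(asym), "symmetric")
})

test_that("normalized adjacency matches the loop oracle on random graphs", {
  set.seed(5)
  for (rep in 1:5) {
    G <- random_graph(7)
    expect_equal(normalized_adjacency(G), ref_normalized_adjacency(G),
                 tolerance = 1e-12)
  }
})

test_that("gcn propagation follows its algebraic definition", {
  # edgeless graph with identity weight is the identity map
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_propagate(diag(4), H, diag(3), "identity"), H)

  # two-node single edge mixes features with weight one half
  two <- normalized_adjacency(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(gcn_propagate(two, diag(2), diag(2), "identity"),
               matrix(0.5, 2, 2))

  # ReLU output is non-negative
  set.seed(6)
  G <- random_graph(6)
  out <- gcn_propagate(normalized_adjacency(G), matrix(rnorm(24), 6, 4),
                       matrix(rnorm(16), 4, 4), "relu")
  expect_true(all(out >= 0))
})

test_that("attention reduces to closed forms on degenerate graphs", {
  # isolated node: softmax over the singleton {i}
  a <- rnorm(4)
  alpha <- attention_coefficients(matrix(0, 1, 1), matrix(rnorm(2), 1, 2),
                                  diag(2), a)
  expect_equal(alpha, matrix(1, 1, 1))

  # identical features -> uniform attention over the neighborhood
  G <- matrix(1, 4, 4) - diag(4)
  H <- matrix(1, 4, 3)
  alpha <- attention_coefficients(G, H, diag(3), rnorm(6))
  expect_equal(alpha, matrix(0.25, 4, 4), tolerance = 1e-12)
})

test_that("attention softmax reproduces the hand-computed example", {
  # fully connected 3-node graph; the attention vector reads the
  # neighbor's first feature, so row logits are (0, 1, 0)
  G <- matrix(1, 3, 3) - diag(3)
  H <- cbind(c(0, 1, 0), 0)
  alpha <- attention_coefficients(G, H, diag(2), c(0, 0, 1, 0))
  expect_equal(alpha[1, ], exp(c(0, 1, 0)) / sum(exp(c(0, 1, 0))),
               tolerance = 1e-4)
  expect_equal(unname(alpha[1, ]), c(0.2119, 0.5761, 0.2119),
               tolerance = 1e-3)
})

test_that("attention rows are probability distributions over the support", {
  set.seed(8)
  for (rep in 1:5) {
    G <- random_graph(9)
    H <- matrix(rnorm(9 * 4), 9, 4)
    alpha <- attention_coefficients(G, H, matrix(rnorm(16), 4, 4), rnorm(8))
    expect_equal(rowSums(alpha), rep(1, 9), tolerance = 1e-8)
    mask <- G
    diag(mask) <- 1
    expect_true(all(alpha[mask == 0] == 0))
  }
})

test_that("attention coefficients match the per-node softmax oracle", {
  set.seed(18)
  G <- random_graph(8)
  H <- matrix(rnorm(8 * 3), 8, 3)
  W <- matrix(rnorm(9), 3, 3)
  a <- rnorm(6)
  expect_equal(attention_coefficients(G, H, W, a),
               ref_attention(G, H, W, a), tolerance = 1e-10)
})

test_that("multi-head aggregation matches identity and averaging cases", {
  # singleton neighborhoods with identity weights return the input
  H <- matrix(rnorm(8), 4, 2)
  out <- gat_aggregate(matrix(0, 4, 4), H,
                       list(list(W = diag(2), a = rep(0, 4))), "identity")
  expect_equal(out, H)

  # duplicated heads equal the single head
  set.seed(9)
  G <- random_graph(6)
  H6 <- matrix(rnorm(18), 6, 3)
  hd <- list(W = matrix(rnorm(9), 3, 3), a = rnorm(6))
  expect_equal(gat_aggregate(G, H6, list(hd)),
               gat_aggregate(G, H6, list(hd, hd)))
})

test_that("multi-head aggregation matches the dense loop oracle", {
  set.seed(10)
  G <- random_graph(5)
  H <- matrix(rnorm(15), 5, 3)
  heads <- list(list(W = matrix(rnorm(9), 3, 3), a = rnorm(6)),
                list(W = matrix(rnorm(9), 3, 3), a = rnorm(6)))
  expect_equal(gat_aggregate(G, H, heads), ref_gat(G, H, heads),
               tolerance = 1e-6)
})

test_that("dual fusion covers its algebraic special cases", {
  Z <- matrix(rnorm(6), 3, 2)
  expect_equal(dual_fuse(list(Z), diag(2), diag(2)), 2 * Z)

  # scalar worked example: concat (2+3) plus product (2*3)
  expect_equal(dual_fuse(list(matrix(2), matrix(3)),
                         matrix(c(1, 1), 2, 1), matrix(1)),
               matrix(11))

  # a zero layer annihilates the Hadamard term
  Z2 <- matrix(rnorm(6), 3, 2)
  W_a <- matrix(rnorm(8), 4, 2)
  out <- dual_fuse(list(Z2, matrix(0, 3, 2)), W_a, matrix(rnorm(4), 2, 2))
  expect_equal(out, cbind(Z2, matrix(0, 3, 2)) %*% W_a)

  expect_error(dual_fuse(list(Z, Z), diag(2), diag(2)), "shapes")
})

test_that("encoder collapses to its closed form on an edgeless graph", {
  # L = 1, identity weights/activations: fused output is 2 * X * W_proj
  n <- 4; Fdim <- 3
  X <- matrix(rnorm(n * 5), n, 5)
  W_proj <- matrix(rnorm(5 * Fdim), 5, Fdim)
  params <- list(W_proj = W_proj, W_gcn = list(diag(Fdim)),
                 W_att = list(list(diag(Fdim))),
                 a_att = list(list(rep(0, 2 * Fdim))),
                 W_a = diag(Fdim), W_b = diag(Fdim))
  st <- gcatmd:::encoder_settings(act_gcn = "identity", act_att = "identity")
  out <- encode(list(adjacency = matrix(0, n, n), features = X), params, st)
  expect_equal(out$Z_fused, 2 * (X %*% W_proj), tolerance = 1e-10)
})

test_that("bipartite assembly of a 2x1 matrix has exactly two adjacency entries", {
  ds <- association_dataset(matrix(c(1, 0), 2, 1), c("m1", "m2"), "d1")
  sp <- full_data_split(ds, seed = 1)
  graphs <- build_graphs(ds, sp, tiny_config())
  G <- graphs$assoc$adjacency
  expect_equal(sum(G != 0), 2)
  expect_equal(G[1, 3], 1)
  expect_equal(G[3, 1], 1)
})

test_that("encoder matches a straight-line reference on a random graph", {
  set.seed(12)
  G <- random_graph(8)
  X <- matrix(rnorm(8 * 6), 8, 6)
  params <- random_encoder_params(6, 4, L = 3, K = 2)
  out <- encode(list(adjacency = G, features = X), params)
  ref <- ref_encode(G, X, params)
  for (l in 1:3) expect_equal(out$Z_list[[l]], ref$Z_list[[l]],
                              tolerance = 1e-6)
  expect_equal(out$Z_fused, ref$Z_fused, tolerance = 1e-6)
})

test_that("encoder is permutation equivariant", {
  set.seed(14)
  G <- random_graph(10)
  X <- matrix(rnorm(10 * 5), 10, 5)
  params <- random_encoder_params(5, 3, L = 2, K = 2)
  out <- encode(list(adjacency = G, features = X), params)
  perm <- sample(10)
  out_p <- encode(list(adjacency = G[perm, perm],
                       features = X[perm, , drop = FALSE]), params)
  expect_equal(out_p$Z_fused, out$Z_fused[perm, , drop = FALSE],
               tolerance = 1e-8)
})

test_that("encoder output is finite for finite inputs", {
  set.seed(15)
  G <- random_graph(7)
  X <- matrix(rnorm(7 * 4, sd = 10), 7, 4)
  params <- random_encoder_params(4, 3, L = 2, K = 2)
  out <- encode(list(adjacency = G, features = X), params)
  expect_true(all(is.finite(out$Z_fused)))
})
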