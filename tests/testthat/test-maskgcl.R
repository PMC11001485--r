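test_that("attribute masking replaces exactly the chosen node rows", {
  vocab <- feature_vocab()
  g <- smiles_to_graph("Cc1ccncc1CCO")  # 10 heavy atoms
  set.seed(4)
  v0 <- mask_attributes(g, mask_config(mask_rate = 0), vocab)
  expect_length(v0$masked_node_indices, 0L)
  expect_identical(v0$graph, g)

  v1 <- mask_attributes(g, mask_config(mask_rate = 1), vocab)
  expect_length(v1$masked_node_indices, nrow(g$node_features))
  expect_true(all(v1$graph$node_features[, 1] == vocab$mask_atom_index))
  expect_identical(v1$graph$edge_index, g$edge_index)
  expect_identical(v1$graph$edge_features, g$edge_features)

  # 0.15 * 20 = 3 under the half-up rounding rule
  g20 <- smiles_to_graph("CCCCCCCCCCCCCCCCCCCC")
  v <- mask_attributes(g20, mask_config(mask_rate = 0.15), vocab)
  expect_length(v$masked_node_indices, 3L)

  # unmasked rows bitwise equal, withheld labels aligned
  set.seed(7)
  v2 <- mask_attributes(g, mask_config(mask_rate = 0.3), vocab)
  keep <- setdiff(seq_len(nrow(g$node_features)), v2$masked_node_indices)
  expect_identical(v2$graph$node_features[keep, ], g$node_features[keep, ])
  expect_identical(v2$withheld_labels,
                   g$node_features[v2$masked_node_indices, 1])

  # deterministic under a fixed RNG state
  set.seed(11); a <- mask_attributes(g, mask_config(0.3), vocab)
  set.seed(11); b <- mask_attributes(g, mask_config(0.3), vocab)
  expect_identical(a, b)
})

test_that("reconstruction loss matches softmax cross-entropy closed forms", {
  vocab <- feature_vocab()
  cfg <- tiny_config()
  params <- init_params(cfg, vocab, seed = 1)
  K <- vocab$atom_type_count - 1L

  # zero head -> uniform logits -> ln K per node
  pz <- params
  pz[["recon.W"]] <- params[["recon.W"]] * 0
  pz[["recon.b"]] <- params[["recon.b"]] * 0
  H <- matrix(rnorm(3 * cfg$hidden_dim), 3)
  expect_equal(reconstruction_loss(H, c(6L, 8L, 7L), pz), log(K),
               tolerance = 1e-12)

  # true class dominating by +1000 -> loss < 1e-6
  psat <- pz
  psat[["recon.b"]][6] <- 1000
  expect_lt(reconstruction_loss(matrix(0, 2, cfg$hidden_dim), c(6L, 6L), psat),
            1e-6)

  # hand-set logits vs an independent softmax oracle
  set.seed(2)
  H3 <- matrix(rnorm(3 * cfg$hidden_dim, sd = 0.5), 3)
  labs <- c(6L, 7L, 17L)
  logits <- H3 %*% params[["recon.W"]] +
    matrix(params[["recon.b"]], 3, K, byrow = TRUE)
  oracle <- -mean(vapply(1:3, function(i)
    log(exp(logits[i, labs[i]]) / sum(exp(logits[i, ]))), numeric(1)))
  expect_equal(reconstruction_loss(H3, labs, params), oracle,
               tolerance = 1e-6)

  # nonnegative on random inputs; zero masked nodes -> 0 with warning
  for (r in 1:20) {
    Hr <- matrix(rnorm(2 * cfg$hidden_dim, sd = 2), 2)
    expect_gte(reconstruction_loss(Hr, sample(K, 2), params), 0)
  }
  expect_warning(l0 <- reconstruction_loss(matrix(0, 0, 8), integer(0), params),
                 "zero masked")
  expect_equal(l0, 0)
})

test_that("NT-Xent has its closed-form values", {
  for (B in c(2, 4, 8)) {
    Z <- matrix(rep(c(1, 0), each = B), B)  # all identical unit vectors
    expect_equal(nt_xent(Z, Z, 0.7), log(B - 1), tolerance = 1e-12)
  }
  # hand-computed B = 2 orthogonal case at tau = 1
  A <- rbind(c(1, 0), c(0, 1))
  expect_equal(nt_xent(A, A, 1), -1, tolerance = 1e-12)
  # all similarities zero -> loss 0
  A2 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  P2 <- rbind(c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_equal(nt_xent(A2, P2, 0.5), 0, tolerance = 1e-12)
  expect_error(nt_xent(matrix(1, 1, 3), matrix(1, 1, 3), 1), "at least 2")
})

test_that("NT-Xent equals the brute-force double-loop oracle", {
  set.seed(31)
  for (trial in 1:100) {
    B <- sample(2:8, 1); d <- sample(2:16, 1)
    A <- matrix(rnorm(B * d), B); P <- matrix(rnorm(B * d), B)
    tau <- runif(1, 0.05, 2)
    expect_equal(nt_xent(A, P, tau), oracle_nt_xent(A, P, tau),
                 tolerance = 1e-6)
  }
})

test_that("NT-Xent is monotone in positive and negative similarities", {
  base <- diag(4) * 0 + matrix(rnorm(16), 4)
  set.seed(1)
  A <- matrix(rnorm(12), 3); P <- matrix(rnorm(12), 3)
  l0 <- nt_xent(A, P, 0.5)
  # move one partner toward its anchor: positive similarity rises, loss falls
  P_up <- P; P_up[1, ] <- P[1, ] + 0.5 * (A[1, ] / sqrt(sum(A[1, ]^2)) *
                                            sqrt(sum(P[1, ]^2)) - P[1, ])
  expect_lt(nt_xent(A, P_up, 0.5), l0)
  # move a negative partner toward a foreign anchor: loss rises
  P_neg <- P; P_neg[2, ] <- A[1, ] * sqrt(sum(P[2, ]^2)) / sqrt(sum(A[1, ]^2))
  expect_gt(nt_xent(A, P_neg, 0.5), l0)
})

test_that("hybrid loss is the stated convex combination", {
  expect_equal(maskgcl_loss(2, 4, 1), 2)
  expect_equal(maskgcl_loss(2, 4, 0), 4)
  expect_equal(maskgcl_loss(2, 4, 0.5), 3)
  expect_error(maskgcl_loss(1, 1, 1.2))
})
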