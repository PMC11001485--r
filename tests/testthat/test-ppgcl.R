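test_that("gradient snapshots are deterministic and shape-aligned", {
  vocab <- feature_vocab()
  cfg <- tiny_config()
  params <- init_params(cfg, vocab, seed = 5)
  graphs <- fixture_graphs(6, seed = 3)
  set.seed(2)
  views <- lapply(graphs, mask_attributes, config = mask_config(0.2),
                  vocab = vocab)
  g1 <- snapshot_cl1_gradient(params, graphs, views, tau = 0.3, cfg)
  g2 <- snapshot_cl1_gradient(params, graphs, views, tau = 0.3, cfg)
  expect_identical(g1, g2)
  expect_setequal(names(g1), names(params))
  for (nm in names(params)) {
    expect_identical(dim(g1[[nm]]), dim(params[[nm]]), info = nm)
    expect_identical(length(g1[[nm]]), length(params[[nm]]), info = nm)
  }
  expect_error(snapshot_cl1_gradient(params, graphs[1], views[1], 0.3, cfg))
})

test_that("snapshot gradients match central finite differences", {
  vocab <- feature_vocab()
  cfg <- tiny_config(layers = 2L, dim = 8L)
  params <- init_params(cfg, vocab, seed = 7)
  graphs <- fixture_graphs(8, seed = 3)
  set.seed(1)
  views <- lapply(graphs, mask_attributes, config = mask_config(0.25),
                  vocab = vocab)
  snap <- snapshot_cl1_gradient(params, graphs, views, tau = 0.5, cfg)
  batch_o <- make_batch(graphs)
  batch_m <- make_batch(lapply(views, `[[`, "graph"))
  loss_at <- function(p) nt_xent(
    molemcl:::.encoder_forward(p, batch_o, cfg, training = TRUE)$z,
    molemcl:::.encoder_forward(p, batch_m, cfg, training = TRUE)$z, 0.5)
  set.seed(9)
  h <- 1e-4
  for (trial in 1:20) {
    dirn <- lapply(params, rand_like)
    nrm <- sqrt(sum(vapply(dirn, function(d) sum(d^2), numeric(1))))
    dirn <- lapply(dirn, function(d) d / nrm)
    pp <- params; pm <- params
    for (nm in names(params)) {
      pp[[nm]] <- params[[nm]] + h * dirn[[nm]]
      pm[[nm]] <- params[[nm]] - h * dirn[[nm]]
    }
    fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    ip <- sum(vapply(names(params), function(nm)
      sum(snap[[nm]] * dirn[[nm]]), numeric(1)))
    expect_lt(abs(fd - ip) / max(abs(fd), 1e-10), 1e-3)
  }
})

test_that("perturbation follows theta' = theta + eta * grad exactly", {
  vocab <- feature_vocab()
  cfg <- tiny_config()
  params <- init_params(cfg, vocab, seed = 5)
  graphs <- fixture_graphs(6, seed = 3)
  set.seed(2)
  views <- lapply(graphs, mask_attributes, config = mask_config(0.2),
                  vocab = vocab)
  snap <- snapshot_cl1_gradient(params, graphs, views, tau = 0.3, cfg)
  before <- params

  # eta = 0 -> bitwise equal
  p0 <- perturb_parameters(params, snap, perturbation_config(eta = 0))
  expect_identical(p0, params)

  # norm identity per tensor, and untouched tensors outside the layer set
  eta <- 2.5
  pp <- perturb_parameters(params, snap, perturbation_config(eta = eta))
  sel <- molemcl:::perturbable_names(params)
  for (nm in sel) {
    expect_equal(sqrt(sum((pp[[nm]] - params[[nm]])^2)),
                 eta * sqrt(sum(snap[[nm]]^2)), tolerance = 1e-6, info = nm)
  }
  for (nm in setdiff(names(params), sel)) {
    expect_identical(pp[[nm]], params[[nm]], info = nm)
  }
  expect_identical(params, before)  # purity

  # arithmetic on a hand-set tensor
  ph <- params; gh <- snap
  ph[["layer1.b2"]][1:2] <- c(1, 1)
  gh[["layer1.b2"]] <- gh[["layer1.b2"]] * 0
  gh[["layer1.b2"]][1:2] <- c(0.5, -0.5)
  out <- perturb_parameters(ph, gh, perturbation_config(eta = 2))
  expect_equal(out[["layer1.b2"]][1:2], c(2, 0))

  # shape mismatch is a structural error naming the tensor
  gbad <- snap; gbad[["layer1.W1"]] <- matrix(0, 2, 2)
  expect_error(perturb_parameters(params, gbad, perturbation_config(eta = 1)),
               "layer1.W1")

  # gaussian mode is seeded-reproducible and pure
  set.seed(3)
  pg1 <- perturb_parameters(params, config = perturbation_config(
    mode = "gaussian", gaussian_scale = 0.05))
  set.seed(3)
  pg2 <- perturb_parameters(params, config = perturbation_config(
    mode = "gaussian", gaussian_scale = 0.05))
  expect_identical(pg1, pg2)
  expect_false(identical(pg1[["layer1.W1"]], params[["layer1.W1"]]))
  expect_identical(params, before)

  # mode none is the identity copy
  expect_identical(perturb_parameters(params,
                                      config = perturbation_config(mode = "none")),
                   params)
})

test_that("perturbed-view contrastive loss matches the NT-Xent contract", {
  vocab <- feature_vocab()
  cfg <- tiny_config()
  params <- init_params(cfg, vocab, seed = 5)
  graphs <- fixture_graphs(6, seed = 3)
  batch <- make_batch(graphs)
  z <- molemcl:::.encoder_forward(params, batch, cfg, training = TRUE)$z

  # eta = 0: perturbed projections identical, every positive similarity 1
  set.seed(2)
  views <- lapply(graphs, mask_attributes, config = mask_config(0.2),
                  vocab = vocab)
  snap <- snapshot_cl1_gradient(params, graphs, views, tau = 0.3, cfg)
  p0 <- perturb_parameters(params, snap, perturbation_config(eta = 0))
  z0 <- molemcl:::.encoder_forward(p0, batch, cfg, training = TRUE)$z
  expect_identical(z0, z)
  sims <- vapply(seq_len(nrow(z)), function(i)
    cosine_similarity(z[i, ], z0[i, ]), numeric(1))
  expect_equal(sims, rep(1, nrow(z)), tolerance = 1e-12)

  # all projections identical across the batch -> ln(B - 1)
  zsame <- matrix(rep(z[1, ], each = nrow(z)), nrow(z))
  expect_equal(ppgcl_loss(zsame, zsame, 0.1), log(nrow(z) - 1),
               tolerance = 1e-9)

  # random projections match the brute-force oracle
  set.seed(8)
  A <- matrix(rnorm(32), 4); P <- matrix(rnorm(32), 4)
  expect_equal(ppgcl_loss(A, P, 0.4), oracle_nt_xent(A, P, 0.4),
               tolerance = 1e-6)
})
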