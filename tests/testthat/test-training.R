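test_that("loss breakdown identities hold on live steps in every arm", {
  vocab <- feature_vocab()
  cfg <- tiny_config()
  graphs <- fixture_graphs(8, seed = 3)
  for (abl in c("molemcl", "maskgcl_only", "ppgcl_only",
                "maskgcl_plus_gaussian")) {
    pc <- pretrain_config(alpha = 0.3, encoder = cfg, batch_size = 8,
                          ablation = abl)
    params <- init_params(cfg, vocab, seed = 1)
    set.seed(5)
    opt <- NULL
    for (step in 1:3) {
      r <- pretrain_step(params, opt, graphs, pc, vocab)
      params <- r$params; opt <- r$opt
      b <- r$breakdown
      expect_lt(abs(b$l_maskgcl - (pc$alpha * b$l_mask +
                                     (1 - pc$alpha) * b$l_cl1)), 1e-6)
      expect_lt(abs(b$total - (b$l_maskgcl + b$l_ppgcl)), 1e-6)
      if (abl == "maskgcl_only") expect_identical(b$l_ppgcl, 0)
      if (abl == "ppgcl_only") {
        expect_identical(b$l_maskgcl, 0)
        expect_identical(b$l_mask, 0)
      }
    }
  }
  expect_error(pretrain_step(init_params(cfg, vocab, 1), NULL, graphs[1],
                             pretrain_config(encoder = cfg), vocab),
               "at least 2")
})

test_that("pre-training is reproducible under a fixed seed", {
  mols <- generate_fixture_molecules(24, seed = 2)
  cfg <- tiny_config()
  f1 <- molemcl_pretrain(mols, epochs = 3, batch_size = 12, seed = 9,
                         encoder = cfg)
  f2 <- molemcl_pretrain(mols, epochs = 3, batch_size = 12, seed = 9,
                         encoder = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  f3 <- molemcl_pretrain(mols, epochs = 3, batch_size = 12, seed = 10,
                         encoder = cfg)
  expect_false(identical(f1$history, f3$history))
})

test_that("gradient and gaussian arms coincide when their magnitudes are zero", {
  vocab <- feature_vocab()
  cfg <- tiny_config()
  graphs <- fixture_graphs(8, seed = 3)
  params <- init_params(cfg, vocab, seed = 1)
  res <- list()
  for (abl in c("molemcl", "maskgcl_plus_gaussian")) {
    pc <- pretrain_config(encoder = cfg, batch_size = 8, ablation = abl,
                          eta = 0, gaussian_scale = 0)
    set.seed(5)
    res[[abl]] <- pretrain_step(params, NULL, graphs, pc, vocab)$breakdown
  }
  expect_equal(res$molemcl$l_ppgcl, res$maskgcl_plus_gaussian$l_ppgcl,
               tolerance = 1e-12)
})

test_that("checkpoint resume reproduces the uninterrupted loss sequence", {
  mols <- generate_fixture_molecules(24, seed = 2)
  cfg <- tiny_config()
  straight <- molemcl_pretrain(mols, epochs = 4, batch_size = 12, seed = 9,
                               encoder = cfg)
  dir <- tempfile(); dir.create(dir)
  half <- molemcl_pretrain(mols, epochs = 2, batch_size = 12, seed = 9,
                           encoder = cfg, checkpoint_dir = dir)
  ckpt <- file.path(dir, "checkpoint_epoch002.rds")
  expect_true(file.exists(ckpt))
  expect_true(file.exists(paste0(ckpt, ".json")))
  resumed <- molemcl_pretrain(mols, epochs = 4, batch_size = 12, seed = 9,
                              encoder = cfg, resume_from = ckpt)
  expect_equal(resumed$history, straight$history, tolerance = 1e-12)
  expect_equal(resumed$params, straight$params, tolerance = 1e-12)

  # mismatched configuration is an explicit refusal
  expect_error(
    molemcl_pretrain(mols, epochs = 4, batch_size = 12, seed = 9,
                     encoder = cfg, alpha = 0.3, resume_from = ckpt),
    "refusing to resume")
})

test_that("run_pretraining writes metrics rows for every epoch", {
  mols <- generate_fixture_molecules(16, seed = 6)
  out <- tempfile();
  fit <- run_pretraining(mols, out, epochs = 3, batch_size = 8,
                         encoder = tiny_config(), seed = 1,
                         ablation = "maskgcl_plus_gaussian")
  metrics <- read.csv(file.path(out, "metrics.csv"))
  expect_equal(nrow(metrics), 3L)
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  expect_s3_class(load_checkpoint(file.path(out, "checkpoint.rds")), "molemcl")
})

test_that("fitted model methods expose the expected surface", {
  mols <- generate_fixture_molecules(16, seed = 6)
  fit <- molemcl_pretrain(mols, epochs = 2, batch_size = 8,
                          encoder = tiny_config(), seed = 1)
  expect_output(print(fit), "pre-training")
  expect_output(summary(fit), "parameter tensors")
  expect_s3_class(fit, "molemcl")
  expect_named(coef(fit)["atom_emb"], "atom_emb")
  emb <- predict(fit, mols[1:3])
  expect_equal(dim(emb), c(3L, 8L))
  pj <- predict(fit, mols[1:3], type = "projection")
  expect_equal(dim(pj), c(3L, 8L))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
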