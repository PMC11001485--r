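# Joint pre-training: one optimizer step couples the masking module and the
# perturbation module, L = L_MaskGCL + L_PPGCL, with the perturbation built
# from the same step's contrastive gradient before the update.

#' Pre-training configuration
#'
#' @param alpha Trade-off between reconstruction and contrastive loss in the
#'   masking module (default 0.5; the protocol grid is 0.3/0.5/0.7).
#' @param eta Perturbation magnitude (default 2; grid 2/4/6/8/10).
#' @param tau NT-Xent temperature (default 0.1), shared by both contrastive
#'   losses.
#' @param mask_rate Node masking rate (default 0.15).
#' @param epochs,batch_size,learning_rate Optimization protocol (defaults
#'   100, 256, 0.001).
#' @param seed Integer seed controlling initialization, shuffling, masking.
#' @param encoder An [encoder_config()].
#' @param ablation `"molemcl"` (full model), `"maskgcl_only"`,
#'   `"ppgcl_only"` or `"maskgcl_plus_gaussian"` (gaussian-noise
#'   perturbation in place of gradient compensation).
#' @param gaussian_scale Noise sd for the gaussian arm.
#' @param min_masked Minimum masked nodes per graph.
#' @return Object of class `pretrain_config`.
#' @export
pretrain_config <- function(alpha = 0.5, eta = 2, tau = 0.1,
                            mask_rate = 0.15, epochs = 100L,
                            batch_size = 256L, learning_rate = 1e-3,
                            seed = 1L, encoder = encoder_config(),
                            ablation = c("molemcl", "maskgcl_only",
                                         "ppgcl_only", "maskgcl_plus_gaussian"),
                            gaussian_scale = 0.1, min_masked = 1L) {
  ablation <- match.arg(ablation)
  stopifnot(alpha >= 0, alpha <= 1, tau > 0, batch_size >= 2L, epochs >= 1L,
            learning_rate > 0, mask_rate >= 0, mask_rate <= 1)
  cfg <- list(alpha = alpha, eta = eta, tau = tau, mask_rate = mask_rate,
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, seed = as.integer(seed),
              encoder = encoder, ablation = ablation,
              gaussian_scale = gaussian_scale,
              min_masked = as.integer(min_masked))
  class(cfg) <- "pretrain_config"
  cfg
}

.use_maskgcl <- function(ablation) ablation != "ppgcl_only"
.use_ppgcl <- function(ablation) ablation != "maskgcl_only"
.perturb_mode <- function(ablation) {
  if (ablation == "maskgcl_plus_gaussian") "gaussian" else "gradient"
}

#' One joint pre-training step
#'
#' Executes, in order: node masking of every graph in the batch; encoding of
#' the original and masked views; the reconstruction loss, the masking
#' contrastive loss and their hybrid; the gradient snapshot of the
#' contrastive loss, the parameter perturbation and the perturbed-view
#' contrastive loss (with the perturbed branch held constant); and a single
#' Adam update on the joint objective. Ablation arms zero out the disabled
#' terms.
#'
#' @param params `encoder_params` registry.
#' @param opt Adam state (internal; pass the value returned previously, or
#'   `NULL` to initialize).
#' @param graphs Batch: list of at least 2 `molgraph`.
#' @param config A [pretrain_config()].
#' @param vocab A [feature_vocab()].
#' @return List with updated `params`, `opt` and `breakdown` (fields
#'   `step`, `l_mask`, `l_cl1`, `l_maskgcl`, `l_ppgcl`, `total`,
#'   `recon_accuracy`).
#' @export
pretrain_step <- function(params, opt, graphs, config,
                          vocab = feature_vocab()) {
  if (length(graphs) < 2L) stop("pre-training batch needs at least 2 graphs")
  if (is.null(opt)) opt <- .adam_init(params, lr = config$learning_rate)
  mcfg <- mask_config(config$mask_rate, config$min_masked)
  views <- lapply(graphs, mask_attributes, config = mcfg, vocab = vocab)

  batch_o <- make_batch(graphs)
  batch_m <- make_batch(lapply(views, `[[`, "graph"))
  nv <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offs <- cumsum(c(0L, nv[-length(nv)]))
  masked_idx <- unlist(lapply(seq_along(views), function(i)
    views[[i]]$masked_node_indices + offs[i]))
  labels <- unlist(lapply(views, `[[`, "withheld_labels"))

  fw_o <- .encoder_forward(params, batch_o, config$encoder, training = TRUE)
  fw_m <- .encoder_forward(params, batch_m, config$encoder, training = TRUE)

  # masking module
  rec <- if (length(masked_idx)) {
    .reconstruction_loss_grad(fw_m$node[masked_idx, , drop = FALSE],
                              labels, params)
  } else {
    list(loss = 0, dnode = NULL, correct = logical(0))
  }
  cl1 <- .nt_xent_grad(fw_o$z, fw_m$z, config$tau)
  l_mask <- rec$loss
  l_cl1 <- cl1$loss

  g_mask <- new.env(parent = emptyenv())
  if (length(masked_idx)) {
    dnode_m <- matrix(0, batch_m$n, config$encoder$hidden_dim)
    dnode_m[masked_idx, ] <- rec$dnode
    .gacc(g_mask, "recon.W", rec$dW)
    .gacc(g_mask, "recon.b", rec$db)
    .encoder_backward(params, config$encoder, batch_m, fw_m,
                      dnode = dnode_m, genv = g_mask)
  }
  g_cl1 <- new.env(parent = emptyenv())
  .encoder_backward(params, config$encoder, batch_o, fw_o, dz = cl1$dA,
                    genv = g_cl1)
  .encoder_backward(params, config$encoder, batch_m, fw_m, dz = cl1$dP,
                    genv = g_cl1)
  g_cl1_list <- .grads_as_list(g_cl1, params, fill_missing = FALSE)

  # perturbation module: the snapshot is this step's contrastive gradient,
  # taken before the optimizer update
  l_ppgcl <- 0
  g_pp_list <- NULL
  if (.use_ppgcl(config$ablation)) {
    pcfg <- perturbation_config(eta = config$eta,
                                mode = .perturb_mode(config$ablation),
                                gaussian_scale = config$gaussian_scale)
    params_pert <- perturb_parameters(params, g_cl1_list, pcfg)
    fw_p <- .encoder_forward(params_pert, batch_o, config$encoder,
                             training = TRUE)
    nt2 <- .nt_xent_grad(fw_o$z, fw_p$z, config$tau)
    l_ppgcl <- nt2$loss
    g_pp <- new.env(parent = emptyenv())
    # stop-gradient through the perturbed branch: only the anchor side flows
    .encoder_backward(params, config$encoder, batch_o, fw_o, dz = nt2$dA,
                      genv = g_pp)
    g_pp_list <- .grads_as_list(g_pp, params, fill_missing = FALSE)
  }

  if (.use_maskgcl(config$ablation)) {
    l_maskgcl <- maskgcl_loss(l_mask, l_cl1, config$alpha)
    gl <- list(.grads_as_list(g_mask, params, fill_missing = FALSE),
               g_cl1_list)
    wt <- c(config$alpha, 1 - config$alpha)
    if (!is.null(g_pp_list)) { gl <- c(gl, list(g_pp_list)); wt <- c(wt, 1) }
  } else {
    l_mask <- 0; l_cl1 <- 0; l_maskgcl <- 0
    gl <- list(g_pp_list); wt <- 1
  }
  total <- l_maskgcl + l_ppgcl
  step_id <- opt$t + 1L
  for (term in c(l_mask = l_mask, l_cl1 = l_cl1, l_ppgcl = l_ppgcl,
                 total = total)) {
    if (!is.finite(term))
      stop("non-finite loss at step ", step_id, ": ",
           paste(names(which(!is.finite(c(l_mask = l_mask, l_cl1 = l_cl1,
                                          l_ppgcl = l_ppgcl)))),
                 collapse = ", "))
  }
  grads <- .combine_grads(gl, wt)
  upd <- .adam_step(params, grads, opt)
  # batch-norm running statistics advance once per step (original view)
  for (nm in names(fw_o$buffers)) upd$params[[nm]] <- fw_o$buffers[[nm]]
  breakdown <- list(step = step_id, l_mask = l_mask, l_cl1 = l_cl1,
                    l_maskgcl = l_maskgcl, l_ppgcl = l_ppgcl, total = total,
                    recon_accuracy = if (length(rec$correct))
                      mean(rec$correct) else NA_real_)
  list(params = upd$params, opt = upd$opt, breakdown = breakdown)
}

.make_epoch_batches <- function(n, batch_size) {
  perm <- sample.int(n)
  if (n < batch_size) return(list(perm))
  nb <- n %/% batch_size
  lapply(seq_len(nb), function(i)
    perm[((i - 1L) * batch_size + 1L):(i * batch_size)])
}

#' Pre-train a molecular encoder
#'
#' The main fitting function: runs joint multi-level contrastive
#' pre-training over a SMILES corpus and returns a fitted `molemcl` model
#' object with `print`, `summary`, `coef`, `predict` and `plot` methods.
#'
#' @param corpus Character vector of SMILES, or the path of a plain-text
#'   SMILES file (one per line, `#` comments allowed).
#' @param ... Passed to [pretrain_config()] (e.g. `alpha`, `eta`, `tau`,
#'   `mask_rate`, `epochs`, `batch_size`, `learning_rate`, `seed`,
#'   `encoder`, `ablation`).
#' @param config A ready [pretrain_config()]; overrides `...`.
#' @param checkpoint_dir Optional directory for periodic checkpoints.
#' @param checkpoint_every Epoch interval for checkpoints (default: final
#'   epoch only).
#' @param resume_from Optional checkpoint path to resume bit-exactly from.
#' @param verbose Print per-epoch loss means.
#' @return An object of class `molemcl`.
#' @examples
#' \donttest{
#' mols <- generate_fixture_molecules(32, seed = 1)
#' fit <- molemcl_pretrain(mols, epochs = 2, batch_size = 16,
#'                         encoder = encoder_config(num_layers = 2,
#'                                                  hidden_dim = 16))
#' fit
#' }
#' @export
molemcl_pretrain <- function(corpus, ..., config = NULL,
                             checkpoint_dir = NULL, checkpoint_every = NULL,
                             resume_from = NULL, verbose = FALSE) {
  if (is.null(config)) config <- pretrain_config(...)
  stopifnot(inherits(config, "pretrain_config"))
  vocab <- feature_vocab()
  smiles <- if (length(corpus) == 1L && file.exists(corpus))
    read_smiles(corpus) else corpus
  graphs <- smiles_to_graph_batch(smiles, vocab = vocab, on_error = "drop")
  n_dropped <- attr(graphs, "n_dropped")
  if (n_dropped > 0L)
    message(n_dropped, " unparseable SMILES dropped from the corpus")
  n <- length(graphs)
  if (n < 2L) stop("pre-training needs at least 2 valid molecules")

  if (!is.null(resume_from)) {
    object <- load_checkpoint(resume_from)
    .check_resume_config(object$config, config)
    params <- object$params
    opt <- object$opt
    history <- object$history
    start_epoch <- object$epoch
    assign(".Random.seed", object$random_state, envir = globalenv())
  } else {
    params <- init_params(config$encoder, vocab, seed = config$seed)
    opt <- .adam_init(params, lr = config$learning_rate)
    history <- NULL
    start_epoch <- 0L
    set.seed(config$seed)
  }

  for (epoch in seq_len(config$epochs)) {
    if (epoch <= start_epoch) next
    idx_batches <- .make_epoch_batches(n, config$batch_size)
    rows <- list()
    for (bi in seq_along(idx_batches)) {
      res <- pretrain_step(params, opt, graphs[idx_batches[[bi]]], config,
                           vocab)
      params <- res$params; opt <- res$opt
      rows[[bi]] <- as.data.frame(res$breakdown)
    }
    steps <- do.call(rbind, rows)
    epoch_row <- data.frame(epoch = epoch,
                            l_mask = mean(steps$l_mask),
                            l_cl1 = mean(steps$l_cl1),
                            l_maskgcl = mean(steps$l_maskgcl),
                            l_ppgcl = mean(steps$l_ppgcl),
                            total = mean(steps$total),
                            recon_accuracy = mean(steps$recon_accuracy,
                                                  na.rm = TRUE))
    history <- rbind(history, epoch_row)
    if (verbose)
      message(sprintf("epoch %3d  total %.4f  (mask %.4f  cl1 %.4f  ppgcl %.4f)",
                      epoch, epoch_row$total, epoch_row$l_mask,
                      epoch_row$l_cl1, epoch_row$l_ppgcl))
    if (!is.null(checkpoint_dir) &&
        (epoch == config$epochs ||
         (!is.null(checkpoint_every) && epoch %% checkpoint_every == 0L))) {
      obj <- .as_molemcl(params, opt, config, vocab, history, epoch, n)
      save_checkpoint(obj, file.path(checkpoint_dir,
                                     sprintf("checkpoint_epoch%03d.rds", epoch)))
    }
  }
  .as_molemcl(params, opt, config, vocab, history, config$epochs, n)
}

.as_molemcl <- function(params, opt, config, vocab, history, epoch, n) {
  obj <- list(params = params, opt = opt, config = config, vocab = vocab,
              history = history, epoch = epoch, n_molecules = n,
              random_state = get(".Random.seed", envir = globalenv()))
  class(obj) <- "molemcl"
  obj
}

.check_resume_config <- function(old, new) {
  keep <- setdiff(names(old), "epochs")
  for (nm in keep) {
    if (!identical(old[[nm]], new[[nm]]))
      stop("refusing to resume: configuration field '", nm,
           "' differs from the checkpoint")
  }
  invisible(TRUE)
}

#' Save / load a pre-training checkpoint
#'
#' The checkpoint is a single serialized archive of the fitted object
#' (parameter tensors, optimizer and RNG state, configuration, vocabulary,
#' history) plus a JSON metadata sidecar (`<path>.json`) with the
#' configuration, epoch and a checksum.
#'
#' @param object A `molemcl` object.
#' @param path Destination file path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(object, path)
  meta <- list(epoch = object$epoch,
               n_molecules = object$n_molecules,
               config = object$config[setdiff(names(object$config), "encoder")],
               encoder = unclass(object$config$encoder),
               vocab = unclass(object$vocab),
               checksum = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!inherits(obj, "molemcl")) stop("not a molemcl checkpoint: ", path)
  obj
}

#' Run pre-training and write artifacts to a directory
#'
#' Convenience wrapper around [molemcl_pretrain()] that writes a per-epoch
#' metrics CSV and a final checkpoint (with JSON metadata) to `output_dir`.
#'
#' @param corpus SMILES vector or corpus file path.
#' @param output_dir Output directory (created if needed).
#' @param ... Passed to [molemcl_pretrain()].
#' @return The fitted `molemcl` object, invisibly.
#' @export
run_pretraining <- function(corpus, output_dir, ...) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(output_dir, 2L) != 0L)
    stop("output directory is not writable: ", output_dir)
  fit <- molemcl_pretrain(corpus, ...)
  utils::write.csv(fit$history, file.path(output_dir, "metrics.csv"),
                   row.names = FALSE)
  save_checkpoint(fit, file.path(output_dir, "checkpoint.rds"))
  invisible(fit)
}
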