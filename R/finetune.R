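# Downstream multi-task fine-tuning with missing-label masking, ROC-AUC
# evaluation and best-validation-epoch reporting.

#' Multi-task ROC-AUC over labels with missing entries
#'
#' Computes the ROC-AUC per task over the non-missing entries (ties counted
#' as 0.5 concordance) and the mean over tasks with both classes present;
#' single-class tasks are excluded from the mean and reported.
#'
#' @param labels n x T matrix in {0, 1, NA}.
#' @param scores n x T numeric score matrix.
#' @return List with `per_task` (named vector, NA for excluded tasks),
#'   `mean`, and `excluded` (indices of skipped tasks).
#' @export
evaluate_auc <- function(labels, scores) {
  labels <- as.matrix(labels); scores <- as.matrix(scores)
  stopifnot(all(dim(labels) == dim(scores)))
  per_task <- rep(NA_real_, ncol(labels))
  for (t in seq_len(ncol(labels))) {
    keep <- !is.na(labels[, t])
    y <- labels[keep, t]; s <- scores[keep, t]
    if (length(unique(y)) < 2L) next
    per_task[t] <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = s, levels = c(0, 1), direction = "<",
      quiet = TRUE)))
  }
  excluded <- which(is.na(per_task))
  if (length(excluded) == ncol(labels))
    stop("all tasks are degenerate (single-class or empty)")
  list(per_task = per_task, mean = mean(per_task, na.rm = TRUE),
       excluded = excluded)
}

.head_forward <- function(params, hG) {
  .addbias(hG %*% params[["head.W"]], params[["head.b"]])
}

# masked sigmoid cross-entropy: mean over non-missing entries
.bce_masked_grad <- function(logits, labels) {
  obs <- !is.na(labels)
  nobs <- sum(obs)
  if (nobs == 0L) return(list(loss = 0, dlogits = logits * 0))
  p <- 1 / (1 + exp(-logits))
  y <- ifelse(obs, labels, 0)
  ll <- ifelse(obs, log(pmax(ifelse(y == 1, p, 1 - p), 1e-12)), 0)
  dlogits <- ifelse(obs, (p - y) / nobs, 0)
  list(loss = -sum(ll) / nobs, dlogits = dlogits)
}

.finetune_one_seed <- function(object, dataset, split, seed, epochs,
                               batch_size, learning_rate, head_only) {
  config <- object$config$encoder
  Tn <- ncol(dataset$labels)
  set.seed(seed)
  params <- object$params
  hd <- .linear_init(config$hidden_dim, Tn)
  params[["head.W"]] <- hd$W
  params[["head.b"]] <- hd$b
  opt <- .adam_init(params, lr = learning_rate)

  tr <- split$train
  batch_valid <- make_batch(dataset$graphs[split$valid])
  batch_test <- make_batch(dataset$graphs[split$test])
  eval_scores <- function(p, b) .head_forward(p, .encoder_forward(p, b, config)$hG)

  best <- list(auc = -Inf, epoch = 0L, params = params)
  for (epoch in seq_len(epochs)) {
    for (idx in .make_epoch_batches(length(tr), batch_size)) {
      take <- tr[idx]
      batch <- make_batch(dataset$graphs[take])
      fw <- .encoder_forward(params, batch, config, training = TRUE)
      logits <- .head_forward(params, fw$hG)
      bce <- .bce_masked_grad(logits, dataset$labels[take, , drop = FALSE])
      genv <- new.env(parent = emptyenv())
      .gacc(genv, "head.W", crossprod(fw$hG, bce$dlogits))
      .gacc(genv, "head.b", colSums(bce$dlogits))
      if (!head_only) {
        dhG <- tcrossprod(bce$dlogits, params[["head.W"]])
        dH <- .readout_backward(dhG, fw$node, batch, config)
        .layers_backward(params, config, batch, fw$caches, dH, genv)
      }
      upd <- .adam_step(params, .grads_as_list(genv, params,
                                               fill_missing = FALSE), opt)
      params <- upd$params; opt <- upd$opt
      for (nm in names(fw$buffers)) params[[nm]] <- fw$buffers[[nm]]
    }
    va <- tryCatch(
      evaluate_auc(dataset$labels[split$valid, , drop = FALSE],
                   eval_scores(params, batch_valid))$mean,
      error = function(e) NA_real_)
    if (!is.na(va) && va > best$auc) {
      best <- list(auc = va, epoch = epoch, params = params)
    }
  }
  if (best$epoch == 0L) {
    # validation AUC was undefined every epoch (degenerate labels):
    # fall back to the final model
    warning("validation AUC undefined in every epoch; reporting the final model")
    best <- list(auc = NA_real_, epoch = epochs, params = params)
  }
  te <- evaluate_auc(dataset$labels[split$test, , drop = FALSE],
                     eval_scores(best$params, batch_test))
  list(seed = seed, valid_auc = best$auc, best_epoch = best$epoch,
       test_auc = te$mean, per_task = te$per_task)
}

#' Fine-tune a pre-trained encoder on a labeled dataset
#'
#' For each seed, attaches a fresh linear head to the pre-trained encoder
#' and trains the full model (or the head only) with sigmoid cross-entropy
#' over the non-missing labels. Validation mean-AUC is evaluated every
#' epoch; the test performance of the best-validation epoch is reported, and
#' results are aggregated as mean and standard deviation over seeds.
#'
#' @param object A fitted `molemcl` model (or checkpoint path).
#' @param dataset A `labeled_dataset`.
#' @param split A `split_indices` from [scaffold_split()].
#' @param seeds Integer vector of fine-tuning seeds.
#' @param epochs,batch_size,learning_rate Protocol (defaults 100, 32, 0.001).
#' @param head_only Freeze the encoder and train the head only.
#' @return Object of class `molemcl_finetune`: per-seed results plus
#'   `mean_auc` and `sd_auc`.
#' @export
finetune <- function(object, dataset, split, seeds = 0:2, epochs = 100L,
                     batch_size = 32L, learning_rate = 1e-3,
                     head_only = FALSE) {
  if (is.character(object)) object <- load_checkpoint(object)
  stopifnot(inherits(object, "molemcl"), inherits(dataset, "labeled_dataset"))
  if (!length(split$valid) || !length(split$test))
    stop("empty validation or test partition; see the scaffold_split warning")
  runs <- lapply(seeds, function(s)
    .finetune_one_seed(object, dataset, split, s, epochs, batch_size,
                       learning_rate, head_only))
  aucs <- vapply(runs, `[[`, numeric(1), "test_auc")
  out <- list(runs = runs, seeds = seeds, mean_auc = mean(aucs),
              sd_auc = if (length(aucs) > 1L) stats::sd(aucs) else NA_real_)
  class(out) <- "molemcl_finetune"
  out
}

#' @export
print.molemcl_finetune <- function(x, ...) {
  cat(sprintf("Fine-tuning over %d seed(s): test ROC-AUC %.3f (%.3f)\n",
              length(x$seeds), x$mean_auc,
              if (is.na(x$sd_auc)) 0 else x$sd_auc))
  for (r in x$runs)
    cat(sprintf("  seed %d: test %.3f (best valid %s at epoch %d)\n",
                r$seed, r$test_auc,
                ifelse(is.na(r$valid_auc), "NA",
                       sprintf("%.3f", r$valid_auc)), r$best_epoch))
  invisible(x)
}
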