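# S3 methods for fitted molemcl objects.

#' @export
print.molemcl <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Multi-level contrastive molecular pre-training (%s)\n", cfg$ablation))
  cat(sprintf("  encoder: %s, %d layers, hidden dim %d, %s readout\n",
              cfg$encoder$backbone, cfg$encoder$num_layers,
              cfg$encoder$hidden_dim, cfg$encoder$readout))
  cat(sprintf("  alpha %.2f  eta %.2f  tau %.2f  mask rate %.2f\n",
              cfg$alpha, cfg$eta, cfg$tau, cfg$mask_rate))
  cat(sprintf("  trained %d epoch(s) on %d molecules\n",
              x$epoch, x$n_molecules))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: total %.4f (mask %.4f, cl1 %.4f, ppgcl %.4f)\n",
                last$total, last$l_mask, last$l_cl1, last$l_ppgcl))
  }
  invisible(x)
}

#' @export
summary.molemcl <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nPer-epoch loss means (first/last 3):\n")
    h <- object$history
    show <- unique(c(seq_len(min(3, nrow(h))),
                     seq(max(1, nrow(h) - 2), nrow(h))))
    print(h[show, ], row.names = FALSE, digits = 4)
  }
  np <- sum(vapply(object$params, length, integer(1)))
  cat(sprintf("\n%d parameter tensors, %d scalar parameters\n",
              length(object$params), np))
  invisible(object)
}

#' @export
coef.molemcl <- function(object, ...) object$params

#' Embed molecules with a fitted encoder
#'
#' @param object A fitted `molemcl` model.
#' @param newdata Character vector of SMILES, a list of `molgraph`, or a
#'   `graph_batch`.
#' @param type `"embedding"` (graph embeddings from the readout, default),
#'   `"projection"` (projection-head output) or `"node"` (per-node
#'   embeddings).
#' @param ... Unused.
#' @return A numeric matrix with one row per molecule (or node).
#' @export
predict.molemcl <- function(object, newdata,
                            type = c("embedding", "projection", "node"), ...) {
  type <- match.arg(type)
  if (is.character(newdata))
    newdata <- smiles_to_graph_batch(newdata, vocab = object$vocab)
  emb <- encode(newdata, object$params, object$config$encoder)
  switch(type,
         embedding = emb$graph_embeddings,
         projection = emb$projections,
         node = emb$node_embeddings)
}

#' Plot pre-training loss curves
#'
#' @param x A fitted `molemcl` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.molemcl <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("no training history to plot")
  graphics::matplot(h$epoch, h[, c("total", "l_maskgcl", "l_ppgcl")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "#1b9e77", "#d95f02"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "MaskGCL", "PPGCL"),
                   col = c("black", "#1b9e77", "#d95f02"), lwd = 2, bty = "n")
  invisible(x)
}
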