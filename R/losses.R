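# Attribute masking, node-attribute reconstruction and the NT-Xent
# contrastive loss.

#' Masking configuration
#'
#' @param mask_rate Fraction of nodes to mask (0 to 1; default 0.15).
#' @param min_masked Minimum number of masked nodes when `mask_rate > 0`
#'   (default 1).
#' @return Object of class `mask_config`.
#' @export
mask_config <- function(mask_rate = 0.15, min_masked = 1L) {
  stopifnot(mask_rate >= 0, mask_rate <= 1, min_masked >= 0)
  cfg <- list(mask_rate = mask_rate, min_masked = as.integer(min_masked))
  class(cfg) <- "mask_config"
  cfg
}

#' Mask node attributes of a molecular graph
#'
#' Chooses `k = max(min_masked, round(mask_rate * |V|))` nodes uniformly
#' without replacement (`k = 0` when `mask_rate = 0`; clamped to `|V|`),
#' replaces their atom-type index with the mask token and resets their
#' chirality tag; edges and edge features are untouched. Rounding is
#' half-up. Uses the current RNG state, so results are deterministic under a
#' fixed seed.
#'
#' @param graph A `molgraph`.
#' @param config A [mask_config()].
#' @param vocab A [feature_vocab()].
#' @return Object of class `masked_view`: list with `graph` (masked copy),
#'   `masked_node_indices` and `withheld_labels` (the original atom-type
#'   indices).
#' @export
mask_attributes <- function(graph, config = mask_config(),
                            vocab = feature_vocab()) {
  n <- nrow(graph$node_features)
  k <- if (config$mask_rate == 0) 0L
       else max(config$min_masked, floor(config$mask_rate * n + 0.5))
  k <- min(k, n)
  idx <- if (k > 0L) sort(sample.int(n, k)) else integer(0)
  g <- graph
  labels <- g$node_features[idx, 1L]
  if (k > 0L) {
    g$node_features[idx, 1L] <- vocab$mask_atom_index
    g$node_features[idx, 2L] <- .CHIRALITY_UNSPECIFIED
  }
  out <- list(graph = g, masked_node_indices = idx, withheld_labels = labels)
  class(out) <- "masked_view"
  out
}

#' Node-attribute reconstruction loss
#'
#' Mean cross-entropy of a single affine head predicting the withheld
#' atom-type class of each masked node from its embedding in the masked
#' view. The mask token itself is excluded from the label space. With zero
#' masked nodes the loss is 0 (with a warning).
#'
#' @param node_embeddings Matrix (k x d) of masked-node embeddings.
#' @param withheld_labels Integer vector of true atom-type indices.
#' @param params Registry holding the head weights `recon.W`, `recon.b`.
#' @return Nonnegative scalar loss.
#' @export
reconstruction_loss <- function(node_embeddings, withheld_labels, params) {
  .reconstruction_loss_grad(node_embeddings, withheld_labels, params,
                            want_grad = FALSE)$loss
}

.reconstruction_loss_grad <- function(node_embeddings, withheld_labels,
                                      params, want_grad = TRUE) {
  k <- length(withheld_labels)
  if (k == 0L) {
    warning("reconstruction loss over zero masked nodes; returning 0")
    return(list(loss = 0, dnode = NULL, dW = NULL, db = NULL,
                correct = integer(0)))
  }
  W <- params[["recon.W"]]; b <- params[["recon.b"]]
  if (any(withheld_labels < 1L | withheld_labels > ncol(W)))
    stop("withheld label outside the reconstructable atom-type range")
  H <- matrix(node_embeddings, nrow = k)
  logits <- .addbias(H %*% W, b)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  p <- ex / Z
  picked <- cbind(seq_len(k), withheld_labels)
  loss <- -mean(log(pmax(p[picked], 1e-300)))
  correct <- max.col(logits, ties.method = "first") == withheld_labels
  if (!want_grad) return(list(loss = loss, correct = correct))
  dlogit <- p
  dlogit[picked] <- dlogit[picked] - 1
  dlogit <- dlogit / k
  list(loss = loss,
       dnode = tcrossprod(dlogit, W),
       dW = crossprod(H, dlogit),
       db = colSums(dlogit),
       correct = correct)
}

#' Normalized temperature-scaled cross-entropy (NT-Xent) loss
#'
#' For anchors a_i and partners p_i (rows of two B x d matrices), the loss is
#' the mean over i of
#' `-log[ exp(sim(a_i, p_i)/tau) / sum_{j != i} exp(sim(a_i, p_j)/tau) ]`
#' where `sim` is cosine similarity: the positive pair is pulled together
#' against the partner views of the other graphs in the batch, and the
#' denominator excludes the positive term itself, so the value can be
#' negative.
#'
#' @param anchors,partners Numeric matrices of equal dimension, B >= 2 rows.
#' @param tau Positive temperature.
#' @return Scalar loss.
#' @export
nt_xent <- function(anchors, partners, tau) {
  .nt_xent_grad(anchors, partners, tau, want_grad = FALSE)$loss
}

.nt_xent_grad <- function(anchors, partners, tau, want_grad = TRUE) {
  stopifnot(tau > 0)
  A <- as.matrix(anchors); P <- as.matrix(partners)
  B <- nrow(A)
  if (B < 2L) stop("NT-Xent needs a batch of at least 2 graphs (no negatives)")
  stopifnot(nrow(P) == B, ncol(P) == ncol(A))
  na <- pmax(sqrt(rowSums(A * A)), 1e-12)
  np <- pmax(sqrt(rowSums(P * P)), 1e-12)
  An <- A / na; Pn <- P / np
  S <- tcrossprod(An, Pn)          # S_ij = cos(a_i, p_j)
  M <- S / tau
  Moff <- M; diag(Moff) <- -Inf    # denominator excludes the positive
  mx <- apply(Moff, 1L, max)
  lse <- log(rowSums(exp(Moff - mx))) + mx
  loss <- mean(-diag(M) + lse)
  if (!want_grad) return(list(loss = loss))
  W <- exp(Moff - lse)             # softmax over negatives, rowwise
  dS <- (W - diag(B)) / (B * tau)
  dAn <- dS %*% Pn
  dPn <- crossprod(dS, An)
  dA <- (dAn - An * rowSums(dAn * An)) / na
  dP <- (dPn - Pn * rowSums(dPn * Pn)) / np
  list(loss = loss, dA = dA, dP = dP)
}

#' Hybrid attribute-masking contrastive (MaskGCL) loss
#'
#' Convex combination `alpha * l_mask + (1 - alpha) * l_cl1` of the
#' reconstruction loss and the graph-level contrastive loss.
#'
#' @param l_mask Reconstruction loss.
#' @param l_cl1 Contrastive loss.
#' @param alpha Trade-off weight in [0, 1].
#' @return Scalar.
#' @export
maskgcl_loss <- function(l_mask, l_cl1, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * l_mask + (1 - alpha) * l_cl1
}
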