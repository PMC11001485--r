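# Hand-derived reverse-mode gradients for the encoder, projection head and
# readout. Gradients accumulate into an environment keyed by parameter name;
# callers combine branches by weighted summation over registries.

.gacc <- function(genv, name, val) {
  cur <- genv[[name]]
  genv[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

.grads_as_list <- function(genv, params, fill_missing = TRUE) {
  out <- list()
  for (nm in names(params)) {
    g <- genv[[nm]]
    if (is.null(g)) {
      if (!fill_missing) next
      g <- params[[nm]] * 0
    }
    out[[nm]] <- g
  }
  out
}

.combine_grads <- function(gl, weights) {
  nms <- unique(unlist(lapply(gl, names)))
  out <- list()
  for (nm in nms) {
    acc <- NULL
    for (i in seq_along(gl)) {
      g <- gl[[i]][[nm]]
      if (is.null(g)) next
      acc <- if (is.null(acc)) weights[i] * g else acc + weights[i] * g
    }
    out[[nm]] <- acc
  }
  out
}

.bn_backward <- function(dy, cache_xhat, istd, gamma, training) {
  n <- nrow(dy)
  d <- ncol(dy)
  dgamma <- colSums(dy * cache_xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * matrix(gamma, n, d, byrow = TRUE)
  if (training) {
    s1 <- colSums(dxhat) / n
    s2 <- colSums(dxhat * cache_xhat) / n
    dz <- (dxhat - matrix(s1, n, d, byrow = TRUE) -
             cache_xhat * matrix(s2, n, d, byrow = TRUE)) *
          matrix(istd, n, d, byrow = TRUE)
  } else {
    dz <- dxhat * matrix(istd, n, d, byrow = TRUE)
  }
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

.projection_backward <- function(params, pj, dz, genv) {
  .gacc(genv, "proj.W2", crossprod(pj$r1, dz))
  .gacc(genv, "proj.b2", colSums(dz))
  dr1 <- tcrossprod(dz, params[["proj.W2"]])
  dp1 <- dr1 * (pj$p1 > 0)
  .gacc(genv, "proj.W1", crossprod(pj$hG, dp1))
  .gacc(genv, "proj.b1", colSums(dp1))
  tcrossprod(dp1, params[["proj.W1"]])
}

.readout_backward <- function(dhG, H_final, batch, config) {
  cnt <- tabulate(batch$gid, nbins = batch$B)
  if (config$readout == "mean") {
    dhG[batch$gid, , drop = FALSE] / cnt[batch$gid]
  } else if (config$readout == "sum") {
    dhG[batch$gid, , drop = FALSE]
  } else {
    dH <- matrix(0, batch$n, ncol(H_final))
    hG <- .readout_forward(H_final, batch, config)
    for (j in seq_len(ncol(H_final))) {
      ismax <- H_final[, j] == hG[batch$gid, j]
      # route gradient to the first maximal node of each graph
      first <- !duplicated(ifelse(ismax, batch$gid, NA_integer_)) & ismax
      dH[first, j] <- dhG[batch$gid[first], j]
    }
    dH
  }
}

# Backward through the message-passing layers. `dH` is the gradient at the
# final node embeddings (n x d). Accumulates parameter gradients into `genv`.
.layers_backward <- function(params, config, batch, caches, dH, genv) {
  L <- config$num_layers
  n <- batch$n
  for (l in rev(seq_len(L))) {
    nm <- function(x) paste0("layer", l, ".", x)
    cache <- caches[[l]]
    dy <- if (l < L) dH * (cache$y > 0) else dH
    bnb <- .bn_backward(dy, cache$xhat, cache$istd,
                        params[[nm("bn_gamma")]], cache$training)
    .gacc(genv, nm("bn_gamma"), bnb$dgamma)
    .gacc(genv, nm("bn_beta"), bnb$dbeta)
    dz2 <- bnb$dz
    if (config$backbone == "gin") {
      .gacc(genv, nm("W2"), crossprod(cache$r1, dz2))
      .gacc(genv, nm("b2"), colSums(dz2))
      dr1 <- tcrossprod(dz2, params[[nm("W2")]])
      dz1 <- dr1 * (cache$z1 > 0)
      .gacc(genv, nm("W1"), crossprod(cache$a, dz1))
      .gacc(genv, nm("b1"), colSums(dz1))
      da <- tcrossprod(dz1, params[[nm("W1")]])
      dH_prev <- da                                   # self term of a = H + M
      dcontrib <- da[batch$dst, , drop = FALSE]       # dM routed to arcs
    } else if (config$backbone == "gcn") {
      .gacc(genv, nm("W"), crossprod(cache$a, dz2))
      .gacc(genv, nm("b"), colSums(dz2))
      da <- tcrossprod(dz2, params[[nm("W")]])
      dH_prev <- da / cache$indeg                      # self-loop term
      dcontrib <- da[batch$dst, , drop = FALSE] * cache$cnorm
    } else {
      .gacc(genv, nm("Wself"), crossprod(cache$H_in, dz2))
      .gacc(genv, nm("Wnb"), crossprod(cache$agg, dz2))
      .gacc(genv, nm("b"), colSums(dz2))
      dH_prev <- tcrossprod(dz2, params[[nm("Wself")]])
      dagg <- tcrossprod(dz2, params[[nm("Wnb")]]) / cache$indeg
      dcontrib <- dagg[batch$dst, , drop = FALSE]
    }
    if (batch$m > 0L) {
      dH_prev <- dH_prev + .scatter_rows(dcontrib, batch$src, n)
      .gacc(genv, nm("bond_emb"),
            .scatter_rows(dcontrib, cache$e_idx1, nrow(params[[nm("bond_emb")]])))
      .gacc(genv, nm("dir_emb"),
            .scatter_rows(dcontrib, cache$e_idx2, nrow(params[[nm("dir_emb")]])))
    }
    dH <- dH_prev
  }
  .gacc(genv, "atom_emb",
        .scatter_rows(dH, batch$X[, 1L], nrow(params$atom_emb)))
  .gacc(genv, "chir_emb",
        .scatter_rows(dH, batch$X[, 2L], nrow(params$chir_emb)))
  invisible(NULL)
}

# Full backward from projection-space gradients dz (B x d_out) and/or node
# embedding gradients dnode (n x d) through one forward cache.
.encoder_backward <- function(params, config, batch, fw, dz = NULL,
                              dnode = NULL, genv) {
  dH <- if (is.null(dnode)) matrix(0, batch$n, config$hidden_dim) else dnode
  if (!is.null(dz)) {
    dhG <- .projection_backward(params, fw$proj_cache, dz, genv)
    dH <- dH + .readout_backward(dhG, fw$node, batch, config)
  }
  .layers_backward(params, config, batch, fw$caches, dH, genv)
  invisible(NULL)
}
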