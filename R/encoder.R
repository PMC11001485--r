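# Message-passing encoders over batched molecular graphs.
#
# The default backbone is the edge-featured GIN of the attribute-masking
# lineage: h_v <- MLP((1+eps) h_v + sum_{u in N(v)} (h_u + e_uv)) with eps
# fixed at 0, a two-layer MLP per layer, batch normalization (train-mode
# batch statistics) and ReLU between layers (none after the last). GCN and
# GraphSAGE variants share the machinery and differ in the aggregation and
# linear map. Parameters live in a flat named registry so they can be
# snapshotted, perturbed and updated tensor by tensor.

#' Encoder configuration
#'
#' @param backbone One of `"gin"`, `"gcn"`, `"graphsage"`.
#' @param num_layers Number of message-passing layers (default 5).
#' @param hidden_dim Hidden dimension (default 300).
#' @param readout Graph readout: `"mean"` (default), `"sum"` or `"max"`.
#' @param dropout_rate Dropout fraction (default 0; the contrastive branches
#'   assume a deterministic encoder).
#' @param projection_hidden_dim,projection_out_dim Projection-head widths
#'   (default `hidden_dim`).
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(backbone = c("gin", "gcn", "graphsage"),
                           num_layers = 5L, hidden_dim = 300L,
                           readout = c("mean", "sum", "max"),
                           dropout_rate = 0,
                           projection_hidden_dim = hidden_dim,
                           projection_out_dim = hidden_dim) {
  backbone <- match.arg(backbone)
  readout <- match.arg(readout)
  stopifnot(num_layers >= 1L, hidden_dim >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  cfg <- list(backbone = backbone, num_layers = as.integer(num_layers),
              hidden_dim = as.integer(hidden_dim), readout = readout,
              dropout_rate = dropout_rate,
              projection_hidden_dim = as.integer(projection_hidden_dim),
              projection_out_dim = as.integer(projection_out_dim))
  class(cfg) <- "encoder_config"
  cfg
}

.xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# affine layers use the fan-in uniform scheme (weights and biases); nonzero
# biases keep dead-ReLU projection rows away from the exact zero vector,
# where the cosine gradient is undefined
.linear_init <- function(nin, nout) {
  lim <- 1 / sqrt(nin)
  list(W = matrix(stats::runif(nin * nout, -lim, lim), nin, nout),
       b = stats::runif(nout, -lim, lim))
}

#' Initialize an encoder parameter registry
#'
#' Deterministic given `(config, vocab, seed)`. The registry is a flat named
#' list of tensors: feature embedding tables (`atom_emb`, `chir_emb`,
#' per-layer `bond_emb`/`dir_emb`), per-layer linear and batch-norm weights
#' (`layer<l>.*`), the projection head (`proj.*`) and the attribute
#' reconstruction head (`recon.*`).
#'
#' @param config An [encoder_config()].
#' @param vocab A [feature_vocab()].
#' @param seed Integer seed.
#' @return Named list of parameter tensors (class `encoder_params`).
#' @export
init_params <- function(config, vocab = feature_vocab(), seed = 0L) {
  stopifnot(inherits(config, "encoder_config"))
  d <- config$hidden_dim
  .with_seed(seed, {
    p <- list(atom_emb = .xavier(vocab$atom_type_count, d),
              chir_emb = .xavier(vocab$chirality_count, d))
    for (l in seq_len(config$num_layers)) {
      nm <- function(x) paste0("layer", l, ".", x)
      if (config$backbone == "gin") {
        l1 <- .linear_init(d, 2L * d); l2 <- .linear_init(2L * d, d)
        p[[nm("W1")]] <- l1$W; p[[nm("b1")]] <- l1$b
        p[[nm("W2")]] <- l2$W; p[[nm("b2")]] <- l2$b
      } else if (config$backbone == "gcn") {
        l1 <- .linear_init(d, d)
        p[[nm("W")]] <- l1$W; p[[nm("b")]] <- l1$b
      } else {
        l1 <- .linear_init(d, d); l2 <- .linear_init(d, d)
        p[[nm("Wself")]] <- l1$W
        p[[nm("Wnb")]] <- l2$W
        p[[nm("b")]] <- l1$b
      }
      p[[nm("bn_gamma")]] <- rep(1, d)
      p[[nm("bn_beta")]] <- numeric(d)
      p[[nm("bn_mean")]] <- numeric(d)      # running stats (buffers)
      p[[nm("bn_var")]] <- rep(1, d)
      p[[nm("bond_emb")]] <- .xavier(vocab$bond_type_count, d)
      p[[nm("dir_emb")]] <- .xavier(vocab$bond_dir_count, d)
    }
    pr1 <- .linear_init(d, config$projection_hidden_dim)
    pr2 <- .linear_init(config$projection_hidden_dim,
                        config$projection_out_dim)
    p[["proj.W1"]] <- pr1$W; p[["proj.b1"]] <- pr1$b
    p[["proj.W2"]] <- pr2$W; p[["proj.b2"]] <- pr2$b
    rc <- .linear_init(d, vocab$atom_type_count - 1L)
    p[["recon.W"]] <- rc$W; p[["recon.b"]] <- rc$b
    class(p) <- "encoder_params"
    p
  })
}

# Names of the tensors Eq-8-style perturbation applies to: per-layer linear
# and batch-norm weights. Feature embedding tables and the projection /
# reconstruction heads are excluded.
perturbable_names <- function(params) {
  grep("^layer[0-9]+\\.(W1|W2|W|Wself|Wnb|b1|b2|b|bn_gamma|bn_beta)$",
       names(params), value = TRUE)
}

# ---- batching --------------------------------------------------------------

#' Collate molecular graphs into a batch
#'
#' Concatenates node and arc arrays with node-index offsets and records the
#' node-to-graph membership map.
#'
#' @param graphs List of `molgraph`.
#' @return A `graph_batch`: list with `X` (n x 2), `src`, `dst`, `EF`
#'   (m x 2), `gid` (node to graph index), `n`, `m`, `B`.
#' @export
make_batch <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  nv <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offs <- cumsum(c(0L, nv[-length(nv)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  src <- integer(0); dst <- integer(0)
  EF <- matrix(integer(0), 0L, 2L)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (ncol(g$edge_index) > 0L) {
      src <- c(src, g$edge_index[1L, ] + offs[i])
      dst <- c(dst, g$edge_index[2L, ] + offs[i])
      EF <- rbind(EF, g$edge_features)
    }
  }
  b <- list(X = X, src = src, dst = dst, EF = EF,
            gid = rep(seq_along(graphs), nv),
            n = sum(nv), m = length(src), B = length(graphs))
  class(b) <- "graph_batch"
  b
}

# scatter-add rows of `mat` into `nbins` bins given by `idx`
.scatter_rows <- function(mat, idx, nbins) {
  out <- matrix(0, nbins, ncol(mat))
  if (nrow(mat) > 0L) {
    rs <- rowsum(mat, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

.addbias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

# train mode: batch statistics (and updated running stats, momentum 0.1);
# eval mode: stored running statistics, so outputs are batch-independent
.bn_forward <- function(z, gamma, beta, run_mean, run_var, training,
                        eps = 1e-5, momentum = 0.1) {
  n <- nrow(z)
  if (training) {
    mu <- colMeans(z)
    v <- colMeans(z * z) - mu * mu
    v <- pmax(v, 0)
    unb <- if (n > 1L) v * n / (n - 1) else v
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * unb
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- .addbias(z, -mu) * matrix(istd, n, length(istd), byrow = TRUE)
  y <- .addbias(xhat * matrix(gamma, n, length(gamma), byrow = TRUE), beta)
  list(y = y, xhat = xhat, istd = istd, new_mean = new_mean,
       new_var = new_var)
}

# ---- forward ---------------------------------------------------------------

.encoder_forward <- function(params, batch, config, training = FALSE) {
  d <- config$hidden_dim
  L <- config$num_layers
  n <- batch$n
  if (max(batch$X[, 1L]) > nrow(params$atom_emb))
    stop("atom type index outside the embedding vocabulary")
  if (max(batch$X[, 2L]) > nrow(params$chir_emb))
    stop("chirality index outside the embedding vocabulary")
  if (batch$m > 0L && max(batch$EF[, 1L]) > nrow(params[["layer1.bond_emb"]]))
    stop("bond type index outside the embedding vocabulary")
  H <- params$atom_emb[batch$X[, 1L], , drop = FALSE] +
       params$chir_emb[batch$X[, 2L], , drop = FALSE]
  caches <- vector("list", L)
  buffers <- list()
  if (config$backbone == "gcn") {
    indeg <- tabulate(batch$dst, nbins = n) + 1  # + self loop
    cnorm <- 1 / sqrt(indeg[batch$src] * indeg[batch$dst])
  } else if (config$backbone == "graphsage") {
    indeg <- pmax(tabulate(batch$dst, nbins = n), 1)
  }
  for (l in seq_len(L)) {
    nm <- function(x) paste0("layer", l, ".", x)
    e <- params[[nm("bond_emb")]][batch$EF[, 1L], , drop = FALSE] +
         params[[nm("dir_emb")]][batch$EF[, 2L], , drop = FALSE]
    contrib <- H[batch$src, , drop = FALSE] + e
    cache <- list(H_in = H, e_idx1 = batch$EF[, 1L], e_idx2 = batch$EF[, 2L])
    if (config$backbone == "gin") {
      M <- .scatter_rows(contrib, batch$dst, n)
      a <- H + M
      z1 <- .addbias(a %*% params[[nm("W1")]], params[[nm("b1")]])
      r1 <- pmax(z1, 0)
      z2 <- .addbias(r1 %*% params[[nm("W2")]], params[[nm("b2")]])
      cache$a <- a; cache$z1 <- z1; cache$r1 <- r1
    } else if (config$backbone == "gcn") {
      a <- .scatter_rows(contrib * cnorm, batch$dst, n) + H / indeg
      z2 <- .addbias(a %*% params[[nm("W")]], params[[nm("b")]])
      cache$a <- a; cache$cnorm <- cnorm; cache$indeg <- indeg
    } else {
      agg <- .scatter_rows(contrib, batch$dst, n) / indeg
      z2 <- .addbias(H %*% params[[nm("Wself")]] +
                     agg %*% params[[nm("Wnb")]], params[[nm("b")]])
      cache$agg <- agg; cache$indeg <- indeg
    }
    bn <- .bn_forward(z2, params[[nm("bn_gamma")]], params[[nm("bn_beta")]],
                      params[[nm("bn_mean")]], params[[nm("bn_var")]],
                      training)
    cache$xhat <- bn$xhat; cache$istd <- bn$istd; cache$y <- bn$y
    cache$training <- training
    if (training) {
      buffers[[nm("bn_mean")]] <- bn$new_mean
      buffers[[nm("bn_var")]] <- bn$new_var
    }
    H <- if (l < L) pmax(bn$y, 0) else bn$y
    caches[[l]] <- cache
  }
  hG <- .readout_forward(H, batch, config)
  pj <- .projection_forward(params, hG)
  list(node = H, hG = hG, z = pj$z, caches = caches, proj_cache = pj,
       buffers = buffers)
}

.readout_forward <- function(H, batch, config) {
  cnt <- tabulate(batch$gid, nbins = batch$B)
  if (config$readout == "mean") {
    .scatter_rows(H, batch$gid, batch$B) / cnt
  } else if (config$readout == "sum") {
    .scatter_rows(H, batch$gid, batch$B)
  } else {
    hG <- matrix(-Inf, batch$B, ncol(H))
    for (j in seq_len(ncol(H))) {
      hG[, j] <- vapply(split(H[, j], batch$gid), max, numeric(1))
    }
    hG
  }
}

.projection_forward <- function(params, hG) {
  p1 <- .addbias(hG %*% params[["proj.W1"]], params[["proj.b1"]])
  r1 <- pmax(p1, 0)
  z <- .addbias(r1 %*% params[["proj.W2"]], params[["proj.b2"]])
  list(z = z, p1 = p1, r1 = r1, hG = hG)
}

#' Encode a batch of molecular graphs
#'
#' Runs the message-passing encoder and projection head and returns the
#' per-node embeddings, graph embeddings (readout) and projections.
#'
#' @param graphs List of `molgraph`, or a `graph_batch`.
#' @param params An `encoder_params` registry.
#' @param config The matching [encoder_config()].
#' @return List with `node_embeddings`, `graph_embeddings`, `projections`
#'   and `graph_membership`.
#' @export
encode <- function(graphs, params, config) {
  batch <- if (inherits(graphs, "graph_batch")) graphs else make_batch(graphs)
  fw <- .encoder_forward(params, batch, config)
  if (!all(is.finite(fw$node)) || !all(is.finite(fw$z)))
    stop("non-finite embeddings produced")
  list(node_embeddings = fw$node, graph_embeddings = fw$hG,
       projections = fw$z, graph_membership = batch$gid)
}

#' Cosine similarity
#'
#' Standard cosine similarity of two vectors; defined as 0 when both vectors
#' are zero (avoids NaN in degenerate inputs).
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in [-1, 1].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
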