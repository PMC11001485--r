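# Shared fixtures, independent oracles and a memoised full-scale smoke fit.

.cache <- new.env(parent = emptyenv())

tiny_config <- function(backbone = "gin", layers = 2L, dim = 8L) {
  encoder_config(backbone, num_layers = layers, hidden_dim = dim,
                 projection_hidden_dim = dim, projection_out_dim = dim)
}

fixture_graphs <- function(n = 8L, seed = 3L) {
  key <- paste0("graphs_", n, "_", seed)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- smiles_to_graph_batch(
      generate_fixture_molecules(n, seed = seed))
  }
  .cache[[key]]
}

# brute-force NT-Xent oracle: explicit double loop over the printed formula
oracle_nt_xent <- function(A, P, tau) {
  B <- nrow(A)
  cosv <- function(a, b) sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)))
  tot <- 0
  for (i in seq_len(B)) {
    num <- exp(cosv(A[i, ], P[i, ]) / tau)
    den <- 0
    for (j in seq_len(B)) if (j != i) den <- den + exp(cosv(A[i, ], P[j, ]) / tau)
    tot <- tot - log(num / den)
  }
  tot / B
}

# brute-force AUC oracle: concordant-pair counting with ties at 0.5
oracle_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# RDKit (via the system python) as the independent SMILES / scaffold oracle
rdkit_oracle <- function(smiles) {
  fin <- tempfile(fileext = ".txt"); fout <- tempfile(fileext = ".json")
  writeLines(smiles, fin)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from rdkit import Chem",
    "from rdkit.Chem.Scaffolds import MurckoScaffold",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "out = []",
    "for line in open(sys.argv[1]):",
    "    smi = line.strip()",
    "    m = Chem.MolFromSmiles(smi)",
    "    sc = MurckoScaffold.MurckoScaffoldSmiles(mol=m) if m else None",
    "    out.append({'smiles': smi,",
    "                'n_atoms': m.GetNumAtoms() if m else None,",
    "                'n_bonds': m.GetNumBonds() if m else None,",
    "                'n_aromatic': sum(b.GetIsAromatic() for b in m.GetBonds()) if m else None,",
    "                'scaffold': sc})",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  res <- system2("python", c(script, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) stop("rdkit oracle failed: ", paste(res, collapse = "\n"))
  jsonlite::fromJSON(fout, simplifyDataFrame = TRUE)
}

rdkit_canonical <- function(smiles) {
  fin <- tempfile(fileext = ".txt"); fout <- tempfile(fileext = ".txt")
  writeLines(smiles, fin)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdkit import Chem",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "with open(sys.argv[2], 'w') as fh:",
    "    for line in open(sys.argv[1]):",
    "        smi = line.rstrip('\\n')",
    "        m = Chem.MolFromSmiles(smi) if smi else None",
    "        fh.write((Chem.MolToSmiles(m) if m else '') + '\\n')"), script)
  system2("python", c(script, fin, fout), stdout = TRUE, stderr = TRUE)
  readLines(fout)
}

# full-scale pre-training smoke fit (the study conditions), computed once
get_smoke_fit <- function() {
  if (is.null(.cache$smoke_fit)) {
    mols <- generate_fixture_molecules(256, seed = 0)
    .cache$smoke_mols <- mols
    .cache$smoke_fit <- molemcl_pretrain(mols, epochs = 30, batch_size = 256,
                                         seed = 1)
  }
  .cache$smoke_fit
}

# fresh-mask reconstruction accuracy of a fitted model over the corpus
masked_recon_accuracy <- function(fit, graphs, draws = 5L, seed = 123L) {
  set.seed(seed)
  nv <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offs <- cumsum(c(0L, nv[-length(nv)]))
  accs <- numeric(draws)
  for (r in seq_len(draws)) {
    views <- lapply(graphs, mask_attributes,
                    config = mask_config(fit$config$mask_rate),
                    vocab = fit$vocab)
    bm <- make_batch(lapply(views, `[[`, "graph"))
    idx <- unlist(lapply(seq_along(views), function(i)
      views[[i]]$masked_node_indices + offs[i]))
    lab <- unlist(lapply(views, `[[`, "withheld_labels"))
    fw <- molemcl:::.encoder_forward(fit$params, bm, fit$config$encoder,
                                     training = TRUE)
    rec <- molemcl:::.reconstruction_loss_grad(
      fw$node[idx, , drop = FALSE], lab, fit$params, want_grad = FALSE)
    accs[r] <- mean(rec$correct)
  }
  mean(accs)
}

majority_class_rate <- function(graphs) {
  atoms <- unlist(lapply(graphs, function(g) g$node_features[, 1L]))
  max(table(atoms)) / length(atoms)
}

rand_like <- function(p) {
  d <- stats::rnorm(length(p))
  if (is.matrix(p)) matrix(d, nrow(p), ncol(p)) else d
}
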