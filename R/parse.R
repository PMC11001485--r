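# SMILES -> attributed molecular graph featurization.
#
# Parsing and chemistry perception are delegated to OpenBabel through
# ChemmineR/ChemmineOB. Two output formats are combined because neither alone
# carries the full attribute set:
#   * SDF   — kekulized bond orders (single/double/triple),
#   * MOL2  — aromaticity perception (".ar" atom types, "ar" bonds).
# OpenBabel also labels delocalized carboxylate bonds "ar" in MOL2; a bond is
# treated as aromatic only when both endpoint atoms are aromatic, otherwise
# the kekulized SDF order is used.
#
# OpenBabel preserves the input SMILES atom order, which lets chirality tags
# (@ / @@ on bracket atoms) be recovered by a token scan of the SMILES string.

#' Convert a SMILES string to an attributed molecular graph
#'
#' Parses a SMILES string and returns a graph with categorical node features
#' (atom type, chirality tag) and edge features (bond type, bond direction).
#' Every chemical bond is stored as two directed arcs with identical features.
#' Hydrogens are implicit. Node order follows the parser's atom order.
#'
#' @param smiles A single SMILES string.
#' @param vocab A [feature_vocab()].
#' @return An object of class `molgraph`: list with `node_features`
#'   (|V| x 2 integer matrix), `edge_index` (2 x |E_directed| integer matrix),
#'   `edge_features` (|E_directed| x 2 integer matrix) and `smiles`.
#' @examples
#' g <- smiles_to_graph("CCO")
#' nrow(g$node_features)  # 3
#' ncol(g$edge_index)     # 4 (two bonds, each as two arcs)
#' @export
smiles_to_graph <- function(smiles, vocab = feature_vocab()) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  gs <- smiles_to_graph_batch(smiles, vocab = vocab, on_error = "stop")
  gs[[1L]]
}

#' Convert many SMILES strings to molecular graphs
#'
#' Batch companion of [smiles_to_graph()]. With `on_error = "drop"`,
#' unparseable SMILES are dropped and counted (attribute `n_dropped`, with
#' the offending strings in attribute `dropped`), as bulk corpus loaders
#' require; with `on_error = "stop"` the first failure is an error naming the
#' offending string.
#'
#' @param smiles Character vector of SMILES.
#' @param vocab A [feature_vocab()].
#' @param on_error `"stop"` or `"drop"`.
#' @return List of `molgraph` objects (attributes `n_dropped`, `dropped`
#'   when `on_error = "drop"`).
#' @export
smiles_to_graph_batch <- function(smiles, vocab = feature_vocab(),
                                  on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  sdf <- .ob_parse_sdf(smiles)
  mol2 <- .ob_parse_mol2(smiles)
  ok <- length(sdf) == length(smiles) && length(mol2) == length(smiles)
  if (ok) {
    graphs <- vector("list", length(smiles))
    for (i in seq_along(smiles)) {
      graphs[[i]] <- .assemble_graph(smiles[i], sdf[[i]], mol2[[i]], vocab)
    }
    attr(graphs, "n_dropped") <- 0L
    attr(graphs, "dropped") <- character(0)
    return(graphs)
  }
  # batch conversion aborted on a bad molecule: identify failures one by one
  graphs <- list()
  dropped <- character(0)
  for (i in seq_along(smiles)) {
    g <- tryCatch({
      s1 <- .ob_parse_sdf(smiles[i])
      m1 <- .ob_parse_mol2(smiles[i])
      if (length(s1) != 1L || length(m1) != 1L) {
        stop("cannot parse SMILES '", smiles[i], "'")
      }
      .assemble_graph(smiles[i], s1[[1L]], m1[[1L]], vocab)
    }, error = function(e) e)
    if (inherits(g, "error")) {
      if (on_error == "stop") stop("cannot parse SMILES '", smiles[i], "'")
      dropped <- c(dropped, smiles[i])
    } else {
      graphs[[length(graphs) + 1L]] <- g
    }
  }
  if (length(graphs) == 0L) stop("no valid SMILES in input")
  attr(graphs, "n_dropped") <- length(dropped)
  attr(graphs, "dropped") <- dropped
  graphs
}

.new_molgraph <- function(node_features, edge_index, edge_features,
                          smiles = "") {
  g <- list(node_features = node_features, edge_index = edge_index,
            edge_features = edge_features, smiles = smiles)
  class(g) <- "molgraph"
  g
}

#' Validate a molecular graph against its vocabulary
#'
#' Checks the structural invariants: feature indices within vocabulary
#' ranges, arc endpoints within the node set, and directed-arc symmetry
#' (every arc (u,v) has a partner (v,u) with identical features).
#'
#' @param g A `molgraph`.
#' @param vocab A [feature_vocab()].
#' @return `g`, invisibly. Errors on violation.
#' @export
validate_molgraph <- function(g, vocab = feature_vocab()) {
  stopifnot(inherits(g, "molgraph"))
  n <- nrow(g$node_features)
  m <- ncol(g$edge_index)
  if (n < 1L) stop("molgraph must have at least one atom")
  if (ncol(g$node_features) != 2L) stop("node_features must have 2 columns")
  if (any(g$node_features[, 1L] < 1L | g$node_features[, 1L] > vocab$atom_type_count))
    stop("atom type index out of vocabulary range")
  if (any(g$node_features[, 2L] < 1L | g$node_features[, 2L] > vocab$chirality_count))
    stop("chirality index out of vocabulary range")
  if (m > 0L) {
    if (nrow(g$edge_features) != m) stop("edge_features/edge_index mismatch")
    if (any(g$edge_index < 1L | g$edge_index > n))
      stop("edge endpoints out of node range")
    if (any(g$edge_features[, 1L] < 1L | g$edge_features[, 1L] > vocab$bond_type_count))
      stop("bond type index out of vocabulary range")
    if (any(g$edge_features[, 2L] < 1L | g$edge_features[, 2L] > vocab$bond_dir_count))
      stop("bond direction index out of vocabulary range")
    key <- function(a, b, f1, f2) paste(a, b, f1, f2)
    fwd <- key(g$edge_index[1L, ], g$edge_index[2L, ],
               g$edge_features[, 1L], g$edge_features[, 2L])
    rev <- key(g$edge_index[2L, ], g$edge_index[1L, ],
               g$edge_features[, 1L], g$edge_features[, 2L])
    if (!setequal(fwd, rev) || length(fwd) != length(rev))
      stop("directed-arc symmetry violated")
  }
  invisible(g)
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d atoms, %d bonds%s\n",
              nrow(x$node_features), ncol(x$edge_index) %/% 2L,
              if (nzchar(x$smiles)) paste0("  ", x$smiles) else ""))
  invisible(x)
}

# ---- OpenBabel interchange -------------------------------------------------

.ob_convert <- function(smiles, to) {
  input <- paste0(paste(smiles, collapse = "\n"), "\n")
  ChemmineOB::convertFormat("SMI", to, input)
}

# SDF: kekulized orders. Returns per molecule list(elements, bonds matrix
# [a1, a2, order]).
.ob_parse_sdf <- function(smiles) {
  txt <- .ob_convert(smiles, "SDF")
  if (!nzchar(txt)) return(list())
  blocks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1L]]
  blocks <- blocks[vapply(blocks, function(b) grepl("V2000", b, fixed = TRUE),
                          logical(1))]
  lapply(blocks, function(b) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1L]]
    cl <- which(grepl("V2000", lines, fixed = TRUE))[1L]
    na <- as.integer(substr(lines[cl], 1L, 3L))
    nb <- as.integer(substr(lines[cl], 4L, 6L))
    atoms <- lines[(cl + 1L):(cl + na)]
    elements <- trimws(substr(atoms, 32L, 34L))
    bonds <- matrix(integer(0), 0L, 3L)
    if (nb > 0L) {
      bl <- lines[(cl + na + 1L):(cl + na + nb)]
      bonds <- cbind(as.integer(substr(bl, 1L, 3L)),
                     as.integer(substr(bl, 4L, 6L)),
                     as.integer(substr(bl, 7L, 9L)))
    }
    list(elements = elements, bonds = bonds)
  })
}

# MOL2: aromaticity. Returns per molecule list(aromatic logical vector,
# ar_bonds character keys "min max").
.ob_parse_mol2 <- function(smiles) {
  txt <- .ob_convert(smiles, "MOL2")
  if (!nzchar(txt)) return(list())
  blocks <- strsplit(txt, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1L]]
  blocks <- blocks[grepl("@<TRIPOS>ATOM", blocks, fixed = TRUE)]
  lapply(blocks, function(b) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1L]]
    ai <- which(lines == "@<TRIPOS>ATOM")
    bi <- which(lines == "@<TRIPOS>BOND")
    stop_at <- function(start) {
      rest <- lines[-seq_len(start)]
      nxt <- grep("^@<TRIPOS>", rest)
      end <- if (length(nxt)) start + nxt[1L] - 1L else length(lines)
      lines[(start + 1L):end][nzchar(trimws(lines[(start + 1L):end]))]
    }
    atom_lines <- stop_at(ai)
    types <- vapply(strsplit(trimws(atom_lines), "[[:space:]]+"),
                    function(f) f[6L], character(1))
    aromatic <- grepl("\\.ar$", types)
    ar_bonds <- character(0)
    if (length(bi) == 1L && bi < length(lines)) {
      bond_lines <- stop_at(bi)
      if (length(bond_lines)) {
        fields <- strsplit(trimws(bond_lines), "[[:space:]]+")
        a1 <- as.integer(vapply(fields, `[`, character(1), 2L))
        a2 <- as.integer(vapply(fields, `[`, character(1), 3L))
        bt <- vapply(fields, `[`, character(1), 4L)
        sel <- bt == "ar"
        ar_bonds <- paste(pmin(a1[sel], a2[sel]), pmax(a1[sel], a2[sel]))
      }
    }
    list(aromatic = aromatic, ar_bonds = ar_bonds)
  })
}

# Chirality tags from a SMILES token scan. Returns integer vector of length
# natoms, or NULL when the token count disagrees with the parsed atom count.
.smiles_chirality <- function(smiles, natoms) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I",
               "b", "c", "n", "o", "p", "s")
  tags <- integer(0)
  i <- 1L
  nc <- length(chars)
  while (i <= nc) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= nc && chars[j] != "]") j <- j + 1L
      if (j > nc) return(NULL)
      tok <- paste(chars[i:j], collapse = "")
      tag <- if (grepl("@@", tok, fixed = TRUE)) .CHIRALITY_CW
             else if (grepl("@", tok, fixed = TRUE)) .CHIRALITY_CCW
             else .CHIRALITY_UNSPECIFIED
      tags <- c(tags, tag)
      i <- j + 1L
    } else if (ch == "C" && i < nc && chars[i + 1L] == "l") {
      tags <- c(tags, .CHIRALITY_UNSPECIFIED); i <- i + 2L
    } else if (ch == "B" && i < nc && chars[i + 1L] == "r") {
      tags <- c(tags, .CHIRALITY_UNSPECIFIED); i <- i + 2L
    } else if (ch %in% organic) {
      tags <- c(tags, .CHIRALITY_UNSPECIFIED); i <- i + 1L
    } else if (ch == "%") {
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  if (length(tags) != natoms) return(NULL)
  tags
}

.assemble_graph <- function(smiles, sdf, mol2, vocab) {
  n <- length(sdf$elements)
  if (n < 1L) stop("cannot parse SMILES '", smiles, "'")
  atom_idx <- .atomic_number(sdf$elements)
  if (any(atom_idx >= vocab$mask_atom_index))
    stop("atomic number exceeds vocabulary for SMILES '", smiles, "'")
  chir <- .smiles_chirality(smiles, n)
  if (is.null(chir) || length(mol2$aromatic) != n) {
    chir <- rep(.CHIRALITY_UNSPECIFIED, n)
  }
  node_features <- cbind(atom_idx, chir)
  dimnames(node_features) <- NULL
  storage.mode(node_features) <- "integer"

  bonds <- sdf$bonds
  nb <- nrow(bonds)
  if (nb == 0L) {
    return(.new_molgraph(node_features,
                         matrix(integer(0), 2L, 0L),
                         matrix(integer(0), 0L, 2L), smiles))
  }
  key <- paste(pmin(bonds[, 1L], bonds[, 2L]), pmax(bonds[, 1L], bonds[, 2L]))
  both_ar <- mol2$aromatic[bonds[, 1L]] & mol2$aromatic[bonds[, 2L]]
  btype <- pmin(bonds[, 3L], 3L)
  btype[bonds[, 3L] == 4L | (key %in% mol2$ar_bonds & both_ar)] <- .BOND_AROMATIC
  src <- as.vector(rbind(bonds[, 1L], bonds[, 2L]))
  dst <- as.vector(rbind(bonds[, 2L], bonds[, 1L]))
  ef <- cbind(rep(btype, each = 2L), rep(.BOND_DIR_NONE, 2L * nb))
  storage.mode(ef) <- "integer"
  edge_index <- rbind(src, dst)
  dimnames(edge_index) <- NULL
  storage.mode(edge_index) <- "integer"
  .new_molgraph(node_features, edge_index, ef, smiles)
}

# ---- corpus I/O ------------------------------------------------------------

#' Read a plain-text SMILES corpus
#'
#' One SMILES per line; blank lines and lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return Character vector of SMILES.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no SMILES in corpus file: ", path)
  # keep only the first whitespace-delimited field (name columns allowed)
  vapply(strsplit(lines, "[[:space:]]+"), `[`, character(1), 1L)
}

#' Write a plain-text SMILES corpus
#'
#' @param smiles Character vector of SMILES.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
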