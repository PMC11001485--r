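# Bemis-Murcko scaffolds and scaffold-based dataset splitting.
#
# The scaffold of a molecule is its ring systems plus the linker atoms
# connecting them (the 2-core of the molecular graph), with atoms attached to
# that core by a double or triple bond retained (exocyclic =O, =CH2, ...).
# Acyclic molecules have the empty scaffold by convention. The scaffold
# subgraph is canonicalized through OpenBabel so equal scaffolds compare
# equal as strings.

#' Bemis-Murcko scaffold of a molecule
#'
#' @param smiles A single SMILES string.
#' @return Canonical scaffold SMILES; `""` for acyclic molecules.
#' @examples
#' scaffold_of("CCO")            # "" (acyclic)
#' scaffold_of("CC(=O)c1ccccc1") # benzene
#' @export
scaffold_of <- function(smiles) {
  g <- smiles_to_graph(smiles)
  n <- nrow(g$node_features)
  m <- ncol(g$edge_index)
  if (m == 0L) return("")
  und <- g$edge_index[1L, ] < g$edge_index[2L, ]
  a1 <- g$edge_index[1L, und]; a2 <- g$edge_index[2L, und]
  order <- g$edge_features[und, 1L]
  # 2-core: iteratively prune degree-1 atoms -> rings + linkers
  keep_bond <- rep(TRUE, length(a1))
  in_core <- rep(TRUE, n)
  repeat {
    deg <- tabulate(c(a1[keep_bond], a2[keep_bond]), nbins = n)
    leaves <- which(in_core & deg <= 1L)
    if (!length(leaves)) break
    in_core[leaves] <- FALSE
    keep_bond <- keep_bond & !(a1 %in% leaves | a2 %in% leaves)
  }
  if (!any(in_core)) return("")
  # retain atoms double/triple-bonded to the core
  exo <- (order >= 2L & order <= 3L) &
    ((in_core[a1] & !in_core[a2]) | (in_core[a2] & !in_core[a1]))
  keep_atom <- in_core
  keep_atom[c(a1[exo], a2[exo])] <- TRUE
  sel <- keep_atom[a1] & keep_atom[a2]
  idx_map <- cumsum(keep_atom)
  elements <- .ELEMENTS[g$node_features[keep_atom, 1L]]
  bonds <- cbind(idx_map[a1[sel]], idx_map[a2[sel]], order[sel])
  mol <- .write_molblock(elements, bonds)
  out <- ChemmineOB::convertFormat("MOL", "CAN", mol)
  sm <- trimws(strsplit(out, "[\t\n]")[[1L]][1L])
  if (!nzchar(sm)) stop("scaffold canonicalization failed for '", smiles, "'")
  sm
}

#' Canonical SMILES
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  out <- .ob_convert(smiles, "CAN")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
  if (length(lines) != length(smiles))
    stop("canonicalization failed (unparseable SMILES in input)")
  vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
}

.write_molblock <- function(elements, bonds) {
  na <- length(elements)
  nb <- nrow(bonds)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, elements)
  bond_lines <- if (nb > 0L) {
    sprintf("%3d%3d%3d  0", bonds[, 1L], bonds[, 2L], bonds[, 3L])
  } else character(0)
  paste(c("", " molemcl", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
          atom_lines, bond_lines, "M  END", ""),
        collapse = "\n")
}

#' Deterministic scaffold split of a labeled dataset
#'
#' Groups molecules by Bemis-Murcko scaffold, orders the groups by size
#' (largest first, ties broken by scaffold string) and fills the training set
#' until it holds at least `fractions[1]` of the molecules, then the
#' validation set until train+valid hold `fractions[1] + fractions[2]`, with
#' the remainder as test. No scaffold appears in more than one partition; a
#' group larger than the training budget still goes entirely to train. The
#' procedure is deterministic (no RNG).
#'
#' @param dataset A `labeled_dataset` (see [make_synthetic_labels()]), or a
#'   list of `molgraph` objects with SMILES.
#' @param fractions Numeric length-3 train/valid/test fractions summing to 1.
#' @return Object of class `split_indices`: list with integer index vectors
#'   `train`, `valid`, `test` and the per-molecule `scaffolds`.
#' @export
scaffold_split <- function(dataset, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  graphs <- if (inherits(dataset, "labeled_dataset")) dataset$graphs else dataset
  smiles <- vapply(graphs, function(g) g$smiles, character(1))
  if (any(!nzchar(smiles))) stop("scaffold_split needs originating SMILES")
  scaffolds <- vapply(smiles, scaffold_of, character(1), USE.NAMES = FALSE)
  groups <- split(seq_along(graphs), scaffolds)
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  n <- length(graphs)
  t_train <- fractions[1L] * n
  t_valid <- (fractions[1L] + fractions[2L]) * n
  train <- integer(0); valid <- integer(0); test <- integer(0)
  for (grp in groups) {
    if (length(train) < t_train) {
      train <- c(train, grp)
    } else if (length(train) + length(valid) < t_valid) {
      valid <- c(valid, grp)
    } else {
      test <- c(test, grp)
    }
  }
  if (length(train) > ceiling(t_train))
    warning("a scaffold group overflowed the training budget (",
            length(train), " > ", ceiling(t_train), " molecules in train)")
  if (!length(valid) || !length(test))
    warning("scaffold split produced an empty validation or test partition")
  out <- list(train = sort(train), valid = sort(valid), test = sort(test),
              scaffolds = scaffolds)
  class(out) <- "split_indices"
  out
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> train %d / valid %d / test %d (%d scaffolds)\n",
              length(x$train), length(x$valid), length(x$test),
              length(unique(x$scaffolds))))
  invisible(x)
}
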