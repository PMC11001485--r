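# Seeded fixture generation: small valid molecules and synthetic
# substructure-based labels for desk-scale testing of the pre-training and
# fine-tuning pipeline.

# Ring and chain cores. Substituents are appended textually to a core; in
# SMILES the appended fragment bonds to the last written atom, so repeated
# appending grows a substituent chain. Halogens are terminal. The set is
# deliberately heteroatom-rich so that the atom-type distribution is not
# dominated by carbon and masked-attribute reconstruction is measured against
# a weak majority baseline.
.FIXTURE_CORES <- c(
  "c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1",
  "c1ocnc1", "c1scnc1", "n1cncnc1",
  "c1ccc2ccccc2c1", "c1ccc2ncccc2c1",
  "O1CCOCC1", "C1CNCCN1", "C1CCOC1",
  "OCCO", "NCCO", "NCCN", "COC", "NC(=O)CO",
  "N[C@@H](C)C(=O)O", "FC(F)(F)CO", "S=C(N)N", "O=C(O)CO", "OCC(O)CO",
  "NC(=O)N", "O=S(=O)(N)N", "OP(=O)(O)O")

# sampling weights: hetero-rich cores favored, fused carbocycles kept rare
.FIXTURE_CORE_W <- c(0.3, 0.5, 0.8, 0.8, 1.2, 1, 2,
                     0.15, 0.25,
                     0.8, 0.8, 0.5,
                     2.5, 2.5, 2.5, 1, 2,
                     1, 2, 2.5, 2.5, 1.5,
                     2.5, 2, 2)

.FIXTURE_SUBST <- c("O", "O", "O", "N", "N", "N", "F", "Cl", "Br", "I",
                    "S", "S", "OC", "NC", "C#N", "C(=O)N", "ON")
.FIXTURE_TERMINAL <- c("F", "Cl", "Br", "I", "C#N")

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a deterministic corpus of small valid molecules
#'
#' Composes a curated list of ring and chain cores (ethers, amines, amides,
#' halides, benzene/pyridine/furan/thiophene/oxazole/triazine derivatives,
#' fused bicyclics) with randomly attached substituents. The output is a pure
#' function of `(n, seed)`: distinct, parseable SMILES spanning several
#' scaffolds and atom types.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed.
#' @return Character vector of `n` distinct SMILES.
#' @examples
#' mols <- generate_fixture_molecules(8, seed = 1)
#' @export
generate_fixture_molecules <- function(n, seed = 0L) {
  stopifnot(n >= 1L)
  capacity <- length(.FIXTURE_CORES) *
    (1L + length(unique(.FIXTURE_SUBST)) * (1L + length(unique(.FIXTURE_SUBST))))
  if (n > capacity) {
    stop("requested ", n, " distinct molecules, above the generator ",
         "capacity of about ", capacity, " for this template set")
  }
  .with_seed(seed, {
    out <- character(0)
    seen <- new.env(parent = emptyenv())
    stale <- 0L
    while (length(out) < n) {
      stale <- stale + 1L
      if (stale > 20000L) {
        stop("fixture generator exhausted after ", length(out),
             " distinct molecules; maximum capacity is about ", capacity,
             " for this template set")
      }
      s <- sample(.FIXTURE_CORES, 1L, prob = .FIXTURE_CORE_W)
      k <- sample(0:2, 1L, prob = c(0.25, 0.45, 0.3))
      while (k > 0L) {
        sub <- sample(.FIXTURE_SUBST, 1L)
        s <- paste0(s, sub)
        if (sub %in% .FIXTURE_TERMINAL) break
        k <- k - 1L
      }
      if (!is.null(seen[[s]])) next
      seen[[s]] <- TRUE
      ok <- tryCatch({ smiles_to_graph(s); TRUE }, error = function(e) FALSE)
      if (ok) { out <- c(out, s); stale <- 0L }
    }
    out
  })
}

#' Attach synthetic substructure-based labels to molecules
#'
#' Builds a binary multi-task dataset: for each SMARTS pattern in `rule`, the
#' label is 1 iff the molecule contains the pattern, then flipped
#' independently with probability `noise_rate`, then set to missing with
#' probability `missing_rate`. Patterns matching no molecule or every
#' molecule are flagged degenerate in the returned metadata.
#'
#' @param graphs List of `molgraph` objects (with SMILES).
#' @param rule Character vector of SMARTS patterns, one per task.
#' @param noise_rate,missing_rate Fractions in [0, 0.5).
#' @param seed Integer seed.
#' @return Object of class `labeled_dataset`: list with `graphs`, `labels`
#'   (n x T matrix, `NA` = missing), `task_names`, and `meta` (list with
#'   `degenerate_tasks`).
#' @export
make_synthetic_labels <- function(graphs, rule, noise_rate = 0,
                                  missing_rate = 0, seed = 0L) {
  stopifnot(noise_rate >= 0, noise_rate < 0.5,
            missing_rate >= 0, missing_rate < 0.5, length(rule) >= 1L)
  smiles <- vapply(graphs, function(g) g$smiles, character(1))
  if (any(!nzchar(smiles))) stop("graphs must carry originating SMILES")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  n <- length(graphs)
  labels <- matrix(NA_real_, n, length(rule))
  degenerate <- character(0)
  for (t in seq_along(rule)) {
    counts <- suppressWarnings(
      ChemmineR::smartsSearchOB(sdf, rule[t], uniqueMatches = FALSE))
    y <- as.numeric(counts > 0)
    if (all(y == 0) || all(y == 1)) degenerate <- c(degenerate, rule[t])
    labels[, t] <- y
  }
  .with_seed(seed, {
    if (noise_rate > 0) {
      flip <- matrix(stats::runif(n * length(rule)) < noise_rate,
                     n, length(rule))
      labels[flip] <- 1 - labels[flip]
    }
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n * length(rule)) < missing_rate,
                     n, length(rule))
      labels[miss] <- NA_real_
    }
  })
  if (length(degenerate))
    warning("degenerate task(s): pattern matches none or all molecules: ",
            paste(degenerate, collapse = ", "))
  new_labeled_dataset(graphs, labels, rule,
                      meta = list(degenerate_tasks = degenerate))
}

#' Construct a labeled multi-task dataset
#'
#' @param graphs List of `molgraph`.
#' @param labels n x T numeric matrix with entries in {0, 1, NA}.
#' @param task_names Character vector of length T.
#' @param meta Optional list of metadata.
#' @return Object of class `labeled_dataset`.
#' @export
new_labeled_dataset <- function(graphs, labels, task_names,
                                meta = list()) {
  labels <- as.matrix(labels)
  stopifnot(nrow(labels) == length(graphs),
            ncol(labels) == length(task_names))
  if (!all(labels %in% c(0, 1) | is.na(labels)))
    stop("labels must be 0, 1 or NA")
  empty <- colSums(!is.na(labels)) == 0L
  if (any(empty)) {
    meta$degenerate_tasks <- unique(c(meta$degenerate_tasks,
                                      task_names[empty]))
    warning("task(s) with no observed labels: ",
            paste(task_names[empty], collapse = ", "))
  }
  d <- list(graphs = graphs, labels = labels, task_names = task_names,
            meta = meta)
  class(d) <- "labeled_dataset"
  d
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d molecules, %d task(s), %d missing labels\n",
              length(x$graphs), ncol(x$labels), sum(is.na(x$labels))))
  invisible(x)
}

#' Load a labeled dataset from a CSV file
#'
#' MoleculeNet-style layout: one SMILES column, remaining columns are binary
#' task labels with empty cells treated as missing. Unparseable SMILES rows
#' are dropped and counted (metadata field `n_dropped`).
#'
#' @param path CSV file path.
#' @param smiles_column Name of the SMILES column.
#' @return A `labeled_dataset`.
#' @export
load_labeled_csv <- function(path, smiles_column = "smiles") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!smiles_column %in% names(df))
    stop("SMILES column '", smiles_column, "' not found in ", path)
  task_names <- setdiff(names(df), smiles_column)
  if (!length(task_names)) stop("no task columns in ", path)
  smiles <- as.character(df[[smiles_column]])
  labels <- as.matrix(df[task_names])
  storage.mode(labels) <- "double"
  graphs <- smiles_to_graph_batch(smiles, on_error = "drop")
  dropped <- attr(graphs, "dropped")
  if (length(dropped)) {
    message(length(dropped), " unparseable SMILES row(s) dropped")
    keep <- !(smiles %in% dropped)
    labels <- labels[keep, , drop = FALSE]
  }
  if (!length(graphs)) stop("no valid rows in ", path)
  new_labeled_dataset(graphs, labels, task_names,
                      meta = list(n_dropped = length(dropped)))
}

#' Write a labeled dataset to CSV
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output path.
#' @param smiles_column Name for the SMILES column.
#' @return `path`, invisibly.
#' @export
write_labeled_csv <- function(dataset, path, smiles_column = "smiles") {
  df <- data.frame(vapply(dataset$graphs, function(g) g$smiles, character(1)),
                   dataset$labels, check.names = FALSE)
  names(df) <- c(smiles_column, dataset$task_names)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
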