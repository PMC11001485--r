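test_that("featurization matches SMILES semantics on closed-form molecules", {
  g <- smiles_to_graph("C")
  expect_equal(nrow(g$node_features), 1L)
  expect_equal(ncol(g$edge_index), 0L)
  expect_equal(g$node_features[1, 1], 6L)  # carbon

  g <- smiles_to_graph("CCO")
  expect_equal(nrow(g$node_features), 3L)
  expect_equal(ncol(g$edge_index), 4L)     # two bonds, two arcs each

  g <- smiles_to_graph("c1ccccc1")
  expect_equal(nrow(g$node_features), 6L)
  expect_equal(ncol(g$edge_index), 12L)
  expect_true(all(g$edge_features[, 1] == 4L))  # all aromatic

  # carboxylate bonds must not be mislabeled aromatic
  g <- smiles_to_graph("CC(=O)O")
  expect_equal(sort(unique(g$edge_features[, 1])), c(1L, 2L))
})

test_that("chirality tags are recovered from bracket atoms", {
  g <- smiles_to_graph("N[C@@H](C)C(=O)O")
  expect_equal(g$node_features[2, 2], 3L)  # @@ -> clockwise tag
  expect_true(all(g$node_features[-2, 2] == 1L))
  g2 <- smiles_to_graph("N[C@H](C)C(=O)O")
  expect_equal(g2$node_features[2, 2], 2L)
})

test_that("graph invariants hold across the fixture corpus", {
  graphs <- fixture_graphs(32, seed = 11)
  vocab <- feature_vocab()
  for (g in graphs) expect_silent(validate_molgraph(g, vocab))
})

test_that("parser agrees with an independent SMILES parser oracle", {
  smiles <- generate_fixture_molecules(24, seed = 5)
  ora <- rdkit_oracle(smiles)
  graphs <- smiles_to_graph_batch(smiles)
  for (i in seq_along(smiles)) {
    g <- graphs[[i]]
    expect_equal(nrow(g$node_features), ora$n_atoms[i], info = smiles[i])
    expect_equal(ncol(g$edge_index) / 2L, ora$n_bonds[i], info = smiles[i])
    expect_equal(sum(g$edge_features[, 1] == 4L) / 2L, ora$n_aromatic[i],
                 info = smiles[i])
  }
})

test_that("unparseable SMILES raise naming errors or are dropped with counts", {
  expect_error(smiles_to_graph("xq(("), "xq\\(\\(")
  b <- smiles_to_graph_batch(c("CCO", "xq((", "CC"), on_error = "drop")
  expect_length(b, 2L)
  expect_equal(attr(b, "n_dropped"), 1L)
  expect_equal(attr(b, "dropped"), "xq((")
})

test_that("fixture generation is a pure seeded function with guaranteed diversity", {
  m1 <- generate_fixture_molecules(64, seed = 0)
  m2 <- generate_fixture_molecules(64, seed = 0)
  expect_identical(m1, m2)
  expect_equal(anyDuplicated(m1), 0L)
  expect_false(identical(m1, generate_fixture_molecules(64, seed = 1)))
  graphs <- smiles_to_graph_batch(m1)
  expect_length(graphs, 64L)
  scaffolds <- vapply(m1, scaffold_of, character(1))
  expect_gte(length(unique(scaffolds)), 5L)
  atom_types <- unique(unlist(lapply(graphs, function(g) g$node_features[, 1])))
  expect_gte(length(atom_types), 8L)
  expect_error(generate_fixture_molecules(1e6, seed = 0), "capacity")
})

test_that("synthetic labels equal the substructure indicator at zero noise", {
  benz <- c("c1ccccc1", "c1ccccc1O", "Cc1ccccc1", "c1ccccc1N")
  alk <- c("CC", "CCC", "CCO", "CCN")
  graphs <- smiles_to_graph_batch(c(benz, alk))
  ds <- make_synthetic_labels(graphs, "c1ccccc1", noise_rate = 0,
                              missing_rate = 0, seed = 1)
  expect_equal(as.numeric(ds$labels), rep(c(1, 0), each = 4))
})

test_that("label noise and missingness are seeded and near their rates", {
  graphs <- fixture_graphs(100, seed = 2)
  ds <- make_synthetic_labels(graphs, "[#6]", noise_rate = 0,
                              missing_rate = 0.2, seed = 7)
  n_missing <- sum(is.na(ds$labels))
  # binomial(100, 0.2) within 3 sigma
  expect_lt(abs(n_missing - 20), 3 * sqrt(100 * 0.2 * 0.8))
  ds2 <- make_synthetic_labels(graphs, "[#6]", noise_rate = 0,
                               missing_rate = 0.2, seed = 7)
  expect_identical(ds$labels, ds2$labels)
  expect_warning(
    make_synthetic_labels(graphs[1:4], "[#115]", seed = 1),
    "degenerate")
})

test_that("labeled CSV round-trips with missing cells and bad rows handled", {
  d <- tempfile(fileext = ".csv")
  writeLines(c("smiles,taskA,taskB",
               "CCO,1,0",
               "CCN,0,",
               "c1ccccc1,1,1",
               "CC,0,0"), d)
  ds <- load_labeled_csv(d, "smiles")
  expect_length(ds$graphs, 4L)
  expect_equal(sum(is.na(ds$labels)), 1L)
  expect_equal(ds$task_names, c("taskA", "taskB"))

  # one bad SMILES among 10 -> 9 graphs, dropped count 1
  smi <- c(generate_fixture_molecules(9, seed = 4), "notasmiles((")
  d2 <- tempfile(fileext = ".csv")
  writeLines(c("smiles,y", paste0(smi, ",", rep(c(1, 0), 5))), d2)
  expect_message(ds2 <- load_labeled_csv(d2, "smiles"), "1 unparseable")
  expect_length(ds2$graphs, 9L)
  expect_equal(ds2$meta$n_dropped, 1L)

  # round trip
  out <- tempfile(fileext = ".csv")
  write_labeled_csv(ds, out)
  ds3 <- load_labeled_csv(out, "smiles")
  expect_identical(unname(ds3$labels), unname(ds$labels))
  expect_equal(length(ds3$graphs), length(ds$graphs))

  expect_error(load_labeled_csv(d, "nosuchcolumn"), "not found")
})

test_that("SMILES corpus files round-trip with comments skipped", {
  p <- tempfile(fileext = ".smi")
  writeLines(c("# header", "CCO", "", "c1ccccc1 benzene"), p)
  expect_equal(read_smiles(p), c("CCO", "c1ccccc1"))
  write_smiles(c("CC", "CO"), p)
  expect_equal(read_smiles(p), c("CC", "CO"))
})
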