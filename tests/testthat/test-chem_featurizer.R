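test_that("molecular graphs carry nine atom and three bond descriptors", {
  g <- build_molecular_graph("C")
  expect_equal(g$num_atoms, 1L)
  expect_equal(g$num_edges, 0L)
  expect_equal(ncol(g$atom_features), 9L)
  expect_equal(g$atom_features[1, "atomic_number"], c(atomic_number = 6L))
  expect_equal(g$atom_features[1, "num_h"], c(num_h = 4L))

  g2 <- build_molecular_graph("CC")
  expect_equal(g2$num_atoms, 2L)
  expect_equal(g2$num_edges, 2L)
  expect_equal(ncol(g2$edge_attrs), 3L)
  expect_true(all(g2$edge_attrs[, "bond_type"] == 1L))       # single bonds
  expect_true(all(g2$edge_attrs[, "conjugation"] == 0L))
  expect_true(all(g2$atom_features[, "in_ring"] == 0L))
})

test_that("both directions of every bond are stored with equal attributes", {
  g <- build_molecular_graph("CC(=O)Oc1ccccc1C(=O)O")
  expect_true(all(g$edge_index >= 0L & g$edge_index < g$num_atoms))
  key <- function(i, j) paste(i, j)
  fwd <- key(g$edge_index[, 1], g$edge_index[, 2])
  rev <- key(g$edge_index[, 2], g$edge_index[, 1])
  expect_setequal(fwd, rev)
  # attributes match across the two directions
  attr_by_edge <- stats::setNames(
    split(g$edge_attrs, seq_len(nrow(g$edge_attrs))), fwd)
  for (e in seq_along(fwd)) {
    expect_equal(attr_by_edge[[fwd[e]]], attr_by_edge[[rev[e]]])
  }
  # aromatic ring atoms flagged
  expect_equal(sum(g$atom_features[, "aromaticity"]), 6L)
  expect_equal(sum(g$edge_attrs[, "bond_type"] == 4L), 12L)  # 6 bonds x 2
})

test_that("malformed SMILES raise a parse error naming the input", {
  expect_error(build_molecular_graph("C("), "C\\(")
  expect_error(build_molecular_graph("C1CC"), "ring")
  expect_error(build_molecular_graph("C=["), "could not be parsed")
})

test_that("SMILES frequency encoding is total, clamped and zero-padded", {
  v <- default_smiles_vocab()
  expect_length(v, 39L)
  expect_setequal(unname(v), 1:39)

  expect_equal(encode_smiles_frequencies(""), integer(128))
  long <- strrep("C", 200)
  expect_length(encode_smiles_frequencies(long), 128L)

  cc <- encode_smiles_frequencies("CC")
  expect_gt(cc[1], 0L)
  expect_equal(cc[1], cc[2])
  expect_equal(cc[3:128], integer(126))

  # characters outside the table encode to 0, never raise
  weird <- encode_smiles_frequencies("CéC")
  expect_equal(weird[2], 0L)
  expect_gt(weird[1], 0L)
})

test_that("computed properties are deterministic and overridable", {
  p <- compute_properties("C")
  expect_length(p, 9L)
  expect_equal(unname(p["mol_weight"]), 16.04, tolerance = 1e-3)
  expect_identical(p, compute_properties("C"))

  over <- compute_properties("C", table_row = c(mol_weight = 99, hba = NA))
  expect_equal(unname(over["mol_weight"]), 99)
  expect_equal(unname(over["hba"]), unname(p["hba"]))   # NA does not override
})

test_that("property standardization matches hand arithmetic and self-fit", {
  expect_equal(
    drop(standardize_properties(matrix(2, 1, 1), means = 1, stds = 0.5)), 2)

  set.seed(1)
  rows <- matrix(rnorm(45, mean = 5, sd = 3), 5, 9)
  sc <- fit_property_scaler(rows)
  z <- standardize_properties(rows, sc$means, sc$stds)
  expect_equal(colMeans(z), rep(0, 9), tolerance = 1e-9)
  expect_equal(apply(z, 2, sd), rep(1, 9), tolerance = 1e-9)

  const <- cbind(rows[, 1:8], 7)
  expect_warning(sc2 <- fit_property_scaler(const), "zero-variance")
  z2 <- standardize_properties(const, sc2$means, sc2$stds)
  expect_equal(z2[, 9], rep(0, 5))

  expect_error(standardize_properties(rows[, 1:3], sc$means, sc$stds),
               "dimension mismatch")
})

test_that("hierarchical node width is 9 + |S| + 9 and global rows broadcast", {
  hg <- featurize_protac("CC(=O)Oc1ccccc1C(=O)O")
  expect_equal(ncol(hg$node_matrix), 146L)
  # columns beyond the atom block are identical across rows
  glob <- hg$node_matrix[, 10:146, drop = FALSE]
  expect_true(all(apply(glob, 2, function(col) all(col == col[1]))))

  hg64 <- featurize_protac("CC", max_len = 64L)
  expect_equal(ncol(hg64$node_matrix), 9L + 64L + 9L)
  # two-atom molecule: rows differ only in the atom block
  expect_equal(hg64$node_matrix[1, 10:82], hg64$node_matrix[2, 10:82])
})

test_that("canonical re-featurization yields an isomorphic graph", {
  for (smi in c("OCCOc1ccccc1", "CC(=O)Nc1ccc(O)cc1", "c1ccncc1CCN")) {
    can <- canonical_smiles(smi)
    g1 <- build_molecular_graph(smi)
    g2 <- build_molecular_graph(can)
    expect_equal(g1$num_atoms, g2$num_atoms)
    expect_equal(g1$num_edges, g2$num_edges)
    sorted_rows <- function(m) m[do.call(order, as.data.frame(m)), ]
    expect_equal(sorted_rows(g1$atom_features), sorted_rows(g2$atom_features))
    expect_equal(sort(table(g1$edge_attrs[, "bond_type"])),
                 sort(table(g2$edge_attrs[, "bond_type"])))
  }
})

test_that("graph bundles round-trip through plain-text arrays", {
  hg <- featurize_protac("CCOc1ccccc1")
  dir <- withr::local_tempdir()
  write_graph_bundle(hg, dir)
  back <- read_graph_bundle(dir)
  expect_equal(unname(back$node_matrix), unname(hg$node_matrix))
  expect_equal(unname(back$edge_index), unname(hg$edge_index))
  expect_equal(unname(back$edge_attrs), unname(hg$edge_attrs))
})
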