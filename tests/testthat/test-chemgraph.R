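# Atom featurization and SMILES -> graph conversion. Expected per-atom
# tuples (symbol, degree, total H, implicit valence, aromatic) were frozen
# from an independent cheminformatics toolkit on the same molecules.

decode_features <- function(g) {
  t(apply(g$node_features, 1, function(v) {
    c(sym = which(v[1:44] == 1), deg = which(v[45:55] == 1) - 1L,
      th = which(v[56:66] == 1) - 1L, iv = which(v[67:77] == 1) - 1L,
      ar = v[78])
  }))
}

test_that("atom_features builds the 44+11+11+11+1 block layout", {
  f <- atom_features("C", 4, 0, 0, FALSE)
  expect_length(f, 78)
  expect_equal(sum(f), 4)
  expect_equal(which(f[1:44] == 1), 1)      # carbon is the first element slot
  expect_equal(which(f[45:55] == 1) - 1, 4) # degree 4

  f_ar <- atom_features("C", 2, 1, 1, TRUE)
  expect_equal(sum(f_ar), 5)                # aromatic flag adds one
  expect_equal(f_ar[78], 1L)

  f_unk <- atom_features("Xx", 0, 0, 0, FALSE)
  expect_equal(which(f_unk[1:44] == 1), 44) # unknown element -> "other" slot

  expect_error(atom_features("C", -1, 0, 0, FALSE), "degree")
  expect_error(atom_features("C", 2, 11, 0, FALSE), "total_hydrogens")
})

test_that("atom_features is total over its domain with at most 5 ones", {
  for (sym in c("C", "N", "Pb", "Zz")) {
    for (d in c(0L, 5L, 10L)) {
      f <- atom_features(sym, d, 10L - d, d, d %% 2 == 0)
      expect_length(f, 78)
      expect_lte(sum(f), 5)
      expect_gte(sum(f), 4)
    }
  }
})

test_that("simple molecules produce the expected graphs", {
  g1 <- smiles_to_graph("C")
  expect_equal(g1$n_atoms, 1)
  expect_equal(g1$adjacency, matrix(0L, 1, 1))

  g2 <- smiles_to_graph("CC")
  expect_equal(g2$n_atoms, 2)
  expect_equal(g2$adjacency, matrix(c(0L, 1L, 1L, 0L), 2, 2))

  benz <- smiles_to_graph("c1ccccc1")
  expect_equal(benz$n_atoms, 6)
  expect_equal(sum(benz$adjacency) / 2, 6)       # 6 undirected bonds
  expect_equal(benz$node_features[, 78], rep(1L, 6)) # all aromatic
})

test_that("featurization matches the frozen toolkit oracle", {
  cases <- list(
    list(smiles = "c1ccccc1",
         atoms = matrix(rep(c(1, 2, 1, 1, 1), 6), ncol = 5, byrow = TRUE)),
    list(smiles = "CCO",
         atoms = rbind(c(1, 1, 3, 3, 0), c(1, 2, 2, 2, 0), c(3, 1, 1, 1, 0))),
    list(smiles = "CC(=O)[O-]",
         atoms = rbind(c(1, 1, 3, 3, 0), c(1, 3, 0, 0, 0),
                       c(3, 1, 0, 0, 0), c(3, 1, 0, 0, 0))),
    list(smiles = "c1ccncc1",
         atoms = rbind(c(1, 2, 1, 1, 1), c(1, 2, 1, 1, 1), c(1, 2, 1, 1, 1),
                       c(2, 2, 0, 0, 1), c(1, 2, 1, 1, 1), c(1, 2, 1, 1, 1)))
  )
  for (cs in cases) {
    got <- decode_features(smiles_to_graph(cs$smiles))
    dimnames(got) <- NULL
    expect_equal(got, cs$atoms, info = cs$smiles)
  }
  # aspirin: spot-check the frozen oracle rows (ester O and carboxyl OH)
  asp <- decode_features(smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O"))
  expect_equal(unname(asp[4, ]), c(3, 2, 0, 0, 0))   # bridging ester oxygen
  expect_equal(unname(asp[13, ]), c(3, 1, 1, 1, 0))  # carboxyl OH oxygen
  expect_equal(unname(asp[5, ]), c(1, 3, 0, 0, 1))   # substituted ring carbon
})

test_that("graphs satisfy the structural invariants", {
  for (smi in c("CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
                "OCC1OC(O)C(O)C(O)C1O", "O=[N+]([O-])c1ccccc1")) {
    g <- smiles_to_graph(smi)
    expect_equal(g$adjacency, t(g$adjacency), info = smi)
    expect_equal(diag(g$adjacency), rep(0L, g$n_atoms), info = smi)
    expect_equal(dim(g$node_features), c(g$n_atoms, 78L), info = smi)
    expect_true(all(rowSums(g$node_features) %in% c(4, 5)), info = smi)
    # degree one-hot agrees with the adjacency row sums
    deg_block <- g$node_features[, 45:55, drop = FALSE]
    deg <- apply(deg_block, 1, function(v) which(v == 1) - 1L)
    expect_equal(deg, as.integer(rowSums(g$adjacency)), info = smi)
  }
})

test_that("smiles_to_graph is deterministic and errors are informative", {
  a <- smiles_to_graph("CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  b <- smiles_to_graph("CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  expect_identical(a$node_features, b$node_features)
  expect_identical(a$adjacency, b$adjacency)

  expect_error(smiles_to_graph("not_a_smiles("), "not_a_smiles")
  expect_error(smiles_to_graph(""), "empty")
})

test_that("edge-list dump round-trips the bond structure", {
  gs <- list(smiles_to_graph("CCO", "ethanol"), smiles_to_graph("C", "methane"))
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- write_graph_edgelist(gs, path)
  expect_equal(nrow(rows), 2)  # methane contributes no edges
  got <- utils::read.delim(path)
  expect_equal(got$drug_id, c("ethanol", "ethanol"))
  expect_equal(got$i, c(1L, 2L))
  expect_equal(got$j, c(2L, 3L))
})
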