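# Classical trunk branches: shapes, determinism, permutation invariance,
# and the graph-convolution propagation rule against a dense oracle.

test_that("cell encoder obeys its shape and determinism contracts", {
  w <- cell_encoder_init(seed = 3)
  set.seed(4)
  prof <- rbinom(735, 1, 0.1)
  e1 <- cell_encoder_forward(prof, w)
  e2 <- cell_encoder_forward(prof, w)
  expect_length(e1, 128)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))
  expect_error(cell_encoder_forward(rep(0, 100), w), "735")
})

test_that("all-zero weights map any profile to the zero embedding", {
  w <- cell_encoder_init(seed = 3)
  for (i in 1:3) w$conv[[i]]$W[] <- 0
  w$fc$W[] <- 0
  set.seed(5)
  expect_equal(cell_encoder_forward(rbinom(735, 1, 0.5), w), rep(0, 128))
  # and the zero profile through nonzero weights stays zero too
  w2 <- cell_encoder_init(seed = 6)
  w2$conv[[1]]$b[] <- 0; w2$conv[[2]]$b[] <- 0; w2$conv[[3]]$b[] <- 0
  w2$fc$b[] <- 0
  expect_equal(cell_encoder_forward(rep(0, 735), w2), rep(0, 128))
})

test_that("gcn layer reproduces the normalized-propagation oracle", {
  # single node with self-loop: Ahat = 1, identity weights -> output = input
  x1 <- matrix(c(2, 3), 1, 2)
  expect_equal(gcn_layer_forward(x1, matrix(0, 1, 1), diag(2)), x1)

  # two connected nodes with identical rows stay identical (symmetry)
  x2 <- matrix(rep(c(1, 2), each = 2), 2, 2)
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  out2 <- gcn_layer_forward(x2, A2, diag(2))
  expect_equal(out2[1, ], out2[2, ])

  # 3-node path graph vs a hand-built dense normalized adjacency
  X <- rbind(c(1, 0), c(0, 1), c(1, 1))
  A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  AI <- A + diag(3)
  Dm <- diag(1 / sqrt(rowSums(AI)))
  oracle <- pmax(Dm %*% AI %*% Dm %*% X, 0)
  expect_equal(gcn_layer_forward(X, A, diag(2)), oracle, tolerance = 1e-12)

  expect_error(gcn_layer_forward(X, A[1:2, ], diag(2)), "symmetric")
  expect_error(gcn_layer_forward(X, A, diag(3)), "rows")
})

test_that("drug encoder embeds graphs deterministically with length 128", {
  w <- drug_encoder_init(seed = 11)
  g <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O", "aspirin")
  e <- drug_encoder_forward(g, w)
  expect_length(e, 128)
  expect_identical(e, drug_encoder_forward(g, w))

  g1 <- smiles_to_graph("C", "methane")  # pooling over a single node
  expect_length(drug_encoder_forward(g1, w), 128)

  bad <- g; bad$n_atoms <- 0L
  expect_error(drug_encoder_forward(bad, w), "at least one atom")
})

test_that("drug embedding is invariant under node permutations", {
  w <- drug_encoder_init(seed = 12)
  g <- smiles_to_graph("c1ccccc1", "benzene")
  e0 <- drug_encoder_forward(g, w)
  set.seed(13)
  for (rep in 1:3) {
    perm <- sample(g$n_atoms)
    gp <- g
    gp$node_features <- g$node_features[perm, , drop = FALSE]
    gp$adjacency <- g$adjacency[perm, perm, drop = FALSE]
    expect_equal(drug_encoder_forward(gp, w), e0, tolerance = 1e-10)
  }
})

test_that("fuse concatenates drug block first", {
  expect_equal(fuse(rep(0, 128), rep(0, 128)), rep(0, 256))
  cell <- seq_len(128) / 128
  drug <- -seq_len(128) / 128
  z <- fuse(cell, drug)
  expect_length(z, 256)
  expect_equal(z[1:128], drug)
  expect_equal(z[129:256], cell)
})

test_that("relu blocks leave non-negative activations", {
  w <- drug_encoder_init(seed = 14)
  g <- smiles_to_graph("Cn1cnc2c1c(=O)n(C)c(=O)n2C", "caffeine")
  cache <- hqdr:::drug_forward_cache(g, w)
  expect_true(all(cache$node_out >= 0))
  expect_true(all(cache$h >= 0))
})
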