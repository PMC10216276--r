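# Statevector engine vs dense Kronecker-product oracles, circuit geometry,
# and exact gradients of the depth-infused layer.

test_that("rotation gates match dense unitaries on 3 qubits", {
  set.seed(101)
  for (rep in 1:5) {
    s <- random_state(3, seed = 200 + rep)
    q <- sample(1:3, 1)
    th <- runif(1, -2 * pi, 2 * pi)
    expect_state_equal(apply_rx(s, q, th),
                       dense_on_qubit(dense_rx(th), q, 3) %*% as.complex(s))
    expect_state_equal(apply_ry(s, q, th),
                       dense_on_qubit(dense_ry(th), q, 3) %*% as.complex(s))
    expect_state_equal(apply_rz(s, q, th),
                       dense_on_qubit(dense_rz(th), q, 3) %*% as.complex(s))
  }
})

test_that("CNOT matches its dense oracle and basic contracts", {
  set.seed(102)
  for (rep in 1:5) {
    s <- random_state(3, seed = 300 + rep)
    qs <- sample(1:3, 2)
    expect_state_equal(apply_cnot(s, qs[1], qs[2]),
                       dense_cnot(qs[1], qs[2], 3) %*% as.complex(s))
    # involution
    expect_state_equal(apply_cnot(apply_cnot(s, qs[1], qs[2]), qs[1], qs[2]), s)
  }
  # |10> (first qubit = control = 1, little-endian index 2) -> |11>
  s <- qubit_state(2)
  s <- apply_rx(s, 1, pi)          # puts qubit 1 into |1> (up to phase)
  out <- apply_cnot(s, 1, 2)
  expect_equal(Mod(out[4])^2, 1, tolerance = 1e-12)  # basis |11>
  # control in |0>: no action
  expect_state_equal(apply_cnot(qubit_state(2), 1, 2), qubit_state(2))
  expect_error(apply_cnot(qubit_state(2), 1, 1), "differ")
})

test_that("gates preserve the statevector norm through long sequences", {
  s <- random_state(3, seed = 77)
  set.seed(78)
  for (i in 1:2000) {
    op <- sample(4, 1)
    q <- sample(1:3, 1)
    th <- runif(1, -pi, pi)
    s <- switch(op,
                apply_rx(s, q, th), apply_ry(s, q, th), apply_rz(s, q, th),
                {
                  t2 <- sample(setdiff(1:3, q), 1)
                  apply_cnot(s, q, t2)
                })
  }
  expect_equal(sum(Mod(s)^2), 1, tolerance = 1e-12)
})

test_that("RZ leaves measurement probabilities unchanged, RY(pi) flips", {
  s0 <- qubit_state(3)
  s <- apply_rz(s0, 2, 1.234)
  expect_equal(Mod(s)^2, Mod(s0)^2, tolerance = 1e-14)

  s1 <- apply_ry(qubit_state(1), 1, pi)
  expect_equal(z_expectation(s1, 1), -1, tolerance = 1e-12)
})

test_that("variational_layer and encode_block follow their contracts", {
  # identity rotations + CNOTs act trivially on the ground state
  expect_state_equal(variational_layer(qubit_state(4), rep(0, 4)),
                     qubit_state(4))
  expect_error(variational_layer(qubit_state(4), rep(0, 3)), "angles")

  s <- random_state(2, seed = 55)
  out <- variational_layer(s, c(0.3, -1.2))
  expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  # dense oracle for one layer on 2 qubits
  U <- dense_cnot(1, 2, 2) %*% dense_on_qubit(dense_ry(-1.2), 2, 2) %*%
    dense_on_qubit(dense_ry(0.3), 1, 2)
  expect_state_equal(out, U %*% as.complex(s))

  # encoding is diagonal: ground-state probabilities unchanged
  enc <- encode_block(qubit_state(2), c(0.7, -0.2))
  expect_equal(Mod(enc)^2, Mod(qubit_state(2))^2, tolerance = 1e-14)
  expect_state_equal(encode_block(s, c(0, 0)), s)
  # on (|0>+|1>)/sqrt(2), phi = pi flips the X-expectation, keeps Z at 0
  plus <- apply_ry(qubit_state(1), 1, pi / 2)
  rot <- encode_block(plus, pi)
  x_exp <- function(v) 2 * Re(Conj(v[1]) * v[2])
  expect_equal(z_expectation(rot, 1), 0, tolerance = 1e-12)
  expect_equal(x_exp(as.complex(rot)), -x_exp(as.complex(plus)),
               tolerance = 1e-12)
})

test_that("count_parameters reproduces the layer-geometry arithmetic", {
  expect_identical(count_parameters(8, 5, 5, 32), 1320L)
  expect_identical(count_parameters(1, 0, 1, 1), 1L)
  expect_identical(count_parameters(4, 2, 3, 5), 68L)
})

test_that("qdi_forward is 1 at zero angles and bounded in general", {
  p <- qdi_params(seed = 9)
  p$theta_init[] <- 0
  p$theta_blocks[] <- 0
  f <- runif(256, -3, 3)
  expect_equal(qdi_forward(f, p), 1.0, tolerance = 1e-12)

  p2 <- qdi_params(seed = 10)
  for (rep in 1:3) {
    val <- qdi_forward(runif(256, -3, 3), p2)
    expect_lte(abs(val), 1 + 1e-12)
  }
  expect_error(qdi_forward(numeric(10), p2), "256")
})

test_that("output is a degree-1 sinusoid in any single encoded feature", {
  p <- qdi_params(seed = 21)
  set.seed(22)
  f <- runif(256, -1, 1)
  for (idx in c(17L, 201L)) {
    probe <- function(phi) {
      ff <- f
      ff[idx] <- phi
      qdi_forward(ff, p)
    }
    y <- vapply(c(0, pi / 2, pi), probe, numeric(1))
    # solve y = a + b cos(phi) + c sin(phi) from the three probes
    A <- cbind(1, cos(c(0, pi / 2, pi)), sin(c(0, pi / 2, pi)))
    abc <- solve(A, y)
    for (phi in runif(10, -2 * pi, 2 * pi)) {
      pred <- abc[1] + abc[2] * cos(phi) + abc[3] * sin(phi)
      expect_equal(probe(phi), pred, tolerance = 1e-9)
    }
  }
})

test_that("adjoint gradients satisfy the parameter-shift identity", {
  p <- qdi_params(seed = 31)
  set.seed(32)
  f <- runif(256, -1, 1)
  g <- qdi_gradient(f, p)
  expect_equal(g$value, qdi_readout(qdi_forward(f, p), p), tolerance = 1e-12)
  expect_equal(g$grad_out_shift, 1)
  expect_equal(g$grad_out_scale, g$raw_expectation)

  shift_init <- function(i, j, d) {
    pp <- p
    pp$theta_init[i, j] <- pp$theta_init[i, j] + d
    qdi_forward(f, pp)
  }
  shift_block <- function(i, j, k, d) {
    pp <- p
    pp$theta_blocks[i, j, k] <- pp$theta_blocks[i, j, k] + d
    qdi_forward(f, pp)
  }
  for (rep in 1:6) {
    i <- sample(8, 1); j <- sample(5, 1); k <- sample(32, 1)
    ps <- (shift_init(i, j, pi / 2) - shift_init(i, j, -pi / 2)) / 2
    expect_equal(g$grad_theta_init[i, j], ps, tolerance = 1e-10)
    ps_b <- (shift_block(i, j, k, pi / 2) - shift_block(i, j, k, -pi / 2)) / 2
    expect_equal(g$grad_theta_blocks[i, j, k], ps_b, tolerance = 1e-10)
  }
  # feature gradients via the same shift rule (features enter one RZ each)
  for (idx in sample(256, 4)) {
    fp <- f; fp[idx] <- fp[idx] + pi / 2
    fm <- f; fm[idx] <- fm[idx] - pi / 2
    ps_f <- (qdi_forward(fp, p) - qdi_forward(fm, p)) / 2
    expect_equal(g$grad_features[idx], ps_f, tolerance = 1e-10)
  }
})

test_that("gradients vanish along features at the all-zero-angle point", {
  p <- qdi_params(seed = 41)
  p$theta_init[] <- 0
  p$theta_blocks[] <- 0
  f <- runif(256, -1, 1)
  g <- qdi_gradient(f, p)
  expect_equal(max(abs(g$grad_features)), 0, tolerance = 1e-12)
  # central differences confirm (output constant 1 along feature directions)
  for (idx in c(3L, 100L)) {
    fp <- f; fp[idx] <- fp[idx] + 1e-4
    fm <- f; fm[idx] <- fm[idx] - 1e-4
    expect_equal((qdi_forward(fp, p) - qdi_forward(fm, p)) / 2e-4, 0,
                 tolerance = 1e-8)
  }
})

test_that("qdi_readout applies the affine readout", {
  p <- qdi_params(seed = 51)
  p$out_scale <- 1; p$out_shift <- 0
  expect_equal(qdi_readout(1.0, p), 1.0)
  p$out_scale <- 0; p$out_shift <- 0.5
  expect_equal(qdi_readout(0.123, p), 0.5)
  p$out_scale <- 0.25; p$out_shift <- 0.5
  expect_equal(qdi_readout(-1, p), 0.25)
})

test_that("describe_circuit prints the full gate program", {
  p <- qdi_params(n_qubits = 2, n_blocks = 2, n_layers_init = 1,
                  n_layers_block = 1, seed = 1)
  lines <- describe_circuit(p, file = nullfile())
  expect_equal(sum(grepl("^RZ", lines)), 4)       # 2 blocks x 2 qubits
  expect_equal(sum(grepl("^RY", lines)), 6)       # 3 variational layers
  expect_equal(sum(grepl("^CNOT", lines)), 3 + 1) # chains + propagation
  expect_true(any(grepl("MEASURE", lines)))
})
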