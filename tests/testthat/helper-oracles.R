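# Dense-unitary oracles for the statevector engine, built independently via
# Kronecker products, plus small shared fixtures.

dense_rx <- function(theta) {
  matrix(c(cos(theta / 2), -1i * sin(theta / 2),
           -1i * sin(theta / 2), cos(theta / 2)), 2, 2)
}
dense_ry <- function(theta) {
  matrix(c(cos(theta / 2), sin(theta / 2),
           -sin(theta / 2), cos(theta / 2)), 2, 2)
}
dense_rz <- function(theta) {
  diag(c(exp(-1i * theta / 2), exp(1i * theta / 2)))
}

# Embed a 2x2 unitary on qubit k (1-based, little-endian basis labels).
dense_on_qubit <- function(U, qubit, n_qubits) {
  left <- diag(2^(n_qubits - qubit))
  right <- diag(2^(qubit - 1))
  kronecker(left, kronecker(U, right))
}

dense_cnot <- function(control, target, n_qubits) {
  dim <- 2^n_qubits
  P <- matrix(0, dim, dim)
  for (i in 0:(dim - 1)) {
    j <- if (bitwAnd(i, bitwShiftL(1L, control - 1L)) != 0L) {
      bitwXor(i, bitwShiftL(1L, target - 1L))
    } else i
    P[j + 1L, i + 1L] <- 1
  }
  P
}

random_state <- function(n_qubits, seed) {
  set.seed(seed)
  v <- complex(real = rnorm(2^n_qubits), imaginary = rnorm(2^n_qubits))
  v <- v / sqrt(sum(Mod(v)^2))
  attr(v, "n_qubits") <- as.integer(n_qubits)
  v
}

# A small shared synthetic bundle (computed once per test run).
tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_fixtures(4, 10, seed = 303,
                                                    noise_sd = 0.05)
    cache
  }
})

expect_state_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(Mod(as.complex(a) - as.complex(b))), tol)
}

model_to_comparable <- function(m) {
  c(list(variant = m$variant), hqdr:::model_param_list(m))
}
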