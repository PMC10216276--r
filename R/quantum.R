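#' @useDynLib hqdr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Create a fresh qubit register
#'
#' Returns the statevector of `n_qubits` qubits initialized to the all-zeros
#' basis state \eqn{|0\ldots0\rangle}. Amplitudes are stored little-endian:
#' bit `k` (0-based) of a basis-state index holds the state of qubit `k + 1`,
#' so qubit 1 is the least-significant bit and is the qubit that is measured
#' by the depth-infused layer.
#'
#' @param n_qubits number of qubits (positive integer; default 8).
#' @return complex vector of length `2^n_qubits` with attribute `n_qubits`.
#' @export
#' @examples
#' s <- qubit_state(2)
#' Mod(s)^2  # probability 1 on |00>
qubit_state <- function(n_qubits = 8L) {
  n_qubits <- as.integer(n_qubits)
  stopifnot(n_qubits >= 1L, n_qubits <= 24L)
  s <- complex(2^n_qubits)
  s[1] <- 1 + 0i
  attr(s, "n_qubits") <- n_qubits
  s
}

state_n_qubits <- function(state) {
  nq <- attr(state, "n_qubits")
  if (is.null(nq)) nq <- as.integer(round(log2(length(state))))
  if (2^nq != length(state)) {
    stop("state length ", length(state), " is not a power of two", call. = FALSE)
  }
  as.integer(nq)
}

check_qubit <- function(qubit, nq) {
  if (length(qubit) != 1L || is.na(qubit) || qubit < 1L || qubit > nq) {
    stop("qubit index must be in 1..", nq, call. = FALSE)
  }
  as.integer(qubit)
}

apply_rotation <- function(state, qubit, angle, axis) {
  nq <- state_n_qubits(state)
  qubit <- check_qubit(qubit, nq)
  stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle))
  out <- cpp_apply_rotation(as.complex(state), qubit - 1L, angle, axis)
  attr(out, "n_qubits") <- nq
  out
}

#' Single-qubit rotation gates
#'
#' Apply the Pauli rotation \eqn{R_P(\theta) = \exp(-i\,\theta\,\sigma_P/2)}
#' to one qubit of a statevector, for \eqn{P \in \{X, Y, Z\}}:
#' \deqn{R_X(\theta) = \begin{pmatrix} \cos(\theta/2) & -i\sin(\theta/2) \\
#'   -i\sin(\theta/2) & \cos(\theta/2) \end{pmatrix}, \quad
#'   R_Y(\theta) = \begin{pmatrix} \cos(\theta/2) & -\sin(\theta/2) \\
#'   \sin(\theta/2) & \cos(\theta/2) \end{pmatrix}, \quad
#'   R_Z(\theta) = \mathrm{diag}(e^{-i\theta/2}, e^{i\theta/2}).}
#'
#' @param state statevector from [qubit_state()] or a previous gate.
#' @param qubit 1-based qubit index.
#' @param angle rotation angle in radians.
#' @return the transformed statevector (unit norm is preserved).
#' @export
apply_rx <- function(state, qubit, angle) apply_rotation(state, qubit, angle, 0L)

#' @rdname apply_rx
#' @export
apply_ry <- function(state, qubit, angle) apply_rotation(state, qubit, angle, 1L)

#' @rdname apply_rx
#' @export
apply_rz <- function(state, qubit, angle) apply_rotation(state, qubit, angle, 2L)

#' Controlled-NOT gate
#'
#' Flips the target qubit on the basis states where the control qubit is 1.
#'
#' @inheritParams apply_rx
#' @param control,target distinct 1-based qubit indices.
#' @return the transformed statevector.
#' @export
apply_cnot <- function(state, control, target) {
  nq <- state_n_qubits(state)
  control <- check_qubit(control, nq)
  target <- check_qubit(target, nq)
  if (control == target) stop("control and target must differ", call. = FALSE)
  out <- cpp_apply_cnot(as.complex(state), control - 1L, target - 1L)
  attr(out, "n_qubits") <- nq
  out
}

#' Pauli-Z expectation of one qubit
#'
#' @inheritParams apply_rx
#' @return real number in \[-1, 1\].
#' @export
z_expectation <- function(state, qubit = 1L) {
  nq <- state_n_qubits(state)
  qubit <- check_qubit(qubit, nq)
  cpp_z_expectation(as.complex(state), qubit - 1L)
}

#' One variational layer: trainable RY rotations plus a CNOT chain
#'
#' Applies `RY(angles[j])` to qubit `j` for every qubit, then the entangling
#' chain `CNOT(1 -> 2), CNOT(2 -> 3), ..., CNOT(q-1 -> q)`.
#'
#' @inheritParams apply_rx
#' @param angles numeric vector with one angle per qubit.
#' @return the transformed statevector.
#' @export
variational_layer <- function(state, angles) {
  nq <- state_n_qubits(state)
  if (length(angles) != nq) {
    stop("expected ", nq, " angles, got ", length(angles), call. = FALSE)
  }
  for (j in seq_len(nq)) state <- apply_ry(state, j, angles[j])
  if (nq >= 2L) {
    for (j in seq_len(nq - 1L)) state <- apply_cnot(state, j, j + 1L)
  }
  state
}

#' Angle-embed one block of features
#'
#' Encodes one lattice block of classical features by rotating qubit `j`
#' around the Z axis by `scale * block_angles[j]`.
#'
#' @inheritParams apply_rx
#' @param block_angles numeric vector with one feature value per qubit.
#' @param scale proportionality constant between feature value and rotation
#'   angle (default 1).
#' @return the transformed statevector.
#' @export
encode_block <- function(state, block_angles, scale = 1) {
  nq <- state_n_qubits(state)
  if (length(block_angles) != nq) {
    stop("expected ", nq, " features, got ", length(block_angles), call. = FALSE)
  }
  for (j in seq_len(nq)) state <- apply_rz(state, j, scale * block_angles[j])
  state
}

#' Count trainable rotation angles of a depth-infused layer
#'
#' `n_qubits * n_layers_init + n_qubits * n_layers_block * n_blocks`. The two
#' affine readout scalars are counted separately (see [qdi_params()]).
#'
#' @param n_qubits qubits in the register.
#' @param n_layers_init variational layers before the first encoding block.
#' @param n_layers_block variational layers after each encoding block.
#' @param n_blocks encoding blocks (lattice length).
#' @return integer count of rotation angles.
#' @export
#' @examples
#' count_parameters()  # default geometry: 8*5 + 8*5*32 = 1320
count_parameters <- function(n_qubits = 8L, n_layers_init = 5L,
                             n_layers_block = 5L, n_blocks = 32L) {
  stopifnot(n_qubits >= 1L, n_layers_init >= 0L, n_layers_block >= 0L,
            n_blocks >= 0L)
  as.integer(n_qubits * n_layers_init + n_qubits * n_layers_block * n_blocks)
}

#' Parameters of the quantum depth-infused layer
#'
#' Allocates the trainable angles of the data re-uploading circuit:
#' `theta_init`, an `n_qubits x n_layers_init` matrix for the variational
#' layers applied before any encoding, and `theta_blocks`, an
#' `n_qubits x n_layers_block x n_blocks` array for the per-block layers.
#' Angles are drawn from Uniform\[0, 2*pi) with the given seed; the affine
#' readout starts at `out_scale = 1`, `out_shift = 0`.
#'
#' @inheritParams count_parameters
#' @param seed integer seed for the angle initialization.
#' @param encoding_scale proportionality constant for the RZ feature encoding.
#' @return an object of class `qdi_params`.
#' @export
qdi_params <- function(n_qubits = 8L, n_blocks = 32L, n_layers_init = 5L,
                       n_layers_block = 5L, seed = 1L, encoding_scale = 1) {
  n_qubits <- as.integer(n_qubits)
  n_blocks <- as.integer(n_blocks)
  n_layers_init <- as.integer(n_layers_init)
  n_layers_block <- as.integer(n_layers_block)
  rng <- local_rng(seed)
  theta_init <- matrix(rng$runif(n_qubits * n_layers_init, 0, 2 * pi),
                       nrow = n_qubits, ncol = n_layers_init)
  theta_blocks <- array(
    rng$runif(n_qubits * n_layers_block * n_blocks, 0, 2 * pi),
    dim = c(n_qubits, n_layers_block, n_blocks)
  )
  structure(
    list(theta_init = theta_init, theta_blocks = theta_blocks,
         out_scale = 1, out_shift = 0,
         n_qubits = n_qubits, n_blocks = n_blocks,
         n_layers_init = n_layers_init, n_layers_block = n_layers_block,
         encoding_scale = encoding_scale),
    class = "qdi_params"
  )
}

#' @export
print.qdi_params <- function(x, ...) {
  cat("Quantum depth-infused layer parameters\n")
  cat(sprintf("  qubits: %d, encoding blocks: %d, layers: %d initial + %d per block\n",
              x$n_qubits, x$n_blocks, x$n_layers_init, x$n_layers_block))
  cat(sprintf("  trainable rotation angles: %d (+ 2 affine readout scalars)\n",
              count_parameters(x$n_qubits, x$n_layers_init, x$n_layers_block,
                               x$n_blocks)))
  invisible(x)
}

check_qdi_inputs <- function(features, params) {
  stopifnot(inherits(params, "qdi_params"))
  n_feat <- params$n_qubits * params$n_blocks
  if (length(features) != n_feat) {
    stop("expected ", n_feat, " features (", params$n_qubits, " qubits x ",
         params$n_blocks, " blocks), got ", length(features), call. = FALSE)
  }
  if (!all(is.finite(features))) stop("features must be finite", call. = FALSE)
  invisible(TRUE)
}

#' Forward pass of the quantum depth-infused layer
#'
#' Runs the full data re-uploading circuit on the all-zeros state — the
#' initial variational layers, then for each of the `n_blocks` lattice
#' blocks an RZ angle embedding of its 8 features followed by that block's
#' variational layers — applies the measurement-propagation chain
#' `CNOT(k -> 1)` for `k = 2..n_qubits`, and returns the Pauli-Z expectation
#' of the first qubit.
#'
#' @param features numeric vector of length `n_qubits * n_blocks` (256 for
#'   the default geometry).
#' @param params a [qdi_params()] object.
#' @return raw expectation value in \[-1, 1\].
#' @export
qdi_forward <- function(features, params) {
  check_qdi_inputs(features, params)
  cpp_qdi_forward(params$encoding_scale * as.numeric(features),
                  as.numeric(params$theta_init),
                  as.numeric(params$theta_blocks),
                  params$n_qubits, params$n_blocks,
                  params$n_layers_init, params$n_layers_block)
}

#' Affine readout of the quantum layer
#'
#' Rescales the raw expectation with the two trainable readout scalars:
#' `out_scale * raw + out_shift`.
#'
#' @param raw_expectation raw \eqn{\langle Z_1 \rangle} value.
#' @param params a [qdi_params()] object.
#' @return the layer prediction.
#' @export
qdi_readout <- function(raw_expectation, params) {
  stopifnot(inherits(params, "qdi_params"))
  params$out_scale * raw_expectation + params$out_shift
}

#' Exact gradient of the quantum layer readout
#'
#' Computes, by adjoint differentiation of the statevector simulation, the
#' exact derivative of `qdi_readout(qdi_forward(features, params), params)`
#' with respect to every trainable rotation angle, the two affine readout
#' scalars, and every encoded feature. Each rotation-angle derivative equals
#' the parameter-shift value
#' \eqn{[f(\theta + \pi/2) - f(\theta - \pi/2)] / 2}.
#'
#' @inheritParams qdi_forward
#' @return list with `value` (the prediction), `raw_expectation`,
#'   `grad_theta_init`, `grad_theta_blocks` (shaped like the parameter
#'   arrays), `grad_out_scale`, `grad_out_shift`, and `grad_features`.
#' @export
qdi_gradient <- function(features, params) {
  check_qdi_inputs(features, params)
  res <- cpp_qdi_gradient(params$encoding_scale * as.numeric(features),
                          as.numeric(params$theta_init),
                          as.numeric(params$theta_blocks),
                          params$n_qubits, params$n_blocks,
                          params$n_layers_init, params$n_layers_block)
  s <- params$out_scale
  list(
    value = qdi_readout(res$value, params),
    raw_expectation = res$value,
    grad_theta_init = matrix(s * res$grad_theta_init,
                             nrow = params$n_qubits),
    grad_theta_blocks = array(s * res$grad_theta_blocks,
                              dim = dim(params$theta_blocks)),
    grad_out_scale = res$value,
    grad_out_shift = 1,
    grad_features = s * params$encoding_scale * res$grad_features
  )
}

#' Print the gate sequence of the depth-infused circuit
#'
#' Writes one line per gate, in execution order, for audit purposes. Feature
#' slots are printed symbolically (`phi[i]`), trainable angles as
#' `theta[block, layer, qubit]`.
#'
#' @param params a [qdi_params()] object.
#' @param file connection or path passed to [base::cat()]; default prints to
#'   the console.
#' @return invisibly, the character vector of gate lines.
#' @export
describe_circuit <- function(params, file = "") {
  stopifnot(inherits(params, "qdi_params"))
  q <- params$n_qubits
  lines <- character(0)
  var_lines <- function(tag) {
    c(sprintf("RY(q%d, theta[%s, q%d])", seq_len(q), tag, seq_len(q)),
      if (q >= 2L) sprintf("CNOT(q%d -> q%d)", seq_len(q - 1L), 2:q))
  }
  for (l in seq_len(params$n_layers_init)) {
    lines <- c(lines, sprintf("# initial variational layer %d", l),
               var_lines(sprintf("init L%d", l)))
  }
  for (b in seq_len(params$n_blocks)) {
    lines <- c(lines, sprintf("# encoding block %d", b),
               sprintf("RZ(q%d, %g * phi[%d])", seq_len(q),
                       params$encoding_scale, (b - 1L) * q + seq_len(q)))
    for (l in seq_len(params$n_layers_block)) {
      lines <- c(lines, sprintf("# block %d variational layer %d", b, l),
                 var_lines(sprintf("B%d L%d", b, l)))
    }
  }
  lines <- c(lines, "# measurement propagation",
             if (q >= 2L) sprintf("CNOT(q%d -> q1)", 2:q),
             "MEASURE <Z_q1>",
             "READOUT out_scale * <Z_q1> + out_shift")
  cat(lines, sep = "\n", file = file)
  invisible(lines)
}
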