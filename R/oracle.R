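# Dense statevector oracle: brute-force circuit simulation and operator
# algebra on the full 2^n space, used as ground truth for the MPS engine.
# Implemented independently of the tensor-network code path (plain R index
# arithmetic), so agreement between the two is a meaningful check.

#' Dense statevector simulation of a circuit
#'
#' Applies the circuit gate by gate to a computational basis state in the
#' full 2^n space. Long-range two-qubit gates are applied directly (no SWAP
#' insertion). Qubit 0 is the most significant bit of the state index.
#'
#' @param circ a \code{\link{circuit}}
#' @param theta parameter vector
#' @param init_bits initial bit string (default all zeros)
#' @return complex amplitude vector of length 2^n
#' @export
dense_statevector <- function(circ, theta = NULL, init_bits = NULL) {
  n <- circ$n_qubits
  stopifnot(n <= 16)
  dim <- 2^n
  if (is.null(init_bits)) init_bits <- strrep("0", n)
  if (is.character(init_bits)) {
    bits <- as.integer(strsplit(init_bits, "")[[1]])
  } else bits <- as.integer(init_bits)
  stopifnot(length(bits) == n)
  v <- complex(dim)
  v[sum(bits * 2^((n - 1):0)) + 1] <- 1
  for (g in circ$gates) {
    m <- gate_matrix(g, theta)
    v <- dense_apply_gate(v, n, g$qubits, m)
  }
  v
}

# apply a 1- or 2-qubit gate to a dense vector (qubit 0 = MSB)
dense_apply_gate <- function(v, n, qubits, m) {
  idx <- 0:(2^n - 1)
  if (length(qubits) == 1L) {
    s <- n - 1 - qubits
    bit <- bitwAnd(bitwShiftR(idx, s), 1L)
    base <- idx[bit == 0L]
    i0 <- base + 1L
    i1 <- base + 2^s + 1L
    new <- v
    new[i0] <- m[1, 1] * v[i0] + m[1, 2] * v[i1]
    new[i1] <- m[2, 1] * v[i0] + m[2, 2] * v[i1]
    return(new)
  }
  a <- qubits[1]; b <- qubits[2]
  sa <- n - 1 - a; sb <- n - 1 - b
  ba <- bitwAnd(bitwShiftR(idx, sa), 1L)
  bb <- bitwAnd(bitwShiftR(idx, sb), 1L)
  base <- idx[ba == 0L & bb == 0L]
  sub <- list(base + 1L, base + 2^sb + 1L, base + 2^sa + 1L,
              base + 2^sa + 2^sb + 1L)
  new <- v
  for (r in 1:4) {
    acc <- 0
    for (c in 1:4) acc <- acc + m[r, c] * v[sub[[c]]]
    new[sub[[r]]] <- acc
  }
  new
}

#' Dense unitary matrix of a circuit (<= 12 qubits)
#' @param circ a \code{\link{circuit}}
#' @param theta parameter vector
#' @export
dense_unitary <- function(circ, theta = NULL) {
  n <- circ$n_qubits
  stopifnot(n <= 12)
  dim <- 2^n
  u <- matrix(0 + 0i, dim, dim)
  for (col in seq_len(dim)) {
    bits <- as.integer(intToBits(col - 1))[n:1]
    u[, col] <- dense_statevector(circ, theta, bits)
  }
  u
}

#' Dense expectation value <psi|P|psi> of a Pauli string
#' @param v dense statevector (qubit 0 = MSB)
#' @param pauli \code{\link{pauli_string}} or op-code vector
#' @export
dense_expect_pauli <- function(v, pauli) {
  n <- as.integer(round(log2(length(v))))
  if (is.character(pauli)) pauli <- pauli_string(pauli, n)
  ops <- matrix(as.integer(unclass(pauli)), 1)
  w <- cpp_pauli_apply(ops, 1.0, 0.0, v)
  Re(sum(Conj(v) * w))
}

#' Dense energy <psi|H|psi> of a qubit Hamiltonian
#' @param v dense statevector
#' @param ham \code{\link{qubit_hamiltonian}}
#' @export
dense_expect_hamiltonian <- function(v, ham) {
  w <- cpp_pauli_apply(ham$ops, ham$coefs, ham$offset, v)
  Re(sum(Conj(v) * w))
}
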