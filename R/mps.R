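# Right-canonical matrix-product-state interface.

#' Initialize an MPS in a computational product state
#'
#' @param bits character string of 0/1 (qubit 0 first, i.e. leftmost site and
#'   most significant bit of dense indices) or integer vector of bits
#' @param max_bond maximum allowed bond dimension D
#' @param trunc_threshold relative singular-value truncation threshold
#' @param backend SVD backend used during two-qubit gates: "reference",
#'   "jacobi" or "cross"
#' @return object of class \code{mps_state}
#' @export
init_product_state <- function(bits, max_bond = 128, trunc_threshold = 1e-12,
                               backend = c("reference", "jacobi", "cross")) {
  backend <- match.arg(backend)
  if (is.character(bits)) {
    stopifnot(length(bits) == 1, nzchar(bits))
    bits <- as.integer(strsplit(bits, "")[[1]])
  }
  bits <- as.integer(bits)
  stopifnot(length(bits) >= 1, all(bits %in% 0:1))
  n <- length(bits)
  tensors <- vector("list", n)
  for (i in seq_len(n)) {
    a <- array(0 + 0i, dim = c(1, 1, 2))
    a[1, 1, bits[i] + 1L] <- 1 + 0i
    tensors[[i]] <- a
  }
  structure(list(tensors = tensors,
                 spectra = rep(list(1), n + 1L),
                 max_bond = as.integer(max_bond),
                 trunc_threshold = trunc_threshold,
                 backend = match(backend, c("reference", "jacobi", "cross")) - 1L,
                 max_bond_reached = 1L,
                 discarded_weight = 0),
            class = "mps_state")
}

#' @export
print.mps_state <- function(x, ...) {
  dims <- vapply(x$tensors, function(t) dim(t)[2], numeric(1))
  cat(sprintf("<mps_state> %d qubits, bond dims [%s], D max %d, discarded %.3e\n",
              length(x$tensors), paste(dims, collapse = " "),
              x$max_bond, x$discarded_weight))
  invisible(x)
}

#' Number of qubits of an MPS
#' @param state an \code{mps_state}
#' @export
n_qubits <- function(state) length(state$tensors)

#' Apply gates to an MPS
#'
#' Applies a compiled circuit (or a single gate) in order. Two-qubit gates
#' must act on adjacent qubits; use \code{\link{compile_adjacent}} first for
#' long-range gates.
#'
#' @param state an \code{mps_state}
#' @param circuit a \code{\link{circuit}} object
#' @param theta parameter vector resolving parameterized rotations
#' @return the evolved \code{mps_state}
#' @export
apply_circuit <- function(state, circuit, theta = NULL) {
  mats <- circuit_matrices(circuit, theta)
  cpp_mps_apply_gates(state, mats$qubits, mats$mats)
}

#' Apply a single one-qubit gate
#' @param state an \code{mps_state}
#' @param qubit 0-based qubit index
#' @param mat unitary 2x2 matrix
#' @export
apply_1q <- function(state, qubit, mat) {
  check_unitary(mat, 2)
  cpp_mps_apply_gates(state, matrix(c(as.integer(qubit), -1L), 1, 2),
                      list(mat))
}

#' Apply a single two-qubit gate on adjacent qubits
#' @param state an \code{mps_state}
#' @param qubit leftmost of the adjacent pair (acts on \code{qubit},
#'   \code{qubit + 1})
#' @param mat unitary 4x4 matrix in the basis |i_q i_{q+1}>
#' @export
apply_2q <- function(state, qubit, mat) {
  check_unitary(mat, 4)
  cpp_mps_apply_gates(state, matrix(c(as.integer(qubit), as.integer(qubit) + 1L),
                                    1, 2), list(mat))
}

check_unitary <- function(mat, d) {
  stopifnot(is.matrix(mat), nrow(mat) == d, ncol(mat) == d)
  if (max(abs(Conj(t(mat)) %*% mat - diag(d))) > 1e-12)
    stop("gate matrix is not unitary to 1e-12")
  invisible(TRUE)
}

#' Expectation value of a Pauli string on an MPS
#'
#' Single left-to-right transfer contraction opened with the squared bond
#' spectrum at the leftmost non-identity site and closed by right-canonicity.
#'
#' @param state a right-canonical \code{mps_state}
#' @param pauli a \code{\link{pauli_string}} (or op-code vector / label)
#' @return real expectation value
#' @export
expectation_pauli <- function(state, pauli) {
  n <- n_qubits(state)
  if (is.character(pauli)) pauli <- pauli_string(pauli, n)
  v <- as.integer(unclass(pauli))
  if (length(v) > n) stop("pauli string longer than the state")
  if (length(v) < n) v <- c(v, integer(n - length(v)))
  z <- cpp_mps_expect_pauli(state, v)
  if (abs(Im(z)) > 1e-10)
    warning("imaginary part ", format(Im(z)), " for Hermitian observable")
  Re(z)
}

#' Energy expectation of a qubit Hamiltonian on an MPS
#'
#' Sums coefficient-weighted Pauli-string expectations (term order
#' independent; accumulation in extended precision) plus the identity offset.
#'
#' @param state a right-canonical \code{mps_state}
#' @param ham a \code{\link{qubit_hamiltonian}}
#' @return energy in Hartree
#' @export
expectation_hamiltonian <- function(state, ham) {
  stopifnot(ham$n_qubits == n_qubits(state))
  cpp_mps_expect_terms(state, ham$ops, ham$coefs, ham$offset)
}

#' Dense statevector of an MPS (<= 16 qubits)
#'
#' @param state an \code{mps_state}
#' @return complex vector of 2^n amplitudes, qubit 0 as the most significant
#'   bit
#' @export
to_dense <- function(state) {
  as.vector(cpp_mps_to_dense(state))
}

#' Right-canonicity defect per site
#'
#' Maximum absolute deviation of \eqn{\sum_i B_i B_i^\dagger} from the
#' identity at each site; near zero for a valid right-canonical MPS.
#'
#' @param state an \code{mps_state}
#' @export
canonical_defect <- function(state) {
  cpp_mps_canonical_defect(state)
}

#' Bond spectra of an MPS
#' @param state an \code{mps_state}
#' @return list of singular-value vectors, one per internal bond
#' @export
bond_spectra <- function(state) {
  n <- n_qubits(state)
  if (n < 2) return(list())
  state$spectra[2:n]
}

#' Save / load an MPS snapshot
#'
#' Serializes tensors, spectra and metadata to a plain JSON snapshot for
#' restarts (not a public exchange format).
#'
#' @param state an \code{mps_state}
#' @param path file path
#' @export
save_mps <- function(state, path) {
  enc <- list(
    n_qubits = n_qubits(state),
    max_bond = state$max_bond,
    trunc_threshold = state$trunc_threshold,
    backend = state$backend,
    max_bond_reached = state$max_bond_reached,
    discarded_weight = state$discarded_weight,
    spectra = state$spectra,
    tensors = lapply(state$tensors, function(a)
      list(dim = dim(a), re = as.numeric(Re(a)), im = as.numeric(Im(a))))
  )
  jsonlite::write_json(enc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_mps
#' @export
load_mps <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tensors <- lapply(seq_len(enc$n_qubits), function(i) {
    t <- if (is.data.frame(enc$tensors)) enc$tensors[i, ] else enc$tensors[[i]]
    a <- complex(real = unlist(t$re), imaginary = unlist(t$im))
    array(a, dim = unlist(t$dim))
  })
  spectra <- enc$spectra
  if (!is.list(spectra)) spectra <- as.list(spectra)
  structure(list(tensors = tensors, spectra = lapply(spectra, as.numeric),
                 max_bond = as.integer(enc$max_bond),
                 trunc_threshold = enc$trunc_threshold,
                 backend = as.integer(enc$backend),
                 max_bond_reached = as.integer(enc$max_bond_reached),
                 discarded_weight = enc$discarded_weight),
            class = "mps_state")
}
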