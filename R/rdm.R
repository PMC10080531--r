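# Reduced density matrices measured from solved states via Jordan-Wigner
# ladder-operator expectations (dense vectors or MPS states).

# expectation of a product of ladder operators on a dense vector or MPS
expect_ladder <- function(state, qubits, daggers, n_qubits) {
  jw <- cpp_jw_ladder(as.integer(qubits), as.integer(daggers), n_qubits)
  acc <- 0 + 0i
  for (k in seq_along(jw$labels)) {
    p <- pauli_string(jw$labels[k], n_qubits)
    val <- if (inherits(state, "mps_state")) {
      Re(cpp_mps_expect_pauli(state, as.integer(unclass(p))))
    } else {
      ops <- matrix(as.integer(unclass(p)), 1)
      Re(sum(Conj(state) * cpp_pauli_apply(ops, 1.0, 0.0, state)))
    }
    acc <- acc + jw$coefs[k] * val
  }
  acc
}

#' Spatial one-particle reduced density matrix of a solved state
#'
#' \eqn{D_{pq} = \sum_\sigma \langle a^\dagger_{p\sigma} a_{q\sigma} \rangle}
#' in the interleaved spin-orbital convention (trace = electron count).
#'
#' @param state dense statevector (qubit 0 = MSB) or \code{mps_state}
#' @param n_orb number of spatial orbitals
#' @return real symmetric n_orb x n_orb matrix
#' @export
measure_rdm1 <- function(state, n_orb) {
  nq <- 2L * n_orb
  d <- matrix(0, n_orb, n_orb)
  for (p in seq_len(n_orb)) for (q in p:n_orb) {
    v <- 0
    for (s in 0:1)
      v <- v + expect_ladder(state, c(2L * (p - 1L) + s, 2L * (q - 1L) + s),
                             c(1L, 0L), nq)
    if (abs(Im(v)) > 1e-6) warning("imaginary part in rdm1: ", format(Im(v)))
    d[p, q] <- d[q, p] <- Re(v)
  }
  d
}

#' Spatial two-particle reduced density matrix (chemists' convention)
#'
#' \eqn{\Gamma_{pqrs} = \sum_{\sigma\tau} \langle a^\dagger_{p\sigma}
#' a^\dagger_{r\tau} a_{s\tau} a_{q\sigma} \rangle}, so the two-electron
#' energy is \eqn{\tfrac12 \sum \Gamma_{pqrs} (pq|rs)}.
#'
#' @param state dense statevector or \code{mps_state}
#' @param n_orb number of spatial orbitals
#' @return real array n_orb^4
#' @export
measure_rdm2 <- function(state, n_orb) {
  nq <- 2L * n_orb
  G <- array(0, dim = rep(n_orb, 4))
  for (p in seq_len(n_orb)) for (q in seq_len(n_orb))
    for (r in seq_len(n_orb)) for (s in seq_len(n_orb)) {
      v <- 0
      for (s1 in 0:1) for (s2 in 0:1) {
        P <- 2L * (p - 1L) + s1; Q <- 2L * (q - 1L) + s1
        R <- 2L * (r - 1L) + s2; S <- 2L * (s - 1L) + s2
        if (P == R || S == Q) next
        v <- v + expect_ladder(state, c(P, R, S, Q), c(1L, 1L, 0L, 0L), nq)
      }
      if (abs(Im(v)) > 1e-6) warning("imaginary part in rdm2: ", format(Im(v)))
      G[p, q, r, s] <- Re(v)
    }
  G
}
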