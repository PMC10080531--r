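# Peephole circuit simplification: cancellation of adjacent inverse gate
# pairs (modulo gates on disjoint qubits in between). Unitarily equivalent
# to the input circuit; used to strip the redundant SWAP/CNOT ladders that
# arise when consecutive Pauli-exponential fragments share their support.

# TRUE when gates a and b act on the same qubits and compose to identity
.inverse_pair <- function(a, b) {
  if (!identical(a$qubits, b$qubits)) return(FALSE)
  if (a$name != b$name) return(FALSE)
  switch(a$name,
    H = , X = , Y = , Z = TRUE,
    SWAP = TRUE,
    CNOT = identical(a$control, b$control),
    RX = , RY = , RZ =
      is.na(a$param_id) && is.na(b$param_id) &&
      isTRUE(all.equal(a$angle, -b$angle, tolerance = 0)),
    FALSE
  )
}

#' Cancel adjacent inverse gate pairs in a circuit
#'
#' Streams through the gate list keeping, per qubit, the most recent pending
#' gate; a gate that exactly inverts the previous gate on the same qubit set
#' (with only disjoint-qubit gates in between) is cancelled together with
#' it. Repeats to a fixed point. The result is unitarily equivalent to the
#' input.
#'
#' @param circ a \code{\link{circuit}}
#' @return simplified \code{\link{circuit}}
#' @export
simplify_circuit <- function(circ) {
  gates <- circ$gates
  repeat {
    n0 <- length(gates)
    kept <- vector("list", length(gates))
    nk <- 0L
    last_on <- integer(circ$n_qubits)   # index into kept, 0 = none
    for (g in gates) {
      qs <- g$qubits + 1L
      prev <- max(last_on[qs])
      cancelled <- FALSE
      if (prev > 0L) {
        p <- kept[[prev]]
        # p must be the most recent gate on *all* qubits of g and vice versa
        if (!is.null(p) && identical(sort(p$qubits), sort(g$qubits)) &&
            all(last_on[qs] == prev) && .inverse_pair(p, g)) {
          kept[prev] <- list(NULL)
          last_on[qs] <- 0L
          cancelled <- TRUE
        }
      }
      if (!cancelled) {
        nk <- nk + 1L
        kept[[nk]] <- g
        last_on[qs] <- nk
      }
    }
    gates <- Filter(Negate(is.null), kept[seq_len(nk)])
    if (length(gates) == n0) break
  }
  circuit(gates, circ$n_qubits, circ$n_params)
}
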