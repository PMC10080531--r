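# UCCSD cluster operators, Jordan-Wigner compilation to Pauli exponentials,
# Trotterized gate circuits, and the windowed operator pool for chains.

#' Build the UCCSD excitation operator list
#'
#' Enumerates all spin-conserving single and double excitations from the
#' occupied to the virtual spin orbitals of a closed-shell reference.
#' Spin orbitals are interleaved (alpha0, beta0, alpha1, ...), and the
#' reference occupies the first \code{n_elec} of them. With
#' \code{spin_adapt = TRUE} excitations related by a global spin flip share
#' one variational parameter.
#'
#' @param n_elec number of electrons (even)
#' @param n_spin_orb number of spin orbitals (> n_elec)
#' @param spin_adapt share parameters across spin-flip partners
#' @return list of excitation records (kind, occ, virt, param_id) with
#'   attribute \code{n_params}
#' @export
build_uccsd <- function(n_elec, n_spin_orb, spin_adapt = TRUE) {
  stopifnot(n_elec %% 2 == 0, n_elec >= 2)
  if (n_spin_orb <= n_elec)
    return(structure(list(), n_params = 0L))
  occ <- 0:(n_elec - 1)
  virt <- n_elec:(n_spin_orb - 1)
  spin <- function(p) p %% 2L
  flip <- function(p) ifelse(spin(p) == 0L, p + 1L, p - 1L)
  keys <- character(0)
  ops <- list()
  pid_of <- function(key) {
    hit <- match(key, keys)
    if (!is.na(hit)) return(hit)
    keys[[length(keys) + 1L]] <<- key
    length(keys)
  }
  canon_key <- function(occ_idx, virt_idx) {
    paste(paste(sort(occ_idx), collapse = ","),
          paste(sort(virt_idx), collapse = ","), sep = "->")
  }
  shared_key <- function(occ_idx, virt_idx) {
    k1 <- canon_key(occ_idx, virt_idx)
    if (!spin_adapt) return(k1)
    k2 <- canon_key(flip(occ_idx), flip(virt_idx))
    min(k1, k2)
  }
  for (i in occ) for (a in virt) {
    if (spin(i) != spin(a)) next
    ops[[length(ops) + 1L]] <- list(kind = "single", occ = i, virt = a,
                                    param_id = pid_of(shared_key(i, a)),
                                    sign = 1)
  }
  no <- length(occ); nv <- length(virt)
  for (ii in seq_len(no - 1)) for (jj in (ii + 1):no) {
    i <- occ[ii]; j <- occ[jj]
    for (aa in seq_len(nv - 1)) for (bb in (aa + 1):nv) {
      a <- virt[aa]; b <- virt[bb]
      if (spin(i) + spin(j) != spin(a) + spin(b)) next
      # fermionic parity of re-sorting the spin-flipped index pairs: when an
      # excitation shares the parameter of its spin-flip partner, its
      # generator enters with this sign (singlet pairing)
      sgn <- 1
      if (spin_adapt) {
        k_own <- canon_key(c(i, j), c(a, b))
        k_flip <- canon_key(flip(c(i, j)), flip(c(a, b)))
        if (k_flip < k_own) {
          fo <- flip(c(i, j)); fv <- flip(c(a, b))
          if (fo[1] > fo[2]) sgn <- -sgn
          if (fv[1] > fv[2]) sgn <- -sgn
        }
      }
      ops[[length(ops) + 1L]] <- list(kind = "double", occ = c(i, j),
                                      virt = c(a, b),
                                      param_id = pid_of(shared_key(c(i, j), c(a, b))),
                                      sign = sgn)
    }
  }
  structure(ops, n_params = length(keys))
}

#' Jordan-Wigner expansion of the antihermitian cluster generators
#'
#' Each excitation contributes the generator \eqn{T - T^\dagger}, whose JW
#' image is a sum of Pauli strings with purely imaginary coefficients
#' \eqn{i c}; the real factors \eqn{c} are returned for exponentiation as
#' \eqn{\exp(i c \theta P)}.
#'
#' @param ops excitation list from \code{\link{build_uccsd}}
#' @param n_qubits number of qubits
#' @return list of terms (pauli = op-code vector, coeff = real c,
#'   param_id); ordering is singles before doubles, each block sorted by
#'   orbital indices, strings of one excitation in a fixed canonical order
#' @export
jw_cluster_to_paulis <- function(ops, n_qubits) {
  terms <- list()
  for (op in ops) {
    if (op$kind == "single") {
      qub <- c(op$virt, op$occ); dag <- c(1L, 0L)
    } else {
      # T = adag_a adag_b a_j a_i
      qub <- c(op$virt[1], op$virt[2], op$occ[2], op$occ[1])
      dag <- c(1L, 1L, 0L, 0L)
    }
    fwd <- cpp_jw_ladder(as.integer(qub), dag, n_qubits)
    rev_ <- cpp_jw_ladder(as.integer(rev(qub)), as.integer(1L - rev(dag)),
                          n_qubits)
    comb <- new.env()
    addl <- function(lab, cf) {
      key <- lab
      cur <- if (!is.null(comb[[key]])) comb[[key]] else 0 + 0i
      assign(key, cur + cf, envir = comb)
    }
    for (k in seq_along(fwd$labels)) addl(fwd$labels[k], fwd$coefs[k])
    for (k in seq_along(rev_$labels)) addl(rev_$labels[k], -rev_$coefs[k])
    labs <- sort(ls(comb))
    for (lab in labs) {
      cf <- get(lab, envir = comb)
      if (Mod(cf) < 1e-14) next
      if (abs(Re(cf)) > 1e-12)
        stop("cluster generator is not antihermitian after JW")
      sgn <- if (is.null(op$sign)) 1 else op$sign
      terms[[length(terms) + 1L]] <- list(
        pauli = as.integer(unclass(pauli_string(lab, n_qubits))),
        coeff = sgn * Im(cf), param_id = op$param_id)
    }
  }
  terms
}

#' Gate fragment for a parameterized Pauli exponential
#'
#' Standard staircase compilation of \eqn{\exp(i \, c \, \theta \, P)}:
#' basis pre-rotations (H for X, Rx(pi/2) for Y), a CNOT ladder onto the
#' last active qubit, Rz with angle \eqn{-2 c \theta}, and the inverse
#' ladder and rotations; \eqn{2(w-1)} CNOTs for a weight-w string.
#'
#' @param pauli op-code vector (or \code{\link{pauli_string}} / label)
#' @param param_id 1-based parameter index (or NA with \code{angle} fixed)
#' @param coeff real prefactor c
#' @param n_qubits number of qubits (inferred from \code{pauli} if a vector)
#' @param angle fixed value of theta when \code{param_id} is NA
#' @return list of gate records
#' @export
exp_pauli_circuit <- function(pauli, param_id, coeff, n_qubits = NULL,
                              angle = NA) {
  if (is.character(pauli)) {
    stopifnot(!is.null(n_qubits))
    pauli <- pauli_string(pauli, n_qubits)
  }
  v <- as.integer(unclass(pauli))
  sup <- which(v != 0L) - 1L          # 0-based support
  if (!length(sup)) stop("cannot exponentiate the identity string")
  gates <- list()
  pre <- list(); post <- list()
  for (q in sup) {
    code <- v[q + 1L]
    if (code == 1L) {                 # X
      pre[[length(pre) + 1L]] <- gate_h(q)
      post[[length(post) + 1L]] <- gate_h(q)
    } else if (code == 2L) {          # Y
      pre[[length(pre) + 1L]] <- gate_rx(q, angle = pi / 2)
      post[[length(post) + 1L]] <- gate_rx(q, angle = -pi / 2)
    }
  }
  ladder <- list()
  if (length(sup) > 1)
    for (k in seq_len(length(sup) - 1))
      ladder[[k]] <- gate_cnot(sup[k], sup[k + 1])
  last <- sup[length(sup)]
  rz <- if (is.na(param_id) || is.null(param_id)) {
    gate_rz(last, angle = -2 * coeff * angle)
  } else {
    gate_rz(last, param_id = param_id, pcoef = -2 * coeff)
  }
  c(pre, ladder, list(rz), rev(ladder), post)
}

#' First-order Trotter step circuit from compiled Pauli terms
#'
#' Concatenates the \code{\link{exp_pauli_circuit}} fragments of the given
#' terms in their stated order (one Trotter step).
#'
#' @param pauli_terms list of (pauli, coeff, param_id) from
#'   \code{\link{jw_cluster_to_paulis}} (or a pool expansion)
#' @param n_qubits number of qubits
#' @param n_params number of variational parameters
#' @param reverse reverse the term order (ordering-sensitivity checks)
#' @return a \code{\link{circuit}}
#' @export
trotterize <- function(pauli_terms, n_qubits, n_params = NULL,
                       reverse = FALSE) {
  if (is.null(n_params))
    n_params <- if (length(pauli_terms))
      max(vapply(pauli_terms, function(t) as.integer(t$param_id), integer(1)))
    else 0L
  if (reverse) pauli_terms <- rev(pauli_terms)
  gates <- list()
  for (t in pauli_terms)
    gates <- c(gates, exp_pauli_circuit(t$pauli, t$param_id, t$coeff))
  circuit(gates, n_qubits, n_params)
}

#' Full UCCSD single-Trotter-step ansatz circuit for a molecular problem
#'
#' With \code{screen_ints} supplied, double excitations whose two-electron
#' integral numerators vanish (below \code{screen_tol}) are dropped: their
#' amplitudes are zero by point-group symmetry, so removing them leaves the
#' variational minimum unchanged while shrinking the circuit. Singles are
#' never screened.
#'
#' @param ham a \code{\link{qubit_hamiltonian}} built by
#'   \code{\link{build_qubit_hamiltonian}} (carries the electron count)
#' @param spin_adapt share spin-flip-partner parameters
#' @param screen_ints optional \code{\link{integral_set}} used to screen
#'   symmetry-forbidden doubles
#' @param screen_tol integral-magnitude threshold for the screening
#' @return a \code{\link{circuit}} acting on the Hartree-Fock reference
#' @export
uccsd_circuit <- function(ham, spin_adapt = TRUE, screen_ints = NULL,
                          screen_tol = 1e-10) {
  stopifnot(!is.null(ham$n_elec))
  ops <- build_uccsd(ham$n_elec, ham$n_qubits, spin_adapt = spin_adapt)
  if (!is.null(screen_ints))
    ops <- screen_doubles(ops, screen_ints, screen_tol)
  terms <- jw_cluster_to_paulis(ops, ham$n_qubits)
  trotterize(terms, ham$n_qubits, attr(ops, "n_params"))
}

# drop double excitations whose MP2-style integral numerators vanish
# (symmetry-forbidden amplitudes); parameter ids are compacted afterwards
screen_doubles <- function(ops, ints, tol) {
  g <- ints$g
  spat <- function(p) p %/% 2L + 1L
  keep <- vapply(ops, function(op) {
    if (op$kind == "single") return(TRUE)
    i <- spat(op$occ[1]); j <- spat(op$occ[2])
    a <- spat(op$virt[1]); b <- spat(op$virt[2])
    max(abs(g[i, a, j, b]), abs(g[i, b, j, a])) > tol
  }, logical(1))
  ops2 <- ops[keep]
  old_ids <- vapply(ops2, function(op) op$param_id, integer(1))
  new_ids <- match(old_ids, sort(unique(old_ids)))
  for (k in seq_along(ops2)) ops2[[k]]$param_id <- new_ids[k]
  structure(ops2, n_params = length(unique(new_ids)))
}

#' Windowed generalized-excitation operator pool for hydrogen chains
#'
#' Builds generalized single and double (GSD) excitation operators over
#' every \code{window} consecutive spatial orbitals (stride-1 sliding
#' window), Jordan-Wigner transforms them, deletes all Pauli-Z factors,
#' discards strings with an even number of Pauli-Ys (the Hamiltonian is
#' real), and deduplicates preserving first occurrence.
#'
#' @param n_spatial number of spatial orbitals
#' @param window window width in spatial orbitals (default 5, i.e. 10
#'   qubits)
#' @param stride window stride (default 1)
#' @return object of class \code{operator_pool}: list of op-code vectors
#'   with a \code{provenance} data.frame attribute
#' @export
build_chain_pool <- function(n_spatial, window = 5, stride = 1) {
  if (window > n_spatial) stop("window exceeds the number of spatial orbitals")
  n_qubits <- 2L * n_spatial
  seen <- new.env()
  strings <- list()
  prov <- list()
  starts <- seq(0L, n_spatial - window, by = stride)
  add_string <- function(v, win, exc) {
    v[v == 3L] <- 0L                        # remove every Pauli-Z
    ny <- sum(v == 2L)
    if (ny %% 2L == 0L) return(invisible()) # even Y count dropped
    key <- paste(v, collapse = "")
    if (!is.null(seen[[key]])) return(invisible())
    assign(key, TRUE, envir = seen)
    strings[[length(strings) + 1L]] <<- v
    prov[[length(prov) + 1L]] <<- data.frame(window = win, excitation = exc)
  }
  for (w0 in starts) {
    orbs <- w0:(w0 + window - 1L)
    so <- sort(c(2L * orbs, 2L * orbs + 1L))  # spin orbitals of the window
    spin <- so %% 2L
    # generalized singles p>q, same spin
    for (qi in seq_along(so)) for (pi in seq_along(so)) {
      p <- so[pi]; q <- so[qi]
      if (p <= q || spin[pi] != spin[qi]) next
      jw <- cpp_jw_ladder(c(p, q), c(1L, 0L), n_qubits)
      for (k in seq_along(jw$labels))
        add_string(as.integer(unclass(pauli_string(jw$labels[k], n_qubits))),
                   w0 + 1L, sprintf("s:%d->%d", q, p))
    }
    # generalized doubles: creation pair p1<p2, annihilation pair q1<q2,
    # Sz conserving, distinct index sets
    cmb <- utils::combn(so, 2)
    for (ci in seq_len(ncol(cmb))) for (cj in seq_len(ncol(cmb))) {
      cr <- cmb[, ci]; an <- cmb[, cj]
      if (ci == cj) next
      if (sum(cr %% 2L) != sum(an %% 2L)) next
      if (ci < cj) next                      # one of each conjugate pair
      jw <- cpp_jw_ladder(c(cr[2], cr[1], an[1], an[2]),
                          c(1L, 1L, 0L, 0L), n_qubits)
      for (k in seq_along(jw$labels))
        add_string(as.integer(unclass(pauli_string(jw$labels[k], n_qubits))),
                   w0 + 1L, sprintf("d:%d,%d->%d,%d", an[1], an[2], cr[1], cr[2]))
    }
  }
  structure(strings, class = "operator_pool",
            provenance = do.call(rbind, prov), n_qubits = n_qubits)
}

#' @export
print.operator_pool <- function(x, ...) {
  cat(sprintf("<operator_pool> %d Pauli strings on %d qubits\n",
              length(x), attr(x, "n_qubits")))
  invisible(x)
}

#' Ansatz circuit from an operator pool
#'
#' Single pass over the pool: \eqn{\prod_j \exp(i \theta_j P_j)} in pool
#' order, one parameter per string.
#'
#' @param pool an \code{operator_pool}
#' @return a \code{\link{circuit}} with \code{length(pool)} parameters
#' @export
pool_circuit <- function(pool) {
  n_qubits <- attr(pool, "n_qubits")
  terms <- lapply(seq_along(pool), function(k)
    list(pauli = pool[[k]], coeff = 1, param_id = k))
  trotterize(terms, n_qubits, length(pool))
}
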