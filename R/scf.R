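# Restricted Hartree-Fock and molecular-orbital integral sets.

#' Restricted Hartree-Fock calculation
#'
#' Solves the closed-shell RHF equations with DIIS acceleration starting from
#' the core-Hamiltonian guess.
#'
#' @param mol a \code{\link{molecular_system}}
#' @param conv_tol convergence threshold on the DIIS error norm and energy
#' @param max_iter maximum SCF iterations
#' @param verbose print per-iteration energies
#' @return list with MO coefficients \code{C} (AO x MO), orbital energies
#'   \code{eps}, density matrix \code{D} (AO basis, trace = n_electrons),
#'   total energy \code{energy}, electronic energy, overlap \code{S}, core
#'   Hamiltonian \code{hcore}, AO two-electron array \code{g_ao}, and
#'   bookkeeping fields
#' @export
scf_rhf <- function(mol, conv_tol = 1e-10, max_iter = 200, verbose = FALSE) {
  shells <- basis_shells(mol$symbols, mol$coords / .bohr, mol$basis)
  z <- .element_numbers[mol$symbols]
  one <- cpp_one_electron(shells, mol$coords / .bohr, as.numeric(z))
  n <- one$nbf
  S <- one$S; Tm <- one$T; V <- one$V
  hcore <- Tm + V
  g_ao <- cpp_eri(shells)
  dim(g_ao) <- c(n, n, n, n)              # g[s,r,q,p] = (pq|rs) (reversed fill)
  g_ao <- aperm(g_ao, c(4, 3, 2, 1))      # now g_ao[p,q,r,s] = (pq|rs)
  enuc <- nuclear_repulsion(mol)
  if (mol$n_electrons %% 2L != 0L)
    stop("restricted closed-shell reference requires an even electron count")
  nocc <- mol$n_electrons %/% 2L
  if (nocc < 1 || nocc > n) stop("electron count incompatible with basis size")

  # symmetric orthogonalization
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-8)
    warning("near-linear dependence in the basis (min overlap eigenvalue ",
            format(min(es$values)), ")")
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)

  Gj <- matrix(g_ao, n * n, n * n)               # (pq) x (rs)
  Gk <- matrix(aperm(g_ao, c(1, 3, 2, 4)), n * n, n * n)  # [(p,q),(r,s)] = (pr|qs)

  fock_of <- function(D) {
    J <- matrix(Gj %*% as.vector(D), n, n)
    K <- matrix(Gk %*% as.vector(D), n, n)
    hcore + J - 0.5 * K
  }
  dens_of <- function(F) {
    Fp <- X %*% F %*% X
    ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ef$values)                 # eigen() sorts decreasing
    C <- X %*% ef$vectors[, ord, drop = FALSE]
    list(C = C, eps = ef$values[ord],
         D = 2 * C[, seq_len(nocc), drop = FALSE] %*% t(C[, seq_len(nocc), drop = FALSE]))
  }

  sol <- dens_of(hcore)
  D <- sol$D
  e_old <- Inf
  err_list <- list(); fock_list <- list()
  for (it in seq_len(max_iter)) {
    F <- fock_of(D)
    e_elec <- 0.5 * sum(D * (hcore + F))
    err <- F %*% D %*% S - S %*% D %*% F
    err_n <- max(abs(err))
    if (verbose)
      message(sprintf("SCF iter %3d  E = %.12f  |err| = %.3e", it,
                      e_elec + enuc, err_n))
    if (err_n < conv_tol && abs(e_elec - e_old) < conv_tol) break
    e_old <- e_elec
    # DIIS
    err_list[[length(err_list) + 1L]] <- err
    fock_list[[length(fock_list) + 1L]] <- F
    if (length(err_list) > 8) { err_list <- err_list[-1]; fock_list <- fock_list[-1] }
    m <- length(err_list)
    if (m >= 2) {
      B <- matrix(-1, m + 1, m + 1); B[m + 1, m + 1] <- 0
      for (i in 1:m) for (j in 1:m)
        B[i, j] <- sum(err_list[[i]] * err_list[[j]])
      rhs <- c(rep(0, m), -1)
      cw <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cw)) {
        F <- Reduce(`+`, Map(`*`, fock_list, cw))
      }
    }
    sol <- dens_of(F)
    D <- sol$D
  }
  if (err_n >= conv_tol * 100)
    stop("SCF failed to converge after ", max_iter, " iterations")
  F <- fock_of(D)
  e_elec <- 0.5 * sum(D * (hcore + F))
  list(C = sol$C, eps = sol$eps, D = D, S = S, hcore = hcore, fock = F,
       g_ao = g_ao, energy = e_elec + enuc, e_electronic = e_elec,
       e_nuclear = enuc, n_occ = nocc, nbf = n, mol = mol)
}

#' Molecular-orbital integrals for a molecular system
#'
#' Runs RHF and transforms the one- and two-electron integrals to the MO
#' basis; an optional active space folds the inactive (frozen-core) orbitals
#' into the effective one-body term and the core energy.
#'
#' @param mol a \code{\link{molecular_system}}; its \code{active_space}
#'   (\code{c(n_elec, n_orb)}) is honoured when present
#' @param scf optional precomputed result of \code{\link{scf_rhf}}
#' @return an object of class \code{integral_set}: \code{h} (one-electron MO
#'   integrals), \code{g} (two-electron MO integrals, chemists' (pq|rs)),
#'   \code{core_energy}, \code{n_orb}, \code{n_elec}, \code{e_hf}
#' @export
compute_integrals <- function(mol, scf = NULL) {
  if (is.null(scf)) scf <- scf_rhf(mol)
  C <- scf$C
  h_mo <- t(C) %*% scf$hcore %*% C
  g_mo <- cpp_ao2mo(as.numeric(scf$g_ao), C)
  n <- ncol(C)
  dim(g_mo) <- c(n, n, n, n)
  g_mo <- aperm(g_mo, c(4, 3, 2, 1))
  core <- scf$e_nuclear
  orbs <- seq_len(n)
  n_elec <- mol$n_electrons
  if (!is.null(mol$active_space)) {
    n_act_e <- mol$active_space[1]
    n_act_o <- mol$active_space[2]
    n_froz <- (mol$n_electrons - n_act_e) %/% 2L
    if (n_froz < 0 || n_froz + n_act_o > n)
      stop("active space incompatible with orbital count")
    act <- seq(n_froz + 1L, n_froz + n_act_o)
    froz <- seq_len(n_froz)
    if (n_froz > 0) {
      for (i in froz)
        core <- core + 2 * h_mo[i, i] +
          sum(vapply(froz, function(j) 2 * g_mo[i, i, j, j] - g_mo[i, j, j, i],
                     numeric(1)))
      heff <- h_mo[act, act, drop = FALSE]
      for (i in froz)
        heff <- heff + 2 * g_mo[act, act, i, i] - g_mo[act, i, i, act]
      h_mo <- heff
    } else {
      h_mo <- h_mo[act, act, drop = FALSE]
    }
    g_mo <- g_mo[act, act, act, act, drop = FALSE]
    n <- n_act_o
    n_elec <- n_act_e
  }
  structure(list(h = (h_mo + t(h_mo)) / 2, g = g_mo, core_energy = core,
                 n_orb = as.integer(n), n_elec = as.integer(n_elec),
                 e_hf = scf$energy, mo_energies = scf$eps, scf = scf),
            class = "integral_set")
}

#' Integrals in the symmetrically orthogonalized (local) orbital basis
#'
#' Expresses the one- and two-electron integrals over Loewdin-orthogonalized
#' atomic orbitals instead of canonical MOs. This local representation is
#' the one used by the embedding (DMET) machinery and by the
#' measurement-circuit counting convention for hydrogen chains.
#'
#' @param mol a \code{\link{molecular_system}}
#' @param scf optional precomputed \code{\link{scf_rhf}} result
#' @return an \code{integral_set} over local orbitals
#' @export
local_integrals <- function(mol, scf = NULL) {
  if (is.null(scf)) scf <- scf_rhf(mol)
  es <- eigen(scf$S, symmetric = TRUE)
  X <- es$vectors %*% ((1 / sqrt(es$values)) * t(es$vectors))
  h_loc <- t(X) %*% scf$hcore %*% X
  g_loc <- cpp_ao2mo(as.numeric(scf$g_ao), X)
  n <- scf$nbf
  dim(g_loc) <- rep(n, 4)
  structure(list(h = (h_loc + t(h_loc)) / 2, g = g_loc,
                 core_energy = scf$e_nuclear, n_orb = as.integer(n),
                 n_elec = mol$n_electrons, e_hf = scf$energy, scf = scf),
            class = "integral_set")
}

#' @export
print.integral_set <- function(x, ...) {
  cat(sprintf("<integral_set> %d spatial orbitals, %d electrons, core %.8f Ha, HF %.8f Ha\n",
              x$n_orb, x$n_elec, x$core_energy, x$e_hf))
  invisible(x)
}
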