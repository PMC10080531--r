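# Density matrix embedding theory: localized orbitals, Schmidt bath
# construction, embedding Hamiltonians, fragment energies, and the
# chemical-potential self-consistency cycle.
#
# Localization uses Loewdin symmetric orthogonalization of the AOs; the bath
# comes from the SVD of the occupied-orbital overlap between fragment and
# environment (at most one bath orbital per fragment orbital); the one-shot
# cycle fits a single global chemical potential so the summed fragment
# electron numbers match the molecule.

#' Mean-field one-particle density matrix in the localized orbital basis
#'
#' Runs RHF and returns the spin-summed 1-RDM over Loewdin-orthogonalized
#' atomic orbitals (idempotent up to the factor 2: D^2 = 2D).
#'
#' @param mol a \code{\link{molecular_system}} (or a precomputed
#'   \code{\link{scf_rhf}} result)
#' @return list with \code{rdm} (n x n), \code{C_occ_loc} (occupied orbitals
#'   in the localized basis), \code{h} and \code{g} (integrals in the
#'   localized basis), \code{scf}
#' @export
mean_field_rdm <- function(mol) {
  scf <- if (inherits(mol, "molecular_system")) scf_rhf(mol) else mol
  es <- eigen(scf$S, symmetric = TRUE)
  Shalf <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  C_loc <- Shalf %*% scf$C                 # orthonormal columns
  n <- scf$nbf
  occ <- seq_len(scf$n_occ)
  Cocc <- C_loc[, occ, drop = FALSE]
  D <- 2 * Cocc %*% t(Cocc)
  X <- es$vectors %*% ((1 / sqrt(es$values)) * t(es$vectors))
  h_loc <- t(X) %*% scf$hcore %*% X
  g_loc <- cpp_ao2mo(as.numeric(scf$g_ao), X)
  dim(g_loc) <- rep(n, 4)
  list(rdm = D, C_occ_loc = Cocc, h = (h_loc + t(h_loc)) / 2, g = g_loc,
       scf = scf)
}

#' Build a DMET embedding problem for one fragment
#'
#' Schmidt bath construction: the SVD of the fragment block of the occupied
#' orbitals yields entangled occupied orbitals; their (normalized)
#' environment tails are the bath orbitals (singular values > bath_tol).
#' The remaining fully-environment orbitals form the frozen environment,
#' whose density is folded into the embedding one-body term as the
#' closed-shell Coulomb-exchange potential. A chemical potential mu is
#' subtracted on the fragment-orbital diagonal.
#'
#' @param mf result of \code{\link{mean_field_rdm}}
#' @param frag 1-based indices of the fragment's localized orbitals
#' @param mu global chemical potential (Hartree)
#' @param bath_tol Schmidt singular-value threshold for keeping a bath
#'   orbital
#' @return object of class \code{embedding_problem}
#' @export
build_embedding <- function(mf, frag, mu = 0, bath_tol = 1e-6) {
  n <- nrow(mf$rdm)
  frag <- sort(as.integer(frag))
  stopifnot(length(frag) >= 1, all(frag >= 1 & frag <= n))
  env <- setdiff(seq_len(n), frag)
  Cocc <- mf$C_occ_loc
  nocc <- ncol(Cocc)
  Ffrag <- Cocc[frag, , drop = FALSE]
  sv <- svd(Ffrag, nu = nrow(Ffrag), nv = nocc)
  s <- sv$d
  ent <- which(s > bath_tol)
  # rotated occupied orbitals with fragment weight
  Phi <- Cocc %*% sv$v
  bath <- matrix(0, n, 0)
  for (k in ent) {
    tail_norm2 <- 1 - s[k]^2
    if (tail_norm2 > 1e-12) {
      b <- Phi[, k]
      b[frag] <- 0
      bath <- cbind(bath, b / sqrt(sum(b^2)))
    }
  }
  nb <- ncol(bath)
  # frozen environment density: occupied minus entangled part
  P <- mf$rdm / 2
  Pent <- Phi[, ent, drop = FALSE] %*% t(Phi[, ent, drop = FALSE])
  Denv <- 2 * (P - Pent)
  n_emb_elec <- round(sum(diag(mf$rdm)) - sum(diag(Denv)))
  # embedding orbitals: fragment identity columns + bath
  E <- matrix(0, n, length(frag) + nb)
  for (k in seq_along(frag)) E[frag[k], k] <- 1
  if (nb > 0) E[, length(frag) + seq_len(nb)] <- bath
  # fold environment density into the one-body term (closed-shell J - K/2)
  G2 <- matrix(mf$g, n * n, n * n)
  J <- matrix(G2 %*% as.vector(Denv), n, n)
  Gk <- matrix(aperm(mf$g, c(1, 3, 2, 4)), n * n, n * n)
  K <- matrix(Gk %*% as.vector(Denv), n, n)
  venv <- J - 0.5 * K
  h_emb <- t(E) %*% (mf$h + venv) %*% E
  h_bare <- t(E) %*% mf$h %*% E
  nemb <- ncol(E)
  g_emb <- cpp_ao2mo(as.numeric(mf$g), E)
  dim(g_emb) <- rep(nemb, 4)
  hmu <- h_emb
  for (k in seq_along(frag)) hmu[k, k] <- hmu[k, k] - mu
  structure(list(
    h = (hmu + t(hmu)) / 2, h_no_mu = (h_emb + t(h_emb)) / 2,
    h_bare = (h_bare + t(h_bare)) / 2, g = g_emb,
    n_frag = length(frag), n_bath = nb, n_orb = nemb,
    n_elec = as.integer(n_emb_elec), frag = frag, mu = mu,
    env_rdm = Denv, orbitals = E, schmidt_sv = s),
    class = "embedding_problem")
}

#' @export
print.embedding_problem <- function(x, ...) {
  cat(sprintf("<embedding_problem> %d fragment + %d bath orbitals, %d electrons, mu = %.6f\n",
              x$n_frag, x$n_bath, x$n_elec, x$mu))
  invisible(x)
}

# closed-shell RHF within an orthonormal orbital space (no overlap matrix);
# returns the MO coefficient matrix, occupied columns first (ascending
# orbital energy)
emb_rhf_orbitals <- function(h, g, n_elec, max_iter = 100, tol = 1e-10) {
  n <- nrow(h)
  nocc <- n_elec %/% 2L
  Gj <- matrix(g, n * n, n * n)
  Gk <- matrix(aperm(array(g, rep(n, 4)), c(1, 3, 2, 4)), n * n, n * n)
  dens <- function(F) {
    ef <- eigen((F + t(F)) / 2, symmetric = TRUE)
    ord <- order(ef$values)
    C <- ef$vectors[, ord, drop = FALSE]
    list(C = C, D = 2 * C[, seq_len(max(nocc, 0)), drop = FALSE] %*%
           t(C[, seq_len(max(nocc, 0)), drop = FALSE]))
  }
  if (nocc == 0L) return(dens(h)$C)
  s <- dens(h)
  for (it in seq_len(max_iter)) {
    J <- matrix(Gj %*% as.vector(s$D), n, n)
    K <- matrix(Gk %*% as.vector(s$D), n, n)
    F <- h + J - 0.5 * K
    s2 <- dens(F)
    if (max(abs(s2$D - s$D)) < tol) { s <- s2; break }
    s <- s2
  }
  s$C
}

# integral_set view of an embedding problem (core energy excluded on purpose:
# fragment energies are assembled from Eq-style contractions, not from a
# total-energy eigenvalue)
embedding_integrals <- function(emb) {
  structure(list(h = emb$h, g = emb$g, core_energy = 0,
                 n_orb = emb$n_orb, n_elec = emb$n_elec, e_hf = NA_real_),
            class = "integral_set")
}

#' Solve an embedding problem with an FCI or MPS-VQE fragment solver
#'
#' Finds the embedded ground state, measures the spatial 1- and 2-RDMs from
#' the solved state (Jordan-Wigner ladder expectations), and assembles the
#' fragment energy: the environment-folded one-body term enters with weight
#' 1/2 and the sums over the second index run over the embedding space while
#' the first index is restricted to fragment orbitals.
#'
#' @param emb an \code{\link{embedding_problem}}
#' @param solver "fci" (dense exact ground state) or "mps_vqe" (UCCSD
#'   MPS-VQE)
#' @param cfg \code{\link{vqe_config}} for the MPS-VQE solver
#' @return object of class \code{fragment_solution}: \code{rdm1},
#'   \code{rdm2}, \code{fragment_energy}, \code{n_elec_fragment},
#'   \code{energy_embedded}
#' @export
solve_fragment <- function(emb, solver = c("fci", "mps_vqe"),
                           cfg = vqe_config()) {
  solver <- match.arg(solver)
  n <- emb$n_orb
  if (solver == "fci") {
    ham <- build_qubit_hamiltonian(embedding_integrals(emb))
    gs <- cpp_pauli_ground_state(ham$ops, ham$coefs, ham$offset)
    state <- as.vector(gs$vector)
    e_emb <- gs$value
    rdm1 <- measure_rdm1(state, n)
    rdm2 <- measure_rdm2(state, n)
  } else {
    # canonicalize within the embedding space so the UCCSD reference is the
    # embedded mean-field determinant, then rotate the RDMs back
    C <- emb_rhf_orbitals(emb$h, emb$g, emb$n_elec)
    g_mo <- cpp_ao2mo(as.numeric(emb$g), C)
    dim(g_mo) <- rep(n, 4)
    ints_mo <- structure(list(h = t(C) %*% emb$h %*% C, g = g_mo,
                              core_energy = 0, n_orb = n,
                              n_elec = emb$n_elec, e_hf = NA_real_),
                         class = "integral_set")
    ham <- build_qubit_hamiltonian(ints_mo)
    circ <- uccsd_circuit(ham, screen_ints = ints_mo)
    fit <- optimize_vqe(ham, circ, cfg)
    r <- evaluate_energy(ham, circ, fit$theta, cfg, detail = TRUE)
    state <- r$state
    e_emb <- fit$energy
    d_mo <- measure_rdm1(state, n)
    g2_mo <- measure_rdm2(state, n)
    rdm1 <- C %*% d_mo %*% t(C)
    rdm2 <- cpp_ao2mo(as.numeric(g2_mo), t(C))
    dim(rdm2) <- rep(n, 4)
  }
  # fragment energy: restrict the first index to fragment orbitals; the
  # environment-folded potential (h_no_mu - h_bare) enters with weight 1/2
  hmix <- emb$h_bare + 0.5 * (emb$h_no_mu - emb$h_bare)
  fa <- seq_len(emb$n_frag)
  e1 <- sum(hmix[fa, , drop = FALSE] * rdm1[fa, , drop = FALSE])
  e2 <- 0
  for (p in fa) e2 <- e2 + 0.5 * sum(emb$g[p, , , ] * rdm2[p, , , ])
  na <- sum(diag(rdm1)[fa])
  structure(list(rdm1 = rdm1, rdm2 = rdm2, fragment_energy = e1 + e2,
                 n_elec_fragment = na, energy_embedded = e_emb,
                 solver = solver),
            class = "fragment_solution")
}

#' @export
print.fragment_solution <- function(x, ...) {
  cat(sprintf("<fragment_solution> E_A = %.8f Ha, N_A = %.6f (%s)\n",
              x$fragment_energy, x$n_elec_fragment, x$solver))
  invisible(x)
}

#' One-shot DMET cycle with chemical-potential fitting
#'
#' Partitions the localized orbitals into fragments, solves each embedding
#' problem at a global chemical potential mu, and root-finds mu so the
#' summed fragment electron numbers match the molecule
#' (\eqn{|N^{DMET} - N| < tol_elec}); the total energy is the sum of
#' fragment energies plus nuclear repulsion.
#'
#' @param mol a \code{\link{molecular_system}}
#' @param fragments list of 1-based localized-orbital index vectors
#'   (disjoint, covering all orbitals)
#' @param solver "fci" or "mps_vqe"
#' @param cfg \code{\link{vqe_config}} for the MPS-VQE solver
#' @param tol_elec electron-number convergence tolerance
#' @param mu_bracket initial symmetric bracket for the chemical potential
#' @return list with \code{energy} (total, Hartree), \code{mu},
#'   \code{n_elec_total}, per-fragment table, and the solutions
#' @export
dmet_cycle <- function(mol, fragments, solver = c("fci", "mps_vqe"),
                       cfg = vqe_config(), tol_elec = 1e-5,
                       mu_bracket = 0.5) {
  solver <- match.arg(solver)
  mf <- mean_field_rdm(mol)
  n <- nrow(mf$rdm)
  allidx <- sort(unlist(fragments))
  if (length(allidx) != n || any(allidx != seq_len(n)))
    stop("fragments must be disjoint and cover all localized orbitals")
  ntot <- mol$n_electrons
  solve_all <- function(mu) {
    lapply(fragments, function(fr)
      solve_fragment(build_embedding(mf, fr, mu = mu), solver, cfg))
  }
  nfun <- function(mu) {
    sols <- solve_all(mu)
    sum(vapply(sols, function(s) s$n_elec_fragment, numeric(1))) - ntot
  }
  f0 <- nfun(0)
  if (abs(f0) < tol_elec) {
    mu_star <- 0
  } else {
    lo <- -mu_bracket; hi <- mu_bracket
    flo <- nfun(lo); fhi <- nfun(hi)
    tries <- 0
    while (flo * fhi > 0 && tries < 4) {
      lo <- 2 * lo; hi <- 2 * hi
      flo <- nfun(lo); fhi <- nfun(hi)
      tries <- tries + 1
    }
    if (flo * fhi > 0)
      stop(sprintf(
        "chemical-potential bracket failure: N(%g)-N = %.3e, N(%g)-N = %.3e",
        lo, flo, hi, fhi))
    if (flo > fhi)
      warning("electron count not monotone non-decreasing in mu over the bracket")
    mu_star <- stats::uniroot(nfun, c(lo, hi), tol = 1e-10)$root
  }
  sols <- solve_all(mu_star)
  eA <- vapply(sols, function(s) s$fragment_energy, numeric(1))
  nA <- vapply(sols, function(s) s$n_elec_fragment, numeric(1))
  list(energy = sum(eA) + nuclear_repulsion(mol), mu = mu_star,
       n_elec_total = sum(nA),
       fragments = data.frame(fragment = seq_along(fragments),
                              n_orb = lengths(fragments),
                              E_A = eA, N_A = nA),
       solutions = sols)
}

#' Atom-to-fragment orbital mapping helper
#'
#' Maps per-atom fragment labels to localized-orbital index sets using the
#' AO shell structure (Loewdin orbitals inherit the AO-to-atom assignment).
#'
#' @param mol a \code{\link{molecular_system}}
#' @param atom_labels vector of fragment labels, one per atom (or a path to
#'   a JSON file mapping atom indices to labels)
#' @return list of orbital index vectors, one per distinct label
#' @export
atom_fragments <- function(mol, atom_labels) {
  if (is.character(atom_labels) && length(atom_labels) == 1 &&
      file.exists(atom_labels)) {
    m <- jsonlite::read_json(atom_labels, simplifyVector = TRUE)
    atom_labels <- m[order(as.integer(names(m)))]
  }
  stopifnot(length(atom_labels) == length(mol$symbols))
  shells <- basis_shells(mol$symbols, mol$coords / .bohr, mol$basis)
  # count basis functions per atom
  ncart <- c(1L, 3L, 6L)
  per_shell_atom <- integer(0)
  k <- 0
  for (i in seq_along(mol$symbols)) {
    key <- tolower(mol$basis)
    for (sh in .basis_library[[key]][[mol$symbols[i]]])
      per_shell_atom <- c(per_shell_atom, rep(i, ncart[sh$l + 1L]))
  }
  lab <- unique(atom_labels)
  lapply(lab, function(l) which(per_shell_atom %in% which(atom_labels == l)))
}
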