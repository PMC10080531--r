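# Determinant-space full configuration interaction (Slater-Condon rules).
# Independent of the Jordan-Wigner/qubit code path; serves as the exact
# diagonalization oracle and cross-check for fci_energy().

# all nocc-bit masks over norb orbitals (integer bit masks, norb <= 30)
.occ_masks <- function(norb, nocc) {
  if (nocc == 0L) return(0L)
  combos <- utils::combn(norb, nocc)
  as.integer(colSums(matrix(bitwShiftL(1L, combos - 1L), nrow = nocc)))
}

.bits_of <- function(mask, norb) which(bitwAnd(mask, bitwShiftL(1L, 0:(norb - 1L))) != 0L)

# parity (+1/-1) of electrons between positions (exclusive) in mask
.parity_between <- function(mask, i, a) {
  lo <- min(i, a); hi <- max(i, a)
  if (hi - lo < 2L) return(1L)
  between <- bitwAnd(mask, bitwShiftL(1L, (lo):(hi - 2L)))
  n <- sum(bitwAnd(bitwShiftR(mask, lo:(hi - 2L)), 1L))
  if (n %% 2L == 0L) 1L else -1L
}

#' Determinant-based FCI energy (independent exact-diagonalization oracle)
#'
#' Builds the Hamiltonian in the basis of Slater determinants with fixed
#' (n_alpha, n_beta) and returns the lowest eigenvalue. Independent of the
#' Jordan-Wigner qubit route.
#'
#' @param ints an \code{\link{integral_set}}
#' @return ground-state total energy in Hartree
#' @export
fci_energy_determinant <- function(ints) {
  n <- ints$n_orb
  na <- ints$n_elec %/% 2L
  nb <- ints$n_elec - na
  h <- ints$h; g <- ints$g
  amasks <- .occ_masks(n, na)
  bmasks <- .occ_masks(n, nb)
  dets <- expand.grid(a = amasks, b = bmasks)
  nd <- nrow(dets)
  if (nd > 4000) stop("determinant space too large for the dense oracle")
  H <- matrix(0, nd, nd)
  occs_a <- lapply(dets$a, .bits_of, norb = n)
  occs_b <- lapply(dets$b, .bits_of, norb = n)
  one_plus_mf <- function(i, a, occ_same, occ_other) {
    # <i|h|a> + same-spin (J - K) + opposite-spin J over occupied orbitals
    v <- h[i, a]
    for (j in occ_same) v <- v + g[i, a, j, j] - g[i, j, j, a]
    for (j in occ_other) v <- v + g[i, a, j, j]
    v
  }
  for (I in seq_len(nd)) {
    oa <- occs_a[[I]]; ob <- occs_b[[I]]
    # diagonal
    e <- sum(h[cbind(oa, oa)]) + sum(h[cbind(ob, ob)])
    for (i in oa) for (j in oa) e <- e + 0.5 * (g[i, i, j, j] - g[i, j, j, i])
    for (i in ob) for (j in ob) e <- e + 0.5 * (g[i, i, j, j] - g[i, j, j, i])
    for (i in oa) for (j in ob) e <- e + g[i, i, j, j]
    H[I, I] <- e
    for (J in seq_len(nd)) {
      if (J == I) next
      da <- bitwXor(dets$a[I], dets$a[J])
      db <- bitwXor(dets$b[I], dets$b[J])
      nda <- sum(bitwAnd(bitwShiftR(da, 0:(n - 1L)), 1L))
      ndb <- sum(bitwAnd(bitwShiftR(db, 0:(n - 1L)), 1L))
      if (nda + ndb > 4L) next
      if (nda == 2L && ndb == 0L) {
        i <- .bits_of(bitwAnd(da, dets$a[I]), n)
        a <- .bits_of(bitwAnd(da, dets$a[J]), n)
        sgn <- .parity_between(dets$a[I], i, a)
        H[I, J] <- sgn * one_plus_mf(i, a, setdiff(occs_a[[I]], i), ob)
      } else if (nda == 0L && ndb == 2L) {
        i <- .bits_of(bitwAnd(db, dets$b[I]), n)
        a <- .bits_of(bitwAnd(db, dets$b[J]), n)
        sgn <- .parity_between(dets$b[I], i, a)
        H[I, J] <- sgn * one_plus_mf(i, a, setdiff(occs_b[[I]], i), oa)
      } else if (nda == 4L && ndb == 0L) {
        ij <- sort(.bits_of(bitwAnd(da, dets$a[I]), n))
        ab <- sort(.bits_of(bitwAnd(da, dets$a[J]), n))
        s1 <- .parity_between(dets$a[I], ij[1], ab[1])
        m2 <- bitwXor(dets$a[I], bitwOr(bitwShiftL(1L, ij[1] - 1L),
                                        bitwShiftL(1L, ab[1] - 1L)))
        s2 <- .parity_between(m2, ij[2], ab[2])
        H[I, J] <- s1 * s2 * (g[ij[1], ab[1], ij[2], ab[2]] -
                              g[ij[1], ab[2], ij[2], ab[1]])
      } else if (nda == 0L && ndb == 4L) {
        ij <- sort(.bits_of(bitwAnd(db, dets$b[I]), n))
        ab <- sort(.bits_of(bitwAnd(db, dets$b[J]), n))
        s1 <- .parity_between(dets$b[I], ij[1], ab[1])
        m2 <- bitwXor(dets$b[I], bitwOr(bitwShiftL(1L, ij[1] - 1L),
                                        bitwShiftL(1L, ab[1] - 1L)))
        s2 <- .parity_between(m2, ij[2], ab[2])
        H[I, J] <- s1 * s2 * (g[ij[1], ab[1], ij[2], ab[2]] -
                              g[ij[1], ab[2], ij[2], ab[1]])
      } else if (nda == 2L && ndb == 2L) {
        i <- .bits_of(bitwAnd(da, dets$a[I]), n)
        a <- .bits_of(bitwAnd(da, dets$a[J]), n)
        j <- .bits_of(bitwAnd(db, dets$b[I]), n)
        b <- .bits_of(bitwAnd(db, dets$b[J]), n)
        sgn <- .parity_between(dets$a[I], i, a) *
               .parity_between(dets$b[I], j, b)
        H[I, J] <- sgn * g[i, a, j, b]
      }
    }
  }
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) + ints$core_energy
}
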