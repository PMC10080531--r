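# Integrals, Hartree-Fock, Jordan-Wigner Hamiltonians, term counting, FCI.

test_that("H2/STO-3G integrals and mean field match the textbook values", {
  ints <- h2_ints()
  expect_equal(ints$n_orb, 2L)
  expect_equal(ints$n_elec, 2L)
  # restricted HF energy at R = 0.7414 Angstrom
  expect_equal(ints$e_hf, -1.116684, tolerance = 2e-6)
  # h is Hermitian, g has the 8-fold permutation symmetry
  expect_equal(ints$h, t(ints$h), tolerance = 1e-12)
  g <- ints$g
  expect_equal(g, aperm(g, c(2, 1, 3, 4)), tolerance = 1e-12)
  expect_equal(g, aperm(g, c(3, 4, 1, 2)), tolerance = 1e-12)
})

test_that("active spaces fold frozen orbitals into h and the core energy", {
  mol <- h2_molecule(0.7414, basis = "cc-pvdz")
  full <- compute_integrals(mol)
  expect_equal(full$core_energy, nuclear_repulsion(mol), tolerance = 1e-12)

  mol_as <- h2_molecule(0.7414, basis = "cc-pvdz", active_space = c(2, 4))
  red <- compute_integrals(mol_as)
  expect_equal(red$n_orb, 4L)
  # no frozen orbitals for 2 electrons: core energy stays nuclear only
  expect_equal(red$core_energy, nuclear_repulsion(mol), tolerance = 1e-12)

  # a genuinely frozen core: H4 chain with a (2e,2o) active space
  m4 <- h_chain(4); m4$active_space <- c(2L, 2L)
  r4 <- compute_integrals(m4)
  expect_equal(r4$n_orb, 2L)
  # frozen-core folding moves the constant away from bare nuclear repulsion
  expect_gt(abs(r4$core_energy - nuclear_repulsion(m4)), 0.1)
  # FCI in the reduced space stays variational wrt HF
  expect_lt(fci_energy_determinant(r4), compute_integrals(m4)$e_hf + 1e-10)
})

test_that("ethane (6e,6o)/6-31G(d) maps to 12 qubits", {
  mol <- ethane(60, basis = "6-31g(d)", active_space = c(6, 6))
  scf <- fixture("ethane_stag_scf", function() scf_rhf(mol))
  ints <- fixture("ethane_stag_ints", function() compute_integrals(mol, scf = scf))
  expect_equal(ints$n_orb, 6L)
  ham <- fixture("ethane_stag_ham", function() build_qubit_hamiltonian(ints))
  expect_equal(ham$n_qubits, 12L)
})

test_that("Jordan-Wigner of a single spin orbital gives (eps/2)(I - Z)", {
  eps <- 0.37
  ints <- structure(list(h = matrix(eps, 1, 1) * diag(1),
                         g = array(0, dim = rep(1, 4)),
                         core_energy = 0, n_orb = 1L, n_elec = 0L),
                    class = "integral_set")
  ham <- build_qubit_hamiltonian(ints)
  # both spin orbitals carry eps: offset = eps, terms -eps/2 Z0, -eps/2 Z1
  expect_equal(ham$offset, eps, tolerance = 1e-14)
  expect_equal(sort(ham$coefs), rep(-eps / 2, 2), tolerance = 1e-14)
})

test_that("the H2 Hamiltonian has 14 terms and its ground state is FCI", {
  ham <- h2_ham()
  expect_equal(count_measurement_circuits(ham), 14L)
  expect_equal(max(abs(Im(ham$coefs))), 0)
  hm <- hamiltonian_matrix(ham)
  expect_lt(max(abs(hm - Conj(t(hm)))), 1e-12)
  evals <- eigen(hm, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(evals), fci_energy(ham), tolerance = 1e-10)
  # independent determinant-CI oracle
  expect_equal(fci_energy(ham), fci_energy_determinant(h2_ints()),
               tolerance = 1e-9)
  # variational principle
  expect_lt(fci_energy(ham), h2_ints()$e_hf)
})

test_that("the dense Hamiltonian commutes with total particle number", {
  ham <- h2_ham()
  hm <- hamiltonian_matrix(ham)
  # JW number operator sum_j (I - Z_j)/2
  nq <- ham$n_qubits
  nops <- do.call(rbind, lapply(seq_len(nq) - 1L, function(q) {
    v <- integer(nq); v[q + 1] <- 3L; v
  }))
  nmat <- hamiltonian_matrix(qubit_hamiltonian(nops, rep(-0.5, nq),
                                               offset = nq / 2))
  expect_lt(max(abs(hm %*% nmat - nmat %*% hm)), 1e-10)
})

test_that("ground energy is stable under cutoff and term order", {
  ints <- h2_ints()
  e0 <- fci_energy(build_qubit_hamiltonian(ints, cutoff = 0))
  e1 <- fci_energy(build_qubit_hamiltonian(ints, cutoff = 1e-12))
  expect_equal(e0, e1, tolerance = 1e-10)
  ham <- h2_ham()
  perm <- rev(seq_len(nrow(ham$ops)))
  hamr <- qubit_hamiltonian(ham$ops[perm, ], ham$coefs[perm], ham$offset)
  expect_equal(fci_energy(hamr), fci_energy(ham), tolerance = 1e-10)
})

test_that("Hamiltonian text and JSON round-trips preserve the operator", {
  ham <- h2_ham()
  f <- tempfile(fileext = ".txt")
  write_hamiltonian(ham, f)
  ham2 <- read_hamiltonian(f, ham$n_qubits)
  expect_equal(ham2$offset, ham$offset, tolerance = 1e-14)
  m1 <- hamiltonian_matrix(ham); m2 <- hamiltonian_matrix(ham2)
  expect_lt(max(abs(m1 - m2)), 1e-12)
  unlink(f)
  fj <- tempfile(fileext = ".json")
  write_hamiltonian(ham, fj, format = "json")
  expect_true(jsonlite::validate(paste(readLines(fj), collapse = "")))
  unlink(fj)
})

test_that("chain term counts grow monotonically and superlinearly", {
  counts <- fixture("chain_counts_small", function() {
    term_count_scaling(c(4, 6, 8), cutoff = 3e-8)
  })
  expect_true(all(diff(counts$counts$n_terms) > 0))
  expect_gt(counts$exponent, 1)
  expect_false(counts$low_confidence)
  # two sizes only: exact two-point slope, flagged low-confidence
  two <- term_count_scaling(c(4, 6), cutoff = 3e-8)
  expect_true(two$low_confidence)
  slope <- with(two$counts, diff(log(n_terms)) / diff(log(n_atoms)))
  expect_equal(two$exponent, slope, tolerance = 1e-12)
})
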