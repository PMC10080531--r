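# Right-canonical MPS engine: product states, gates, expectations,
# truncation bookkeeping, dense-oracle equivalence.

test_that("product states have one-hot amplitudes and are right-canonical", {
  st <- init_product_state("1100")
  v <- to_dense(st)
  expect_equal(which(v != 0), strtoi("1100", base = 2) + 1L)
  expect_equal(v[strtoi("1100", base = 2) + 1L], 1 + 0i)
  expect_lt(max(canonical_defect(st)), 1e-12)

  st0 <- init_product_state("00")
  expect_equal(expectation_pauli(st0, "Z0"), 1)
  expect_equal(expectation_pauli(st0, "Z1"), 1)
  expect_error(init_product_state(""), "nzchar|>= 1")
})

test_that("single-qubit gates act exactly and preserve canonical form", {
  H <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
  X <- matrix(c(0, 1, 1, 0), 2, 2)
  st <- apply_1q(init_product_state("0"), 0, X)
  expect_equal(to_dense(st), c(0i, 1 + 0i))
  st <- apply_1q(init_product_state("0"), 0, H)
  expect_equal(expectation_pauli(st, "X0"), 1, tolerance = 1e-14)
  expect_equal(expectation_pauli(st, "Z0"), 0, tolerance = 1e-14)
  expect_error(apply_1q(init_product_state("0"), 3, X), "range")
  expect_error(apply_1q(init_product_state("0"), 0, matrix(c(1, 0, 0, 2), 2)),
               "unitary")

  # random unitary on a random 8-qubit state vs the full-space embedding
  set.seed(21)
  circ <- random_circuit(8, 30, seed = 77, p_long = 0)
  st <- apply_circuit(init_product_state(strrep("0", 8), max_bond = 64), circ)
  u <- haar_unitary(2)
  q <- 3L
  st2 <- apply_1q(st, q, u)
  v2 <- dense_statevector(circuit(c(circ$gates, list(gate_u(q, u))), 8))
  expect_lt(max(abs(to_dense(st2) - v2)), 1e-12)
})

test_that("two-qubit gates reproduce Bell correlations and the Schmidt spectrum", {
  H <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
  cn <- gate_matrix(gate_cnot(0, 1))
  st <- apply_2q(apply_1q(init_product_state("00"), 0, H), 0, cn)
  expect_equal(to_dense(st), c(1, 0, 0, 1) / sqrt(2) + 0i, tolerance = 1e-14)
  expect_equal(bond_spectra(st)[[1]], rep(1 / sqrt(2), 2), tolerance = 1e-14)
  expect_equal(expectation_pauli(st, "X0 X1"), 1, tolerance = 1e-13)
  expect_equal(expectation_pauli(st, "Y0 Y1"), -1, tolerance = 1e-13)
  expect_equal(expectation_pauli(st, "Z0 Z1"), 1, tolerance = 1e-13)
  expect_equal(expectation_pauli(st, "Z0"), 0, tolerance = 1e-13)

  # CNOT flips the target for a definite control
  st <- apply_2q(init_product_state("10"), 0, cn)
  expect_equal(to_dense(st), c(0, 0, 0, 1) + 0i)
})

test_that("100 random adjacent two-qubit unitaries match the dense oracle", {
  set.seed(4)
  gates <- lapply(1:100, function(k) {
    a <- sample.int(9, 1) - 1L
    gate_u(c(a, a + 1L), haar_unitary(4))
  })
  circ <- circuit(gates, 10)
  st <- apply_circuit(init_product_state(strrep("0", 10), max_bond = 32), circ)
  v <- dense_statevector(circ)
  expect_lt(max(abs(to_dense(st) - v)), 1e-10)
  expect_lt(max(canonical_defect(st)), 1e-10)
  expect_equal(sum(Mod(to_dense(st))^2), 1, tolerance = 1e-10)
})

test_that("canonical form holds after every gate of a long random circuit", {
  circ <- compile_adjacent(random_circuit(6, 300, seed = 15))
  st <- init_product_state(strrep("0", 6), max_bond = 32)
  worst <- 0
  for (g in circ$gates) {
    mats <- circuit_matrices(circuit(list(g), 6), NULL)
    st <- cpp_mps_apply_gates(st, mats$qubits, mats$mats)
    worst <- max(worst, max(canonical_defect(st)))
  }
  expect_lt(worst, 1e-10)
})

test_that("Pauli expectations match the dense oracle on random states", {
  set.seed(9)
  circ <- compile_adjacent(random_circuit(9, 60, seed = 31))
  st <- apply_circuit(init_product_state(strrep("0", 9), max_bond = 64), circ)
  v <- dense_statevector(random_circuit(9, 60, seed = 31))
  for (k in 1:200) {
    ops <- sample(0:3, 9, replace = TRUE)
    if (all(ops == 0)) ops[1] <- 3
    p <- pauli_string(ops, 9)
    expect_equal(expectation_pauli(st, p), dense_expect_pauli(v, p),
                 tolerance = 1e-10)
  }
})

test_that("expectation of a Hamiltonian is partition independent and linear", {
  ham <- h2_ham()
  st <- apply_circuit(init_product_state("1100"),
                      compile_adjacent(random_circuit(4, 20, seed = 3)))
  e_all <- expectation_hamiltonian(st, ham)
  # identity Hamiltonian
  id_ham <- qubit_hamiltonian(matrix(integer(0), 0, 4), numeric(0), offset = 2)
  expect_equal(expectation_hamiltonian(st, id_ham), 2, tolerance = 1e-14)
  # chunked evaluation sums to the same energy
  idx <- split(seq_len(nrow(ham$ops)), rep(1:8, length.out = nrow(ham$ops)))
  e_chunks <- ham$offset + sum(vapply(idx, function(i) {
    expectation_hamiltonian(st, qubit_hamiltonian(ham$ops[i, , drop = FALSE],
                                                  ham$coefs[i], 0))
  }, numeric(1)))
  expect_equal(e_all, e_chunks, tolerance = 1e-12)
})

test_that("truncation renormalizes the state and discarded weight shrinks with D", {
  circ <- compile_adjacent(random_circuit(8, 120, seed = 5))
  dws <- c()
  for (D in c(4, 8, 16)) {
    st <- apply_circuit(init_product_state(strrep("0", 8), max_bond = D), circ)
    expect_equal(sum(Mod(to_dense(st))^2), 1, tolerance = 1e-12)
    dws <- c(dws, st$discarded_weight)
  }
  expect_true(all(diff(dws) <= 1e-14))
  # with D >= 2^(n/2) a random circuit is represented exactly
  stx <- apply_circuit(init_product_state(strrep("0", 8), max_bond = 16), circ)
  v <- dense_statevector(random_circuit(8, 120, seed = 5))
  expect_gt(fidelity(to_dense(stx), v), 1 - 1e-10)
})

test_that("all SVD backends produce the same evolution", {
  circ <- compile_adjacent(random_circuit(6, 50, seed = 8))
  v <- dense_statevector(random_circuit(6, 50, seed = 8))
  for (bk in c("reference", "jacobi", "cross")) {
    st <- apply_circuit(init_product_state(strrep("0", 6), max_bond = 32,
                                           backend = bk), circ)
    expect_gt(fidelity(to_dense(st), v), 1 - 1e-10)
  }
})

test_that("MPS snapshots round-trip through serialization", {
  st <- apply_circuit(init_product_state("0000", max_bond = 8),
                      compile_adjacent(random_circuit(4, 25, seed = 12)))
  f <- tempfile(fileext = ".json")
  save_mps(st, f)
  st2 <- load_mps(f)
  expect_equal(to_dense(st2), to_dense(st), tolerance = 1e-14)
  expect_equal(st2$spectra, st$spectra, tolerance = 1e-14)
  unlink(f)
})
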