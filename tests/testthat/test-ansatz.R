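# UCCSD construction, JW cluster compilation, Pauli exponentials, pools.

test_that("UCCSD enumeration matches the combinatorial counts", {
  # H2 minimal basis: 2 electrons in 4 spin orbitals
  ops <- build_uccsd(2, 4)
  kinds <- vapply(ops, `[[`, "", "kind")
  expect_equal(sum(kinds == "single"), 2L)
  expect_equal(sum(kinds == "double"), 1L)
  expect_equal(attr(ops, "n_params"), 2L)  # spin-shared singles + 1 double

  # without spin adaptation each excitation keeps its own parameter
  ops_f <- build_uccsd(2, 4, spin_adapt = FALSE)
  expect_equal(attr(ops_f, "n_params"), 3L)

  # no virtual orbitals -> empty list
  expect_equal(length(build_uccsd(2, 2)), 0L)

  # (6e, 12 spin orbitals): 9 alpha + 9 beta singles before adaptation
  ops6 <- build_uccsd(6, 12, spin_adapt = FALSE)
  expect_equal(sum(vapply(ops6, `[[`, "", "kind") == "single"), 18L)
})

test_that("JW cluster generators are antihermitian with the textbook form", {
  # single excitation on 2 qubits: adag_1 a_0 - h.c. -> (i/2)(X0 Y1 - Y0 X1)
  ops <- list(list(kind = "single", occ = 0L, virt = 1L, param_id = 1L))
  terms <- jw_cluster_to_paulis(ops, 2)
  expect_equal(length(terms), 2L)
  labs <- vapply(terms, function(t) mpsvqe:::pauli_label(t$pauli), "")
  cf <- vapply(terms, `[[`, 0, "coeff")
  expect_setequal(labs, c("X0 Y1", "Y0 X1"))
  expect_equal(sort(cf), c(-0.5, 0.5))

  # double excitation -> 8 weight-4 strings
  opsd <- list(list(kind = "double", occ = c(0L, 1L), virt = c(2L, 3L),
                    param_id = 1L))
  td <- jw_cluster_to_paulis(opsd, 4)
  expect_equal(length(td), 8L)
  expect_true(all(vapply(td, function(t) sum(t$pauli != 0), 0L) == 4L))

  # dense check: i * sum(c_k P_k) is antihermitian
  nq <- 4
  G <- matrix(0 + 0i, 2^nq, 2^nq)
  for (t in td) {
    hterm <- qubit_hamiltonian(matrix(t$pauli, 1), 1.0, 0, nq)
    G <- G + 1i * t$coeff * hamiltonian_matrix(hterm)
  }
  expect_lt(max(abs(G + Conj(t(G)))), 1e-12)
})

test_that("exp_pauli_circuit reproduces the matrix exponential", {
  # Z0: a single Rz, no CNOTs
  fr <- exp_pauli_circuit("Z0", param_id = NA, coeff = 1, n_qubits = 1,
                          angle = 0.4)
  expect_equal(count_cnots(circuit(fr, 1)), 0L)
  u <- dense_unitary(circuit(fr, 1))
  expect_lt(max(abs(u - diag(c(exp(0.4i), exp(-0.4i))))), 1e-12)

  # X0 Y1 at theta = 0.3: 2 CNOTs, against expm via eigen decomposition
  fr2 <- exp_pauli_circuit("X0 Y1", param_id = NA, coeff = 1, n_qubits = 2,
                           angle = 0.3)
  expect_equal(count_cnots(circuit(fr2, 2)), 2L)
  P <- hamiltonian_matrix(qubit_hamiltonian(matrix(c(1L, 2L), 1), 1, 0))
  ep <- eigen(P)
  expm_ref <- ep$vectors %*% diag(exp(0.3i * ep$values)) %*% Conj(t(ep$vectors))
  expect_lt(max(abs(dense_unitary(circuit(fr2, 2)) - expm_ref)), 1e-12)

  # weight-4 string: 2(w-1) = 6 CNOTs, oracle-verified with a coefficient
  fr4 <- exp_pauli_circuit("Y0 X1 X2 X3", param_id = NA, coeff = -0.25,
                           n_qubits = 4, angle = 0.7)
  expect_equal(count_cnots(circuit(fr4, 4)), 6L)
  P4 <- hamiltonian_matrix(qubit_hamiltonian(matrix(c(2L, 1L, 1L, 1L), 1), 1, 0))
  ep4 <- eigen(P4)
  ref4 <- ep4$vectors %*% diag(exp(-0.25 * 0.7i * ep4$values)) %*% Conj(t(ep4$vectors))
  expect_lt(max(abs(dense_unitary(circuit(fr4, 4)) - ref4)), 1e-12)

  expect_error(exp_pauli_circuit(pauli_string("", 3), NA, 1), "identity")
})

test_that("CNOT count equals the 2(w-1) formula plus SWAP insertions", {
  ham <- h2_ham()
  circ <- uccsd_circuit(ham)
  ops <- build_uccsd(2, 4)
  terms <- jw_cluster_to_paulis(ops, 4)
  formula <- sum(vapply(terms, function(t) 2L * (sum(t$pauli != 0) - 1L),
                        integer(1)))
  expect_equal(count_cnots(circ), formula)
  cc <- compile_adjacent(circ)
  n_swap <- sum(vapply(cc$gates, function(g) g$name == "SWAP", logical(1)))
  expect_equal(count_cnots(cc), formula + 3L * n_swap)
})

test_that("theta = 0 reproduces the reference and compiled circuits conserve particle number", {
  ham <- h2_ham()
  circ <- uccsd_circuit(ham)
  expect_equal(evaluate_energy(ham, circ, rep(0, circ$n_params)),
               h2_ints()$e_hf, tolerance = 1e-10)
  # particle-number conservation of the compiled unitary
  u <- dense_unitary(compile_adjacent(circ), theta = c(0.13, -0.27))
  nq <- 4
  nops <- do.call(rbind, lapply(seq_len(nq) - 1L, function(q) {
    v <- integer(nq); v[q + 1] <- 3L; v
  }))
  nmat <- hamiltonian_matrix(qubit_hamiltonian(nops, rep(-0.5, nq), nq / 2))
  expect_lt(max(abs(u %*% nmat - nmat %*% u)), 1e-10)
})

test_that("Trotter term ordering changes the optimum only marginally for H2", {
  ham <- h2_ham()
  ops <- build_uccsd(2, 4)
  terms <- jw_cluster_to_paulis(ops, 4)
  c1 <- trotterize(terms, 4, attr(ops, "n_params"))
  c2 <- trotterize(terms, 4, attr(ops, "n_params"), reverse = TRUE)
  cfg <- vqe_config(rhoend = 1e-8, max_bond = 8)
  e1 <- optimize_vqe(ham, c1, cfg)$energy
  e2 <- optimize_vqe(ham, c2, cfg)$energy
  expect_lt(abs(e1 - e2), 1e-6)
})

test_that("symmetry screening drops only zero-amplitude doubles", {
  ints <- h2_ints()
  ham <- h2_ham()
  c_full <- uccsd_circuit(ham)
  c_scr <- uccsd_circuit(ham, screen_ints = ints)
  cfg <- vqe_config(rhoend = 1e-8, max_bond = 8)
  e_full <- optimize_vqe(ham, c_full, cfg)$energy
  e_scr <- optimize_vqe(ham, c_scr, cfg)$energy
  expect_equal(e_full, e_scr, tolerance = 1e-8)
})

test_that("the chain pool obeys the Z-removal and odd-Y rules", {
  pool <- build_chain_pool(6, window = 5)
  expect_gt(length(pool), 0)
  for (p in pool) {
    expect_false(any(p == 3L))              # no Pauli-Z anywhere
    expect_equal(sum(p == 2L) %% 2L, 1L)    # odd number of Pauli-Ys
  }
  # dedup: all strings unique
  keys <- vapply(pool, paste, "", collapse = "")
  expect_equal(anyDuplicated(keys), 0L)
  # window arithmetic: stride-1 windows
  prov <- attr(pool, "provenance")
  expect_equal(sort(unique(prov$window)), 1:2)
  expect_error(build_chain_pool(4, window = 5), "window")

  # the rule applied to a concrete generator: the generalized single
  # alpha0 -> alpha1 contributes X0 Z1 Y2 and Y0 Z1 X2 strings, whose
  # Z-stripped images X0 Y2 / Y0 X2 (one Y each, odd) survive
  expect_true(any(keys == paste(c(1L, 0L, 2L, rep(0L, 9)), collapse = "")))
  expect_true(any(keys == paste(c(2L, 0L, 1L, rep(0L, 9)), collapse = "")))
})

test_that("pool circuits follow prod_j exp(i theta_j P_j) in pool order", {
  pool <- build_chain_pool(5, window = 5)
  circ <- pool_circuit(pool)
  expect_equal(circ$n_params, length(pool))
  # dense check on a truncated pool at random theta
  small <- structure(pool[1:3], class = "operator_pool",
                     n_qubits = attr(pool, "n_qubits"))
  csm <- pool_circuit(small)
  set.seed(2)
  th <- runif(3, -0.3, 0.3)
  ref <- diag(2^attr(pool, "n_qubits")) + 0i
  for (k in 3:1) {
    P <- hamiltonian_matrix(qubit_hamiltonian(matrix(small[[k]], 1), 1, 0))
    ep <- eigen(P)
    ref <- ref %*% (ep$vectors %*% diag(exp(1i * th[k] * ep$values)) %*%
                    Conj(t(ep$vectors)))
  }
  # compare the action on a handful of basis states (cheaper than the full
  # 10-qubit unitary)
  for (bits in c("0000000000", "1100000000", "0101010101")) {
    v <- dense_statevector(compile_adjacent(csm), theta = th, init_bits = bits)
    expect_lt(max(abs(v - ref[, strtoi(bits, base = 2) + 1L])), 1e-10)
  }
})
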