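# VQE driver: evaluation, optimization, determinism, one-shot mode,
# bond-dimension selection.

test_that("MPS energy evaluation equals the dense-circuit oracle", {
  ham <- h2_ham()
  circ <- uccsd_circuit(ham)
  set.seed(6)
  for (k in 1:5) {
    th <- runif(circ$n_params, -0.2, 0.2)
    e_mps <- evaluate_energy(ham, circ, th, vqe_config(max_bond = 16))
    v <- dense_statevector(compile_adjacent(circ), theta = th,
                           init_bits = "1100")
    expect_equal(e_mps, dense_expect_hamiltonian(v, ham), tolerance = 1e-10)
  }
})

test_that("H2 VQE reaches FCI and recovers the dense-oracle amplitude", {
  ham <- h2_ham()
  circ <- uccsd_circuit(ham)
  cfg <- vqe_config(rhoend = 1e-10, max_bond = 16, polish = TRUE)
  fit <- optimize_vqe(ham, circ, cfg)
  e_fci <- fci_energy(ham)
  expect_lt(abs(fit$energy - e_fci), 1e-11)
  # energy trace is the non-increasing best-so-far record
  expect_true(all(diff(fit$energy_trace) <= 0))
  expect_true(fit$converged)

  # dense-oracle optimum of the double amplitude via 1-d golden search
  efun_dense <- function(t2) {
    v <- dense_statevector(compile_adjacent(circ), theta = c(0, t2), "1100")
    dense_expect_hamiltonian(v, ham)
  }
  opt <- stats::optimize(efun_dense, c(-0.5, 0.5), tol = 1e-12)
  i_double <- 2L   # parameter 2 is the double amplitude
  expect_lt(abs(abs(fit$theta[i_double]) - abs(opt$minimum)), 1e-5)
})

test_that("energy is invariant to an unsaturated bond-dimension cap", {
  ham <- h2_ham()
  circ <- uccsd_circuit(ham)
  th <- c(0.02, -0.1)
  e16 <- evaluate_energy(ham, circ, th, vqe_config(max_bond = 16))
  e64 <- evaluate_energy(ham, circ, th, vqe_config(max_bond = 64))
  expect_equal(e16, e64, tolerance = 1e-12)
})

test_that("runs are deterministic for a fixed config and seed", {
  ham <- h2_ham()
  circ <- uccsd_circuit(ham)
  cfg <- vqe_config(rhoend = 1e-6, max_bond = 8, seed = 7,
                    theta_init = "random", theta_range = 0.1)
  f1 <- optimize_vqe(ham, circ, cfg)
  f2 <- optimize_vqe(ham, circ, cfg)
  expect_identical(f1$energy_trace, f2$energy_trace)
  expect_identical(f1$theta, f2$theta)
})

test_that("a parameter-free circuit returns the reference energy in one evaluation", {
  ham <- h2_ham()
  circ <- circuit(list(), 4, 0)
  fit <- optimize_vqe(ham, circ)
  expect_equal(fit$energy, h2_ints()$e_hf, tolerance = 1e-10)
  expect_equal(fit$n_evals, 1L)
})

test_that("H4 chain UCCSD-VQE agrees with FCI to the stated tolerance", {
  ints <- fixture("h4_chain_ints", function() compute_integrals(h_chain(4)))
  ham <- fixture("h4_chain_ham", function() build_qubit_hamiltonian(ints))
  circ <- uccsd_circuit(ham, screen_ints = ints)
  fit <- optimize_vqe(ham, circ, vqe_config(rhoend = 1e-7, max_bond = 32,
                                            trunc_threshold = 1e-9))
  e_fci <- fci_energy_determinant(ints)
  # the single-Trotter UCCSD residual for this 4-electron chain is ~3e-5 Ha
  # (ansatz error, not optimizer error); well inside chemical accuracy
  expect_lt(fit$energy - e_fci, 1e-4)
  expect_gt(fit$energy - e_fci, -1e-9)      # variational bound
})

test_that("the variational bound holds at every accepted optimizer step", {
  ham <- h2_ham()
  circ <- uccsd_circuit(ham)
  fit <- optimize_vqe(ham, circ, vqe_config(rhoend = 1e-8, max_bond = 16))
  e_fci <- fci_energy(ham)
  expect_true(all(fit$energy_trace >= e_fci - 1e-10))
})

test_that("one-shot mode saturates the bond cap on an entangling circuit", {
  ints <- fixture("h6_chain_ints", function() compute_integrals(h_chain(6)))
  ham <- fixture("h6_chain_ham", function() build_qubit_hamiltonian(ints))
  circ <- uccsd_circuit(ham, screen_ints = ints)
  cfg <- vqe_config(max_bond = 16, trunc_threshold = 1e-9)
  r <- one_shot_energy(ham, circ, cfg, seed = 11)
  expect_equal(r$max_bond_reached, 16L)
  expect_true(r$saturated)
  # reproducible for the same seed
  r2 <- one_shot_energy(ham, circ, cfg, seed = 11)
  expect_identical(r$energy, r2$energy)
  # variational bound survives normalized truncation
  expect_gt(r$energy, fci_energy_determinant(ints) - 1e-9)
  # theta = 0: identity rotations leave the reference product state, so all
  # final bond spectra are trivial (the basis-rotation/CNOT ladders only
  # touch D = 2 transiently)
  r0 <- evaluate_energy(ham, circ, rep(0, circ$n_params), cfg, detail = TRUE)
  expect_true(all(lengths(bond_spectra(r0$state)) == 1L))
  expect_lte(r0$max_bond_reached, 2L)
  expect_equal(r0$energy, ints$e_hf, tolerance = 1e-9)
})

test_that("bond-dimension scan selects the smallest converged D", {
  ham <- h2_ham()
  circ <- uccsd_circuit(ham)
  sc <- bond_dimension_scan(ham, circ, c(1, 2, 4),
                            vqe_config(rhoend = 1e-8, max_bond = 4))
  expect_true(sc$met_criterion)
  # H2 has Schmidt rank 2: D = 2 and D = 4 give identical energies
  e <- sc$table$energy
  expect_lt(abs(e[2] - e[3]), 1e-9)
  expect_lte(sc$selected_d, 2)
  # energies non-increasing in D within optimizer noise
  expect_true(all(diff(e) < 1e-6))
})
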