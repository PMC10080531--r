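# Shared fixtures, computed once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

h2_ints <- function(R = 0.7414, basis = "sto-3g") {
  fixture(paste0("h2_ints_", R, "_", basis),
          function() compute_integrals(h2_molecule(R, basis = basis)))
}

h2_ham <- function(R = 0.7414) {
  fixture(paste0("h2_ham_", R),
          function() build_qubit_hamiltonian(h2_ints(R)))
}

h4_ring_ints <- function() {
  fixture("h4_ring_ints", function() compute_integrals(h_ring(4, 1.0)))
}

# dense statevector norm-squared overlap
fidelity <- function(u, v) abs(sum(Conj(u) * v))^2

kcal_per_hartree <- 627.5094740631
ev_per_hartree <- 27.211386245988

expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
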