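# DMET: localization, bath construction, fragment solutions, the
# electron-number cycle, and the whole-molecule limit.

test_that("mean-field RDM in the local basis is idempotent with correct trace", {
  mf <- fixture("h4_mf", function() mean_field_rdm(h_ring(4, 1.0)))
  D <- mf$rdm
  expect_equal(sum(diag(D)), 4, tolerance = 1e-10)
  expect_lt(max(abs(D %*% D - 2 * D)), 1e-8)
  # localization preserves the electron count exactly
  mf2 <- mean_field_rdm(h2_molecule(0.7414))
  expect_equal(sum(diag(mf2$rdm)), 2, tolerance = 1e-12)
  expect_equal(sort(eigen(mf2$rdm, symmetric = TRUE)$values), c(0, 2),
               tolerance = 1e-10)
})

test_that("the Schmidt construction yields the expected bath structure", {
  mf <- fixture("h4_mf", function() mean_field_rdm(h_ring(4, 1.0)))
  emb <- build_embedding(mf, 1:2)
  expect_equal(emb$n_bath, 2L)
  expect_equal(emb$n_elec, 4L)
  expect_lte(emb$n_bath, emb$n_frag)
  expect_equal(emb$h, t(emb$h), tolerance = 1e-12)

  # whole molecule as the fragment: no bath, no environment
  embw <- build_embedding(mf, 1:4)
  expect_equal(embw$n_bath, 0L)
  expect_lt(max(abs(embw$env_rdm)), 1e-10)
  expect_equal(embw$h_no_mu, mf$h, tolerance = 1e-10)

  # mu shifts only the fragment diagonal
  e0 <- build_embedding(mf, 1:2, mu = 0)
  e1 <- build_embedding(mf, 1:2, mu = 0.1)
  d <- e0$h - e1$h                       # e1 has -0.1 on the fragment diagonal
  expect_equal(diag(d)[1:2], rep(0.1, 2), tolerance = 1e-12)
  d[cbind(1:2, 1:2)] <- 0
  expect_lt(max(abs(d)), 1e-12)
})

test_that("whole-molecule fragments reproduce FCI at machine precision", {
  d <- fixture("dmet_h2_whole", function()
    dmet_cycle(h2_molecule(0.7414), list(1:2), solver = "fci"))
  expect_equal(d$energy, fci_energy(h2_ham()), tolerance = 1e-9)
  expect_equal(d$mu, 0)
  d4 <- fixture("dmet_h4_whole", function()
    dmet_cycle(h_ring(4, 1.0), list(1:4), solver = "fci"))
  expect_equal(d4$energy, fci_energy_determinant(h4_ring_ints()),
               tolerance = 1e-8)
})

test_that("two-fragment H4 ring conserves electrons and is near FCI", {
  d <- fixture("dmet_h4_2frag", function()
    dmet_cycle(h_ring(4, 1.0), list(1:2, 3:4), solver = "fci"))
  expect_lt(abs(d$n_elec_total - 4), 1e-5)
  e_fci <- fci_energy_determinant(h4_ring_ints())
  expect_lt(abs(d$energy - e_fci), 0.02)
  # ring symmetry: identical fragment energies
  expect_equal(d$fragments$E_A[1], d$fragments$E_A[2], tolerance = 1e-6)
  # fragment-label permutation leaves the total energy unchanged
  d2 <- dmet_cycle(h_ring(4, 1.0), list(3:4, 1:2), solver = "fci")
  expect_equal(d2$energy, d$energy, tolerance = 1e-8)
})

test_that("fragment solutions have physical reduced density matrices", {
  mf <- fixture("h4_mf", function() mean_field_rdm(h_ring(4, 1.0)))
  emb <- build_embedding(mf, 1:2)
  sol <- fixture("h4_frag_sol", function() solve_fragment(emb, "fci"))
  ev <- eigen(sol$rdm1, symmetric = TRUE)$values
  expect_true(all(ev > -1e-8 & ev < 2 + 1e-8))
  expect_equal(sum(diag(sol$rdm1)), emb$n_elec, tolerance = 1e-6)
  expect_equal(sol$rdm1, t(sol$rdm1), tolerance = 1e-8)
  # N^A = sum over fragment diagonal
  expect_equal(sol$n_elec_fragment, sum(diag(sol$rdm1)[1:2]), tolerance = 1e-12)
})

test_that("FCI and MPS-VQE fragment solvers agree on a small embedding", {
  mf <- fixture("h2s_mf", function() mean_field_rdm(h2_molecule(0.9)))
  emb <- build_embedding(mf, 1:2)   # whole molecule, 4-qubit embedding
  s_fci <- solve_fragment(emb, "fci")
  s_vqe <- solve_fragment(emb, "mps_vqe",
                          vqe_config(rhoend = 1e-8, max_bond = 8))
  expect_lt(abs(s_fci$fragment_energy - s_vqe$fragment_energy), 1e-6)
  expect_lt(max(abs(s_fci$rdm1 - s_vqe$rdm1)), 1e-4)
  # MPS-measured rdm1 matches the dense-state rdm1 closely
  expect_equal(sum(diag(s_vqe$rdm1)), emb$n_elec, tolerance = 1e-6)
})

test_that("atom fragment mapping follows the AO shell structure", {
  mol <- h_ring(4, 1.0)
  fr <- atom_fragments(mol, c("A", "A", "B", "B"))
  expect_equal(fr, list(1:2, 3:4))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(`1` = "A", `2` = "A", `3` = "B", `4` = "B"), f,
                       auto_unbox = TRUE)
  fr2 <- atom_fragments(mol, f)
  expect_equal(fr2, fr)
  unlink(f)
})
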