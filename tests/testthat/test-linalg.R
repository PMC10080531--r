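# SVD backends: one-sided Jacobi, cross-product baseline, truncation.

test_that("rotation parameters follow the tangent/cosine closed forms", {
  # construct a real pair with tau = 3/4 exactly:
  # |a_i|^2 - |a_j|^2 = 3, 2 a_i.a_j = 4
  ci <- c(2, 1, 0)                      # norm2 5
  cj <- c(1, 0, 1)                      # norm2 2, dot 2
  r <- rotation_params(ci, cj)
  expect_equal(r$tau, 3 / 4)
  expect_equal(r$t, 0.5)
  expect_equal(r$c, 2 / sqrt(5), tolerance = 1e-15)
  expect_equal(r$s, 1 / sqrt(5), tolerance = 1e-15)
  expect_equal(r$c^2 + r$s^2, 1, tolerance = 1e-15)
  expect_identical(r$s, r$t * r$c)

  # equal-norm columns: tau = 0, sign(0) := +1 -> 45 degree rotation
  a <- c(3, 4, 0); b <- c(4, 3, 0)            # equal norm 25, dot 24
  r0 <- rotation_params(a, b)
  expect_equal(r0$tau, 0)
  expect_equal(r0$t, 1)
  expect_equal(r0$c, 1 / sqrt(2), tolerance = 1e-15)
  expect_equal(r0$s, 1 / sqrt(2), tolerance = 1e-15)

  # |tau| -> infinity approaches the identity rotation
  rbig <- rotation_params(c(1e8, 0), c(1e-8, 1e-8))
  expect_lt(abs(rbig$t), 1e-7)
  expect_gt(rbig$c, 1 - 1e-14)

  # degenerate zero-norm column is flagged and skipped
  rz <- rotation_params(c(0, 0), c(1, 0))
  expect_true(rz$skipped)
  expect_true(rz$degenerate)
})

test_that("plane rotations preserve the Frobenius norm of the pair", {
  set.seed(11)
  for (k in 1:20) {
    a <- rnorm(6) + 1i * rnorm(6)
    b <- rnorm(6) + 1i * rnorm(6)
    r <- rotation_params(a, b)
    if (isTRUE(r$skipped)) next
    ph <- sum(Conj(a) * b); ph <- ph / Mod(ph)
    a2 <- r$c * a + r$s * Conj(ph) * b
    b2 <- -r$s * a + r$c * Conj(ph) * b
    expect_equal(sum(Mod(a2)^2) + sum(Mod(b2)^2),
                 sum(Mod(a)^2) + sum(Mod(b)^2), tolerance = 1e-13)
  }
})

test_that("one-sided Jacobi SVD handles the elementary cases", {
  r <- one_sided_jacobi_svd(diag(4))
  expect_equal(r$d, rep(1, 4))
  expect_equal(abs(diag(r$u)), rep(1, 4))
  r <- one_sided_jacobi_svd(diag(c(3, 2, 1)))
  expect_equal(r$d, c(3, 2, 1))
  z <- one_sided_jacobi_svd(matrix(0, 3, 3))
  expect_equal(z$d, rep(0, 3))
})

test_that("Jacobi singular values match an independent eigenvalue oracle", {
  set.seed(7)
  a <- matrix(rnorm(24) + 1i * rnorm(24), 6, 4)
  r <- one_sided_jacobi_svd(a)
  # oracle: sqrt of eigenvalues of A^H A (descending)
  ev <- eigen(Conj(t(a)) %*% a, symmetric = TRUE, only.values = TRUE)$values
  expect_close(r$d, sqrt(ev), 1e-12)
  expect_close(svd_reconstruct(r), a, 1e-12)
})

test_that("Jacobi agrees with the reference backend over random matrices", {
  set.seed(123)
  worst_sig <- 0; worst_orth <- 0
  for (k in 1:200) {
    m <- sample(2:64, 1); n <- sample(2:min(m, 32), 1)
    a <- matrix(rnorm(m * n), m, n)
    if (k %% 2 == 0) a <- a + 1i * matrix(rnorm(m * n), m, n)
    r <- one_sided_jacobi_svd(a)
    ref <- svd(a)$d
    worst_sig <- max(worst_sig, max(abs(r$d - ref)) / max(ref))
    worst_orth <- max(worst_orth,
                      max(abs(Conj(t(r$u)) %*% r$u - diag(ncol(r$u)))))
  }
  expect_lt(worst_sig, 1e-10)
  expect_lt(worst_orth, 1e-10)
})

test_that("non-convergence within max_sweeps raises an informative error", {
  set.seed(5)
  a <- matrix(rnorm(100), 10, 10)
  expect_error(one_sided_jacobi_svd(a, max_sweeps = 1), "converge")
  expect_error(one_sided_jacobi_svd(matrix(c(NaN, 1, 2, 3), 2, 2)), "NaN")
})

test_that("cross-product SVD matches on well-conditioned input and degrades on ill-conditioned", {
  set.seed(31)
  u <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  v <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  a <- u %*% diag(c(2, 1, 0.5)) %*% t(v)
  rc <- cross_product_svd(a)
  rr <- reference_svd(a)
  expect_close(rc$d, rr$d, 1e-12)

  # condition number 1e9: the squared condition number destroys the small
  # singular values for the cross-product route but not for Jacobi
  n <- 8
  u <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  v <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  d <- exp(seq(0, -log(1e9), length.out = n))
  a <- u %*% (d * t(v))
  ref <- svd(a)$d
  ej <- abs(one_sided_jacobi_svd(a)$d - ref) / ref
  ec <- abs(cross_product_svd(a)$d - ref) / ref
  expect_gt(ec[n], ej[n])
  expect_true(cross_product_svd(a)$ill_conditioned)
  expect_equal(cross_product_svd(matrix(0, 3, 3))$d, rep(0, 3))
})

test_that("truncation keeps rank, records discarded weight, renormalizes", {
  r <- mpsvqe:::new_svd_result(diag(4), c(1, 0, 0, 0), diag(4), "reference")
  t1 <- truncate_svd(r, max_rank = 2)
  expect_equal(length(t1$d), 1)            # zeros fall below any threshold>0? kept by rank
  expect_equal(t1$discarded_weight, 0)

  r2 <- mpsvqe:::new_svd_result(diag(2), c(0.8, 0.6), diag(2), "reference")
  t2 <- truncate_svd(r2, max_rank = 1)
  expect_equal(t2$d, 1.0)
  expect_equal(t2$discarded_weight, 0.36, tolerance = 1e-15)

  # identity operation when nothing is below threshold and rank is free
  d <- c(5, 3, 2, 1)
  r3 <- mpsvqe:::new_svd_result(diag(4), d, diag(4), "reference")
  t3 <- truncate_svd(r3, max_rank = 4, threshold = 0)
  expect_equal(t3$d * sqrt(sum(d^2)), d, tolerance = 1e-14)
  expect_equal(t3$discarded_weight, 0)

  # weight bookkeeping: discarded + retained (pre-renormalization) = total
  t4 <- truncate_svd(r3, max_rank = 2)
  expect_equal(t4$discarded_weight + sum((t4$d * sqrt(sum(d^2) - t4$discarded_weight))^2),
               sum(d^2), tolerance = 1e-12)
})

test_that("svd_benchmark reports backend accuracy", {
  b <- svd_benchmark(c(6, 10), seed = 2, n_rep = 2)
  expect_true(all(b$sigma_err[b$backend == "jacobi"] < 1e-10))
  expect_true(all(b$orth_defect < 1e-10))
})
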