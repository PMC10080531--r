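# Singular value decomposition backends and truncation utilities.

new_svd_result <- function(u, d, vt, backend_tag, discarded_weight = 0,
                           extra = list()) {
  structure(c(list(u = u, d = as.numeric(d), vt = vt,
                   discarded_weight = discarded_weight,
                   backend_tag = backend_tag), extra),
            class = "svd_result")
}

#' @export
print.svd_result <- function(x, ...) {
  cat(sprintf("<svd_result> backend %s, rank %d, sigma_max %.6g, discarded %.3e\n",
              x$backend_tag, length(x$d), if (length(x$d)) x$d[1] else 0,
              x$discarded_weight))
  invisible(x)
}

#' Jacobi plane-rotation parameters for a column pair
#'
#' Computes the column-pair asymmetry \eqn{\tau = (a_i^H a_i - a_j^H a_j) /
#' (2 |a_i^H a_j|)}, the tangent \eqn{t = sign(\tau) / (|\tau| +
#' \sqrt{1+\tau^2})} (with \eqn{sign(0) := +1}), and the rotation cosine/sine
#' \eqn{c = 1/\sqrt{1+t^2}}, \eqn{s = t c}. For complex columns the inner
#' product magnitude is used (a phase pre-rotation is applied inside the
#' sweep).
#'
#' @param col_i,col_j columns of equal length
#' @return list with \code{tau}, \code{t}, \code{c}, \code{s},
#'   \code{skipped} (TRUE when the inner product vanishes) and
#'   \code{degenerate} (TRUE for a zero-norm column)
#' @export
rotation_params <- function(col_i, col_j) {
  cpp_rotation_params(as.complex(col_i), as.complex(col_j))
}

#' One-sided Jacobi singular value decomposition
#'
#' Hestenes one-sided Jacobi: sweeps over all column pairs applying plane
#' rotations until every pair satisfies
#' \eqn{|a_i^H a_j| \le tol \, \|a_i\| \|a_j\|}. The singular values are the
#' final column norms, U the normalized columns and V the accumulated
#' rotations.
#'
#' @param a real or complex matrix (transposed internally when rows < cols)
#' @param orth_tol pairwise orthogonality tolerance; default
#'   \code{1e-14 * sqrt(nrow)}
#' @param max_sweeps maximum number of sweeps
#' @return an \code{svd_result} with descending singular values
#' @export
one_sided_jacobi_svd <- function(a, orth_tol = NULL, max_sweeps = 30) {
  a <- as.matrix(a)
  if (any(!is.finite(Re(a))) || any(!is.finite(Im(a))))
    stop("matrix contains NaN/Inf entries")
  storage.mode(a) <- "complex"
  r <- cpp_jacobi_svd(a, if (is.null(orth_tol)) -1 else orth_tol,
                      as.integer(max_sweeps))
  if (!r$converged)
    stop(sprintf(
      "one-sided Jacobi SVD did not converge in %d sweeps (off-orthogonality %.3e)",
      max_sweeps, r$max_off_orthogonality))
  new_svd_result(r$u, r$d, Conj(t(r$v)), "jacobi",
                 extra = list(sweeps = r$sweeps))
}

#' Cross-product SVD (instability baseline)
#'
#' Eigendecomposes \eqn{A^H A} and back-solves for U. The condition number
#' is squared in the intermediate step, so small singular values lose
#' relative accuracy; provided as the numerical baseline against the Jacobi
#' kernel.
#'
#' @param a real or complex matrix
#' @return an \code{svd_result}; \code{ill_conditioned} flags singular
#'   values below \code{sqrt(.Machine$double.eps)} of the largest
#' @export
cross_product_svd <- function(a) {
  a <- as.matrix(a)
  if (any(!is.finite(Re(a))) || any(!is.finite(Im(a))))
    stop("matrix contains NaN/Inf entries")
  storage.mode(a) <- "complex"
  r <- cpp_cross_svd(a)
  new_svd_result(r$u, r$d, Conj(t(r$v)), "cross",
                 extra = list(ill_conditioned = r$ill_conditioned))
}

#' Reference SVD (platform LAPACK routine)
#'
#' @param a real or complex matrix
#' @return an \code{svd_result}
#' @export
reference_svd <- function(a) {
  a <- as.matrix(a)
  s <- svd(a)
  new_svd_result(s$u, s$d, Conj(t(s$v)), "reference")
}

#' Truncate a singular value decomposition
#'
#' Keeps \code{min(max_rank, #\{sigma > threshold * sigma_1\})} singular
#' values (at least one), records the discarded weight (sum of squared
#' dropped values), and renormalizes the retained spectrum to unit 2-norm so
#' a truncated MPS stays a normalized state.
#'
#' @param svd an \code{svd_result}
#' @param max_rank maximum retained rank (>= 1)
#' @param threshold relative singular-value cutoff (>= 0)
#' @return truncated \code{svd_result}
#' @export
truncate_svd <- function(svd, max_rank, threshold = 0) {
  stopifnot(max_rank >= 1, threshold >= 0)
  d <- svd$d
  if (!length(d)) return(svd)
  k <- sum(d > threshold * d[1])
  k <- max(1L, min(as.integer(max_rank), k))
  dropped <- if (k < length(d)) sum(d[(k + 1):length(d)]^2) else 0
  kept <- d[seq_len(k)]
  renorm <- sqrt(sum(kept^2))
  new_svd_result(svd$u[, seq_len(k), drop = FALSE],
                 if (renorm > 0) kept / renorm else kept,
                 svd$vt[seq_len(k), , drop = FALSE],
                 svd$backend_tag,
                 discarded_weight = svd$discarded_weight + dropped)
}

#' Reconstruct the matrix from an \code{svd_result}
#' @param svd an \code{svd_result}
#' @export
svd_reconstruct <- function(svd) {
  svd$u %*% (svd$d * svd$vt)
}

#' Benchmark SVD backends on generated matrices
#'
#' Runs the Jacobi and cross-product backends against the reference SVD on
#' seeded random (and optionally ill-conditioned) matrices and reports
#' singular-value and orthogonality errors.
#'
#' @param sizes integer vector of matrix sizes
#' @param seed RNG seed
#' @param n_rep matrices per size
#' @param cond condition number for constructed ill-conditioned cases
#'   (\code{NULL} to use plain Gaussian matrices)
#' @return data.frame with per-case maximum relative sigma errors and
#'   orthogonality defects
#' @export
svd_benchmark <- function(sizes, seed = 1, n_rep = 3, cond = NULL) {
  if (!length(sizes)) stop("empty size list")
  rows <- list()
  for (n in sizes) for (rep in seq_len(n_rep)) {
    a <- withr::with_seed(seed + 1000 * n + rep, {
      if (is.null(cond)) {
        matrix(stats::rnorm(n * n), n, n)
      } else {
        u <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
        v <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
        d <- exp(seq(0, -log(cond), length.out = n))
        u %*% (d * t(v))
      }
    })
    ref <- reference_svd(a)
    for (fn in c("jacobi", "cross")) {
      r <- if (fn == "jacobi") one_sided_jacobi_svd(a) else cross_product_svd(a)
      sig_err <- max(abs(r$d - ref$d)) / ref$d[1]
      orth <- max(abs(Conj(t(r$u)) %*% r$u - diag(ncol(r$u))))
      recon <- max(abs(svd_reconstruct(r) - a)) / ref$d[1]
      rows[[length(rows) + 1L]] <- data.frame(
        size = n, rep = rep, backend = fn, sigma_err = sig_err,
        orth_defect = orth, recon_err = recon)
    }
  }
  do.call(rbind, rows)
}
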