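// SVD backends: one-sided Jacobi (Hestenes), cross-product baseline, and
// helpers shared with the MPS engine.
//
// The one-sided Jacobi method orthogonalizes all column pairs in sweeps with
// plane rotations; on convergence the singular values are the column norms,
// U the normalized columns, and V the accumulated rotations.  Complex input
// is handled with a phase pre-rotation on one column so the working inner
// product is real.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// one sweep over all pairs (p < q), cyclic row order; returns number of
// rotations applied and the largest relative off-orthogonality encountered
static int jacobi_sweep(arma::cx_mat& A, arma::cx_mat& V, double tol,
                        double& max_off) {
  int n = A.n_cols, rot = 0;
  max_off = 0.0;
  for (int p = 0; p < n - 1; ++p)
    for (int q = p + 1; q < n; ++q) {
      double app = std::real(arma::cdot(A.col(p), A.col(p)));
      double aqq = std::real(arma::cdot(A.col(q), A.col(q)));
      std::complex<double> apq = arma::cdot(A.col(p), A.col(q));
      double g = std::abs(apq);
      double denom = std::sqrt(app) * std::sqrt(aqq);
      if (denom <= 0.0) continue;  // zero column: nothing to rotate
      double off = g / denom;
      if (off > max_off) max_off = off;
      if (g <= tol * denom) continue;
      // phase pre-rotation on column q makes <a_p, a_q> real positive
      std::complex<double> ph = apq / g;
      A.col(q) *= std::conj(ph);
      V.col(q) *= std::conj(ph);
      double tau = (app - aqq) / (2.0 * g);
      double sgn = (tau >= 0.0) ? 1.0 : -1.0;  // sign(0) := +1
      double t = sgn / (std::abs(tau) + std::sqrt(1.0 + tau * tau));
      double c = 1.0 / std::sqrt(1.0 + t * t);
      double s = t * c;
      // [a_p, a_q] <- [a_p, a_q] * [[c, -s], [s, c]]
      arma::cx_vec ap = A.col(p);
      A.col(p) = c * ap + s * A.col(q);
      A.col(q) = -s * ap + c * A.col(q);
      arma::cx_vec vp = V.col(p);
      V.col(p) = c * vp + s * V.col(q);
      V.col(q) = -s * vp + c * V.col(q);
      ++rot;
    }
  return rot;
}

// economy one-sided Jacobi SVD of an m x n matrix (any shape).
// On output: U (m x k), s (k), V (n x k) with k = min(m, n), A = U S V^H.
bool jacobi_svd_econ(const arma::cx_mat& A0, arma::cx_mat& U, arma::vec& s,
                     arma::cx_mat& V, double orth_tol, int max_sweeps,
                     int* sweeps_out, double* off_out) {
  bool transposed = A0.n_rows < A0.n_cols;
  arma::cx_mat A = transposed ? arma::cx_mat(A0.t()) : A0;
  int m = A.n_rows, n = A.n_cols;
  if (orth_tol <= 0) orth_tol = 1e-14 * std::sqrt((double)m);
  arma::cx_mat Vw(n, n, arma::fill::eye);
  double max_off = 0.0;
  int sw = 0;
  bool converged = false;
  for (; sw < max_sweeps; ++sw) {
    int rot = jacobi_sweep(A, Vw, orth_tol, max_off);
    if (rot == 0) { converged = true; break; }
  }
  if (sweeps_out) *sweeps_out = sw + (converged ? 1 : 0);
  if (off_out) *off_out = max_off;
  // extract factors
  arma::vec nrm(n);
  for (int j = 0; j < n; ++j) nrm[j] = arma::norm(A.col(j));
  arma::uvec ord = arma::sort_index(nrm, "descend");
  s.set_size(n);
  arma::cx_mat Us(m, n), Vs(n, n);
  double smax = nrm.max();
  for (int j = 0; j < n; ++j) {
    int src = ord[j];
    s[j] = nrm[src];
    Vs.col(j) = Vw.col(src);
    if (nrm[src] > smax * 1e-300 && nrm[src] > 0) {
      Us.col(j) = A.col(src) / nrm[src];
    } else {
      Us.col(j).zeros();
    }
  }
  // complete null columns of U orthonormally (rank-deficient input)
  for (int j = 0; j < n; ++j) {
    if (arma::norm(Us.col(j)) > 0.5) continue;
    for (int e = 0; e < m; ++e) {
      arma::cx_vec cand(m, arma::fill::zeros);
      cand[e] = 1.0;
      for (int k2 = 0; k2 < n; ++k2)
        if (k2 != j && arma::norm(Us.col(k2)) > 0.5)
          cand -= arma::cdot(Us.col(k2), cand) * Us.col(k2);
      for (int k2 = 0; k2 < j; ++k2)
        cand -= arma::cdot(Us.col(k2), cand) * Us.col(k2);
      double nn = arma::norm(cand);
      if (nn > 1e-6) { Us.col(j) = cand / nn; break; }
    }
  }
  if (!transposed) {
    U = Us; V = Vs;
  } else {
    U = Vs; V = Us;  // A0 = A^H = (U S V^H)^H = V S U^H
  }
  return converged;
}

// [[Rcpp::export]]
List cpp_jacobi_svd(arma::cx_mat A, double orth_tol = -1.0,
                    int max_sweeps = 30) {
  if (!A.is_finite()) stop("matrix contains NaN/Inf entries");
  arma::cx_mat U, V;
  arma::vec s;
  int sweeps = 0;
  double off = 0.0;
  bool conv = jacobi_svd_econ(A, U, s, V, orth_tol, max_sweeps, &sweeps, &off);
  return List::create(_["u"] = U, _["d"] = s, _["v"] = V,
                      _["converged"] = conv, _["sweeps"] = sweeps,
                      _["max_off_orthogonality"] = off);
}

// cross-product SVD: eigendecompose A^H A, back-solve U = A V / sigma.
// The condition number is squared in the intermediate step, which is the
// known numerical weakness of this baseline.
// [[Rcpp::export]]
List cpp_cross_svd(arma::cx_mat A) {
  if (!A.is_finite()) stop("matrix contains NaN/Inf entries");
  bool transposed = A.n_rows < A.n_cols;
  arma::cx_mat Aw = transposed ? arma::cx_mat(A.t()) : A;
  int m = Aw.n_rows, n = Aw.n_cols;
  arma::cx_mat G = Aw.t() * Aw;
  arma::vec ev;
  arma::cx_mat W;
  arma::eig_sym(ev, W, (G + G.t()) / 2.0);
  // eig_sym is ascending; reverse for descending singular values
  arma::vec s(n);
  arma::cx_mat V(n, n), U(m, n, arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    double lam = ev[n - 1 - j];
    s[j] = lam > 0 ? std::sqrt(lam) : 0.0;
    V.col(j) = W.col(n - 1 - j);
  }
  double eps_s = std::sqrt(std::numeric_limits<double>::epsilon());
  bool ill = false;
  for (int j = 0; j < n; ++j) {
    if (s[j] > eps_s * s[0] && s[j] > 0) {
      U.col(j) = Aw * V.col(j) / s[j];
      double nn = arma::norm(U.col(j));
      if (nn > 0) U.col(j) /= nn;
    } else {
      ill = true;
      // orthonormal completion
      for (int e = 0; e < m; ++e) {
        arma::cx_vec cand(m, arma::fill::zeros);
        cand[e] = 1.0;
        for (int k2 = 0; k2 < j; ++k2)
          cand -= arma::cdot(U.col(k2), cand) * U.col(k2);
        double nn = arma::norm(cand);
        if (nn > 1e-6) { U.col(j) = cand / nn; break; }
      }
    }
  }
  if (transposed) return List::create(_["u"] = V, _["d"] = s, _["v"] = U,
                                      _["ill_conditioned"] = ill);
  return List::create(_["u"] = U, _["d"] = s, _["v"] = V,
                      _["ill_conditioned"] = ill);
}

// plane-rotation parameters for a column pair (exported for unit tests)
// [[Rcpp::export]]
List cpp_rotation_params(arma::cx_vec col_i, arma::cx_vec col_j) {
  if (col_i.n_elem != col_j.n_elem) stop("columns must have equal length");
  double aii = std::real(arma::cdot(col_i, col_i));
  double ajj = std::real(arma::cdot(col_j, col_j));
  std::complex<double> aij = arma::cdot(col_i, col_j);
  double g = std::abs(aij);
  bool degenerate = (aii == 0.0 || ajj == 0.0);
  if (g == 0.0 || degenerate)
    return List::create(_["tau"] = NA_REAL, _["t"] = NA_REAL,
                        _["c"] = NA_REAL, _["s"] = NA_REAL,
                        _["skipped"] = true, _["degenerate"] = degenerate);
  double tau = (aii - ajj) / (2.0 * g);
  double sgn = (tau >= 0.0) ? 1.0 : -1.0;
  double t = sgn / (std::abs(tau) + std::sqrt(1.0 + tau * tau));
  double c = 1.0 / std::sqrt(1.0 + t * t);
  double s = t * c;
  return List::create(_["tau"] = tau, _["t"] = t, _["c"] = c, _["s"] = s,
                      _["skipped"] = false, _["degenerate"] = false);
}
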