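// Right-canonical matrix-product-state circuit engine.
//
// Site tensors B^{i}_{a,b} are stored per qubit as complex cubes with
// dimensions (left bond, right bond, physical), kept right-canonical:
// sum_i B_i B_i^H = I.  Bond spectra lambda are stored per bond including
// trivial boundaries.  Two-qubit gates on adjacent sites follow the
// contract / lambda-weight / SVD / truncate sequence, with the new left
// tensor rebuilt division-free from C and V*.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

bool jacobi_svd_econ(const arma::cx_mat& A0, arma::cx_mat& U, arma::vec& s,
                     arma::cx_mat& V, double orth_tol, int max_sweeps,
                     int* sweeps_out, double* off_out);

struct MPS {
  std::vector<arma::cx_cube> B;   // (Dl, Dr, 2) per site
  std::vector<arma::vec> lam;     // n+1 spectra, boundaries trivial
  int max_bond;
  double trunc_threshold;
  int backend;                    // 0 reference, 1 jacobi, 2 cross-product
  int max_bond_reached;
  double discarded_weight;
};

static MPS mps_from_r(const List& st) {
  MPS m;
  List tensors = st["tensors"];
  List spectra = st["spectra"];
  int n = tensors.size();
  m.B.resize(n);
  for (int i = 0; i < n; ++i) {
    ComplexVector a = tensors[i];
    IntegerVector d = a.attr("dim");
    arma::cx_cube c(reinterpret_cast<std::complex<double>*>(a.begin()), d[0],
                    d[1], d[2], true);
    m.B[i] = c;
  }
  m.lam.resize(n + 1);
  for (int i = 0; i <= n; ++i) m.lam[i] = as<arma::vec>(spectra[i]);
  m.max_bond = as<int>(st["max_bond"]);
  m.trunc_threshold = as<double>(st["trunc_threshold"]);
  m.backend = as<int>(st["backend"]);
  m.max_bond_reached = as<int>(st["max_bond_reached"]);
  m.discarded_weight = as<double>(st["discarded_weight"]);
  return m;
}

static List mps_to_r(const MPS& m) {
  int n = m.B.size();
  List tensors(n), spectra(n + 1);
  for (int i = 0; i < n; ++i) {
    ComplexVector a(m.B[i].n_elem);
    std::memcpy(a.begin(), m.B[i].memptr(), sizeof(double) * 2 * m.B[i].n_elem);
    a.attr("dim") = IntegerVector::create(m.B[i].n_rows, m.B[i].n_cols, 2);
    tensors[i] = a;
  }
  for (int i = 0; i <= n; ++i)
    spectra[i] = NumericVector(m.lam[i].begin(), m.lam[i].end());
  List st = List::create(
      _["tensors"] = tensors, _["spectra"] = spectra,
      _["max_bond"] = m.max_bond, _["trunc_threshold"] = m.trunc_threshold,
      _["backend"] = m.backend, _["max_bond_reached"] = m.max_bond_reached,
      _["discarded_weight"] = m.discarded_weight);
  st.attr("class") = "mps_state";
  return st;
}

static void svd_dispatch(const arma::cx_mat& M, arma::cx_mat& U, arma::vec& s,
                         arma::cx_mat& V, int backend) {
  if (backend == 1) {
    if (!jacobi_svd_econ(M, U, s, V, -1.0, 60, nullptr, nullptr))
      stop("one-sided Jacobi SVD failed to converge during gate application");
    return;
  }
  if (backend == 2) {
    // cross-product via eigendecomposition of M^H M
    arma::cx_mat G = M.t() * M;
    arma::vec ev;
    arma::cx_mat W;
    if (!arma::eig_sym(ev, W, (G + G.t()) / 2.0))
      stop("cross-product SVD eigendecomposition failed");
    int n = M.n_cols, k = std::min((int)M.n_rows, n);
    s.set_size(k);
    V.set_size(n, k);
    U.set_size(M.n_rows, k);
    for (int j = 0; j < k; ++j) {
      double lam = ev[n - 1 - j];
      s[j] = lam > 0 ? std::sqrt(lam) : 0.0;
      V.col(j) = W.col(n - 1 - j);
      if (s[j] > 0) {
        U.col(j) = M * V.col(j) / s[j];
        double nn = arma::norm(U.col(j));
        if (nn > 0) U.col(j) /= nn;
      } else
        U.col(j).zeros();
    }
    return;
  }
  if (!arma::svd_econ(U, s, V, M, "both", "dc"))
    if (!arma::svd_econ(U, s, V, M, "both", "std"))
      stop("reference SVD failed");
}

static void apply_1q(MPS& m, int q, const arma::cx_mat& Q) {
  arma::cx_cube& B = m.B[q];
  arma::cx_mat b0 = B.slice(0), b1 = B.slice(1);
  B.slice(0) = Q(0, 0) * b0 + Q(0, 1) * b1;
  B.slice(1) = Q(1, 0) * b0 + Q(1, 1) * b1;
}

// two-qubit gate on adjacent sites (q, q+1); gate basis |i_q i_{q+1}> with
// i_q the more significant bit
static void apply_2q(MPS& m, int q, const arma::cx_mat& Q) {
  arma::cx_cube& B1 = m.B[q];
  arma::cx_cube& B2 = m.B[q + 1];
  int Dl = B1.n_rows, Dm = B1.n_cols, Dr = B2.n_cols;
  // raw two-site tensors per (i, j)
  arma::cx_mat P[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) P[i][j] = B1.slice(i) * B2.slice(j);
  arma::cx_mat C[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) {
      C[i][j].zeros(Dl, Dr);
      for (int ip = 0; ip < 2; ++ip)
        for (int jp = 0; jp < 2; ++jp) {
          std::complex<double> w = Q(2 * i + j, 2 * ip + jp);
          if (w != std::complex<double>(0, 0)) C[i][j] += w * P[ip][jp];
        }
    }
  // lambda-weight the left bond and assemble M((i,a),(j,b)), a fastest
  const arma::vec& ll = m.lam[q];
  arma::cx_mat M(2 * Dl, 2 * Dr);
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) {
      arma::cx_mat Ct = C[i][j];
      Ct.each_col() %= arma::conv_to<arma::cx_vec>::from(ll);
      M.submat(i * Dl, j * Dr, i * Dl + Dl - 1, j * Dr + Dr - 1) = Ct;
    }
  arma::cx_mat U, V;
  arma::vec s;
  svd_dispatch(M, U, s, V, m.backend);
  // truncate: rank cap + relative threshold, keep at least one
  int kmax = std::min((int)s.n_elem, m.max_bond);
  double thr = m.trunc_threshold * (s.n_elem ? s[0] : 0.0);
  int k = 0;
  for (int j2 = 0; j2 < kmax; ++j2)
    if (s[j2] > thr) ++k; else break;
  if (k < 1) k = 1;
  double tot = arma::dot(s, s);
  double kept = 0.0;
  for (int j2 = 0; j2 < k; ++j2) kept += s[j2] * s[j2];
  m.discarded_weight += std::max(0.0, tot - kept);
  double renorm = std::sqrt(kept);
  arma::vec snew = s.head(k) / renorm;
  arma::cx_mat Vk = V.cols(0, k - 1);
  // new right tensor: rows of V^H
  arma::cx_cube B2n(k, Dr, 2);
  for (int j = 0; j < 2; ++j)
    B2n.slice(j) = Vk.rows(j * Dr, j * Dr + Dr - 1).t();
  // new left tensor, division-free: B1_i = sum_j C[i,j] * conj(V_j)^T / renorm
  arma::cx_cube B1n(Dl, k, 2);
  for (int i = 0; i < 2; ++i) {
    arma::cx_mat acc(Dl, k, arma::fill::zeros);
    // B2 rows already hold V^H, so contracting C with conj(B2) is C * V
    for (int j = 0; j < 2; ++j)
      acc += C[i][j] * Vk.rows(j * Dr, j * Dr + Dr - 1);
    B1n.slice(i) = acc / renorm;
  }
  m.B[q] = B1n;
  m.B[q + 1] = B2n;
  m.lam[q + 1] = snew;
  if (k > m.max_bond_reached) m.max_bond_reached = k;
}

// [[Rcpp::export]]
List cpp_mps_apply_gates(List state, IntegerMatrix gate_qubits,
                         List gate_mats) {
  MPS m = mps_from_r(state);
  int n = m.B.size();
  for (int g = 0; g < gate_qubits.nrow(); ++g) {
    int q1 = gate_qubits(g, 0), q2 = gate_qubits(g, 1);
    arma::cx_mat Q = as<arma::cx_mat>(gate_mats[g]);
    if (q2 < 0) {
      if (q1 < 0 || q1 >= n) stop("qubit index out of range");
      if (Q.n_rows != 2) stop("one-qubit gate must be 2x2");
      apply_1q(m, q1, Q);
    } else {
      if (q2 != q1 + 1) stop("two-qubit gates must act on adjacent qubits");
      if (q1 < 0 || q2 >= n) stop("qubit index out of range");
      if (Q.n_rows != 4) stop("two-qubit gate must be 4x4");
      apply_2q(m, q1, Q);
    }
  }
  return mps_to_r(m);
}

// expectation value of a single Pauli string (ops codes 0..3 per site)
static std::complex<double> expect_pauli(const MPS& m, const int* ops) {
  int n = m.B.size();
  int first = -1, last = -1;
  for (int i = 0; i < n; ++i)
    if (ops[i] != 0) { if (first < 0) first = i; last = i; }
  if (first < 0) return 1.0;  // identity on a normalized state
  static const std::complex<double> I(0, 1);
  // 2x2 op matrices indexed [code][row][col]
  static const std::complex<double> OPS[4][2][2] = {
      {{1, 0}, {0, 1}},          // I
      {{0, 1}, {1, 0}},          // X
      {{0, -I}, {I, 0}},         // Y
      {{1, 0}, {0, -1}}};        // Z
  const arma::vec& ll = m.lam[first];
  arma::cx_mat L = arma::diagmat(arma::conv_to<arma::cx_vec>::from(ll % ll));
  for (int t = first; t <= last; ++t) {
    const arma::cx_cube& B = m.B[t];
    arma::cx_mat Ln(B.n_cols, B.n_cols, arma::fill::zeros);
    int code = ops[t];
    for (int i = 0; i < 2; ++i)
      for (int ip = 0; ip < 2; ++ip) {
        std::complex<double> w = OPS[code][i][ip];
        if (w == std::complex<double>(0, 0)) continue;
        Ln += w * (B.slice(ip).st() * L * arma::conj(B.slice(i)));
      }
    L = Ln;
  }
  return arma::trace(L);
}

// [[Rcpp::export]]
ComplexVector cpp_mps_expect_pauli(List state, IntegerVector ops) {
  MPS m = mps_from_r(state);
  if ((int)ops.size() != (int)m.B.size()) stop("ops length mismatch");
  std::complex<double> v = expect_pauli(m, ops.begin());
  ComplexVector out(1);
  out[0] = Rcomplex{v.real(), v.imag()};
  return out;
}

// weighted sum over many Pauli terms with long-double accumulation
// [[Rcpp::export]]
double cpp_mps_expect_terms(List state, IntegerMatrix ops, NumericVector coefs,
                            double offset) {
  MPS m = mps_from_r(state);
  int n = m.B.size();
  if (ops.ncol() != n) stop("ops width mismatch");
  long double acc = offset;
  std::vector<int> row(n);
  for (int t = 0; t < ops.nrow(); ++t) {
    for (int j = 0; j < n; ++j) row[j] = ops(t, j);
    std::complex<double> v = expect_pauli(m, row.data());
    acc += (long double)coefs[t] * (long double)v.real();
  }
  return (double)acc;
}

// imaginary-part diagnostic for Hermitian observables
// [[Rcpp::export]]
double cpp_mps_expect_terms_imag(List state, IntegerMatrix ops,
                                 NumericVector coefs) {
  MPS m = mps_from_r(state);
  int n = m.B.size();
  double worst = 0.0;
  std::vector<int> row(n);
  for (int t = 0; t < ops.nrow(); ++t) {
    for (int j = 0; j < n; ++j) row[j] = ops(t, j);
    std::complex<double> v = expect_pauli(m, row.data());
    worst = std::max(worst, std::abs(coefs[t] * v.imag()));
  }
  return worst;
}

// dense amplitudes; qubit 0 is the most significant bit of the index
// [[Rcpp::export]]
arma::cx_vec cpp_mps_to_dense(List state) {
  MPS m = mps_from_r(state);
  int n = m.B.size();
  if (n > 16) stop("to_dense limited to 16 qubits");
  arma::cx_mat P(1, 1, arma::fill::ones);
  for (int t = 0; t < n; ++t) {
    const arma::cx_cube& B = m.B[t];
    arma::cx_mat Pn(2 * P.n_rows, B.n_cols);
    for (arma::uword p = 0; p < P.n_rows; ++p)
      for (int i = 0; i < 2; ++i)
        Pn.row(2 * p + i) = P.row(p) * B.slice(i);
    P = Pn;
  }
  return P.col(0);
}

// per-site right-canonicity defect max |sum_i B_i B_i^H - I|
// [[Rcpp::export]]
NumericVector cpp_mps_canonical_defect(List state) {
  MPS m = mps_from_r(state);
  int n = m.B.size();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    const arma::cx_cube& B = m.B[t];
    arma::cx_mat acc(B.n_rows, B.n_rows, arma::fill::zeros);
    for (int i = 0; i < 2; ++i) acc += B.slice(i) * B.slice(i).t();
    acc -= arma::eye<arma::cx_mat>(B.n_rows, B.n_rows);
    out[t] = arma::abs(acc).max();
  }
  return out;
}
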