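// Jordan-Wigner transformation of second-quantized operators.
//
// Pauli strings are held as bit masks over <=128 qubits in the "XZ" frame:
// W(x, z) = prod_j X_j^{x_j} Z_j^{z_j}.  Single-qubit dictionary:
// I=(0,0), X=(1,0), Z=(0,1), XZ=(1,1)=-iY.  Products obey
// W(x1,z1) W(x2,z2) = (-1)^{|z1 & x2|} W(x1^x2, z1^z2).
// Ladder operators (annihilation a_j lowers |1> -> |0>):
//   a_j   = Z_{<j} (X_j - X_j Z_j)/2,   a_j^dag = Z_{<j} (X_j + X_j Z_j)/2.
#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct PKey {
  uint64_t x0, x1, z0, z1;
  bool operator==(const PKey& o) const {
    return x0 == o.x0 && x1 == o.x1 && z0 == o.z0 && z1 == o.z1;
  }
};
struct PKeyHash {
  size_t operator()(const PKey& k) const {
    auto mix = [](uint64_t v) {
      v += 0x9e3779b97f4a7c15ULL;
      v = (v ^ (v >> 30)) * 0xbf58476d1ce4e5b9ULL;
      v = (v ^ (v >> 27)) * 0x94d049bb133111ebULL;
      return v ^ (v >> 31);
    };
    return mix(k.x0 ^ mix(k.x1 ^ mix(k.z0 ^ mix(k.z1))));
  }
};

static inline int parity128(uint64_t a0, uint64_t a1) {
  return (__builtin_popcountll(a0) + __builtin_popcountll(a1)) & 1;
}
static inline void setbit(uint64_t& m0, uint64_t& m1, int j) {
  if (j < 64) m0 |= (1ULL << j); else m1 |= (1ULL << (j - 64));
}
static inline void chainbits(uint64_t& m0, uint64_t& m1, int j) {
  // bits 0..j-1
  if (j <= 0) { m0 = m1 = 0; return; }
  if (j < 64) { m0 = (1ULL << j) - 1; m1 = 0; }
  else if (j == 64) { m0 = ~0ULL; m1 = 0; }
  else { m0 = ~0ULL; m1 = (j == 128) ? ~0ULL : ((1ULL << (j - 64)) - 1); }
}

typedef std::unordered_map<PKey, std::complex<double>, PKeyHash> PMap;

struct WTerm {
  PKey k;
  std::complex<double> c;
};

// multiply accumulated term by W(xw, zw) with sign
static inline void wmul(WTerm& t, uint64_t xw0, uint64_t xw1, uint64_t zw0,
                        uint64_t zw1, double sgn) {
  if (parity128(t.k.z0 & xw0, t.k.z1 & xw1)) sgn = -sgn;
  t.k.x0 ^= xw0; t.k.x1 ^= xw1; t.k.z0 ^= zw0; t.k.z1 ^= zw1;
  t.c *= sgn;
}

// expand a product of ladder operators (qubit indices, dagger flags) times
// coeff into the accumulator map
static void add_ladder_product(PMap& acc, const int* qubits, const int* dagger,
                               int nops, std::complex<double> coeff) {
  WTerm terms[16];
  int nt = 1;
  terms[0].k = PKey{0, 0, 0, 0};
  terms[0].c = coeff;
  for (int o = 0; o < nops; ++o) {
    int j = qubits[o];
    uint64_t ch0, ch1, e0 = 0, e1 = 0;
    chainbits(ch0, ch1, j);
    setbit(e0, e1, j);
    double s2 = dagger[o] ? 1.0 : -1.0;  // sign of the XZ component
    for (int t = nt - 1; t >= 0; --t) {
      WTerm t2 = terms[t];
      // component 1: W(e, chain) * 1/2
      wmul(terms[t], e0, e1, ch0, ch1, 0.5);
      // component 2: W(e, chain ^ e) * (+-1/2)
      wmul(t2, e0, e1, ch0 ^ e0, ch1 ^ e1, 0.5 * s2);
      terms[nt + t] = t2;  // placed after current block
    }
    // interleave: we appended second components at offset nt
    nt *= 2;
  }
  for (int t = 0; t < nt; ++t) {
    auto it = acc.find(terms[t].k);
    if (it == acc.end()) acc.emplace(terms[t].k, terms[t].c);
    else it->second += terms[t].c;
  }
}

// convert accumulated W-frame map into (labels, coeffs);
// XZ = -iY per qubit, so W(x,z) = (-i)^{nY} P  =>  coeff_P = coeff_W * (-i)^{nY}.
static std::string key_label(const PKey& k, int n_qubits, int& ny) {
  std::string lab;
  ny = 0;
  for (int j = 0; j < n_qubits; ++j) {
    int xb = j < 64 ? ((k.x0 >> j) & 1) : ((k.x1 >> (j - 64)) & 1);
    int zb = j < 64 ? ((k.z0 >> j) & 1) : ((k.z1 >> (j - 64)) & 1);
    if (!xb && !zb) continue;
    char op = xb && zb ? 'Y' : (xb ? 'X' : 'Z');
    if (op == 'Y') ++ny;
    if (!lab.empty()) lab += ' ';
    lab += op;
    lab += std::to_string(j);
  }
  return lab;
}

static void accumulate_hamiltonian(PMap& acc, const arma::mat& h,
                                   const double* g, int n, double tiny) {
  // one-body: sum_pq,sigma h_pq adag_{p sigma} a_{q sigma}
  for (int p = 0; p < n; ++p)
    for (int q = 0; q < n; ++q) {
      if (std::abs(h(p, q)) < tiny) continue;
      for (int sp = 0; sp < 2; ++sp) {
        int qu[2] = {2 * p + sp, 2 * q + sp};
        int dg[2] = {1, 0};
        add_ladder_product(acc, qu, dg, 2, h(p, q));
      }
    }
  // two-body: 1/2 sum (pq|rs) adag_{p s1} adag_{r s2} a_{s s2} a_{q s1}
  auto G = [g, n](int p, int q, int r, int s) {
    return g[(((size_t)p * n + q) * n + r) * n + s];
  };
  for (int p = 0; p < n; ++p)
    for (int q = 0; q < n; ++q)
      for (int r = 0; r < n; ++r)
        for (int s = 0; s < n; ++s) {
          double v = G(p, q, r, s);
          if (std::abs(v) < tiny) continue;
          for (int s1 = 0; s1 < 2; ++s1)
            for (int s2 = 0; s2 < 2; ++s2) {
              int P = 2 * p + s1, R = 2 * r + s2, S = 2 * s + s2, Q = 2 * q + s1;
              if (P == R || S == Q) continue;  // adag adag / a a collision
              int qu[4] = {P, R, S, Q};
              int dg[4] = {1, 1, 0, 0};
              add_ladder_product(acc, qu, dg, 4, 0.5 * v);
            }
        }
}

// [[Rcpp::export]]
List cpp_jw_hamiltonian(NumericMatrix h_, NumericVector g_, double core_energy,
                        double cutoff, bool count_only = false) {
  int n = h_.nrow();
  int n_qubits = 2 * n;
  if (n_qubits > 128) stop("more than 128 qubits not supported");
  arma::mat h(h_.begin(), n, n, false);
  PMap acc;
  acc.reserve(1 << 14);
  accumulate_hamiltonian(acc, h, g_.begin(), n, 1e-15);
  // identity term -> offset
  double offset = core_energy;
  PKey id{0, 0, 0, 0};
  auto it = acc.find(id);
  if (it != acc.end()) {
    offset += it->second.real();
    acc.erase(it);
  }
  R_xlen_t kept = 0;
  double max_imag = 0.0;
  std::vector<std::string> labels;
  std::vector<double> coefs;
  const std::complex<double> mI(0, -1);
  for (auto& kv : acc) {
    std::complex<double> cW = kv.second;
    if (std::abs(cW) <= cutoff) continue;
    ++kept;
    if (count_only) continue;
    int ny = 0;
    std::string lab = key_label(kv.first, n_qubits, ny);
    std::complex<double> cP = cW;
    for (int t = 0; t < (ny & 3); ++t) cP *= mI;
    max_imag = std::max(max_imag, std::abs(cP.imag()));
    labels.push_back(lab);
    coefs.push_back(cP.real());
  }
  if (count_only)
    return List::create(_["n_terms"] = (double)kept, _["offset"] = offset);
  return List::create(_["labels"] = wrap(labels), _["coefs"] = wrap(coefs),
                      _["offset"] = offset, _["n_qubits"] = n_qubits,
                      _["max_imag"] = max_imag);
}

// JW expansion of a single product of ladder operators (for cluster
// operators); returns complex coefficients in the Pauli (not XZ) frame.
// [[Rcpp::export]]
List cpp_jw_ladder(IntegerVector qubits, IntegerVector dagger, int n_qubits) {
  PMap acc;
  add_ladder_product(acc, qubits.begin(), dagger.begin(), qubits.size(), 1.0);
  std::vector<std::string> labels;
  std::vector<std::complex<double> > coefs;
  const std::complex<double> mI(0, -1);
  for (auto& kv : acc) {
    if (std::abs(kv.second) < 1e-15) continue;
    int ny = 0;
    labels.push_back(key_label(kv.first, n_qubits, ny));
    std::complex<double> cP = kv.second;
    for (int t = 0; t < (ny & 3); ++t) cP *= mI;
    coefs.push_back(cP);
  }
  return List::create(_["labels"] = wrap(labels), _["coefs"] = wrap(coefs));
}

// ---- dense validation helpers -------------------------------------------

// encode ops: integer matrix n_terms x n_qubits with 0=I,1=X,2=Y,3=Z
// dense basis-state convention: qubit 0 is the MOST significant bit of the
// state index (qubit n-1 is bit 0)
static void term_masks(const IntegerMatrix& ops, int t, uint64_t& x,
                       uint64_t& z, int& ny) {
  x = z = 0; ny = 0;
  int nq = ops.ncol();
  for (int j = 0; j < nq; ++j) {
    uint64_t bit = 1ULL << (nq - 1 - j);
    switch (ops(t, j)) {
      case 1: x |= bit; break;
      case 2: x |= bit; z |= bit; ++ny; break;
      case 3: z |= bit; break;
      default: break;
    }
  }
}

// y convention: P = i^{nY} ... W(x,z) = (-i)^{nY} P so applying P to a basis
// state via masks needs the i^{nY} correction.
// W(x,z)|b> = (-1)^{popcount(z & b)} |b ^ x>.

// apply the Pauli-sum operator to vector v (2^n), matrix-free
static void pauli_apply(const IntegerMatrix& ops, const NumericVector& coefs,
                        double offset, const arma::cx_vec& v, arma::cx_vec& out) {
  int nq = ops.ncol();
  size_t dim = (size_t)1 << nq;
  out = offset * v;
  const std::complex<double> I(0, 1);
  for (int t = 0; t < ops.nrow(); ++t) {
    uint64_t x, z; int ny;
    term_masks(ops, t, x, z, ny);
    std::complex<double> ph = coefs[t];
    for (int k = 0; k < (ny & 3); ++k) ph *= I;
    for (size_t b = 0; b < dim; ++b) {
      double sgn = (__builtin_popcountll(z & b) & 1) ? -1.0 : 1.0;
      out[b ^ x] += ph * sgn * v[b];
    }
  }
}

// [[Rcpp::export]]
arma::cx_vec cpp_pauli_apply(IntegerMatrix ops, NumericVector coefs,
                             double offset, arma::cx_vec v) {
  arma::cx_vec out;
  pauli_apply(ops, coefs, offset, v, out);
  return out;
}

// Lanczos ground state of a Hermitian Pauli-sum operator (matrix-free,
// full reorthogonalization); returns eigenvalue and eigenvector.
// [[Rcpp::export]]
List cpp_pauli_ground_state(IntegerMatrix ops, NumericVector coefs,
                            double offset, int max_iter = 300,
                            double tol = 1e-14) {
  int nq = ops.ncol();
  if (nq > 24) stop("dense ground-state solver limited to 24 qubits");
  size_t dim = (size_t)1 << nq;
  arma::cx_vec v(dim, arma::fill::zeros);
  // deterministic start with support everywhere
  for (size_t b = 0; b < dim; ++b)
    v[b] = std::complex<double>(1.0 + std::cos(0.7 * (double)b),
                                0.3 + std::sin(0.3 * (double)b));
  v /= arma::norm(v);
  std::vector<arma::cx_vec> V;
  std::vector<double> alpha, beta;
  arma::cx_vec w;
  double e_prev = 1e300, e_curr = 0.0;
  arma::vec evals; arma::mat evecs;
  int m = 0;
  for (int it = 0; it < max_iter; ++it) {
    V.push_back(v);
    pauli_apply(ops, coefs, offset, v, w);
    double a = std::real(arma::cdot(v, w));
    alpha.push_back(a);
    w -= a * v;
    if (it > 0) w -= beta.back() * V[it - 1];
    // full reorthogonalization
    for (size_t k = 0; k < V.size(); ++k) w -= arma::cdot(V[k], w) * V[k];
    double b = arma::norm(w);
    m = it + 1;
    // tridiagonal eigensolve
    arma::mat Tm(m, m, arma::fill::zeros);
    for (int i = 0; i < m; ++i) {
      Tm(i, i) = alpha[i];
      if (i + 1 < m) Tm(i, i + 1) = Tm(i + 1, i) = beta[i];
    }
    arma::eig_sym(evals, evecs, Tm);
    e_curr = evals(0);
    if (std::abs(e_curr - e_prev) < tol * std::max(1.0, std::abs(e_curr)) &&
        it > 5) break;
    e_prev = e_curr;
    if (b < 1e-13 || (size_t)m >= dim) break;
    beta.push_back(b);
    v = w / b;
  }
  arma::cx_vec gs(dim, arma::fill::zeros);
  for (int i = 0; i < m; ++i) gs += evecs(i, 0) * V[i];
  gs /= arma::norm(gs);
  // Rayleigh-quotient polish in long double accumulation
  pauli_apply(ops, coefs, offset, gs, w);
  long double num_r = 0.0L, den = 0.0L;
  for (size_t b = 0; b < dim; ++b) {
    num_r += (long double)std::real(std::conj(gs[b]) * w[b]);
    den += (long double)std::norm(gs[b]);
  }
  double e_refined = (double)(num_r / den);
  return List::create(_["value"] = e_refined, _["vector"] = gs,
                      _["lanczos_dim"] = m);
}
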