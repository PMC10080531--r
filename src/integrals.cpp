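// Molecular integrals over contracted Cartesian Gaussians (s, p, d shells)
// via the McMurchie-Davidson scheme: Hermite expansion coefficients E_t^{ij},
// Hermite Coulomb integrals R_{tuv} built on the Boys function.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// Boys function F_m(T) for m = 0..mmax, written into F.
static void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2 * m + 1) - T / (2 * m + 3);
    return;
  }
  if (T <= 35.0) {
    // series at the top order, then stable downward recursion
    double term = 1.0 / (2 * mmax + 1), sum = term;
    int k = 1;
    while (term > 1e-17 * sum && k < 300) {
      term *= 2.0 * T / (2 * mmax + 2 * k + 1);
      sum += term;
      ++k;
    }
    double eT = std::exp(-T);
    F[mmax] = eT * sum;
    for (int m = mmax - 1; m >= 0; --m)
      F[m] = (2.0 * T * F[m + 1] + eT) / (2 * m + 1);
  } else {
    double eT = std::exp(-T);
    F[0] = 0.5 * std::sqrt(PI / T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2 * m + 1) * F[m] - eT) / (2.0 * T);
  }
}

// Hermite expansion coefficients for one Cartesian direction.
// E[t] for given (i, j); recursion over i then j. lmax <= 2 so sizes are tiny.
struct ETab {
  // E[i][j][t], i,j <= 4 (need i+2 for kinetic), t <= i+j
  double E[7][7][13];
};

static void build_E(double a, double b, double AB, int imax, int jmax, ETab& tab) {
  double p = a + b, mu = a * b / p;
  double XPA = -b * AB / p;  // P - A where AB = A - B
  double XPB = a * AB / p;   // P - B
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j <= jmax; ++j)
      for (int t = 0; t <= 12; ++t) tab.E[i][j][t] = 0.0;
  tab.E[0][0][0] = std::exp(-mu * AB * AB);
  for (int i = 1; i <= imax; ++i)
    for (int t = 0; t <= i; ++t) {
      double v = 0.0;
      if (t > 0) v += tab.E[i - 1][0][t - 1] / (2.0 * p);
      v += XPA * tab.E[i - 1][0][t];
      v += (t + 1) * tab.E[i - 1][0][t + 1];
      tab.E[i][0][t] = v;
    }
  for (int j = 1; j <= jmax; ++j)
    for (int i = 0; i <= imax; ++i)
      for (int t = 0; t <= i + j; ++t) {
        double v = 0.0;
        if (t > 0) v += tab.E[i][j - 1][t - 1] / (2.0 * p);
        v += XPB * tab.E[i][j - 1][t];
        v += (t + 1) * tab.E[i][j - 1][t + 1];
        tab.E[i][j][t] = v;
      }
}

// Hermite Coulomb integrals R_{tuv} = R^0_{tuv}(p, PC).
static void build_R(int tmax, int umax, int vmax, double p, const double* PC,
                    double* R, int su, int sv) {
  // R indexed R[t*su + u*sv + v]; helper with auxiliary order built in 4D
  int nmax = tmax + umax + vmax;
  double T = p * (PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2]);
  std::vector<double> F(nmax + 1);
  boys(nmax, T, F.data());
  // Rn[n][t][u][v]
  static thread_local double Rn[13][13][13][13];
  for (int n = nmax; n >= 0; --n) {
    double f = 1.0;
    for (int k = 0; k < n; ++k) f *= -2.0 * p;
    Rn[n][0][0][0] = f * F[n];
  }
  for (int tot = 1; tot <= nmax; ++tot)
    for (int t = 0; t <= std::min(tot, tmax); ++t)
      for (int u = 0; u <= std::min(tot - t, umax); ++u) {
        int v = tot - t - u;
        if (v < 0 || v > vmax) continue;
        for (int n = 0; n <= nmax - tot; ++n) {
          double val;
          if (t > 0) {
            val = (t - 1 > 0 ? (t - 1) * Rn[n + 1][t - 2][u][v] : 0.0) +
                  PC[0] * Rn[n + 1][t - 1][u][v];
          } else if (u > 0) {
            val = (u - 1 > 0 ? (u - 1) * Rn[n + 1][t][u - 2][v] : 0.0) +
                  PC[1] * Rn[n + 1][t][u - 1][v];
          } else {
            val = (v - 1 > 0 ? (v - 1) * Rn[n + 1][t][u][v - 2] : 0.0) +
                  PC[2] * Rn[n + 1][t][u][v - 1];
          }
          Rn[n][t][u][v] = val;
        }
      }
  for (int t = 0; t <= tmax; ++t)
    for (int u = 0; u <= umax; ++u)
      for (int v = 0; v <= vmax; ++v) R[t * su + u * sv + v] = Rn[0][t][u][v];
}

static double dfact(int n) {  // (2n-1)!! with n>=0 -> 1,1,3,15
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

struct BasisFn {
  double center[3];
  int l[3];  // Cartesian powers
  std::vector<double> exps, coefs;  // coefs include primitive norms
};

// Cartesian component ordering per shell
static const int CART[3][6][3] = {
    {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {0, 0, 0}},
    {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {0, 0, 0}, {0, 0, 0}, {0, 0, 0}},
    {{2, 0, 0}, {1, 1, 0}, {1, 0, 1}, {0, 2, 0}, {0, 1, 1}, {0, 0, 2}}};
static const int NCART[3] = {1, 3, 6};

static std::vector<BasisFn> expand_shells(const List& shells) {
  std::vector<BasisFn> fns;
  for (int s = 0; s < shells.size(); ++s) {
    List sh = shells[s];
    int l = as<int>(sh["l"]);
    NumericVector ctr = sh["center"];
    NumericVector ex = sh["exps"];
    NumericVector cf = sh["coefs"];
    // primitive norms for reference component (l,0,0)
    std::vector<double> c0(ex.size());
    for (int i = 0; i < ex.size(); ++i) {
      double a = ex[i];
      c0[i] = cf[i] * std::pow(2.0 * a / PI, 0.75) *
              std::pow(4.0 * a, 0.5 * l) / std::sqrt(dfact(l));
    }
    // rescale so the reference component has unit self-overlap
    double s00 = 0.0;
    for (size_t i = 0; i < c0.size(); ++i)
      for (size_t j = 0; j < c0.size(); ++j) {
        double a = ex[i], b = ex[j], p = a + b;
        // 1D overlap of (l,0,0)x(l,0,0) on same center times (pi/p)^{3/2}
        double s1 = dfact(l) / std::pow(2.0 * p, l) * std::sqrt(PI / p);
        double s0 = std::sqrt(PI / p);
        s00 += c0[i] * c0[j] * s1 * s0 * s0;
      }
    double scale = 1.0 / std::sqrt(s00);
    for (int comp = 0; comp < NCART[l]; ++comp) {
      BasisFn f;
      for (int d = 0; d < 3; ++d) {
        f.center[d] = ctr[d];
        f.l[d] = CART[l][comp][d];
      }
      // component norm correction relative to reference
      double corr = std::sqrt(dfact(l) / (dfact(f.l[0]) * dfact(f.l[1]) * dfact(f.l[2])));
      f.exps.assign(ex.begin(), ex.end());
      f.coefs.resize(ex.size());
      for (int i = 0; i < ex.size(); ++i) f.coefs[i] = c0[i] * scale * corr;
      fns.push_back(f);
    }
  }
  return fns;
}

// one-electron integrals: overlap, kinetic, nuclear attraction
// [[Rcpp::export]]
List cpp_one_electron(List shells, NumericMatrix atom_coords, NumericVector atom_charges) {
  std::vector<BasisFn> bf = expand_shells(shells);
  int n = bf.size();
  arma::mat S(n, n, arma::fill::zeros), T(n, n, arma::fill::zeros),
      V(n, n, arma::fill::zeros);
  int natom = atom_coords.nrow();
  for (int p = 0; p < n; ++p)
    for (int q = p; q < n; ++q) {
      const BasisFn &A = bf[p], &B = bf[q];
      double Sv = 0, Tv = 0, Vv = 0;
      for (size_t ia = 0; ia < A.exps.size(); ++ia)
        for (size_t ib = 0; ib < B.exps.size(); ++ib) {
          double a = A.exps[ia], b = B.exps[ib], pp = a + b;
          double cc = A.coefs[ia] * B.coefs[ib];
          ETab E[3];
          for (int d = 0; d < 3; ++d)
            build_E(a, b, A.center[d] - B.center[d], A.l[d] + 2, B.l[d] + 2, E[d]);
          double fac = std::pow(PI / pp, 1.5);
          // overlap 1D factors
          double sx = E[0].E[A.l[0]][B.l[0]][0];
          double sy = E[1].E[A.l[1]][B.l[1]][0];
          double sz = E[2].E[A.l[2]][B.l[2]][0];
          Sv += cc * fac * sx * sy * sz;
          // kinetic 1D factors
          double tf[3];
          for (int d = 0; d < 3; ++d) {
            int i = A.l[d], j = B.l[d];
            double t = -2.0 * b * b * E[d].E[i][j + 2][0] +
                       b * (2 * j + 1) * E[d].E[i][j][0];
            if (j >= 2) t -= 0.5 * j * (j - 1) * E[d].E[i][j - 2][0];
            tf[d] = t;
          }
          Tv += cc * fac * (tf[0] * sy * sz + sx * tf[1] * sz + sx * sy * tf[2]);
          // nuclear attraction
          double P[3];
          for (int d = 0; d < 3; ++d)
            P[d] = (a * A.center[d] + b * B.center[d]) / pp;
          int tmax = A.l[0] + B.l[0], umax = A.l[1] + B.l[1], vmax = A.l[2] + B.l[2];
          std::vector<double> R((tmax + 1) * (umax + 1) * (vmax + 1));
          for (int at = 0; at < natom; ++at) {
            double PC[3] = {P[0] - atom_coords(at, 0), P[1] - atom_coords(at, 1),
                            P[2] - atom_coords(at, 2)};
            build_R(tmax, umax, vmax, pp, PC, R.data(), (umax + 1) * (vmax + 1),
                    vmax + 1);
            double acc = 0.0;
            for (int t = 0; t <= tmax; ++t)
              for (int u = 0; u <= umax; ++u)
                for (int v = 0; v <= vmax; ++v)
                  acc += E[0].E[A.l[0]][B.l[0]][t] * E[1].E[A.l[1]][B.l[1]][u] *
                         E[2].E[A.l[2]][B.l[2]][v] *
                         R[t * (umax + 1) * (vmax + 1) + u * (vmax + 1) + v];
            Vv -= atom_charges[at] * cc * (2.0 * PI / pp) * acc;
          }
        }
      S(p, q) = S(q, p) = Sv;
      T(p, q) = T(q, p) = Tv;
      V(p, q) = V(q, p) = Vv;
    }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V, _["nbf"] = n);
}

// precomputed data for one ordered basis-function pair
struct PairData {
  int p, q;
  struct Prim {
    double p;         // exponent sum
    double P[3];      // Gaussian product center
    double coef;      // contraction coefficient product
    double E[3][13];  // E_t factors for fixed (la, lb), per direction
    int tmax[3];
  };
  std::vector<Prim> prims;
};

static void make_pair(const BasisFn& A, const BasisFn& B, PairData& pd) {
  for (size_t ia = 0; ia < A.exps.size(); ++ia)
    for (size_t ib = 0; ib < B.exps.size(); ++ib) {
      double a = A.exps[ia], b = B.exps[ib], pp = a + b;
      PairData::Prim pr;
      pr.p = pp;
      pr.coef = A.coefs[ia] * B.coefs[ib];
      double screen = 1.0;
      for (int d = 0; d < 3; ++d) {
        pr.P[d] = (a * A.center[d] + b * B.center[d]) / pp;
        ETab E;
        build_E(a, b, A.center[d] - B.center[d], A.l[d], B.l[d], E);
        pr.tmax[d] = A.l[d] + B.l[d];
        for (int t = 0; t <= pr.tmax[d]; ++t) pr.E[d][t] = E.E[A.l[d]][B.l[d]][t];
        screen *= E.E[0][0][0];
      }
      if (std::abs(pr.coef) * std::abs(screen) < 1e-16) continue;
      pd.prims.push_back(pr);
    }
}

// two-electron repulsion integrals, chemists' notation (pq|rs), full n^4 array
// [[Rcpp::export]]
NumericVector cpp_eri(List shells) {
  std::vector<BasisFn> bf = expand_shells(shells);
  int n = bf.size();
  std::vector<PairData> pairs;
  std::vector<std::vector<int> > pidx(n, std::vector<int>(n, -1));
  for (int p = 0; p < n; ++p)
    for (int q = p; q < n; ++q) {
      PairData pd;
      pd.p = p;
      pd.q = q;
      make_pair(bf[p], bf[q], pd);
      pidx[p][q] = pairs.size();
      pairs.push_back(pd);
    }
  NumericVector out((R_xlen_t)n * n * n * n);
  double* g = out.begin();
  auto IDX = [n](int p, int q, int r, int s) -> R_xlen_t {
    return (((R_xlen_t)p * n + q) * n + r) * n + s;
  };
  double R[13 * 13 * 13];
  for (int p = 0; p < n; ++p)
    for (int q = p; q < n; ++q) {
      const PairData& AB = pairs[pidx[p][q]];
      for (int r = p; r < n; ++r)
        for (int s = (r == p ? q : r); s < n; ++s) {
          const PairData& CD = pairs[pidx[r][s]];
          double val = 0.0;
          for (const auto& pr1 : AB.prims)
            for (const auto& pr2 : CD.prims) {
              double pp = pr1.p, qq = pr2.p;
              double alpha = pp * qq / (pp + qq);
              double PQ[3] = {pr1.P[0] - pr2.P[0], pr1.P[1] - pr2.P[1],
                              pr1.P[2] - pr2.P[2]};
              int tm = pr1.tmax[0] + pr2.tmax[0], um = pr1.tmax[1] + pr2.tmax[1],
                  vm = pr1.tmax[2] + pr2.tmax[2];
              build_R(tm, um, vm, alpha, PQ, R, (um + 1) * (vm + 1), vm + 1);
              double acc = 0.0;
              for (int t1 = 0; t1 <= pr1.tmax[0]; ++t1)
                for (int u1 = 0; u1 <= pr1.tmax[1]; ++u1)
                  for (int v1 = 0; v1 <= pr1.tmax[2]; ++v1) {
                    double e1 = pr1.E[0][t1] * pr1.E[1][u1] * pr1.E[2][v1];
                    if (e1 == 0.0) continue;
                    for (int t2 = 0; t2 <= pr2.tmax[0]; ++t2)
                      for (int u2 = 0; u2 <= pr2.tmax[1]; ++u2)
                        for (int v2 = 0; v2 <= pr2.tmax[2]; ++v2) {
                          double e2 = pr2.E[0][t2] * pr2.E[1][u2] * pr2.E[2][v2];
                          if (e2 == 0.0) continue;
                          double sgn = ((t2 + u2 + v2) % 2) ? -1.0 : 1.0;
                          acc += e1 * e2 * sgn *
                                 R[(t1 + t2) * (um + 1) * (vm + 1) +
                                   (u1 + u2) * (vm + 1) + (v1 + v2)];
                        }
                  }
              val += pr1.coef * pr2.coef * 2.0 * std::pow(PI, 2.5) /
                     (pp * qq * std::sqrt(pp + qq)) * acc;
            }
          // 8-fold symmetry images
          g[IDX(p, q, r, s)] = g[IDX(q, p, r, s)] = g[IDX(p, q, s, r)] =
              g[IDX(q, p, s, r)] = g[IDX(r, s, p, q)] = g[IDX(s, r, p, q)] =
                  g[IDX(r, s, q, p)] = g[IDX(s, r, q, p)] = val;
        }
    }
  return out;
}

// AO -> MO transform of the two-electron array (chemists' notation kept).
// [[Rcpp::export]]
NumericVector cpp_ao2mo(NumericVector g_ao, NumericMatrix C_) {
  int n = C_.nrow(), m = C_.ncol();
  arma::mat C(C_.begin(), n, m, false);
  // g[(p,q,r,s)] with s fastest: treat as matrix (pqr) x s etc., 4 quarter steps
  arma::vec g(g_ao.begin(), (R_xlen_t)n * n * n * n, false);
  // step 1: transform s index
  arma::mat G1 = arma::reshape(g, n, (R_xlen_t)n * n * n);  // s x (r,q,p)
  arma::mat H1 = C.t() * G1;                                // m x (r,q,p)
  // step 2: r index: reshape to r x (q,p,S)
  arma::mat H1r = arma::reshape(H1.t(), n, (R_xlen_t)n * n * m);
  arma::mat H2 = C.t() * H1r;  // m x (q,p,S)
  // step 3: q
  arma::mat H2r = arma::reshape(H2.t(), n, (R_xlen_t)n * m * m);
  arma::mat H3 = C.t() * H2r;  // m x (p,S,R)
  // step 4: p
  arma::mat H3r = arma::reshape(H3.t(), n, (R_xlen_t)m * m * m);
  arma::mat H4 = C.t() * H3r;  // m x (S,R,Q)
  // H4(P, (S,R,Q)) ; want out[(P,Q,R,S)] with S fastest: out = t(H4) reshaped
  arma::mat H4t = H4.t();  // (S,R,Q) x P
  NumericVector out((R_xlen_t)m * m * m * m);
  double* o = out.begin();
  R_xlen_t idx = 0;
  // H4t linear index: s + m*r + m*m*q  (rows), col p
  for (R_xlen_t p = 0; p < m; ++p)
    for (R_xlen_t q = 0; q < m; ++q)
      for (R_xlen_t r = 0; r < m; ++r)
        for (R_xlen_t s = 0; s < m; ++s)
          o[idx++] = H4t(s + m * r + m * m * q, p);
  return out;
}
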