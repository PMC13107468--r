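// Gaussian integral engine: McMurchie-Davidson recurrences over contracted
// Cartesian shells, with per-shell transformation to (normalized) real solid
// harmonics supplied from the R side.  All lengths in Bohr, energies Hartree.
//
// Conventions
//   - Cartesian components of a shell of angular momentum l are enumerated
//     lx = l..0, ly = (l-lx)..0, lz = l-lx-ly (x-major).
//   - AO pair packing: for mu >= nu (0-based), pid = mu(mu+1)/2 + nu.
//   - Packed ERI: for pid >= qid, eid = pid(pid+1)/2 + qid.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double M_PI_ = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys F_m(T)
static void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0) - T / (2.0 * m + 3.0);
    return;
  }
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI_ / T);
    double invT = 1.0 / T;
    for (int m = 0; m < mmax; ++m) F[m + 1] = F[m] * (m + 0.5) * invT;
    return;
  }
  double e = std::exp(-T);
  double term = 1.0 / (2.0 * mmax + 1.0), sum = term;
  for (int k = 1; k < 20000; ++k) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0);
    sum += term;
    if (term < sum * 1e-17) break;
  }
  F[mmax] = e * sum;
  for (int m = mmax; m > 0; --m) F[m - 1] = (2.0 * T * F[m] + e) / (2.0 * m - 1.0);
}

// ------------------------------------------------- Hermite E coefficients, 1D
// E[(i*(lb+1)+j)*tdim + t] for i<=la, j<=lb, t<=i+j; tdim >= la+lb+1.
static void ecoefs(int la, int lb, double a, double b, double A, double B,
                   double* E, int tdim) {
  const double p = a + b, invp2 = 0.5 / p;
  const double mu = a * b / p;
  const double P = (a * A + b * B) / p;
  const double PA = P - A, PB = P - B;
  const int nj = lb + 1;
  std::fill(E, E + (la + 1) * nj * tdim, 0.0);
  E[0] = std::exp(-mu * (A - B) * (A - B));
  for (int i = 0; i < la; ++i) {
    for (int t = 0; t <= i + 1; ++t) {
      double v = PA * E[(i * nj) * tdim + t];
      if (t > 0) v += invp2 * E[(i * nj) * tdim + t - 1];
      if (t + 1 <= i) v += (t + 1.0) * E[(i * nj) * tdim + t + 1];
      E[((i + 1) * nj) * tdim + t] = v;
    }
  }
  for (int j = 0; j < lb; ++j) {
    for (int i = 0; i <= la; ++i) {
      for (int t = 0; t <= i + j + 1; ++t) {
        double v = PB * E[(i * nj + j) * tdim + t];
        if (t > 0) v += invp2 * E[(i * nj + j) * tdim + t - 1];
        if (t + 1 <= i + j) v += (t + 1.0) * E[(i * nj + j) * tdim + t + 1];
        E[(i * nj + j + 1) * tdim + t] = v;
      }
    }
  }
}

// --------------------------------------------------------- Hermite R_{tuv}
// R[(t*(L+1)+u)*(L+1)+v] = R^{(0)}_{tuv}(p, X, Y, Z)
static void rtensor(int L, double p, double X, double Y, double Z, double* R,
                    double* scratch /* (L+1)^4 */) {
  const int d = L + 1;
  double T = p * (X * X + Y * Y + Z * Z);
  std::vector<double> F(d);
  boys(L, T, F.data());
  // scratch[n][t][u][v]
  auto idx = [d](int n, int t, int u, int v) {
    return ((n * d + t) * d + u) * d + v;
  };
  std::fill(scratch, scratch + (size_t)d * d * d * d, 0.0);
  double pw = 1.0;
  for (int n = 0; n <= L; ++n) { scratch[idx(n, 0, 0, 0)] = pw * F[n]; pw *= -2.0 * p; }
  for (int tot = 1; tot <= L; ++tot) {
    for (int t = 0; t <= tot; ++t)
      for (int u = 0; u <= tot - t; ++u) {
        int v = tot - t - u;
        for (int n = 0; n <= L - tot; ++n) {
          double val;
          if (t > 0) {
            val = X * scratch[idx(n + 1, t - 1, u, v)];
            if (t > 1) val += (t - 1.0) * scratch[idx(n + 1, t - 2, u, v)];
          } else if (u > 0) {
            val = Y * scratch[idx(n + 1, t, u - 1, v)];
            if (u > 1) val += (u - 1.0) * scratch[idx(n + 1, t, u - 2, v)];
          } else {
            val = Z * scratch[idx(n + 1, t, u, v - 1)];
            if (v > 1) val += (v - 1.0) * scratch[idx(n + 1, t, u, v - 2)];
          }
          scratch[idx(n, t, u, v)] = val;
        }
      }
  }
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u <= L - t; ++u)
      for (int v = 0; v <= L - t - u; ++v)
        R[(t * d + u) * d + v] = scratch[idx(0, t, u, v)];
}

// ------------------------------------------------------------------- shells
struct ShellC {
  int l;
  arma::vec ex, cf;        // raw contraction coefficients (primitive norms folded in)
  double cen[3];
  arma::mat Q;             // nsph x ncart transform (normalization folded in)
  int aoff;                // offset in spherical AO basis
  int ncart() const { return (l + 1) * (l + 2) / 2; }
  int nsph() const { return Q.n_rows; }
};

static void cart_components(int l, std::vector<std::array<int, 3>>& comps) {
  comps.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly) comps.push_back({lx, ly, l - lx - ly});
}

static std::vector<ShellC> parse_shells(const List& shells) {
  std::vector<ShellC> out;
  int aoff = 0;
  for (int i = 0; i < shells.size(); ++i) {
    List s = shells[i];
    ShellC sh;
    sh.l = as<int>(s["l"]);
    sh.ex = as<arma::vec>(s["exps"]);
    sh.cf = as<arma::vec>(s["coefs"]);
    NumericVector c = s["center"];
    sh.cen[0] = c[0]; sh.cen[1] = c[1]; sh.cen[2] = c[2];
    sh.Q = as<arma::mat>(s["Q"]);
    sh.aoff = aoff;
    aoff += sh.nsph();
    out.push_back(std::move(sh));
  }
  return out;
}

static int nbf_of(const std::vector<ShellC>& sh) {
  int n = 0;
  for (auto& s : sh) n += s.nsph();
  return n;
}

// ------------------------------------------------- shell-pair primitive data
struct PP {
  double p, P[3], c;           // total exponent, center, contraction weight
  std::vector<double> Ex, Ey, Ez;
};
struct SPair {
  int s1, s2, la, lb, tdim;
  std::vector<PP> pps;
};

static SPair make_pair(const std::vector<ShellC>& sh, int i1, int i2,
                       double prune = 1e-18) {
  const ShellC &a = sh[i1], &b = sh[i2];
  SPair sp;
  sp.s1 = i1; sp.s2 = i2; sp.la = a.l; sp.lb = b.l;
  sp.tdim = a.l + b.l + 1;
  double AB2 = 0;
  for (int d = 0; d < 3; ++d) AB2 += (a.cen[d] - b.cen[d]) * (a.cen[d] - b.cen[d]);
  int esz = (a.l + 1) * (b.l + 1) * sp.tdim;
  for (arma::uword ia = 0; ia < a.ex.n_elem; ++ia)
    for (arma::uword ib = 0; ib < b.ex.n_elem; ++ib) {
      double ea = a.ex(ia), eb = b.ex(ib);
      double p = ea + eb, mu = ea * eb / p;
      double K = std::exp(-mu * AB2);
      double c = a.cf(ia) * b.cf(ib);
      if (std::abs(c) * K < prune) continue;
      PP pp;
      pp.p = p; pp.c = c;
      for (int d = 0; d < 3; ++d) pp.P[d] = (ea * a.cen[d] + eb * b.cen[d]) / p;
      pp.Ex.resize(esz); pp.Ey.resize(esz); pp.Ez.resize(esz);
      ecoefs(a.l, b.l, ea, eb, a.cen[0], b.cen[0], pp.Ex.data(), sp.tdim);
      ecoefs(a.l, b.l, ea, eb, a.cen[1], b.cen[1], pp.Ey.data(), sp.tdim);
      ecoefs(a.l, b.l, ea, eb, a.cen[2], b.cen[2], pp.Ez.data(), sp.tdim);
      sp.pps.push_back(std::move(pp));
    }
  return sp;
}

// single shell as a "pair" with a unit dummy s partner (for 2c/3c integrals)
static SPair make_single(const std::vector<ShellC>& sh, int i1) {
  const ShellC& a = sh[i1];
  SPair sp;
  sp.s1 = i1; sp.s2 = -1; sp.la = a.l; sp.lb = 0;
  sp.tdim = a.l + 1;
  int esz = (a.l + 1) * sp.tdim;
  for (arma::uword ia = 0; ia < a.ex.n_elem; ++ia) {
    PP pp;
    pp.p = a.ex(ia); pp.c = a.cf(ia);
    for (int d = 0; d < 3; ++d) pp.P[d] = a.cen[d];
    pp.Ex.resize(esz); pp.Ey.resize(esz); pp.Ez.resize(esz);
    ecoefs(a.l, 0, a.ex(ia), 0.0, a.cen[0], a.cen[0], pp.Ex.data(), sp.tdim);
    ecoefs(a.l, 0, a.ex(ia), 0.0, a.cen[1], a.cen[1], pp.Ey.data(), sp.tdim);
    ecoefs(a.l, 0, a.ex(ia), 0.0, a.cen[2], a.cen[2], pp.Ez.data(), sp.tdim);
    sp.pps.push_back(std::move(pp));
  }
  return sp;
}

// ------------------------------------------------------- ERI quartet (cart)
// out has nc1*nc2*nc3*nc4 entries, index (((c1)*nc2+c2)*nc3+c3)*nc4+c4.
static void eri_quartet(const SPair& bra, const SPair& ket,
                        const std::vector<std::array<int, 3>>& cb1,
                        const std::vector<std::array<int, 3>>& cb2,
                        const std::vector<std::array<int, 3>>& ck1,
                        const std::vector<std::array<int, 3>>& ck2,
                        double* out, double* R, double* scratch) {
  const int nc1 = cb1.size(), nc2 = cb2.size(), nc3 = ck1.size(), nc4 = ck2.size();
  const int L = bra.la + bra.lb + ket.la + ket.lb;
  const int d = L + 1;
  const int tb = bra.tdim, tk = ket.tdim;
  const int njb = bra.lb + 1, njk = ket.lb + 1;
  std::fill(out, out + (size_t)nc1 * nc2 * nc3 * nc4, 0.0);
  for (const PP& bp : bra.pps) {
    for (const PP& kp : ket.pps) {
      double alpha = bp.p * kp.p / (bp.p + kp.p);
      rtensor(L, alpha, bp.P[0] - kp.P[0], bp.P[1] - kp.P[1], bp.P[2] - kp.P[2],
              R, scratch);
      double pref = 2.0 * std::pow(M_PI_, 2.5) /
                    (bp.p * kp.p * std::sqrt(bp.p + kp.p)) * bp.c * kp.c;
      size_t idx = 0;
      for (int c1 = 0; c1 < nc1; ++c1)
        for (int c2 = 0; c2 < nc2; ++c2) {
          const int ix = (cb1[c1][0] * njb + cb2[c2][0]) * tb;
          const int iy = (cb1[c1][1] * njb + cb2[c2][1]) * tb;
          const int iz = (cb1[c1][2] * njb + cb2[c2][2]) * tb;
          const int tx = cb1[c1][0] + cb2[c2][0];
          const int ty = cb1[c1][1] + cb2[c2][1];
          const int tz = cb1[c1][2] + cb2[c2][2];
          for (int c3 = 0; c3 < nc3; ++c3)
            for (int c4 = 0; c4 < nc4; ++c4, ++idx) {
              const int jx = (ck1[c3][0] * njk + ck2[c4][0]) * tk;
              const int jy = (ck1[c3][1] * njk + ck2[c4][1]) * tk;
              const int jz = (ck1[c3][2] * njk + ck2[c4][2]) * tk;
              const int sx = ck1[c3][0] + ck2[c4][0];
              const int sy = ck1[c3][1] + ck2[c4][1];
              const int sz = ck1[c3][2] + ck2[c4][2];
              double s = 0.0;
              for (int t = 0; t <= tx; ++t) {
                double ebx = bp.Ex[ix + t];
                if (ebx == 0.0) continue;
                for (int u = 0; u <= ty; ++u) {
                  double eby = bp.Ey[iy + u] * ebx;
                  if (eby == 0.0) continue;
                  for (int v = 0; v <= tz; ++v) {
                    double eb = bp.Ez[iz + v] * eby;
                    if (eb == 0.0) continue;
                    for (int tt = 0; tt <= sx; ++tt) {
                      double ekx = kp.Ex[jx + tt];
                      if (ekx == 0.0) continue;
                      for (int uu = 0; uu <= sy; ++uu) {
                        double eky = kp.Ey[jy + uu] * ekx;
                        if (eky == 0.0) continue;
                        for (int vv = 0; vv <= sz; ++vv) {
                          double ek = kp.Ez[jz + vv] * eky;
                          if (ek == 0.0) continue;
                          double r = R[((t + tt) * d + (u + uu)) * d + (v + vv)];
                          s += ((tt + uu + vv) & 1) ? -eb * ek * r : eb * ek * r;
                        }
                      }
                    }
                  }
                }
              }
              out[idx] += pref * s;
            }
        }
    }
  }
}

// -------------------------------------------- 4-index cart->sph transform
static void transform4(const double* cart, const arma::mat& Q1, const arma::mat& Q2,
                       const arma::mat& Q3, const arma::mat& Q4, double* sph,
                       std::vector<double>& buf1, std::vector<double>& buf2) {
  const int nc1 = Q1.n_cols, nc2 = Q2.n_cols, nc3 = Q3.n_cols, nc4 = Q4.n_cols;
  const int ns1 = Q1.n_rows, ns2 = Q2.n_rows, ns3 = Q3.n_rows, ns4 = Q4.n_rows;
  // stage 1: index 4
  buf1.assign((size_t)nc1 * nc2 * nc3 * ns4, 0.0);
  for (int a = 0; a < nc1 * nc2 * nc3; ++a)
    for (int s = 0; s < ns4; ++s) {
      double acc = 0;
      for (int c = 0; c < nc4; ++c) acc += Q4(s, c) * cart[(size_t)a * nc4 + c];
      buf1[(size_t)a * ns4 + s] = acc;
    }
  // stage 2: index 3
  buf2.assign((size_t)nc1 * nc2 * ns3 * ns4, 0.0);
  for (int a = 0; a < nc1 * nc2; ++a)
    for (int s = 0; s < ns3; ++s)
      for (int b = 0; b < ns4; ++b) {
        double acc = 0;
        for (int c = 0; c < nc3; ++c)
          acc += Q3(s, c) * buf1[((size_t)a * nc3 + c) * ns4 + b];
        buf2[((size_t)a * ns3 + s) * ns4 + b] = acc;
      }
  // stage 3: index 2
  buf1.assign((size_t)nc1 * ns2 * ns3 * ns4, 0.0);
  const int m34 = ns3 * ns4;
  for (int a = 0; a < nc1; ++a)
    for (int s = 0; s < ns2; ++s)
      for (int b = 0; b < m34; ++b) {
        double acc = 0;
        for (int c = 0; c < nc2; ++c)
          acc += Q2(s, c) * buf2[((size_t)a * nc2 + c) * m34 + b];
        buf1[((size_t)a * ns2 + s) * m34 + b] = acc;
      }
  // stage 4: index 1
  const int m234 = ns2 * m34;
  for (int s = 0; s < ns1; ++s)
    for (int b = 0; b < m234; ++b) {
      double acc = 0;
      for (int c = 0; c < nc1; ++c) acc += Q1(s, c) * buf1[(size_t)c * m234 + b];
      sph[(size_t)s * m234 + b] = acc;
    }
}

// ----------------------------------------------------------- one-electron
// [[Rcpp::export]]
List cpp_oneint(List shells) {
  auto sh = parse_shells(shells);
  int N = nbf_of(sh);
  arma::mat S(N, N, arma::fill::zeros), T(N, N, arma::fill::zeros);
  std::vector<std::array<int, 3>> c1, c2;
  for (size_t i = 0; i < sh.size(); ++i) {
    for (size_t j = 0; j <= i; ++j) {
      const ShellC &A = sh[i], &B = sh[j];
      cart_components(A.l, c1);
      cart_components(B.l, c2);
      int la = A.l, lb = B.l, tdim = la + lb + 3;
      int esz = (la + 1) * (lb + 3) * tdim, njb = lb + 3;
      std::vector<double> Ex(esz), Ey(esz), Ez(esz);
      arma::mat Sc(A.ncart(), B.ncart(), arma::fill::zeros), Tc = Sc;
      for (arma::uword ia = 0; ia < A.ex.n_elem; ++ia)
        for (arma::uword ib = 0; ib < B.ex.n_elem; ++ib) {
          double a = A.ex(ia), b = B.ex(ib), p = a + b;
          double c = A.cf(ia) * B.cf(ib);
          ecoefs(la, lb + 2, a, b, A.cen[0], B.cen[0], Ex.data(), tdim);
          ecoefs(la, lb + 2, a, b, A.cen[1], B.cen[1], Ey.data(), tdim);
          ecoefs(la, lb + 2, a, b, A.cen[2], B.cen[2], Ez.data(), tdim);
          double sq = std::sqrt(M_PI_ / p);
          auto s1d = [&](const std::vector<double>& E, int ii, int jj) {
            if (ii < 0 || jj < 0) return 0.0;
            return E[(ii * njb + jj) * tdim] * sq;
          };
          auto k1d = [&](const std::vector<double>& E, int ii, int jj) {
            double v = -2.0 * b * b * s1d(E, ii, jj + 2) +
                       b * (2.0 * jj + 1.0) * s1d(E, ii, jj);
            if (jj >= 2) v -= 0.5 * jj * (jj - 1.0) * s1d(E, ii, jj - 2);
            return v;
          };
          for (size_t p1 = 0; p1 < c1.size(); ++p1)
            for (size_t p2 = 0; p2 < c2.size(); ++p2) {
              double sx = s1d(Ex, c1[p1][0], c2[p2][0]);
              double sy = s1d(Ey, c1[p1][1], c2[p2][1]);
              double sz = s1d(Ez, c1[p1][2], c2[p2][2]);
              double kx = k1d(Ex, c1[p1][0], c2[p2][0]);
              double ky = k1d(Ey, c1[p1][1], c2[p2][1]);
              double kz = k1d(Ez, c1[p1][2], c2[p2][2]);
              Sc(p1, p2) += c * sx * sy * sz;
              Tc(p1, p2) += c * (kx * sy * sz + sx * ky * sz + sx * sy * kz);
            }
        }
      arma::mat Ss = A.Q * Sc * B.Q.t();
      arma::mat Ts = A.Q * Tc * B.Q.t();
      S.submat(A.aoff, B.aoff, A.aoff + Ss.n_rows - 1, B.aoff + Ss.n_cols - 1) = Ss;
      T.submat(A.aoff, B.aoff, A.aoff + Ts.n_rows - 1, B.aoff + Ts.n_cols - 1) = Ts;
      if (i != j) {
        S.submat(B.aoff, A.aoff, B.aoff + Ss.n_cols - 1, A.aoff + Ss.n_rows - 1) = Ss.t();
        T.submat(B.aoff, A.aoff, B.aoff + Ts.n_cols - 1, A.aoff + Ts.n_rows - 1) = Ts.t();
      }
    }
  }
  return List::create(_["S"] = S, _["T"] = T);
}

// overlap block between two separate shell sets (rows: first set)
// [[Rcpp::export]]
arma::mat cpp_cross_overlap(List shellsA, List shellsB) {
  auto sa = parse_shells(shellsA);
  auto sb = parse_shells(shellsB);
  int NA_ = nbf_of(sa), NB_ = nbf_of(sb);
  arma::mat S(NA_, NB_, arma::fill::zeros);
  std::vector<std::array<int, 3>> c1, c2;
  for (size_t i = 0; i < sa.size(); ++i) {
    for (size_t j = 0; j < sb.size(); ++j) {
      const ShellC &A = sa[i], &B = sb[j];
      cart_components(A.l, c1);
      cart_components(B.l, c2);
      int la = A.l, lb = B.l, tdim = la + lb + 1;
      int esz = (la + 1) * (lb + 1) * tdim, njb = lb + 1;
      std::vector<double> Ex(esz), Ey(esz), Ez(esz);
      arma::mat Sc(A.ncart(), B.ncart(), arma::fill::zeros);
      double AB2 = 0;
      for (int d = 0; d < 3; ++d)
        AB2 += (A.cen[d] - B.cen[d]) * (A.cen[d] - B.cen[d]);
      bool touched = false;
      for (arma::uword ia = 0; ia < A.ex.n_elem; ++ia)
        for (arma::uword ib = 0; ib < B.ex.n_elem; ++ib) {
          double a = A.ex(ia), b = B.ex(ib), p = a + b;
          if (a * b / p * AB2 > 40.0) continue;  // overlap < ~4e-18
          touched = true;
          double c = A.cf(ia) * B.cf(ib);
          ecoefs(la, lb, a, b, A.cen[0], B.cen[0], Ex.data(), tdim);
          ecoefs(la, lb, a, b, A.cen[1], B.cen[1], Ey.data(), tdim);
          ecoefs(la, lb, a, b, A.cen[2], B.cen[2], Ez.data(), tdim);
          double sq = std::pow(M_PI_ / p, 1.5);
          for (size_t p1 = 0; p1 < c1.size(); ++p1)
            for (size_t p2 = 0; p2 < c2.size(); ++p2)
              Sc(p1, p2) += c * sq *
                Ex[(c1[p1][0] * njb + c2[p2][0]) * tdim] *
                Ey[(c1[p1][1] * njb + c2[p2][1]) * tdim] *
                Ez[(c1[p1][2] * njb + c2[p2][2]) * tdim];
        }
      if (!touched) continue;
      arma::mat Ss = A.Q * Sc * B.Q.t();
      S.submat(A.aoff, B.aoff, A.aoff + Ss.n_rows - 1,
               B.aoff + Ss.n_cols - 1) = Ss;
    }
  }
  return S;
}

// raw contracted Cartesian self-overlap of one shell (for normalization)
// [[Rcpp::export]]
arma::mat cpp_cart_selfoverlap(List shell) {
  List one = List::create(shell);
  // temporarily bypass Q: caller passes Q = identity(ncart)
  auto sh = parse_shells(one);
  const ShellC& A = sh[0];
  std::vector<std::array<int, 3>> cc;
  cart_components(A.l, cc);
  int la = A.l, tdim = 2 * la + 1, njb = la + 1;
  std::vector<double> Ex((la + 1) * (la + 1) * tdim), Ey(Ex.size()), Ez(Ex.size());
  arma::mat Sc(A.ncart(), A.ncart(), arma::fill::zeros);
  for (arma::uword ia = 0; ia < A.ex.n_elem; ++ia)
    for (arma::uword ib = 0; ib < A.ex.n_elem; ++ib) {
      double a = A.ex(ia), b = A.ex(ib), p = a + b;
      double c = A.cf(ia) * A.cf(ib);
      ecoefs(la, la, a, b, A.cen[0], A.cen[0], Ex.data(), tdim);
      ecoefs(la, la, a, b, A.cen[1], A.cen[1], Ey.data(), tdim);
      ecoefs(la, la, a, b, A.cen[2], A.cen[2], Ez.data(), tdim);
      double sq = std::sqrt(M_PI_ / p);
      for (size_t p1 = 0; p1 < cc.size(); ++p1)
        for (size_t p2 = 0; p2 < cc.size(); ++p2) {
          double sx = Ex[(cc[p1][0] * njb + cc[p2][0]) * tdim] * sq;
          double sy = Ey[(cc[p1][1] * njb + cc[p2][1]) * tdim] * sq;
          double sz = Ez[(cc[p1][2] * njb + cc[p2][2]) * tdim] * sq;
          Sc(p1, p2) += c * sx * sy * sz;
        }
    }
  return Sc;
}

// ------------------------------------------------------- nuclear attraction
// [[Rcpp::export]]
arma::mat cpp_nucattr(List shells, arma::vec Z, arma::mat pos) {
  auto sh = parse_shells(shells);
  int N = nbf_of(sh);
  arma::mat V(N, N, arma::fill::zeros);
  std::vector<std::array<int, 3>> c1, c2;
  for (size_t i = 0; i < sh.size(); ++i) {
    for (size_t j = 0; j <= i; ++j) {
      SPair sp = make_pair(sh, i, j);
      const ShellC &A = sh[i], &B = sh[j];
      cart_components(A.l, c1);
      cart_components(B.l, c2);
      int L = A.l + B.l, d = L + 1;
      std::vector<double> R((size_t)d * d * d), scratch((size_t)d * d * d * d);
      arma::mat Vc(A.ncart(), B.ncart(), arma::fill::zeros);
      const int njb = B.l + 1, tdim = sp.tdim;
      for (const PP& pp : sp.pps) {
        double pref = -2.0 * M_PI_ / pp.p * pp.c;
        for (arma::uword n = 0; n < Z.n_elem; ++n) {
          rtensor(L, pp.p, pp.P[0] - pos(n, 0), pp.P[1] - pos(n, 1),
                  pp.P[2] - pos(n, 2), R.data(), scratch.data());
          for (size_t p1 = 0; p1 < c1.size(); ++p1)
            for (size_t p2 = 0; p2 < c2.size(); ++p2) {
              double s = 0;
              int tx = c1[p1][0] + c2[p2][0], ty = c1[p1][1] + c2[p2][1],
                  tz = c1[p1][2] + c2[p2][2];
              int ix = (c1[p1][0] * njb + c2[p2][0]) * tdim;
              int iy = (c1[p1][1] * njb + c2[p2][1]) * tdim;
              int iz = (c1[p1][2] * njb + c2[p2][2]) * tdim;
              for (int t = 0; t <= tx; ++t)
                for (int u = 0; u <= ty; ++u)
                  for (int v = 0; v <= tz; ++v)
                    s += pp.Ex[ix + t] * pp.Ey[iy + u] * pp.Ez[iz + v] *
                         R[(t * d + u) * d + v];
              Vc(p1, p2) += pref * Z(n) * s;
            }
        }
      }
      arma::mat Vs = A.Q * Vc * B.Q.t();
      V.submat(A.aoff, B.aoff, A.aoff + Vs.n_rows - 1, B.aoff + Vs.n_cols - 1) = Vs;
      if (i != j)
        V.submat(B.aoff, A.aoff, B.aoff + Vs.n_cols - 1, A.aoff + Vs.n_rows - 1) = Vs.t();
    }
  }
  return V;
}

// ----------------------------------------------------- Schwarz shell pairs
static arma::vec schwarz_pairs(const std::vector<ShellC>& sh,
                               const std::vector<SPair>& pairs) {
  arma::vec q(pairs.size());
  std::vector<std::array<int, 3>> c1, c2;
  std::vector<double> out, R, scratch, b1, b2;
  for (size_t k = 0; k < pairs.size(); ++k) {
    const SPair& sp = pairs[k];
    cart_components(sh[sp.s1].l, c1);
    cart_components(sh[sp.s2].l, c2);
    int L = 2 * (sh[sp.s1].l + sh[sp.s2].l), d = L + 1;
    R.resize((size_t)d * d * d);
    scratch.resize((size_t)d * d * d * d);
    size_t nc = (size_t)c1.size() * c2.size();
    out.assign(nc * nc, 0.0);
    eri_quartet(sp, sp, c1, c2, c1, c2, out.data(), R.data(), scratch.data());
    double mx = 0;
    for (size_t a = 0; a < nc; ++a) mx = std::max(mx, std::abs(out[a * nc + a]));
    q(k) = std::sqrt(mx);
  }
  return q;
}

// ------------------------------------------------------------ packed ERIs
// [[Rcpp::export]]
arma::vec cpp_eri_packed(List shells, double screen_tol = 1e-12,
                         double max_gb = 4.0) {
  auto sh = parse_shells(shells);
  int N = nbf_of(sh);
  size_t npair = (size_t)N * (N + 1) / 2;
  size_t nquad = npair * (npair + 1) / 2;
  double gb = nquad * 8.0 / 1073741824.0;
  if (gb > max_gb)
    stop("packed ERI tensor would need %.2f GiB (cap %.2f GiB)", gb, max_gb);
  arma::vec eri(nquad, arma::fill::zeros);

  std::vector<SPair> pairs;
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j <= i; ++j) pairs.push_back(make_pair(sh, i, j));
  arma::vec qsz = schwarz_pairs(sh, pairs);

  std::vector<std::array<int, 3>> c1, c2, c3, c4;
  std::vector<double> cart, sph, R, scratch, b1, b2;
  for (size_t a = 0; a < pairs.size(); ++a) {
    for (size_t b = 0; b <= a; ++b) {
      if (qsz(a) * qsz(b) < screen_tol) continue;
      const SPair &bra = pairs[a], &ket = pairs[b];
      const ShellC &S1 = sh[bra.s1], &S2 = sh[bra.s2], &S3 = sh[ket.s1],
                   &S4 = sh[ket.s2];
      cart_components(S1.l, c1);
      cart_components(S2.l, c2);
      cart_components(S3.l, c3);
      cart_components(S4.l, c4);
      int L = S1.l + S2.l + S3.l + S4.l, d = L + 1;
      R.resize((size_t)d * d * d);
      scratch.resize((size_t)d * d * d * d);
      cart.assign((size_t)S1.ncart() * S2.ncart() * S3.ncart() * S4.ncart(), 0.0);
      sph.assign((size_t)S1.nsph() * S2.nsph() * S3.nsph() * S4.nsph(), 0.0);
      eri_quartet(bra, ket, c1, c2, c3, c4, cart.data(), R.data(), scratch.data());
      transform4(cart.data(), S1.Q, S2.Q, S3.Q, S4.Q, sph.data(), b1, b2);
      int n2 = S2.nsph(), n3 = S3.nsph(), n4 = S4.nsph();
      size_t idx = 0;
      for (int x1 = 0; x1 < S1.nsph(); ++x1)
        for (int x2 = 0; x2 < n2; ++x2)
          for (int x3 = 0; x3 < n3; ++x3)
            for (int x4 = 0; x4 < n4; ++x4, ++idx) {
              int gi = S1.aoff + x1, gj = S2.aoff + x2, gk = S3.aoff + x3,
                  gl = S4.aoff + x4;
              if (gi < gj || gk < gl) continue;
              size_t pid = (size_t)gi * (gi + 1) / 2 + gj;
              size_t qid = (size_t)gk * (gk + 1) / 2 + gl;
              // AO pair ids of distinct shell pairs interleave, so the
              // bra/ket pair ordering does not imply pid >= qid; store the
              // canonical slot via (ab|cd) = (cd|ab).
              if (pid < qid) std::swap(pid, qid);
              eri(pid * (pid + 1) / 2 + qid) = sph[idx];
            }
    }
  }
  return eri;
}

// ------------------------------------------------------ J/K from packed ERI
// [[Rcpp::export]]
List cpp_jk_packed(const arma::vec& eri, const arma::mat& D) {
  int N = D.n_rows;
  arma::mat J(N, N, arma::fill::zeros), K(N, N, arma::fill::zeros);
  size_t idx = 0;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j <= i; ++j) {
      size_t pid = (size_t)i * (i + 1) / 2 + j;
      for (size_t qid = 0; qid <= pid; ++qid) {
        double g = eri(idx++);
        if (g == 0.0) continue;
        // decode qid -> (k,l)
        int k = (int)((std::sqrt(8.0 * qid + 1.0) - 1.0) / 2.0);
        while ((size_t)k * (k + 1) / 2 > qid) --k;
        while ((size_t)(k + 1) * (k + 2) / 2 <= qid) ++k;
        int l = (int)(qid - (size_t)k * (k + 1) / 2);
        bool ij_eq = (i == j), kl_eq = (k == l), same = (pid == qid);
        J(i, j) += g * D(k, l) * (kl_eq ? 1.0 : 2.0);
        if (!same) J(k, l) += g * D(i, j) * (ij_eq ? 1.0 : 2.0);
        auto addK = [&](int p, int q, int r, int s) { K(p, r) += D(q, s) * g; };
        addK(i, j, k, l);
        if (!kl_eq) addK(i, j, l, k);
        if (!ij_eq) {
          addK(j, i, k, l);
          if (!kl_eq) addK(j, i, l, k);
        }
        if (!same) {
          addK(k, l, i, j);
          if (!ij_eq) addK(k, l, j, i);
          if (!kl_eq) {
            addK(l, k, i, j);
            if (!ij_eq) addK(l, k, j, i);
          }
        }
      }
    }
  J = arma::symmatl(J);
  return List::create(_["J"] = J, _["K"] = K);
}

// ----------------------------------------------------------- 2c/3c integrals
// [[Rcpp::export]]
arma::mat cpp_metric2c(List aux) {
  auto sh = parse_shells(aux);
  int N = nbf_of(sh);
  arma::mat M(N, N, arma::fill::zeros);
  std::vector<std::array<int, 3>> c1, c3, c0{{{0, 0, 0}}};
  std::vector<double> cart, sph, R, scratch, b1, b2;
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j <= i; ++j) {
      SPair bra = make_single(sh, i), ket = make_single(sh, j);
      const ShellC &S1 = sh[i], &S3 = sh[j];
      cart_components(S1.l, c1);
      cart_components(S3.l, c3);
      int L = S1.l + S3.l, d = L + 1;
      R.resize((size_t)d * d * d);
      scratch.resize((size_t)d * d * d * d);
      cart.assign((size_t)S1.ncart() * S3.ncart(), 0.0);
      sph.assign((size_t)S1.nsph() * S3.nsph(), 0.0);
      eri_quartet(bra, ket, c1, c0, c3, c0, cart.data(), R.data(), scratch.data());
      arma::mat one(1, 1, arma::fill::ones);
      transform4(cart.data(), S1.Q, one, S3.Q, one, sph.data(), b1, b2);
      for (int x1 = 0; x1 < S1.nsph(); ++x1)
        for (int x3 = 0; x3 < S3.nsph(); ++x3) {
          M(S1.aoff + x1, S3.aoff + x3) = sph[(size_t)x1 * S3.nsph() + x3];
          M(S3.aoff + x3, S1.aoff + x1) = sph[(size_t)x1 * S3.nsph() + x3];
        }
    }
  return M;
}

// B(P, pid) with pid the packed (mu >= nu) AO pair index; the tensor is
// filled in place in R-owned memory so no return-value copy is made
// [[Rcpp::export]]
NumericMatrix cpp_3center(List shells, List aux, double screen_tol = 1e-12,
                          double max_gb = 4.0) {
  auto sh = parse_shells(shells);
  auto ax = parse_shells(aux);
  int N = nbf_of(sh), Naux = nbf_of(ax);
  size_t npair = (size_t)N * (N + 1) / 2;
  double gb = (double)Naux * npair * 8.0 / 1073741824.0;
  if (gb > max_gb)
    stop("3-center tensor would need %.2f GiB (cap %.2f GiB)", gb, max_gb);
  NumericMatrix Bout(Naux, (int)npair);
  arma::mat B(Bout.begin(), Naux, npair, false, true);
  B.zeros();

  std::vector<SPair> pairs;
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j <= i; ++j) pairs.push_back(make_pair(sh, i, j));
  arma::vec qsz = schwarz_pairs(sh, pairs);
  // aux Schwarz
  arma::vec qaux(ax.size());
  {
    std::vector<std::array<int, 3>> c1, c0{{{0, 0, 0}}};
    std::vector<double> cart, R, scratch;
    for (size_t i = 0; i < ax.size(); ++i) {
      SPair s1 = make_single(ax, i);
      cart_components(ax[i].l, c1);
      int L = 2 * ax[i].l, d = L + 1;
      R.resize((size_t)d * d * d);
      scratch.resize((size_t)d * d * d * d);
      size_t nc = c1.size();
      cart.assign(nc * nc, 0.0);
      eri_quartet(s1, s1, c1, c0, c1, c0, cart.data(), R.data(), scratch.data());
      double mx = 0;
      for (size_t a = 0; a < nc; ++a) mx = std::max(mx, std::abs(cart[a * nc + a]));
      qaux(i) = std::sqrt(mx);
    }
  }
  double qauxmax = qaux.max();

  std::vector<std::array<int, 3>> c1, c2, c3, c0{{{0, 0, 0}}};
  std::vector<double> cart, sph, R, scratch, b1, b2;
  arma::mat one(1, 1, arma::fill::ones);
  for (size_t a = 0; a < pairs.size(); ++a) {
    if (qsz(a) * qauxmax < screen_tol) continue;
    const SPair& bra = pairs[a];
    const ShellC &S1 = sh[bra.s1], &S2 = sh[bra.s2];
    cart_components(S1.l, c1);
    cart_components(S2.l, c2);
    for (size_t p = 0; p < ax.size(); ++p) {
      if (qsz(a) * qaux(p) < screen_tol) continue;
      SPair ket = make_single(ax, p);
      const ShellC& SP = ax[p];
      cart_components(SP.l, c3);
      int L = S1.l + S2.l + SP.l, d = L + 1;
      R.resize((size_t)d * d * d);
      scratch.resize((size_t)d * d * d * d);
      cart.assign((size_t)S1.ncart() * S2.ncart() * SP.ncart(), 0.0);
      sph.assign((size_t)S1.nsph() * S2.nsph() * SP.nsph(), 0.0);
      eri_quartet(bra, ket, c1, c2, c3, c0, cart.data(), R.data(), scratch.data());
      transform4(cart.data(), S1.Q, S2.Q, SP.Q, one, sph.data(), b1, b2);
      size_t idx = 0;
      for (int x1 = 0; x1 < S1.nsph(); ++x1)
        for (int x2 = 0; x2 < S2.nsph(); ++x2)
          for (int x3 = 0; x3 < SP.nsph(); ++x3, ++idx) {
            int gi = S1.aoff + x1, gj = S2.aoff + x2;
            if (gi < gj) continue;
            B(SP.aoff + x3, (size_t)gi * (gi + 1) / 2 + gj) = sph[idx];
          }
    }
  }
  return Bout;
}

// ---------------------------------------------------------------- DF J & K
static arma::mat unpack_row(const arma::mat& B, size_t P, int N) {
  arma::mat M(N, N);
  size_t pid = 0;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j <= i; ++j, ++pid) {
      M(i, j) = B(P, pid);
      M(j, i) = B(P, pid);
    }
  return M;
}

// [[Rcpp::export]]
List cpp_df_jk(NumericMatrix Bin, const arma::mat& Lchol, const arma::mat& Cocc,
               const arma::mat& D) {
  // reuse the R-owned 3-center memory; no copy of the (large) tensor
  const arma::mat B(Bin.begin(), Bin.nrow(), Bin.ncol(), false, true);
  int N = D.n_rows, nocc = Cocc.n_cols;
  size_t Naux = B.n_rows;
  // J
  arma::vec dpack(B.n_cols);
  {
    size_t pid = 0;
    for (int i = 0; i < N; ++i)
      for (int j = 0; j <= i; ++j, ++pid) dpack(pid) = (i == j) ? D(i, j) : 2.0 * D(i, j);
  }
  arma::vec gamma = B * dpack;
  arma::vec w = arma::solve(arma::trimatl(Lchol), gamma);
  w = arma::solve(arma::trimatu(Lchol.t()), w);
  arma::vec Jp = B.t() * w;
  arma::mat J(N, N);
  {
    size_t pid = 0;
    for (int i = 0; i < N; ++i)
      for (int j = 0; j <= i; ++j, ++pid) { J(i, j) = Jp(pid); J(j, i) = Jp(pid); }
  }
  // K: V(P, i*N+mu) = sum_nu (P|mu nu) C(nu,i); whiten over P; K = sum_i Vi' Vi
  // processed in occupied-orbital blocks to bound the working memory
  int nb = std::max(1, (int)(1.0e8 / (8.0 * Naux * N)));
  arma::mat K(N, N, arma::fill::zeros);
  for (int i0 = 0; i0 < nocc; i0 += nb) {
    int ni = std::min(nb, nocc - i0);
    arma::mat V(Naux, (size_t)N * ni);
    for (size_t P = 0; P < Naux; ++P) {
      arma::mat M = unpack_row(B, P, N);
      arma::mat X = M * Cocc.cols(i0, i0 + ni - 1);  // N x ni
      for (int i = 0; i < ni; ++i)
        for (int mu = 0; mu < N; ++mu) V(P, (size_t)i * N + mu) = X(mu, i);
    }
    arma::mat W = arma::solve(arma::trimatl(Lchol), V);
    for (int i = 0; i < ni; ++i) {
      arma::mat Wi = W.cols((size_t)i * N, (size_t)i * N + N - 1);
      K += Wi.t() * Wi;
    }
  }
  return List::create(_["J"] = J, _["K"] = K);
}

// (P|xy) for MO pairs of one or two coefficient sets: returns Naux x (K1*K2)
// [[Rcpp::export]]
arma::mat cpp_mo_pairs(NumericMatrix Bin, const arma::mat& C1, const arma::mat& C2) {
  const arma::mat B(Bin.begin(), Bin.nrow(), Bin.ncol(), false, true);
  int N = C1.n_rows, K1 = C1.n_cols, K2 = C2.n_cols;
  size_t Naux = B.n_rows;
  arma::mat out(Naux, (size_t)K1 * K2);
  for (size_t P = 0; P < Naux; ++P) {
    arma::mat M = unpack_row(B, P, N);
    arma::mat G = C1.t() * M * C2;  // K1 x K2
    for (int b = 0; b < K2; ++b)
      for (int a = 0; a < K1; ++a) out(P, (size_t)b * K1 + a) = G(a, b);
  }
  return out;
}
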