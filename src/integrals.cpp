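// McMurchie-Davidson evaluation of Gaussian one- and two-electron integrals
// over contracted Cartesian shells, plus the derivative contractions needed
// for nuclear gradients and real-space density evaluation.
//
// Conventions: all coordinates in Bohr, energies in Hartree.  Shell data
// arrive as flat vectors (see R/backend.R); primitive coefficients already
// include primitive and contraction normalization, so everything here works
// with bare Cartesian primitives  x^i y^j z^k exp(-a r^2).

#include <RcppArmadillo.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// Boys function F_m(T), m = 0..mmax
// ---------------------------------------------------------------------------
static void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T <= 30.0) {
    // series for the highest order, then stable downward recursion
    double num = 1.0, den = 2.0 * mmax + 1.0, term = 1.0 / den, sum = term;
    for (int i = 1; i < 400; ++i) {
      num *= 2.0 * T;
      den *= (2.0 * mmax + 2.0 * i + 1.0);
      term = num / den;
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    double eT = std::exp(-T);
    F[mmax] = eT * sum;
    for (int m = mmax; m > 0; --m)
      F[m - 1] = (2.0 * T * F[m] + eT) / (2.0 * m - 1.0);
  } else {
    double eT = std::exp(-T);
    F[0] = 0.5 * std::sqrt(PI / T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - eT) / (2.0 * T);
  }
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficient E_t^{ij} for one Cartesian direction
// ---------------------------------------------------------------------------
static double Ecoef(int i, int j, int t, double Qx, double a, double b) {
  double p = a + b, q = a * b / p;
  if (t < 0 || t > i + j) return 0.0;
  if (i == 0 && j == 0 && t == 0) return std::exp(-q * Qx * Qx);
  if (j == 0) {
    return (1.0 / (2.0 * p)) * Ecoef(i - 1, j, t - 1, Qx, a, b)
         - (q * Qx / a)      * Ecoef(i - 1, j, t,     Qx, a, b)
         + (t + 1.0)         * Ecoef(i - 1, j, t + 1, Qx, a, b);
  }
  return (1.0 / (2.0 * p)) * Ecoef(i, j - 1, t - 1, Qx, a, b)
       + (q * Qx / b)      * Ecoef(i, j - 1, t,     Qx, a, b)
       + (t + 1.0)         * Ecoef(i, j - 1, t + 1, Qx, a, b);
}

// ---------------------------------------------------------------------------
// Hermite Coulomb integral R^n_{tuv}
// ---------------------------------------------------------------------------
static double Rtuv(int t, int u, int v, int n, double p,
                   double X, double Y, double Z, const double* F) {
  if (t == 0 && u == 0 && v == 0)
    return std::pow(-2.0 * p, n) * F[n];
  if (t > 0) {
    double val = X * Rtuv(t - 1, u, v, n + 1, p, X, Y, Z, F);
    if (t > 1) val += (t - 1) * Rtuv(t - 2, u, v, n + 1, p, X, Y, Z, F);
    return val;
  }
  if (u > 0) {
    double val = Y * Rtuv(t, u - 1, v, n + 1, p, X, Y, Z, F);
    if (u > 1) val += (u - 1) * Rtuv(t, u - 2, v, n + 1, p, X, Y, Z, F);
    return val;
  }
  double val = Z * Rtuv(t, u, v - 1, n + 1, p, X, Y, Z, F);
  if (v > 1) val += (v - 1) * Rtuv(t, u, v - 2, n + 1, p, X, Y, Z, F);
  return val;
}

// ---------------------------------------------------------------------------
// primitive integrals
// ---------------------------------------------------------------------------
static double prim_overlap(const int* la, const int* lb,
                           double a, double b,
                           const double* A, const double* B) {
  double p = a + b, s = 1.0;
  for (int d = 0; d < 3; ++d)
    s *= Ecoef(la[d], lb[d], 0, A[d] - B[d], a, b);
  return s * std::pow(PI / p, 1.5);
}

// 1D overlap factor (without the sqrt(pi/p), applied once in 3D assembly)
static double ov1d(int i, int j, double Qx, double a, double b) {
  return Ecoef(i, j, 0, Qx, a, b);
}

static double prim_kinetic(const int* la, const int* lb,
                           double a, double b,
                           const double* A, const double* B) {
  double p = a + b;
  double S[3], K[3];
  for (int d = 0; d < 3; ++d) {
    double Qx = A[d] - B[d];
    int i = la[d], j = lb[d];
    S[d] = ov1d(i, j, Qx, a, b);
    double t = -2.0 * b * b * ov1d(i, j + 2, Qx, a, b)
             + b * (2.0 * j + 1.0) * S[d];
    if (j >= 2) t -= 0.5 * j * (j - 1.0) * ov1d(i, j - 2, Qx, a, b);
    K[d] = t;
  }
  double pref = std::pow(PI / p, 1.5);
  return pref * (K[0] * S[1] * S[2] + S[0] * K[1] * S[2] + S[0] * S[1] * K[2]);
}

// <a| 1/|r - C| |b>, positive-definite kernel (multiply by -Z outside)
static double prim_nuclear(const int* la, const int* lb,
                           double a, double b,
                           const double* A, const double* B, const double* C) {
  double p = a + b;
  double P[3];
  for (int d = 0; d < 3; ++d) P[d] = (a * A[d] + b * B[d]) / p;
  int tmax = la[0] + lb[0], umax = la[1] + lb[1], vmax = la[2] + lb[2];
  int mmax = tmax + umax + vmax;
  double PC[3] = {P[0] - C[0], P[1] - C[1], P[2] - C[2]};
  double T = p * (PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2]);
  std::vector<double> F(mmax + 1);
  boys(mmax, T, F.data());
  double sum = 0.0;
  for (int t = 0; t <= tmax; ++t) {
    double Ex = Ecoef(la[0], lb[0], t, A[0] - B[0], a, b);
    if (Ex == 0.0) continue;
    for (int u = 0; u <= umax; ++u) {
      double Ey = Ecoef(la[1], lb[1], u, A[1] - B[1], a, b);
      if (Ey == 0.0) continue;
      for (int v = 0; v <= vmax; ++v) {
        double Ez = Ecoef(la[2], lb[2], v, A[2] - B[2], a, b);
        if (Ez == 0.0) continue;
        sum += Ex * Ey * Ez * Rtuv(t, u, v, 0, p, PC[0], PC[1], PC[2], F.data());
      }
    }
  }
  return sum * 2.0 * PI / p;
}

// (ab|cd) over primitives
static double prim_eri(const int* la, const int* lb, const int* lc, const int* ld,
                       double a, double b, double c, double d,
                       const double* A, const double* B,
                       const double* C, const double* D) {
  double p = a + b, q = c + d;
  double P[3], Q[3];
  for (int k = 0; k < 3; ++k) {
    P[k] = (a * A[k] + b * B[k]) / p;
    Q[k] = (c * C[k] + d * D[k]) / q;
  }
  double alpha = p * q / (p + q);
  double PQ[3] = {P[0] - Q[0], P[1] - Q[1], P[2] - Q[2]};
  double T = alpha * (PQ[0] * PQ[0] + PQ[1] * PQ[1] + PQ[2] * PQ[2]);
  int t1 = la[0] + lb[0], u1 = la[1] + lb[1], v1 = la[2] + lb[2];
  int t2 = lc[0] + ld[0], u2 = lc[1] + ld[1], v2 = lc[2] + ld[2];
  int mmax = t1 + u1 + v1 + t2 + u2 + v2;
  std::vector<double> F(mmax + 1);
  boys(mmax, T, F.data());
  double sum = 0.0;
  for (int t = 0; t <= t1; ++t) {
    double E1x = Ecoef(la[0], lb[0], t, A[0] - B[0], a, b);
    if (E1x == 0.0) continue;
    for (int u = 0; u <= u1; ++u) {
      double E1y = Ecoef(la[1], lb[1], u, A[1] - B[1], a, b);
      if (E1y == 0.0) continue;
      for (int v = 0; v <= v1; ++v) {
        double E1z = Ecoef(la[2], lb[2], v, A[2] - B[2], a, b);
        if (E1z == 0.0) continue;
        double bra = E1x * E1y * E1z;
        for (int tt = 0; tt <= t2; ++tt) {
          double E2x = Ecoef(lc[0], ld[0], tt, C[0] - D[0], c, d);
          if (E2x == 0.0) continue;
          for (int uu = 0; uu <= u2; ++uu) {
            double E2y = Ecoef(lc[1], ld[1], uu, C[1] - D[1], c, d);
            if (E2y == 0.0) continue;
            for (int vv = 0; vv <= v2; ++vv) {
              double E2z = Ecoef(lc[2], ld[2], vv, C[2] - D[2], c, d);
              if (E2z == 0.0) continue;
              double sign = ((tt + uu + vv) % 2 == 0) ? 1.0 : -1.0;
              sum += bra * E2x * E2y * E2z * sign *
                     Rtuv(t + tt, u + uu, v + vv, 0, alpha,
                          PQ[0], PQ[1], PQ[2], F.data());
            }
          }
        }
      }
    }
  }
  return sum * 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q));
}

// ---------------------------------------------------------------------------
// shell bookkeeping
// ---------------------------------------------------------------------------
struct Shell {
  int l;
  int atom;
  int nprim;
  std::vector<double> exps;
  std::vector<double> coefs;   // final coefficients incl. normalization
  double center[3];
  int ao_offset;               // first AO index of this shell
  int ncomp;
};

// Cartesian components of angular momentum l, ordered x-major
static void components(int l, std::vector<std::array<int, 3>>& comp) {
  comp.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      comp.push_back({lx, ly, l - lx - ly});
}

static std::vector<Shell> unpack_shells(const IntegerVector& shell_l,
                                        const IntegerVector& shell_atom,
                                        const IntegerVector& shell_nprim,
                                        const NumericVector& prim_exp,
                                        const NumericVector& prim_coef,
                                        const NumericMatrix& atom_xyz) {
  int ns = shell_l.size();
  std::vector<Shell> shells(ns);
  int ip = 0, ao = 0;
  for (int s = 0; s < ns; ++s) {
    Shell& sh = shells[s];
    sh.l = shell_l[s];
    sh.atom = shell_atom[s];
    sh.nprim = shell_nprim[s];
    for (int k = 0; k < sh.nprim; ++k) {
      sh.exps.push_back(prim_exp[ip + k]);
      sh.coefs.push_back(prim_coef[ip + k]);
    }
    ip += sh.nprim;
    for (int d = 0; d < 3; ++d) sh.center[d] = atom_xyz(sh.atom, d);
    sh.ncomp = (sh.l + 1) * (sh.l + 2) / 2;
    sh.ao_offset = ao;
    ao += sh.ncomp;
  }
  return shells;
}

typedef double (*pair_integral_fn)(const int*, const int*, double, double,
                                   const double*, const double*);

// contracted matrix block for a one-electron operator without extra centers
static void pair_block(const Shell& sa, const Shell& sb, pair_integral_fn fn,
                       arma::mat& out) {
  std::vector<std::array<int, 3>> ca, cb;
  components(sa.l, ca);
  components(sb.l, cb);
  for (size_t i = 0; i < ca.size(); ++i)
    for (size_t j = 0; j < cb.size(); ++j) {
      double val = 0.0;
      for (int p = 0; p < sa.nprim; ++p)
        for (int q = 0; q < sb.nprim; ++q)
          val += sa.coefs[p] * sb.coefs[q] *
                 fn(ca[i].data(), cb[j].data(), sa.exps[p], sb.exps[q],
                    sa.center, sb.center);
      out(sa.ao_offset + i, sb.ao_offset + j) = val;
    }
}

// [[Rcpp::export]]
List cxx_ao_integrals(IntegerVector shell_l, IntegerVector shell_atom,
                      IntegerVector shell_nprim, NumericVector prim_exp,
                      NumericVector prim_coef, NumericMatrix atom_xyz,
                      NumericVector atom_charge, bool do_eri) {
  std::vector<Shell> shells =
      unpack_shells(shell_l, shell_atom, shell_nprim, prim_exp, prim_coef, atom_xyz);
  int ns = shells.size();
  int nao = shells.back().ao_offset + shells.back().ncomp;
  int natom = atom_xyz.nrow();

  arma::mat S(nao, nao, arma::fill::zeros);
  arma::mat T(nao, nao, arma::fill::zeros);
  arma::mat V(nao, nao, arma::fill::zeros);

  for (int i = 0; i < ns; ++i)
    for (int j = 0; j <= i; ++j) {
      pair_block(shells[i], shells[j], prim_overlap, S);
      pair_block(shells[i], shells[j], prim_kinetic, T);
      // nuclear attraction: sum over nuclei
      std::vector<std::array<int, 3>> ca, cb;
      components(shells[i].l, ca);
      components(shells[j].l, cb);
      for (size_t ii = 0; ii < ca.size(); ++ii)
        for (size_t jj = 0; jj < cb.size(); ++jj) {
          double val = 0.0;
          for (int p = 0; p < shells[i].nprim; ++p)
            for (int q = 0; q < shells[j].nprim; ++q) {
              double cc = shells[i].coefs[p] * shells[j].coefs[q];
              for (int c = 0; c < natom; ++c) {
                double Cc[3] = {atom_xyz(c, 0), atom_xyz(c, 1), atom_xyz(c, 2)};
                val -= atom_charge[c] * cc *
                       prim_nuclear(ca[ii].data(), cb[jj].data(),
                                    shells[i].exps[p], shells[j].exps[q],
                                    shells[i].center, shells[j].center, Cc);
              }
            }
          V(shells[i].ao_offset + ii, shells[j].ao_offset + jj) = val;
        }
    }
  S = arma::symmatl(S);
  T = arma::symmatl(T);
  V = arma::symmatl(V);

  List out = List::create(Named("S") = S, Named("T") = T, Named("V") = V,
                          Named("n_ao") = nao);

  if (do_eri) {
    NumericVector eri((R_xlen_t)nao * nao * nao * nao);
    double* E = eri.begin();
    std::vector<std::array<int, 3>> ca, cb, cc, cd;
    for (int i = 0; i < ns; ++i)
      for (int j = 0; j <= i; ++j)
        for (int k = 0; k <= i; ++k)
          for (int l = 0; l <= (k == i ? j : k); ++l) {
            components(shells[i].l, ca);
            components(shells[j].l, cb);
            components(shells[k].l, cc);
            components(shells[l].l, cd);
            for (size_t ii = 0; ii < ca.size(); ++ii)
              for (size_t jj = 0; jj < cb.size(); ++jj)
                for (size_t kk = 0; kk < cc.size(); ++kk)
                  for (size_t ll = 0; ll < cd.size(); ++ll) {
                    double val = 0.0;
                    for (int p = 0; p < shells[i].nprim; ++p)
                      for (int q = 0; q < shells[j].nprim; ++q)
                        for (int r = 0; r < shells[k].nprim; ++r)
                          for (int s = 0; s < shells[l].nprim; ++s)
                            val += shells[i].coefs[p] * shells[j].coefs[q] *
                                   shells[k].coefs[r] * shells[l].coefs[s] *
                                   prim_eri(ca[ii].data(), cb[jj].data(),
                                            cc[kk].data(), cd[ll].data(),
                                            shells[i].exps[p], shells[j].exps[q],
                                            shells[k].exps[r], shells[l].exps[s],
                                            shells[i].center, shells[j].center,
                                            shells[k].center, shells[l].center);
                    int mu = shells[i].ao_offset + ii;
                    int nu = shells[j].ao_offset + jj;
                    int la_ = shells[k].ao_offset + kk;
                    int si = shells[l].ao_offset + ll;
                    R_xlen_t n = nao;
                    // fill the 8 permutation-equivalent slots
                    int idx[8][4] = {{mu, nu, la_, si}, {nu, mu, la_, si},
                                     {mu, nu, si, la_}, {nu, mu, si, la_},
                                     {la_, si, mu, nu}, {si, la_, mu, nu},
                                     {la_, si, nu, mu}, {si, la_, nu, mu}};
                    for (int z = 0; z < 8; ++z)
                      E[idx[z][0] + n * (idx[z][1] + n * (idx[z][2] + n * idx[z][3]))] = val;
                  }
          }
    out["eri"] = eri;
  }
  return out;
}

// ---------------------------------------------------------------------------
// derivatives: d/dA of a primitive raises/lowers the Cartesian power
//   d/dAx  x_A^i e^{-a rA^2} = 2a (i+1 power) - i (i-1 power)
// ---------------------------------------------------------------------------
template <typename F>
static double bra_deriv(const int* la, int dim, double a, F base) {
  int lp[3] = {la[0], la[1], la[2]};
  lp[dim] += 1;
  double val = 2.0 * a * base(lp);
  if (la[dim] > 0) {
    int lm[3] = {la[0], la[1], la[2]};
    lm[dim] -= 1;
    val -= la[dim] * base(lm);
  }
  return val;
}

// [[Rcpp::export]]
List cxx_gradient_terms(IntegerVector shell_l, IntegerVector shell_atom,
                        IntegerVector shell_nprim, NumericVector prim_exp,
                        NumericVector prim_coef, NumericMatrix atom_xyz,
                        NumericVector atom_charge, NumericMatrix Ptot,
                        NumericMatrix Pa, NumericMatrix Pb, NumericMatrix Wew) {
  std::vector<Shell> shells =
      unpack_shells(shell_l, shell_atom, shell_nprim, prim_exp, prim_coef, atom_xyz);
  int ns = shells.size();
  int natom = atom_xyz.nrow();

  arma::mat g_core(natom, 3, arma::fill::zeros);   // dT + dV (incl. operator term)
  arma::mat g_ovl(natom, 3, arma::fill::zeros);    // -Tr[Wew dS]
  arma::mat g_eri(natom, 3, arma::fill::zeros);

  std::vector<std::array<int, 3>> ca, cb, cc, cd;

  // one-electron terms: loop all ordered shell pairs, bra derivatives only;
  // ket derivatives of T and S are covered by the transposed pair.
  for (int i = 0; i < ns; ++i) {
    const Shell& A = shells[i];
    components(A.l, ca);
    for (int j = 0; j < ns; ++j) {
      const Shell& B = shells[j];
      components(B.l, cb);
      for (size_t ii = 0; ii < ca.size(); ++ii)
        for (size_t jj = 0; jj < cb.size(); ++jj) {
          int mu = A.ao_offset + ii, nu = B.ao_offset + jj;
          double pmn = Ptot(mu, nu), wmn = Wew(mu, nu);
          for (int dim = 0; dim < 3; ++dim) {
            double dT = 0.0, dS = 0.0;
            for (int p = 0; p < A.nprim; ++p)
              for (int q = 0; q < B.nprim; ++q) {
                double cpq = A.coefs[p] * B.coefs[q];
                double ea = A.exps[p], eb = B.exps[q];
                dT += cpq * bra_deriv(ca[ii].data(), dim, ea, [&](const int* lp) {
                  return prim_kinetic(lp, cb[jj].data(), ea, eb, A.center, B.center);
                });
                dS += cpq * bra_deriv(ca[ii].data(), dim, ea, [&](const int* lp) {
                  return prim_overlap(lp, cb[jj].data(), ea, eb, A.center, B.center);
                });
              }
            // factor 2: ket derivative of the transposed element (P, W symmetric)
            g_core(A.atom, dim) += 2.0 * pmn * dT;
            g_ovl(A.atom, dim) -= 2.0 * wmn * dS;
          }
          // nuclear attraction: bra, ket and operator-center derivatives
          for (int c = 0; c < natom; ++c) {
            double Cc[3] = {atom_xyz(c, 0), atom_xyz(c, 1), atom_xyz(c, 2)};
            for (int dim = 0; dim < 3; ++dim) {
              double dA = 0.0, dB = 0.0;
              for (int p = 0; p < A.nprim; ++p)
                for (int q = 0; q < B.nprim; ++q) {
                  double cpq = A.coefs[p] * B.coefs[q];
                  double ea = A.exps[p], eb = B.exps[q];
                  dA += cpq * bra_deriv(ca[ii].data(), dim, ea, [&](const int* lp) {
                    return prim_nuclear(lp, cb[jj].data(), ea, eb,
                                        A.center, B.center, Cc);
                  });
                  dB += cpq * bra_deriv(cb[jj].data(), dim, eb, [&](const int* lp) {
                    return prim_nuclear(ca[ii].data(), lp, ea, eb,
                                        A.center, B.center, Cc);
                  });
                }
              double z = -atom_charge[c] * pmn;
              g_core(A.atom, dim) += z * dA;
              g_core(B.atom, dim) += z * dB;
              g_core(c, dim) -= z * (dA + dB);  // translational invariance
            }
          }
        }
    }
  }

  // two-electron term: loop all ordered shell quartets, derivative on slot 1,
  // contracted with the slot-symmetrized two-particle density
  //   2 P(mu,nu) P(la,si) - sum_s [P^s(mu,la) P^s(nu,si) + P^s(nu,la) P^s(mu,si)]
  for (int i = 0; i < ns; ++i) {
    const Shell& A = shells[i];
    components(A.l, ca);
    for (int j = 0; j < ns; ++j) {
      const Shell& B = shells[j];
      components(B.l, cb);
      for (int k = 0; k < ns; ++k) {
        const Shell& C = shells[k];
        components(C.l, cc);
        for (int l = 0; l < ns; ++l) {
          const Shell& D = shells[l];
          components(D.l, cd);
          for (size_t ii = 0; ii < ca.size(); ++ii)
            for (size_t jj = 0; jj < cb.size(); ++jj)
              for (size_t kk = 0; kk < cc.size(); ++kk)
                for (size_t ll = 0; ll < cd.size(); ++ll) {
                  int mu = A.ao_offset + ii, nu = B.ao_offset + jj;
                  int la_ = C.ao_offset + kk, si = D.ao_offset + ll;
                  double gam = 2.0 * Ptot(mu, nu) * Ptot(la_, si)
                      - (Pa(mu, la_) * Pa(nu, si) + Pa(nu, la_) * Pa(mu, si))
                      - (Pb(mu, la_) * Pb(nu, si) + Pb(nu, la_) * Pb(mu, si));
                  if (std::abs(gam) < 1e-12) continue;
                  for (int dim = 0; dim < 3; ++dim) {
                    double dA = 0.0;
                    for (int p = 0; p < A.nprim; ++p)
                      for (int q = 0; q < B.nprim; ++q)
                        for (int r = 0; r < C.nprim; ++r)
                          for (int s = 0; s < D.nprim; ++s) {
                            double cpq = A.coefs[p] * B.coefs[q] *
                                         C.coefs[r] * D.coefs[s];
                            double ea = A.exps[p];
                            dA += cpq * bra_deriv(ca[ii].data(), dim, ea,
                              [&](const int* lp) {
                                return prim_eri(lp, cb[jj].data(), cc[kk].data(),
                                                cd[ll].data(), ea, B.exps[q],
                                                C.exps[r], D.exps[s], A.center,
                                                B.center, C.center, D.center);
                              });
                          }
                    g_eri(A.atom, dim) += gam * dA;
                  }
                }
        }
      }
    }
  }

  // nuclear repulsion derivative
  arma::mat g_nn(natom, 3, arma::fill::zeros);
  for (int a = 0; a < natom; ++a)
    for (int b = 0; b < natom; ++b) {
      if (a == b) continue;
      double R[3] = {atom_xyz(a, 0) - atom_xyz(b, 0),
                     atom_xyz(a, 1) - atom_xyz(b, 1),
                     atom_xyz(a, 2) - atom_xyz(b, 2)};
      double r2 = R[0] * R[0] + R[1] * R[1] + R[2] * R[2];
      double r3 = std::pow(r2, 1.5);
      for (int dim = 0; dim < 3; ++dim)
        g_nn(a, dim) -= atom_charge[a] * atom_charge[b] * R[dim] / r3;
    }

  return List::create(Named("core") = g_core, Named("overlap") = g_ovl,
                      Named("eri") = g_eri, Named("nn") = g_nn);
}

// ---------------------------------------------------------------------------
// AO values / density on a set of points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cxx_density_on_points(IntegerVector shell_l, IntegerVector shell_atom,
                                    IntegerVector shell_nprim, NumericVector prim_exp,
                                    NumericVector prim_coef, NumericMatrix atom_xyz,
                                    NumericMatrix P, NumericMatrix pts) {
  std::vector<Shell> shells =
      unpack_shells(shell_l, shell_atom, shell_nprim, prim_exp, prim_coef, atom_xyz);
  int ns = shells.size();
  int nao = shells.back().ao_offset + shells.back().ncomp;
  int npt = pts.nrow();
  NumericVector rho(npt);
  std::vector<double> ao(nao);
  std::vector<std::array<int, 3>> comp;
  arma::mat Pm(P.begin(), nao, nao, false);

  for (int ipt = 0; ipt < npt; ++ipt) {
    double x = pts(ipt, 0), y = pts(ipt, 1), z = pts(ipt, 2);
    for (int s = 0; s < ns; ++s) {
      const Shell& sh = shells[s];
      double dx = x - sh.center[0], dy = y - sh.center[1], dz = z - sh.center[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double radial = 0.0;
      for (int p = 0; p < sh.nprim; ++p)
        radial += sh.coefs[p] * std::exp(-sh.exps[p] * r2);
      components(sh.l, comp);
      for (int c = 0; c < sh.ncomp; ++c)
        ao[sh.ao_offset + c] = radial *
            std::pow(dx, comp[c][0]) * std::pow(dy, comp[c][1]) *
            std::pow(dz, comp[c][2]);
    }
    double val = 0.0;
    for (int m = 0; m < nao; ++m) {
      double t = 0.0;
      for (int n = 0; n < nao; ++n) t += Pm(m, n) * ao[n];
      val += ao[m] * t;
    }
    rho[ipt] = val;
  }
  return rho;
}
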