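// McMurchie-Davidson evaluation of Gaussian integrals over contracted
// Cartesian shells (s, p, d, ... general l).  Shells arrive flattened from R:
// per shell an angular momentum, a center, and primitive exponents/coefficients
// with primitive normalization already folded in.  Final AO normalization is
// applied on the R side from the diagonal of the raw overlap matrix.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double PI = 3.141592653589793238462643383279502884;

// ---------------------------------------------------------------- Boys F_m(T)
static void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T <= 35.0) {
    // series at m = mmax, then downward recursion
    double term = 1.0 / (2.0 * mmax + 1.0), sum = term;
    int k = 1;
    while (term > 1e-17 * sum && k < 400) {
      term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0);
      sum += term;
      ++k;
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

// ------------------------------------------------- Hermite expansion E_t^{ij}
// E indexed as E[(i*(jmax+1) + j)*(tmax+1) + t]
struct EArr {
  std::vector<double> v;
  int jmax, tmax;
  double at(int i, int j, int t) const {
    if (t < 0 || t > tmax) return 0.0;
    return v[(size_t)(i * (jmax + 1) + j) * (tmax + 1) + t];
  }
  void set(int i, int j, int t, double x) {
    v[(size_t)(i * (jmax + 1) + j) * (tmax + 1) + t] = x;
  }
};

static void buildE(EArr& E, int imax, int jmax, double a, double b,
                   double AB) {
  double p = a + b, q = a * b / p;
  double PA = -b / p * AB;  // P - A with AB = A - B
  double PB = a / p * AB;   // P - B
  int tmax = imax + jmax;
  E.jmax = jmax; E.tmax = tmax;
  E.v.assign((size_t)(imax + 1) * (jmax + 1) * (tmax + 1), 0.0);
  E.set(0, 0, 0, std::exp(-q * AB * AB));
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val;
        if (j == 0) {
          val = 1.0 / (2.0 * p) * E.at(i - 1, 0, t - 1) +
                PA * E.at(i - 1, 0, t) +
                (t + 1.0) * E.at(i - 1, 0, t + 1);
        } else {
          val = 1.0 / (2.0 * p) * E.at(i, j - 1, t - 1) +
                PB * E.at(i, j - 1, t) +
                (t + 1.0) * E.at(i, j - 1, t + 1);
        }
        E.set(i, j, t, val);
      }
    }
  }
}

// --------------------------------------------- Hermite Coulomb repulsion R^0
// Fills R0[t][u][v] = R^0_{tuv}(alpha, PC) for t+u+v <= L.
struct RArr {
  std::vector<double> v;
  int L;
  double& at(int t, int u, int w) {
    return v[(size_t)((t * (L + 1)) + u) * (L + 1) + w];
  }
};

static void buildR(RArr& R, int L, double alpha, double x, double y, double z) {
  double T = alpha * (x * x + y * y + z * z);
  std::vector<double> F(L + 1);
  boys(L, T, F.data());
  // Rn[n][t][u][v], built downward in n
  int dim = L + 1;
  std::vector<double> cur((size_t)dim * dim * dim, 0.0),
      nxt((size_t)dim * dim * dim, 0.0);
  auto idx = [dim](int t, int u, int w) {
    return (size_t)(t * dim + u) * dim + w;
  };
  // start: only (0,0,0) defined at each n; recursion consumes higher n
  // cur holds R^{n} values; iterate n from L down to 0
  std::vector<std::vector<double> > Rn(L + 1,
      std::vector<double>((size_t)dim * dim * dim, 0.0));
  double pw = 1.0;
  for (int n = 0; n <= L; ++n) {
    Rn[n][idx(0, 0, 0)] = pw * F[n];
    pw *= -2.0 * alpha;
  }
  for (int total = 1; total <= L; ++total) {
    for (int n = 0; n <= L - total; ++n) {
      for (int t = 0; t <= total; ++t)
        for (int u = 0; u <= total - t; ++u) {
          int w = total - t - u;
          double val;
          if (t > 0) {
            val = x * Rn[n + 1][idx(t - 1, u, w)];
            if (t > 1) val += (t - 1) * Rn[n + 1][idx(t - 2, u, w)];
          } else if (u > 0) {
            val = y * Rn[n + 1][idx(t, u - 1, w)];
            if (u > 1) val += (u - 1) * Rn[n + 1][idx(t, u - 2, w)];
          } else {
            val = z * Rn[n + 1][idx(t, u, w - 1)];
            if (w > 1) val += (w - 1) * Rn[n + 1][idx(t, u, w - 2)];
          }
          Rn[n][idx(t, u, w)] = val;
        }
    }
  }
  R.L = L;
  R.v.assign((size_t)dim * dim * dim, 0.0);
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u <= L - t; ++u)
      for (int w = 0; w <= L - t - u; ++w)
        R.at(t, u, w) = Rn[0][idx(t, u, w)];
  (void)cur; (void)nxt;
}

// ------------------------------------------------------------ shell plumbing
struct Shell {
  int l;
  double cx, cy, cz;
  std::vector<double> exps, coefs;
  int ncart() const { return (l + 1) * (l + 2) / 2; }
};

static std::vector<Shell> unpackShells(IntegerVector l, NumericMatrix centers,
                                       IntegerVector nprim, NumericVector exps,
                                       NumericVector coefs) {
  std::vector<Shell> sh(l.size());
  int off = 0;
  for (int s = 0; s < l.size(); ++s) {
    sh[s].l = l[s];
    sh[s].cx = centers(s, 0); sh[s].cy = centers(s, 1); sh[s].cz = centers(s, 2);
    for (int k = 0; k < nprim[s]; ++k) {
      sh[s].exps.push_back(exps[off + k]);
      sh[s].coefs.push_back(coefs[off + k]);
    }
    off += nprim[s];
  }
  return sh;
}

// cartesian component list for angular momentum l, canonical order
static void cartList(int l, std::vector<int>& lx, std::vector<int>& ly,
                     std::vector<int>& lz) {
  lx.clear(); ly.clear(); lz.clear();
  for (int a = l; a >= 0; --a)
    for (int b = l - a; b >= 0; --b) {
      lx.push_back(a); ly.push_back(b); lz.push_back(l - a - b);
    }
}

static int nbasTotal(const std::vector<Shell>& sh) {
  int n = 0;
  for (size_t s = 0; s < sh.size(); ++s) n += sh[s].ncart();
  return n;
}

// ------------------------------------------------------- one-electron matrix
// [[Rcpp::export]]
List cppOneElectron(IntegerVector l, NumericMatrix centers, IntegerVector nprim,
                    NumericVector exps, NumericVector coefs,
                    NumericMatrix atompos, NumericVector atomZ,
                    NumericVector origin) {
  std::vector<Shell> sh = unpackShells(l, centers, nprim, exps, coefs);
  int n = nbasTotal(sh);
  NumericMatrix S(n, n), T(n, n), V(n, n), Dx(n, n), Dy(n, n), Dz(n, n);
  int offA = 0;
  for (size_t A = 0; A < sh.size(); ++A) {
    std::vector<int> ax, ay, az;
    cartList(sh[A].l, ax, ay, az);
    int offB = 0;
    for (size_t B = 0; B < sh.size(); ++B) {
      std::vector<int> bx, by, bz;
      cartList(sh[B].l, bx, by, bz);
      double ABx = sh[A].cx - sh[B].cx, ABy = sh[A].cy - sh[B].cy,
             ABz = sh[A].cz - sh[B].cz;
      for (size_t ka = 0; ka < sh[A].exps.size(); ++ka)
        for (size_t kb = 0; kb < sh[B].exps.size(); ++kb) {
          double a = sh[A].exps[ka], b = sh[B].exps[kb];
          double cc = sh[A].coefs[ka] * sh[B].coefs[kb];
          double p = a + b;
          double Px = (a * sh[A].cx + b * sh[B].cx) / p;
          double Py = (a * sh[A].cy + b * sh[B].cy) / p;
          double Pz = (a * sh[A].cz + b * sh[B].cz) / p;
          int la = sh[A].l, lb = sh[B].l;
          EArr Ex, Ey, Ez;
          buildE(Ex, la, lb + 2, a, b, ABx);
          buildE(Ey, la, lb + 2, a, b, ABy);
          buildE(Ez, la, lb + 2, a, b, ABz);
          double sp = std::sqrt(PI / p);
          // nuclear attraction hermite integrals per atom
          int L = la + lb;
          std::vector<RArr> Rat(atompos.nrow());
          for (int at = 0; at < atompos.nrow(); ++at)
            buildR(Rat[at], L, p, Px - atompos(at, 0), Py - atompos(at, 1),
                   Pz - atompos(at, 2));
          for (size_t ia = 0; ia < ax.size(); ++ia)
            for (size_t ib = 0; ib < bx.size(); ++ib) {
              int i1 = ax[ia], i2 = ay[ia], i3 = az[ia];
              int j1 = bx[ib], j2 = by[ib], j3 = bz[ib];
              double sx = Ex.at(i1, j1, 0) * sp;
              double sy = Ey.at(i2, j2, 0) * sp;
              double sz = Ez.at(i3, j3, 0) * sp;
              // kinetic 1d pieces
              auto t1d = [&](EArr& E, int i, int j) {
                double s0 = E.at(i, j, 0) * sp;
                double s2 = E.at(i, j + 2, 0) * sp;
                double sm = (j >= 2) ? E.at(i, j - 2, 0) * sp : 0.0;
                return -2.0 * b * b * s2 + b * (2.0 * j + 1.0) * s0 -
                       0.5 * j * (j - 1.0) * sm;
              };
              double tx = t1d(Ex, i1, j1), ty = t1d(Ey, i2, j2),
                     tz = t1d(Ez, i3, j3);
              // dipole 1d: <x - O>
              double dx1 = (Ex.at(i1, j1, 1) + (Px - origin[0]) *
                            Ex.at(i1, j1, 0)) * sp;
              double dy1 = (Ey.at(i2, j2, 1) + (Py - origin[1]) *
                            Ey.at(i2, j2, 0)) * sp;
              double dz1 = (Ez.at(i3, j3, 1) + (Pz - origin[2]) *
                            Ez.at(i3, j3, 0)) * sp;
              int I = offA + ia, J = offB + ib;
              S(I, J) += cc * sx * sy * sz;
              T(I, J) += cc * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
              Dx(I, J) += cc * dx1 * sy * sz;
              Dy(I, J) += cc * sx * dy1 * sz;
              Dz(I, J) += cc * sx * sy * dz1;
              // nuclear attraction
              double vsum = 0.0;
              for (int at = 0; at < atompos.nrow(); ++at) {
                double acc = 0.0;
                for (int t = 0; t <= i1 + j1; ++t)
                  for (int u = 0; u <= i2 + j2; ++u)
                    for (int w = 0; w <= i3 + j3; ++w)
                      acc += Ex.at(i1, j1, t) * Ey.at(i2, j2, u) *
                             Ez.at(i3, j3, w) * Rat[at].at(t, u, w);
                vsum += -atomZ[at] * acc;
              }
              V(I, J) += cc * 2.0 * PI / p * vsum;
            }
        }
      offB += sh[B].ncart();
    }
    offA += sh[A].ncart();
  }
  return List::create(Named("S") = S, Named("T") = T, Named("V") = V,
                      Named("Dx") = Dx, Named("Dy") = Dy, Named("Dz") = Dz);
}

// ---------------------------------------------------- generic ERI over pairs
// hermite representation of a contracted shell-pair primitive combination
struct PrimPair {
  double p, Px, Py, Pz, cc;
  EArr Ex, Ey, Ez;
};

static void pairPrims(const Shell& A, const Shell& B,
                      std::vector<PrimPair>& out) {
  out.clear();
  double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
  for (size_t ka = 0; ka < A.exps.size(); ++ka)
    for (size_t kb = 0; kb < B.exps.size(); ++kb) {
      PrimPair pp;
      double a = A.exps[ka], b = B.exps[kb];
      pp.p = a + b;
      pp.Px = (a * A.cx + b * B.cx) / pp.p;
      pp.Py = (a * A.cy + b * B.cy) / pp.p;
      pp.Pz = (a * A.cz + b * B.cz) / pp.p;
      pp.cc = A.coefs[ka] * B.coefs[kb];
      buildE(pp.Ex, A.l, B.l, a, b, ABx);
      buildE(pp.Ey, A.l, B.l, a, b, ABy);
      buildE(pp.Ez, A.l, B.l, a, b, ABz);
      out.push_back(pp);
    }
}

// contract one (bra-pair, ket-pair) primitive combination into the target
static void eriBlock(const Shell& A, const Shell& B, const Shell& C,
                     const Shell& D, std::vector<double>& block) {
  // block sized ncA*ncB*ncC*ncD, row-major (a,b,c,d)
  std::vector<int> axl, ayl, azl, bxl, byl, bzl, cxl, cyl, czl, dxl, dyl, dzl;
  cartList(A.l, axl, ayl, azl);
  cartList(B.l, bxl, byl, bzl);
  cartList(C.l, cxl, cyl, czl);
  cartList(D.l, dxl, dyl, dzl);
  int nA = axl.size(), nB = bxl.size(), nC = cxl.size(), nD = dxl.size();
  block.assign((size_t)nA * nB * nC * nD, 0.0);
  std::vector<PrimPair> bra, ket;
  pairPrims(A, B, bra);
  pairPrims(C, D, ket);
  int Lb = A.l + B.l, Lk = C.l + D.l, L = Lb + Lk;
  for (size_t ib = 0; ib < bra.size(); ++ib)
    for (size_t ik = 0; ik < ket.size(); ++ik) {
      const PrimPair& P1 = bra[ib];
      const PrimPair& P2 = ket[ik];
      double p = P1.p, q = P2.p;
      double alpha = p * q / (p + q);
      RArr R;
      buildR(R, L, alpha, P1.Px - P2.Px, P1.Py - P2.Py, P1.Pz - P2.Pz);
      double pref = 2.0 * std::pow(PI, 2.5) /
                    (p * q * std::sqrt(p + q)) * P1.cc * P2.cc;
      size_t id4 = 0;
      for (int a = 0; a < nA; ++a)
        for (int b = 0; b < nB; ++b) {
          int i1 = axl[a] + bxl[b] + 0;  // max t ranges below
          (void)i1;
          for (int c = 0; c < nC; ++c)
            for (int d = 0; d < nD; ++d, ++id4) {
              double acc = 0.0;
              int tmax = axl[a] + bxl[b], umax = ayl[a] + byl[b],
                  wmax = azl[a] + bzl[b];
              int tmax2 = cxl[c] + dxl[d], umax2 = cyl[c] + dyl[d],
                  wmax2 = czl[c] + dzl[d];
              for (int t = 0; t <= tmax; ++t) {
                double ex = P1.Ex.at(axl[a], bxl[b], t);
                if (ex == 0.0) continue;
                for (int u = 0; u <= umax; ++u) {
                  double ey = P1.Ey.at(ayl[a], byl[b], u);
                  if (ey == 0.0) continue;
                  for (int w = 0; w <= wmax; ++w) {
                    double ez = P1.Ez.at(azl[a], bzl[b], w);
                    if (ez == 0.0) continue;
                    double e1 = ex * ey * ez;
                    for (int t2 = 0; t2 <= tmax2; ++t2) {
                      double fx = P2.Ex.at(cxl[c], dxl[d], t2);
                      if (fx == 0.0) continue;
                      for (int u2 = 0; u2 <= umax2; ++u2) {
                        double fy = P2.Ey.at(cyl[c], dyl[d], u2);
                        if (fy == 0.0) continue;
                        for (int w2 = 0; w2 <= wmax2; ++w2) {
                          double fz = P2.Ez.at(czl[c], dzl[d], w2);
                          if (fz == 0.0) continue;
                          double sgn = ((t2 + u2 + w2) % 2) ? -1.0 : 1.0;
                          acc += e1 * fx * fy * fz * sgn *
                                 R.at(t + t2, u + u2, w + w2);
                        }
                      }
                    }
                  }
                }
              }
              block[id4] += pref * acc;
            }
        }
      (void)id4;
    }
}

// full four-center tensor (small systems only; guarded on the R side)
// [[Rcpp::export]]
NumericVector cppERI4(IntegerVector l, NumericMatrix centers,
                      IntegerVector nprim, NumericVector exps,
                      NumericVector coefs) {
  std::vector<Shell> sh = unpackShells(l, centers, nprim, exps, coefs);
  int n = nbasTotal(sh);
  NumericVector out((R_xlen_t)n * n * n * n);
  std::vector<int> off(sh.size());
  {
    int o = 0;
    for (size_t s = 0; s < sh.size(); ++s) { off[s] = o; o += sh[s].ncart(); }
  }
  std::vector<double> block;
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B < sh.size(); ++B)
      for (size_t C = 0; C < sh.size(); ++C)
        for (size_t D = 0; D < sh.size(); ++D) {
          eriBlock(sh[A], sh[B], sh[C], sh[D], block);
          int nA = sh[A].ncart(), nB = sh[B].ncart(), nC = sh[C].ncart(),
              nD = sh[D].ncart();
          size_t id4 = 0;
          for (int a = 0; a < nA; ++a)
            for (int b = 0; b < nB; ++b)
              for (int c = 0; c < nC; ++c)
                for (int d = 0; d < nD; ++d, ++id4) {
                  R_xlen_t I = off[A] + a, J = off[B] + b, K = off[C] + c,
                           Ld = off[D] + d;
                  out[((Ld * n + K) * n + J) * n + I] = block[id4];
                }
        }
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  return out;
}

// three-center (P|pq), P from the auxiliary set (treated as aux x s-dummy pair)
// [[Rcpp::export]]
NumericVector cppERI3(IntegerVector la, NumericMatrix ca, IntegerVector npa,
                      NumericVector ea, NumericVector coa, IntegerVector lp,
                      NumericMatrix cp, IntegerVector npp, NumericVector ep,
                      NumericVector cop) {
  std::vector<Shell> aux = unpackShells(la, ca, npa, ea, coa);
  std::vector<Shell> pri = unpackShells(lp, cp, npp, ep, cop);
  int naux = nbasTotal(aux), n = nbasTotal(pri);
  NumericVector out((R_xlen_t)naux * n * n);
  Shell dummy;  // unit s function with zero exponent: exp(-0 r^2) = 1
  dummy.l = 0; dummy.cx = dummy.cy = dummy.cz = 0.0;
  dummy.exps.push_back(0.0);
  dummy.coefs.push_back(1.0);
  std::vector<int> offA(aux.size()), offP(pri.size());
  {
    int o = 0;
    for (size_t s = 0; s < aux.size(); ++s) { offA[s] = o; o += aux[s].ncart(); }
    o = 0;
    for (size_t s = 0; s < pri.size(); ++s) { offP[s] = o; o += pri[s].ncart(); }
  }
  std::vector<double> block;
  for (size_t P = 0; P < aux.size(); ++P)
    for (size_t A = 0; A < pri.size(); ++A)
      for (size_t B = 0; B < pri.size(); ++B) {
        eriBlock(aux[P], dummy, pri[A], pri[B], block);
        int nP = aux[P].ncart(), nA = pri[A].ncart(), nB = pri[B].ncart();
        size_t id4 = 0;
        for (int pI = 0; pI < nP; ++pI)
          for (int a = 0; a < nA; ++a)
            for (int b = 0; b < nB; ++b, ++id4) {
              R_xlen_t I = offA[P] + pI, J = offP[A] + a, K = offP[B] + b;
              out[(K * n + J) * naux + I] = block[id4];
            }
      }
  out.attr("dim") = IntegerVector::create(naux, n, n);
  return out;
}

// two-center (P|Q) Coulomb metric over the auxiliary set
// [[Rcpp::export]]
NumericMatrix cppERI2(IntegerVector l, NumericMatrix centers,
                      IntegerVector nprim, NumericVector exps,
                      NumericVector coefs) {
  std::vector<Shell> sh = unpackShells(l, centers, nprim, exps, coefs);
  int n = nbasTotal(sh);
  NumericMatrix out(n, n);
  Shell dummy;
  dummy.l = 0; dummy.cx = dummy.cy = dummy.cz = 0.0;
  dummy.exps.push_back(0.0);
  dummy.coefs.push_back(1.0);
  std::vector<int> off(sh.size());
  {
    int o = 0;
    for (size_t s = 0; s < sh.size(); ++s) { off[s] = o; o += sh[s].ncart(); }
  }
  std::vector<double> block;
  for (size_t P = 0; P < sh.size(); ++P)
    for (size_t Q = 0; Q < sh.size(); ++Q) {
      eriBlock(sh[P], dummy, sh[Q], dummy, block);
      int nP = sh[P].ncart(), nQ = sh[Q].ncart();
      size_t id4 = 0;
      for (int a = 0; a < nP; ++a)
        for (int b = 0; b < nQ; ++b, ++id4)
          out(off[P] + a, off[Q] + b) = block[id4];
    }
  return out;
}
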