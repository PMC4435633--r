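// Compiled core of the cyclic-cluster NDDO engine.
//
// Internal unit conventions: distances in bohr unless a variable is suffixed
// _ang; interaction kernels in hartree, converted to eV at the assembly
// boundary; the core-repulsion exponential/Gaussian terms use Angstrom, as in
// the original MNDO/AM1 parameterizations.

#include <RcppArmadillo.h>
#include <vector>
#include <array>
#include <cmath>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double EV = 27.21;               // eV per hartree (legacy)
static const double A0 = 0.529167;            // Angstrom per bohr (legacy)

// apar column layout (kept in sync with .atom_params_matrix on the R side)
enum {
  C_ZV = 0, C_NB, C_NQ, C_ZS, C_ZP, C_USS, C_UPP, C_BETAS, C_BETAP,
  C_GSS, C_GSP, C_GPP, C_GP2, C_HSP,
  C_ALP, C_D1, C_D2, C_RHO0, C_RHO1, C_RHO2, C_GMONO,
  C_ELEMZ, C_EISOL, C_HFAT, C_NGAUSS, C_GAUSS0 /* 12 more */
};

// ---------------------------------------------------------------------------
// Auxiliary integrals for two-center Slater-orbital overlaps
// A_k(p) = int_1^inf x^k e^{-p x} dx, B_k(q) = int_{-1}^{1} x^k e^{-q x} dx
// ---------------------------------------------------------------------------

static void aux_A(double p, int kmax, double* A) {
  double ep = std::exp(-p);
  A[0] = ep / p;
  for (int k = 1; k <= kmax; ++k) A[k] = (ep + k * A[k - 1]) / p;
}

static void aux_B(double q, int kmax, double* B) {
  // Taylor series in q; upward recursion is catastrophically unstable for
  // small and moderate q, while the series is accurate (relative error
  // ~ eps * e^{|q|} / |B_k|, benign here because overlaps carry e^{-p} with
  // p >= |q|). Callers bail out earlier for |q| beyond ~300.
  int nterm = 40 + (int)(2.5 * std::fabs(q));
  for (int k = 0; k <= kmax; ++k) {
    double sum = 0.0, term = 1.0;
    for (int m = 0; m <= nterm; ++m) {
      if (m > 0) term *= (-q) / m;
      int kk = k + m;
      if ((kk % 2) == 0) sum += term * 2.0 / (kk + 1);
    }
    B[k] = sum;
  }
}

// small dense polynomial in (xi, eta): c[i][j] * xi^i eta^j
struct Poly {
  static const int NMAX = 14;
  double c[NMAX][NMAX];
  Poly() { for (int i = 0; i < NMAX; ++i) for (int j = 0; j < NMAX; ++j) c[i][j] = 0.0; }
  void addmono(int i, int j, double v) { c[i][j] += v; }
};

static Poly pmul(const Poly& a, const Poly& b) {
  Poly r;
  for (int i = 0; i < Poly::NMAX; ++i)
    for (int j = 0; j < Poly::NMAX; ++j) {
      if (a.c[i][j] == 0.0) continue;
      for (int k = 0; k + i < Poly::NMAX; ++k)
        for (int l = 0; l + j < Poly::NMAX; ++l) {
          if (b.c[k][l] == 0.0) continue;
          r.c[i + k][j + l] += a.c[i][j] * b.c[k][l];
        }
    }
  return r;
}

// (xi + s*eta)^n
static Poly pbin(int n, double s) {
  Poly r;
  double binom = 1.0;
  for (int k = 0; k <= n; ++k) {
    r.addmono(n - k, k, binom * std::pow(s, k));
    binom = binom * (n - k) / (k + 1.0);
  }
  return r;
}

static double factorial(int n) {
  double f = 1.0;
  for (int i = 2; i <= n; ++i) f *= i;
  return f;
}

// Overlap of two Slater orbitals separated by R along +z (local frame).
// la/lb: 0 = s, 1 = p; type: 0 = sigma, 1 = pi. Signs follow the convention
// that both p_sigma orbitals point along +z (from a towards b).
static double sto_overlap(int na, int la, int nb, int lb, double za,
                          double zb, double R, int type) {
  if (R < 1e-12) {
    // co-centered: orthonormality of the angular parts
    if (la != lb) return 0.0;
    // radial overlap of normalized STOs
    double num = std::pow(2 * za, na + 0.5) * std::pow(2 * zb, nb + 0.5) *
                 factorial(na + nb) /
                 std::sqrt(factorial(2 * na) * factorial(2 * nb));
    return num / std::pow(za + zb, na + nb + 1);
  }
  double p = 0.5 * R * (za + zb);
  double q = 0.5 * R * (za - zb);
  if (p > 280.0) return 0.0;     // exponentially zero overlap
  Poly poly;
  double ang;
  if (la == 0 && lb == 0) {
    poly = pmul(pbin(na, 1.0), pbin(nb, -1.0));
    ang = 0.5;
  } else if (la == 0 && lb == 1) {          // s | p_sigma
    Poly t = pmul(pbin(na, 1.0), pbin(nb - 1, -1.0));
    Poly f; f.addmono(1, 1, 1.0); f.addmono(0, 0, -1.0);   // (xi*eta - 1)
    poly = pmul(t, f);
    ang = std::sqrt(3.0) / 2.0;
  } else if (la == 1 && lb == 0) {          // p_sigma | s
    Poly t = pmul(pbin(na - 1, 1.0), pbin(nb, -1.0));
    Poly f; f.addmono(1, 1, 1.0); f.addmono(0, 0, 1.0);    // (1 + xi*eta)
    poly = pmul(t, f);
    ang = std::sqrt(3.0) / 2.0;
  } else if (type == 0) {                   // p_sigma | p_sigma
    Poly t = pmul(pbin(na - 1, 1.0), pbin(nb - 1, -1.0));
    Poly f; f.addmono(2, 2, 1.0); f.addmono(0, 0, -1.0);   // (xi^2 eta^2 - 1)
    poly = pmul(t, f);
    ang = 1.5;
  } else {                                  // p_pi | p_pi
    Poly t = pmul(pbin(na - 1, 1.0), pbin(nb - 1, -1.0));
    Poly f1; f1.addmono(2, 0, 1.0); f1.addmono(0, 0, -1.0); // (xi^2 - 1)
    Poly f2; f2.addmono(0, 0, 1.0); f2.addmono(0, 2, -1.0); // (1 - eta^2)
    poly = pmul(pmul(t, f1), f2);
    ang = 0.75;
  }
  double Na = std::pow(2 * za, na + 0.5) / std::sqrt(factorial(2 * na));
  double Nb = std::pow(2 * zb, nb + 0.5) / std::sqrt(factorial(2 * nb));
  double pref = Na * Nb * ang * std::pow(R / 2.0, na + nb + 1);

  int kmax = Poly::NMAX - 1;
  double Avals[Poly::NMAX], Bvals[Poly::NMAX];
  aux_A(p, kmax, Avals);
  aux_B(q, kmax, Bvals);
  double s = 0.0;
  for (int i = 0; i < Poly::NMAX; ++i)
    for (int j = 0; j < Poly::NMAX; ++j)
      if (poly.c[i][j] != 0.0) s += poly.c[i][j] * Avals[i] * Bvals[j];
  return pref * s;
}

// [[Rcpp::export]]
double sto_overlap_cpp(int na, int la, int nb, int lb, double za, double zb,
                       double r_bohr, int type) {
  return sto_overlap(na, la, nb, lb, za, zb, r_bohr, type);
}

// local frame: columns of U (4x4, s + p block) express local orbitals in the
// global basis; local z points from A to B. Deterministic completion for the
// z-aligned case.
static void local_frame(const double* dr, double R, double U[4][4]) {
  double zx = dr[0] / R, zy = dr[1] / R, zz = dr[2] / R;
  double vx, vy, vz;
  if (std::fabs(zx) < 0.9) { vx = 1; vy = 0; vz = 0; }
  else { vx = 0; vy = 1; vz = 0; }
  double dot = vx * zx + vy * zy + vz * zz;
  double xx = vx - dot * zx, xy = vy - dot * zy, xz = vz - dot * zz;
  double nx = std::sqrt(xx * xx + xy * xy + xz * xz);
  xx /= nx; xy /= nx; xz /= nx;
  double yx = zy * xz - zz * xy;
  double yy = zz * xx - zx * xz;
  double yz = zx * xy - zy * xx;
  for (int i = 0; i < 4; ++i) for (int j = 0; j < 4; ++j) U[i][j] = 0.0;
  U[0][0] = 1.0;
  // global p index 1,2,3 = px,py,pz; local columns 1,2,3 = xl,yl,zl
  U[1][1] = xx; U[2][1] = xy; U[3][1] = xz;
  U[1][2] = yx; U[2][2] = yy; U[3][2] = yz;
  U[1][3] = zx; U[2][3] = zy; U[3][3] = zz;
}

// Overlap block between the bases of two atoms, global frame, dr in bohr.
static void overlap_block(const double* pa, const double* pb,
                          const double* dr, double* S /* 4x4 row-major */) {
  int nba = (int)pa[C_NB], nbb = (int)pb[C_NB];
  double R = std::sqrt(dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2]);
  for (int i = 0; i < 16; ++i) S[i] = 0.0;
  if (R < 1e-9) return;                   // same site handled elsewhere
  int na = (int)pa[C_NQ], nb = (int)pb[C_NQ];
  double Sl[4][4] = {{0}};
  Sl[0][0] = sto_overlap(na, 0, nb, 0, pa[C_ZS], pb[C_ZS], R, 0);
  if (nbb == 4)
    Sl[0][3] = sto_overlap(na, 0, nb, 1, pa[C_ZS], pb[C_ZP], R, 0);
  if (nba == 4)
    Sl[3][0] = sto_overlap(na, 1, nb, 0, pa[C_ZP], pb[C_ZS], R, 0);
  if (nba == 4 && nbb == 4) {
    Sl[3][3] = sto_overlap(na, 1, nb, 1, pa[C_ZP], pb[C_ZP], R, 0);
    double spi = sto_overlap(na, 1, nb, 1, pa[C_ZP], pb[C_ZP], R, 1);
    Sl[1][1] = spi; Sl[2][2] = spi;
  }
  double U[4][4];
  local_frame(dr, R, U);
  for (int m = 0; m < nba; ++m)
    for (int l = 0; l < nbb; ++l) {
      double v = 0.0;
      for (int c = 0; c < 4; ++c) {
        if (U[m][c] == 0.0) continue;
        for (int e = 0; e < 4; ++e)
          if (Sl[c][e] != 0.0) v += U[m][c] * Sl[c][e] * U[l][e];
      }
      S[m * 4 + l] = v;
    }
}

// [[Rcpp::export]]
NumericMatrix overlap_block_cpp(NumericVector pa, NumericVector pb,
                                NumericVector dr_bohr) {
  double S[16];
  overlap_block(pa.begin(), pb.begin(), dr_bohr.begin(), S);
  NumericMatrix out(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = S[i * 4 + j];
  return out;
}

// ---------------------------------------------------------------------------
// Two-electron integrals via distributed multipoles
// ---------------------------------------------------------------------------

// canonical pair index for (mu <= nu), basis order s,px,py,pz
static const int PAIR_I[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
static const int PAIR_J[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};
static int pair_index(int i, int j) {
  if (i > j) std::swap(i, j);
  static const int map[4][4] = {{0, 1, 2, 3}, {1, 4, 5, 6},
                                {2, 5, 7, 8}, {3, 6, 8, 9}};
  return map[i][j];
}

// Point-charge configuration of one orbital-pair distribution (local frame)
struct Config {
  int ncharge;
  double q[4];
  double o[4][3];   // offsets, bohr
  double rho;       // additive Klopman radius, bohr
};

// distributions: each pair has up to 2 configurations
static int pair_configs(int pidx, const double* par, Config cfg[2]) {
  double d1 = par[C_D1], d2 = par[C_D2];
  double r0 = par[C_RHO0], r1 = par[C_RHO1], r2 = par[C_RHO2];
  int i = PAIR_I[pidx], j = PAIR_J[pidx];
  int n = 0;
  auto zero3 = [](double* v) { v[0] = v[1] = v[2] = 0.0; };
  if (i == 0 && j == 0) {                       // (ss) : monopole
    cfg[0].ncharge = 1; cfg[0].q[0] = 1.0; zero3(cfg[0].o[0]);
    cfg[0].rho = r0; n = 1;
  } else if (i == 0) {                          // (s p_k) : dipole along k
    int k = j - 1;
    cfg[0].ncharge = 2; cfg[0].rho = r1;
    cfg[0].q[0] = 0.5; cfg[0].q[1] = -0.5;
    zero3(cfg[0].o[0]); zero3(cfg[0].o[1]);
    cfg[0].o[0][k] = d1; cfg[0].o[1][k] = -d1;
    n = 1;
  } else if (i == j) {                          // (p_k p_k) : mono + lin quad
    int k = i - 1;
    cfg[0].ncharge = 1; cfg[0].q[0] = 1.0; zero3(cfg[0].o[0]);
    cfg[0].rho = r0;
    cfg[1].ncharge = 3; cfg[1].rho = r2;
    cfg[1].q[0] = 0.25; cfg[1].q[1] = 0.25; cfg[1].q[2] = -0.5;
    zero3(cfg[1].o[0]); zero3(cfg[1].o[1]); zero3(cfg[1].o[2]);
    cfg[1].o[0][k] = 2 * d2; cfg[1].o[1][k] = -2 * d2;
    n = 2;
  } else {                                      // (p_k p_l) : square quad
    int k = i - 1, l = j - 1;
    cfg[0].ncharge = 4; cfg[0].rho = r2;
    cfg[0].q[0] = 0.25; cfg[0].q[1] = 0.25;
    cfg[0].q[2] = -0.25; cfg[0].q[3] = -0.25;
    for (int t = 0; t < 4; ++t) zero3(cfg[0].o[t]);
    cfg[0].o[0][k] = d2;  cfg[0].o[0][l] = d2;
    cfg[0].o[1][k] = -d2; cfg[0].o[1][l] = -d2;
    cfg[0].o[2][k] = d2;  cfg[0].o[2][l] = -d2;
    cfg[0].o[3][k] = -d2; cfg[0].o[3][l] = d2;
    n = 1;
  }
  return n;
}

// Gaussian damping additive term (bohr) for center distance r > ccut.
// conv 0: paper grouping, exp(-0.5 (r-c)^2 (1/GA + 1/GB));
// conv 1: alternate grouping, [exp(-0.25 (r-c)^2) (1/GA + 1/GB)]^2.
static double damp_additive(double r, double ccut, double ginvsum, int conv) {
  double x = r - ccut;
  if (conv == 0) {
    double e = -0.5 * x * x * ginvsum;
    return (e < -700.0) ? 0.0 : std::exp(e);
  }
  double g = std::exp(-0.25 * x * x);
  double t = g * ginvsum;
  return t * t;
}

// Local-frame 10x10 ERI block (hartree), centers separated by r along +z,
// with screening (r_eff, lambda) and damping already decided by the caller:
// reff = effective center distance (bohr), lam = multipole contraction,
// damped = use 1/(d + add) kernel with additive `add`, else Klopman.
static void eri_local(const double* pa, const double* pb, double reff,
                      double lam, bool damped, double add,
                      double G[10][10]) {
  int npa = ((int)pa[C_NB] == 1) ? 1 : 10;
  int npb = ((int)pb[C_NB] == 1) ? 1 : 10;
  for (int i = 0; i < 10; ++i) for (int j = 0; j < 10; ++j) G[i][j] = 0.0;
  Config ca[2], cb[2];
  for (int ip = 0; ip < npa; ++ip) {
    int na = pair_configs(ip, pa, ca);
    for (int jp = 0; jp < npb; ++jp) {
      int nb = pair_configs(jp, pb, cb);
      double v = 0.0;
      for (int a = 0; a < na; ++a) {
        for (int b = 0; b < nb; ++b) {
          double rho = ca[a].rho + cb[b].rho;
          for (int s = 0; s < ca[a].ncharge; ++s) {
            double ax = ca[a].o[s][0] * lam;
            double ay = ca[a].o[s][1] * lam;
            double az = ca[a].o[s][2] * lam;
            for (int t = 0; t < cb[b].ncharge; ++t) {
              double dx = cb[b].o[t][0] * lam - ax;
              double dy = cb[b].o[t][1] * lam - ay;
              double dz = reff + cb[b].o[t][2] * lam - az;
              double d2 = dx * dx + dy * dy + dz * dz;
              double qq = ca[a].q[s] * cb[b].q[t];
              if (damped) v += qq / (std::sqrt(d2) + add);
              else v += qq / std::sqrt(d2 + rho * rho);
            }
          }
        }
      }
      G[ip][jp] = v;
    }
  }
  // Azimuthal gauge consistency: the (p_x p_y)-type distribution interacts
  // only with its own kind in the local frame, and its value is fixed by
  // the axial-symmetry identity [xy|xy] = ([xx|xx] - [xx|yy]) / 2 (required
  // for the rotated tensor to be independent of the arbitrary local x axis).
  if (npa == 10 && npb == 10) {
    G[5][5] = 0.5 * (G[4][4] - G[4][7]);
  }
}

// screening helpers (Angstrom domain mirrors the R implementation)
static double eff_dist_ang(double r, double alpha) {
  if (r < alpha) return r;
  if (r <= 2 * alpha) return -alpha / 2 + 2 * r - r * r / (2 * alpha);
  return 1.5 * alpha;
}
static double contraction(double r, double alpha) {
  if (r < alpha) return 1.0;
  double l = 2.0 - r / alpha;
  return (l > 0.0) ? l : 0.0;
}

// Global-frame condensed 10x10 ERI block for displacement dr (bohr).
static void eri_block(const double* pa, const double* pb, const double* dr,
                      double alpha_bohr, double ccut, int conv, bool screen,
                      double G[10][10]) {
  double R = std::sqrt(dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2]);
  double reff = R, lam = 1.0;
  if (screen && R >= alpha_bohr) {
    double a_ang = alpha_bohr * A0, r_ang = R * A0;
    reff = eff_dist_ang(r_ang, a_ang) / A0;
    lam = contraction(r_ang, a_ang);
  }
  bool damped = (R >= ccut);
  double add = 0.0;
  if (damped) {
    double ginvsum = 1.0 / pa[C_GMONO] + 1.0 / pb[C_GMONO];
    add = damp_additive(R, ccut, ginvsum, conv);
  }
  double Gl[10][10];
  eri_local(pa, pb, reff, lam, damped, add, Gl);

  int npa = ((int)pa[C_NB] == 1) ? 1 : 10;
  int npb = ((int)pb[C_NB] == 1) ? 1 : 10;
  if (npa == 1 && npb == 1) {
    for (int i = 0; i < 10; ++i) for (int j = 0; j < 10; ++j) G[i][j] = 0.0;
    G[0][0] = Gl[0][0];
    return;
  }
  double U[4][4];
  local_frame(dr, R, U);
  // condensed pair transform K[(global pair),(local pair)]
  double KA[10][10], KB[10][10];
  for (int gp = 0; gp < 10; ++gp) {
    int m = PAIR_I[gp], n = PAIR_J[gp];
    for (int lp = 0; lp < 10; ++lp) {
      int c = PAIR_I[lp], e = PAIR_J[lp];
      double v = U[m][c] * U[n][e];
      if (c != e) v += U[m][e] * U[n][c];
      KA[gp][lp] = v;
      KB[gp][lp] = v;
    }
  }
  // G = KA * Gl * KB^T
  double tmp[10][10];
  for (int i = 0; i < 10; ++i)
    for (int j = 0; j < 10; ++j) {
      double v = 0.0;
      for (int k = 0; k < 10; ++k)
        if (KA[i][k] != 0.0) v += KA[i][k] * Gl[k][j];
      tmp[i][j] = v;
    }
  for (int i = 0; i < 10; ++i)
    for (int j = 0; j < 10; ++j) {
      double v = 0.0;
      for (int k = 0; k < 10; ++k)
        if (KB[j][k] != 0.0) v += tmp[i][k] * KB[j][k];
      G[i][j] = v;
    }
  if (npa == 1)
    for (int i = 1; i < 10; ++i) for (int j = 0; j < 10; ++j) G[i][j] = 0.0;
  if (npb == 1)
    for (int i = 0; i < 10; ++i) for (int j = 1; j < 10; ++j) G[i][j] = 0.0;
}

// [[Rcpp::export]]
NumericMatrix eri_block_cpp(NumericVector pa, NumericVector pb,
                            NumericVector dr_bohr, double alpha_bohr,
                            double ccut_bohr, int conv, bool screen) {
  double G[10][10];
  eri_block(pa.begin(), pb.begin(), dr_bohr.begin(), alpha_bohr, ccut_bohr,
            conv, screen, G);
  NumericMatrix out(10, 10);
  for (int i = 0; i < 10; ++i)
    for (int j = 0; j < 10; ++j) out(i, j) = G[i][j];
  return out;
}

// Core-core repulsion for one pair at distance r (bohr); returns eV.
// gss_ev: the (ss|ss) integral of this pair in eV (damped/screened upstream).
static double core_core(const double* pa, const double* pb, double r_bohr,
                        double gss_ev) {
  double r_ang = r_bohr * A0;
  double za = pa[C_ZV], zb = pb[C_ZV];
  int ea = (int)pa[C_ELEMZ], eb = (int)pb[C_ELEMZ];
  double ta = std::exp(-pa[C_ALP] * r_ang);
  double tb = std::exp(-pb[C_ALP] * r_ang);
  // O-H / N-H special form of the MNDO-family core repulsion
  if ((ea == 7 || ea == 8) && eb == 1) ta *= r_ang;
  if ((eb == 7 || eb == 8) && ea == 1) tb *= r_ang;
  double e = za * zb * gss_ev * (1.0 + ta + tb);
  // AM1 core Gaussians (K eV*A, L A^-2, M A)
  double gsum = 0.0;
  int nga = (int)pa[C_NGAUSS];
  for (int k = 0; k < nga; ++k) {
    double K = pa[C_GAUSS0 + 3 * k], L = pa[C_GAUSS0 + 3 * k + 1],
           M = pa[C_GAUSS0 + 3 * k + 2];
    gsum += K * std::exp(-L * (r_ang - M) * (r_ang - M));
  }
  int ngb = (int)pb[C_NGAUSS];
  for (int k = 0; k < ngb; ++k) {
    double K = pb[C_GAUSS0 + 3 * k], L = pb[C_GAUSS0 + 3 * k + 1],
           M = pb[C_GAUSS0 + 3 * k + 2];
    gsum += K * std::exp(-L * (r_ang - M) * (r_ang - M));
  }
  e += za * zb / r_ang * gsum;
  return e;
}

// [[Rcpp::export]]
double core_core_cpp(NumericVector pa, NumericVector pb, double r_bohr,
                     double alpha_bohr, double ccut_bohr, int conv,
                     bool screen) {
  double dr[3] = {0.0, 0.0, r_bohr};
  double G[10][10];
  eri_block(pa.begin(), pb.begin(), dr, alpha_bohr, ccut_bohr, conv, screen,
            G);
  return core_core(pa.begin(), pb.begin(), r_bohr, G[0][0] * EV);
}

// ---------------------------------------------------------------------------
// translation enumeration (lattice rows in bohr)
// ---------------------------------------------------------------------------

static std::vector<std::array<double, 3>>
translations_within(const arma::mat& lat, double radius) {
  std::vector<std::array<double, 3>> out;
  int d = lat.n_rows;
  if (d == 0) {
    out.push_back({0.0, 0.0, 0.0});
    return out;
  }
  arma::mat gram = lat * lat.t();
  arma::mat ginv = arma::inv_sympd(gram);
  std::vector<int> nmax(d);
  for (int i = 0; i < d; ++i)
    nmax[i] = (int)std::ceil(radius * std::sqrt(ginv(i, i))) + 1;
  std::vector<int> idx(d, 0);
  std::function<void(int)> rec = [&](int dim) {
    if (dim == d) {
      double t[3] = {0, 0, 0};
      for (int i = 0; i < d; ++i)
        for (int c = 0; c < 3; ++c) t[c] += idx[i] * lat(i, c);
      double n = std::sqrt(t[0] * t[0] + t[1] * t[1] + t[2] * t[2]);
      if (n <= radius + 1e-9) out.push_back({t[0], t[1], t[2]});
      return;
    }
    for (int k = -nmax[dim]; k <= nmax[dim]; ++k) {
      idx[dim] = k;
      rec(dim + 1);
    }
  };
  rec(0);
  // deterministic order: by |T|, ties lexicographic; zero translation first
  std::sort(out.begin(), out.end(),
            [](const std::array<double, 3>& a, const std::array<double, 3>& b) {
              double na = a[0] * a[0] + a[1] * a[1] + a[2] * a[2];
              double nb = b[0] * b[0] + b[1] * b[1] + b[2] * b[2];
              if (std::fabs(na - nb) > 1e-9) return na < nb;
              if (std::fabs(a[0] - b[0]) > 1e-12) return a[0] < b[0];
              if (std::fabs(a[1] - b[1]) > 1e-12) return a[1] < b[1];
              return a[2] < b[2];
            });
  return out;
}

// minimum image of dr over the translation list (tie-break: lexicographic)
static void min_image(const double* dr,
                      const std::vector<std::array<double, 3>>& tr,
                      double* out) {
  double best = 1e300;
  out[0] = dr[0]; out[1] = dr[1]; out[2] = dr[2];
  for (const auto& t : tr) {
    double x = dr[0] + t[0], y = dr[1] + t[1], z = dr[2] + t[2];
    double n = x * x + y * y + z * z;
    if (n < best - 1e-9 ||
        (n < best + 1e-9 &&
         (x < out[0] - 1e-12 ||
          (std::fabs(x - out[0]) <= 1e-12 &&
           (y < out[1] - 1e-12 ||
            (std::fabs(y - out[1]) <= 1e-12 && z < out[2] - 1e-12)))))) {
      best = n; out[0] = x; out[1] = y; out[2] = z;
    }
  }
}

// ---------------------------------------------------------------------------
// assembly: core Hamiltonian, image-summed Coulomb blocks, exchange blocks,
// core-core energy, near-image counts for the far-field plateau
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List assemble_cpp(NumericMatrix apar, NumericMatrix xyz_ang,
                  NumericMatrix lattice_ang, double alpha_ang,
                  double ccut_bohr, int conv) {
  int n = apar.nrow();
  std::vector<int> off(n), nb(n);
  int norb = 0;
  for (int a = 0; a < n; ++a) {
    off[a] = norb;
    nb[a] = (int)apar(a, C_NB);
    norb += nb[a];
  }
  arma::mat lat(lattice_ang.nrow(), 3);
  for (int i = 0; i < (int)lattice_ang.nrow(); ++i)
    for (int c = 0; c < 3; ++c) lat(i, c) = lattice_ang(i, c) / A0;
  arma::mat x(n, 3);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) x(a, c) = xyz_ang(a, c) / A0;

  double alpha = alpha_ang / A0;       // bohr
  double two_alpha = 2.0 * alpha;
  // resonance range: overlap floor 1e-8 with the most diffuse exponent
  double zmin = 1e9;
  for (int a = 0; a < n; ++a) {
    zmin = std::min(zmin, apar(a, C_ZS));
    if (nb[a] == 4) zmin = std::min(zmin, apar(a, C_ZP));
  }
  double rres = std::min(30.0 / zmin, two_alpha);
  double renum = std::max(two_alpha, rres) + 1e-6;

  double diam = 0.0;
  if (lat.n_rows > 0) {
    // diagonal of the repeat box
    for (int mask = 1; mask < (1 << lat.n_rows); ++mask) {
      arma::rowvec v(3, arma::fill::zeros);
      for (int i = 0; i < (int)lat.n_rows; ++i)
        if (mask & (1 << i)) v += lat.row(i);
      diam = std::max(diam, arma::norm(v));
    }
  }
  auto tr = translations_within(lat, renum + diam);
  auto tr_shell = translations_within(lat, 3.0 * (diam > 0 ? diam : 1.0));

  int npair = n * (n + 1) / 2;
  NumericMatrix Wsum(npair, 100), Wx(npair, 100);
  IntegerVector pair_a(npair), pair_b(npair);
  IntegerMatrix Nnear(n, n);
  NumericMatrix H(norb, norb);
  double enuc = 0.0, enuc_c = 0.0;   // Neumaier-compensated

  auto kadd = [&](double v) {
    double t = enuc + v;
    if (std::fabs(enuc) >= std::fabs(v)) enuc_c += (enuc - t) + v;
    else enuc_c += (v - t) + enuc;
    enuc = t;
  };

  // one-electron diagonal U terms
  for (int a = 0; a < n; ++a) {
    H(off[a], off[a]) = apar(a, C_USS);
    for (int k = 1; k < nb[a]; ++k) H(off[a] + k, off[a] + k) = apar(a, C_UPP);
  }

  double G[10][10];
  double S[16];
  int pidx = 0;
  // NumericMatrix is column-major: copy parameter rows into contiguous
  // buffers before passing them down.
  std::vector<double> parow_a(apar.ncol()), parow_b(apar.ncol());
  for (int A = 0; A < n; ++A) {
    for (int c = 0; c < (int)apar.ncol(); ++c) parow_a[c] = apar(A, c);
    for (int B = A; B < n; ++B, ++pidx) {
      pair_a[pidx] = A; pair_b[pidx] = B;
      for (int c = 0; c < (int)apar.ncol(); ++c) parow_b[c] = apar(B, c);
      double dr0[3] = {x(B, 0) - x(A, 0), x(B, 1) - x(A, 1),
                       x(B, 2) - x(A, 2)};
      int count_near = 0;
      for (const auto& t : tr) {
        double dr[3] = {dr0[0] + t[0], dr0[1] + t[1], dr0[2] + t[2]};
        double R = std::sqrt(dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2]);
        if (A == B && R < 1e-9) continue;          // self
        if (R < 0.5) stop("atoms closer than 0.5 bohr");
        // resonance (image-summed, upper triangle only)
        if (R <= rres) {
          overlap_block(parow_a.data(), parow_b.data(), dr, S);
          for (int m = 0; m < nb[A]; ++m) {
            double bm = (m == 0) ? parow_a[C_BETAS] : parow_a[C_BETAP];
            for (int l = 0; l < nb[B]; ++l) {
              if (A == B && m > l) continue;   // keep one triangle
              double bl = (l == 0) ? parow_b[C_BETAS] : parow_b[C_BETAP];
              double s = S[m * 4 + l];
              if (std::fabs(s) < 1e-8) continue;
              H(off[A] + m, off[B] + l) += 0.5 * (bm + bl) * s;
            }
          }
        }
        if (R <= two_alpha) {
          ++count_near;
          eri_block(parow_a.data(), parow_b.data(), dr, alpha, ccut_bohr,
                    conv, true, G);
          for (int i = 0; i < 100; ++i)
            Wsum(pidx, i) += G[i / 10][i % 10] * EV;
          // electron-core attraction (for A == B the -T image covers the
          // reverse direction, so only the A side is accumulated)
          for (int ip = 0; ip < ((nb[A] == 1) ? 1 : 10); ++ip) {
            int m = PAIR_I[ip], l = PAIR_J[ip];
            H(off[A] + m, off[A] + l) += -parow_b[C_ZV] * G[ip][0] * EV;
          }
          if (A != B) {
            for (int jp = 0; jp < ((nb[B] == 1) ? 1 : 10); ++jp) {
              int m = PAIR_I[jp], l = PAIR_J[jp];
              H(off[B] + m, off[B] + l) += -parow_a[C_ZV] * G[0][jp] * EV;
            }
          }
          // core-core (A == A image pairs are shared between the two cells)
          double ecc = core_core(parow_a.data(), parow_b.data(), R,
                                 G[0][0] * EV);
          kadd((A == B) ? 0.5 * ecc : ecc);
        }
      }
      Nnear(A, B) = count_near;
      Nnear(B, A) = count_near;
      // exchange block at the minimum image (Wigner-Seitz restriction).
      // Degenerate boundary ties are averaged over all tied images: the
      // symmetric choice, invariant under relabeling and rigid translation.
      if (A != B) {
        double rmin2 = 1e300;
        for (const auto& t : tr_shell) {
          double x1 = dr0[0] + t[0], y1 = dr0[1] + t[1], z1 = dr0[2] + t[2];
          double n2 = x1 * x1 + y1 * y1 + z1 * z1;
          if (n2 < rmin2) rmin2 = n2;
        }
        double rmin = std::sqrt(rmin2);
        int ntied = 0;
        for (const auto& t : tr_shell) {
          double drm[3] = {dr0[0] + t[0], dr0[1] + t[1], dr0[2] + t[2]};
          double rr = std::sqrt(drm[0] * drm[0] + drm[1] * drm[1] +
                                drm[2] * drm[2]);
          if (rr > rmin + 1e-9) continue;
          ++ntied;
          eri_block(parow_a.data(), parow_b.data(), drm, alpha, ccut_bohr,
                    conv, true, G);
          for (int i = 0; i < 100; ++i)
            Wx(pidx, i) += G[i / 10][i % 10] * EV;
        }
        for (int i = 0; i < 100; ++i) Wx(pidx, i) /= ntied;
      }
    }
  }
  // all off-diagonal writes above target the upper triangle; mirror it
  for (int i = 0; i < norb; ++i)
    for (int j = i + 1; j < norb; ++j) H(j, i) = H(i, j);
  return List::create(
      _["H"] = H, _["enuc"] = enuc + enuc_c, _["Wsum"] = Wsum, _["Wx"] = Wx,
      _["pair_a"] = pair_a, _["pair_b"] = pair_b, _["Nnear"] = Nnear,
      _["gbar_ev"] = EV / (1.5 * alpha), _["norb"] = norb,
      _["offsets"] = IntegerVector(off.begin(), off.end()));
}

// ---------------------------------------------------------------------------
// Fock build
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fock_cpp(NumericMatrix apar, NumericMatrix H, NumericMatrix Wsum,
              NumericMatrix Wx, IntegerVector pair_a, IntegerVector pair_b,
              IntegerMatrix Nnear, double gbar_ev, IntegerVector offsets,
              NumericMatrix P) {
  int n = apar.nrow();
  int norb = H.nrow();
  NumericMatrix F(norb, norb);
  std::vector<int> nb(n);
  for (int a = 0; a < n; ++a) nb[a] = (int)apar(a, C_NB);

  // start from H
  for (int i = 0; i < norb; ++i)
    for (int j = 0; j < norb; ++j) F(i, j) = H(i, j);

  // one-center two-electron terms
  for (int a = 0; a < n; ++a) {
    int o = offsets[a];
    double gss = apar(a, C_GSS), gsp = apar(a, C_GSP), gpp = apar(a, C_GPP),
           gp2 = apar(a, C_GP2), hsp = apar(a, C_HSP);
    double pss = P(o, o);
    if (nb[a] == 1) {
      F(o, o) += 0.5 * pss * gss;
      continue;
    }
    double ppp[3] = {P(o + 1, o + 1), P(o + 2, o + 2), P(o + 3, o + 3)};
    double psum = ppp[0] + ppp[1] + ppp[2];
    F(o, o) += 0.5 * pss * gss + psum * (gsp - 0.5 * hsp);
    for (int k = 1; k <= 3; ++k) {
      F(o + k, o + k) += pss * (gsp - 0.5 * hsp) + 0.5 * ppp[k - 1] * gpp +
                         (psum - ppp[k - 1]) * (1.25 * gp2 - 0.25 * gpp);
      F(o, o + k) += P(o, o + k) * (1.5 * hsp - 0.5 * gsp);
      F(o + k, o) = F(o, o + k);
      for (int l = k + 1; l <= 3; ++l) {
        F(o + k, o + l) += P(o + k, o + l) * (0.75 * gpp - 1.25 * gp2);
        F(o + l, o + k) = F(o + k, o + l);
      }
    }
  }

  // two-center Coulomb (image-summed) and Wigner-Seitz exchange
  int npair = Wsum.nrow();
  std::vector<double> PA(10), PB(10);
  for (int p = 0; p < npair; ++p) {
    int A = pair_a[p], B = pair_b[p];
    int oa = offsets[A], ob = offsets[B];
    int npa = (nb[A] == 1) ? 1 : 10, npb = (nb[B] == 1) ? 1 : 10;
    for (int jp = 0; jp < npb; ++jp) {
      int m = PAIR_I[jp], l = PAIR_J[jp];
      PB[jp] = P(ob + m, ob + l) * ((m == l) ? 1.0 : 2.0);
    }
    for (int ip = 0; ip < npa; ++ip) {
      int m = PAIR_I[ip], l = PAIR_J[ip];
      PA[ip] = P(oa + m, oa + l) * ((m == l) ? 1.0 : 2.0);
    }
    if (A == B) {
      // Coulomb with own periodic images
      for (int ip = 0; ip < npa; ++ip) {
        double v = 0.0;
        for (int jp = 0; jp < npa; ++jp) v += Wsum(p, ip * 10 + jp) * PA[jp];
        int m = PAIR_I[ip], l = PAIR_J[ip];
        F(oa + m, oa + l) += v;
        if (m != l) F(oa + l, oa + m) += v;
      }
      continue;
    }
    for (int ip = 0; ip < npa; ++ip) {
      double v = 0.0;
      for (int jp = 0; jp < npb; ++jp) v += Wsum(p, ip * 10 + jp) * PB[jp];
      int m = PAIR_I[ip], l = PAIR_J[ip];
      F(oa + m, oa + l) += v;
      if (m != l) F(oa + l, oa + m) += v;
    }
    for (int jp = 0; jp < npb; ++jp) {
      double v = 0.0;
      for (int ip = 0; ip < npa; ++ip) v += Wsum(p, ip * 10 + jp) * PA[ip];
      int m = PAIR_I[jp], l = PAIR_J[jp];
      F(ob + m, ob + l) += v;
      if (m != l) F(ob + l, ob + m) += v;
    }
    // exchange at the minimum image
    for (int m = 0; m < nb[A]; ++m)
      for (int l = 0; l < nb[B]; ++l) {
        double v = 0.0;
        for (int nu = 0; nu < nb[A]; ++nu)
          for (int sg = 0; sg < nb[B]; ++sg)
            v += P(oa + nu, ob + sg) *
                 Wx(p, pair_index(m, nu) * 10 + pair_index(l, sg));
        F(oa + m, ob + l) -= 0.5 * v;
        F(ob + l, oa + m) = F(oa + m, ob + l);
      }
  }

  // far-field plateau correction (complete-cell neutrality)
  std::vector<double> q(n);
  for (int a = 0; a < n; ++a) {
    double na_el = 0.0;
    for (int k = 0; k < nb[a]; ++k) na_el += P(offsets[a] + k, offsets[a] + k);
    q[a] = apar(a, C_ZV) - na_el;
  }
  double efar = 0.0;
  for (int a = 0; a < n; ++a) {
    double s = 0.0;
    for (int b = 0; b < n; ++b) s += Nnear(a, b) * q[b];
    double corr = gbar_ev * (s + q[a]);
    for (int k = 0; k < nb[a]; ++k) F(offsets[a] + k, offsets[a] + k) += corr;
    efar += -0.5 * gbar_ev * q[a] * (s + q[a]);
  }

  // near-field electronic energy 0.5 * Tr P (H + F_near); the far diagonal
  // has already been added to F, so subtract its trace contribution
  double e2 = 0.0, c2 = 0.0;
  for (int i = 0; i < norb; ++i)
    for (int j = 0; j < norb; ++j) {
      double v = 0.5 * P(i, j) * (H(i, j) + F(i, j));
      double t = e2 + v;
      if (std::fabs(e2) >= std::fabs(v)) c2 += (e2 - t) + v;
      else c2 += (v - t) + e2;
      e2 = t;
    }
  double far_trace = 0.0;
  for (int a = 0; a < n; ++a) {
    double s = 0.0;
    for (int b = 0; b < n; ++b) s += Nnear(a, b) * q[b];
    double corr = gbar_ev * (s + q[a]);
    double na_el = 0.0;
    for (int k = 0; k < nb[a]; ++k) na_el += P(offsets[a] + k, offsets[a] + k);
    far_trace += 0.5 * na_el * corr;
  }
  double e_elec = (e2 + c2) - far_trace + efar;
  return List::create(_["F"] = F, _["e_elec"] = e_elec, _["e_far"] = efar);
}

// ---------------------------------------------------------------------------
// real-space grids
// ---------------------------------------------------------------------------

// image-summed basis values at arbitrary points (Born-von-Karman crystal
// basis functions); points and coordinates in Angstrom, values in bohr^-3/2
// [[Rcpp::export]]
NumericMatrix basis_matrix_cpp(NumericMatrix apar, NumericMatrix xyz_ang,
                               NumericMatrix lattice_ang,
                               NumericMatrix pts_ang, double rcut_bohr) {
  int n = apar.nrow(), m = pts_ang.nrow();
  std::vector<int> off(n), nb(n);
  int norb = 0;
  for (int a = 0; a < n; ++a) {
    off[a] = norb; nb[a] = (int)apar(a, C_NB); norb += nb[a];
  }
  arma::mat lat(lattice_ang.nrow(), 3);
  for (int i = 0; i < (int)lattice_ang.nrow(); ++i)
    for (int c = 0; c < 3; ++c) lat(i, c) = lattice_ang(i, c) / A0;
  double diam = 0.0;
  for (int i = 0; i < (int)lat.n_rows; ++i) diam += arma::norm(lat.row(i));
  auto tr = translations_within(lat, rcut_bohr + 3.0 * diam);
  NumericMatrix Phi(m, norb);
  for (int ip = 0; ip < m; ++ip) {
    for (int a = 0; a < n; ++a) {
      int nq = (int)apar(a, C_NQ);
      double zs = apar(a, C_ZS), zp = apar(a, C_ZP);
      double Ns = std::pow(2 * zs, nq + 0.5) / std::sqrt(factorial(2 * nq));
      double Np = std::pow(2 * zp, nq + 0.5) / std::sqrt(factorial(2 * nq));
      double d0[3];
      for (int c = 0; c < 3; ++c)
        d0[c] = (pts_ang(ip, c) - xyz_ang(a, c)) / A0;
      for (const auto& t : tr) {
        double dx = d0[0] - t[0], dy = d0[1] - t[1], dz = d0[2] - t[2];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r > rcut_bohr) continue;
        double rr = (r < 1e-12) ? 1e-12 : r;
        double rad_s = Ns * std::pow(rr, nq - 1) * std::exp(-zs * rr);
        Phi(ip, off[a]) += rad_s * 0.28209479177387814; // 1/sqrt(4pi)
        if (nb[a] == 4) {
          double rad_p = Np * std::pow(rr, nq - 1) * std::exp(-zp * rr) *
                         0.4886025119029199 / rr;       // sqrt(3/4pi)/r
          Phi(ip, off[a] + 1) += rad_p * dx;
          Phi(ip, off[a] + 2) += rad_p * dy;
          Phi(ip, off[a] + 3) += rad_p * dz;
        }
      }
    }
  }
  return Phi;
}

// image-summed real-overlap matrix of the Born-von-Karman basis functions
// over one cell: S_uv = sum_T <phi_u(0) | phi_v(T)>
// [[Rcpp::export]]
NumericMatrix overlap_matrix_cpp(NumericMatrix apar, NumericMatrix xyz_ang,
                                 NumericMatrix lattice_ang,
                                 double rcut_bohr) {
  int n = apar.nrow();
  std::vector<int> off(n), nb(n);
  int norb = 0;
  for (int a = 0; a < n; ++a) {
    off[a] = norb; nb[a] = (int)apar(a, C_NB); norb += nb[a];
  }
  arma::mat lat(lattice_ang.nrow(), 3);
  for (int i = 0; i < (int)lattice_ang.nrow(); ++i)
    for (int c = 0; c < 3; ++c) lat(i, c) = lattice_ang(i, c) / A0;
  double diam = 0.0;
  for (int i = 0; i < (int)lat.n_rows; ++i) diam += arma::norm(lat.row(i));
  auto tr = translations_within(lat, rcut_bohr + diam);
  NumericMatrix S(norb, norb);
  for (int i = 0; i < norb; ++i) S(i, i) = 0.0;
  std::vector<double> pra(apar.ncol()), prb(apar.ncol());
  double Sb[16];
  for (int a = 0; a < n; ++a) {
    for (int c = 0; c < (int)apar.ncol(); ++c) pra[c] = apar(a, c);
    for (int b = a; b < n; ++b) {
      for (int c = 0; c < (int)apar.ncol(); ++c) prb[c] = apar(b, c);
      double d0[3] = {(xyz_ang(b, 0) - xyz_ang(a, 0)) / A0,
                      (xyz_ang(b, 1) - xyz_ang(a, 1)) / A0,
                      (xyz_ang(b, 2) - xyz_ang(a, 2)) / A0};
      for (const auto& t : tr) {
        double dr[3] = {d0[0] + t[0], d0[1] + t[1], d0[2] + t[2]};
        double R = std::sqrt(dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2]);
        if (R > rcut_bohr) continue;
        if (a == b && R < 1e-9) {
          for (int m = 0; m < nb[a]; ++m) S(off[a] + m, off[a] + m) += 1.0;
          continue;
        }
        overlap_block(pra.data(), prb.data(), dr, Sb);
        for (int m = 0; m < nb[a]; ++m)
          for (int l = 0; l < nb[b]; ++l) {
            if (a == b && m > l) continue;
            S(off[a] + m, off[b] + l) += Sb[m * 4 + l];
          }
      }
    }
  }
  for (int i = 0; i < norb; ++i)
    for (int j = i + 1; j < norb; ++j) S(j, i) = S(i, j);
  return S;
}

// screened molecular electrostatic potential at points (hartree per unit
// probe charge). Cores as bare point charges, electrons as the atomwise
// distributed multipoles of the density matrix; screening beyond alpha and
// the complete-cell far-field correction as in the energy code.
// [[Rcpp::export]]
NumericVector mep_cpp(NumericMatrix apar, NumericMatrix xyz_ang,
                      NumericMatrix lattice_ang, NumericMatrix pts_ang,
                      NumericMatrix P, IntegerVector offsets,
                      double alpha_ang) {
  int n = apar.nrow(), m = pts_ang.nrow();
  std::vector<int> nb(n);
  for (int a = 0; a < n; ++a) nb[a] = (int)apar(a, C_NB);
  arma::mat lat(lattice_ang.nrow(), 3);
  for (int i = 0; i < (int)lattice_ang.nrow(); ++i)
    for (int c = 0; c < 3; ++c) lat(i, c) = lattice_ang(i, c) / A0;
  double alpha = alpha_ang / A0, two_alpha = 2 * alpha;
  double diam = 0.0;
  for (int i = 0; i < (int)lat.n_rows; ++i)
    diam += arma::norm(lat.row(i));
  auto tr = translations_within(lat, two_alpha + diam + 1.0);
  double gbar = 1.0 / (1.5 * alpha);
  NumericVector V(m);
  Config cfg[2];
  for (int ip = 0; ip < m; ++ip) {
    double v = 0.0, qnear = 0.0;
    for (int a = 0; a < n; ++a) {
      std::vector<double> par(apar.ncol());
      for (int c = 0; c < (int)apar.ncol(); ++c) par[c] = apar(a, c);
      double na_el = 0.0;
      for (int k = 0; k < nb[a]; ++k)
        na_el += P(offsets[a] + k, offsets[a] + k);
      double qa = par[C_ZV] - na_el;
      double d0[3];
      for (int c = 0; c < 3; ++c)
        d0[c] = (xyz_ang(a, c) - pts_ang(ip, c)) / A0;
      for (const auto& t : tr) {
        double dx = d0[0] + t[0], dy = d0[1] + t[1], dz = d0[2] + t[2];
        double R = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (R > two_alpha) continue;
        qnear += qa;
        double reff = R, lam = 1.0;
        if (R >= alpha) {
          reff = eff_dist_ang(R * A0, alpha_ang) / A0;
          lam = contraction(R * A0, alpha_ang);
        }
        double scale = (R < 1e-9) ? 1.0 : reff / std::max(R, 1e-9);
        double cx = dx * scale, cy = dy * scale, cz = dz * scale;
        v += par[C_ZV] / std::max(reff, 1e-9);
        int npa = (nb[a] == 1) ? 1 : 10;
        for (int pp = 0; pp < npa; ++pp) {
          int mi = PAIR_I[pp], li = PAIR_J[pp];
          double pd = P(offsets[a] + mi, offsets[a] + li) *
                      ((mi == li) ? 1.0 : 2.0);
          if (std::fabs(pd) < 1e-14) continue;
          int ncfg = pair_configs(pp, par.data(), cfg);
          for (int cc = 0; cc < ncfg; ++cc)
            for (int s = 0; s < cfg[cc].ncharge; ++s) {
              double ox = cx + lam * cfg[cc].o[s][0];
              double oy = cy + lam * cfg[cc].o[s][1];
              double oz = cz + lam * cfg[cc].o[s][2];
              double d = std::sqrt(ox * ox + oy * oy + oz * oz);
              v -= pd * cfg[cc].q[s] / std::max(d, 1e-9);
            }
        }
      }
    }
    V[ip] = v - gbar * qnear;    // far-field complete-cell correction
  }
  return V;
}
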