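// Two-phase (marrow/air) incompressible flow on a 2D structured section,
// MAC staggered grid, pressure projection, flux-limited VOF, plus Lagrangian
// particle kinematics.  Metrics (face areas, cell volumes) are supplied by R,
// so the same kernels serve axisymmetric r-z sections (area = 2*pi*r*dz etc.)
// and planar Cartesian sections (unit depth).
//
// Face type codes: 0 interior fluid-fluid (unknown), 1 blocked (wall/solid),
// 2 inlet (prescribed normal velocity), 3 outlet (pressure = 0 ghost).
// Cell type codes: 0 fluid, 1 scaffold solid, 2 exterior/wall solid, 3 cap.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

namespace {

struct Geom {
  int nx, nz;
  double dx, dz;
  const int *ctype, *fx, *fz;
  const double *Ax, *Az, *vol, *sx, *sz;  // sx/sz: inlet inflow direction sign
  inline int C(int i, int k) const { return i + nx * k; }
  inline int FX(int i, int k) const { return i + (nx + 1) * k; }
  inline int FZ(int i, int k) const { return i + nx * k; }
  inline bool fluid(int i, int k) const {
    return i >= 0 && i < nx && k >= 0 && k < nz && ctype[C(i, k)] == 0;
  }
};

Geom unpack_geom(const List& g) {
  Geom gm;
  gm.nx = as<int>(g["nx"]); gm.nz = as<int>(g["nz"]);
  gm.dx = as<double>(g["dx"]); gm.dz = as<double>(g["dz"]);
  gm.ctype = INTEGER(g["ctype"]); gm.fx = INTEGER(g["fx"]); gm.fz = INTEGER(g["fz"]);
  gm.Ax = REAL(g["Ax"]); gm.Az = REAL(g["Az"]); gm.vol = REAL(g["vol"]);
  gm.sx = REAL(g["sx"]); gm.sz = REAL(g["sz"]);
  return gm;
}

// Sparse 5-point SPD system  (aP*x - sum coef_j*x[nb_j] = b), Jacobi-PCG.
struct LinSys {
  int n = 0;
  std::vector<double> aP, b, x, scale;  // residual test: max |r_i|/scale_i
  std::vector<int> nb;       // 4*n neighbour positions, -1 if none
  std::vector<double> coef;  // 4*n coefficients (>= 0)
  void init(int n_) {
    n = n_;
    aP.assign(n, 0.0); b.assign(n, 0.0); x.assign(n, 0.0);
    scale.assign(n, 1.0);
    nb.assign(4 * n, -1); coef.assign(4 * n, 0.0);
  }
  void apply(const std::vector<double>& v, std::vector<double>& out) const {
    for (int i = 0; i < n; ++i) {
      double s = aP[i] * v[i];
      for (int j = 0; j < 4; ++j) {
        int p = nb[4 * i + j];
        if (p >= 0) s -= coef[4 * i + j] * v[p];
      }
      out[i] = s;
    }
  }
  // symmetric Gauss-Seidel preconditioner M = (D-L) D^-1 (D-U)
  void precond(const std::vector<double>& r, std::vector<double>& z) const {
    for (int i = 0; i < n; ++i) {
      double s = r[i];
      for (int j = 0; j < 4; ++j) {
        int p = nb[4 * i + j];
        if (p >= 0 && p < i) s += coef[4 * i + j] * z[p];
      }
      z[i] = s / aP[i];
    }
    for (int i = n - 1; i >= 0; --i) {
      double s = z[i] * aP[i];
      for (int j = 0; j < 4; ++j) {
        int p = nb[4 * i + j];
        if (p >= 0 && p > i) s += coef[4 * i + j] * z[p];
      }
      z[i] = s / aP[i];
    }
  }
  // returns iterations; stops on max|r| <= tol_inf
  int cg(double tol_inf, int maxit) {
    std::vector<double> r(n), z(n), d(n), q(n);
    apply(x, q);
    double rmax = 0.0;
    for (int i = 0; i < n; ++i) { r[i] = b[i] - q[i]; rmax = std::max(rmax, std::fabs(r[i]) / scale[i]); }
    if (rmax <= tol_inf) return 0;
    precond(r, z);
    d = z;
    double rz = 0.0;
    for (int i = 0; i < n; ++i) rz += r[i] * z[i];
    int it = 0;
    for (; it < maxit; ++it) {
      apply(d, q);
      double dq = 0.0;
      for (int i = 0; i < n; ++i) dq += d[i] * q[i];
      if (dq <= 0.0) break;
      double al = rz / dq;
      rmax = 0.0;
      for (int i = 0; i < n; ++i) {
        x[i] += al * d[i];
        r[i] -= al * q[i];
        rmax = std::max(rmax, std::fabs(r[i]) / scale[i]);
      }
      if (rmax <= tol_inf) { ++it; break; }
      precond(r, z);
      double rz2 = 0.0;
      for (int i = 0; i < n; ++i) rz2 += r[i] * z[i];
      double be = rz2 / rz;
      rz = rz2;
      for (int i = 0; i < n; ++i) d[i] = z[i] + be * d[i];
    }
    return it;
  }
};

inline double power_law_eta(double gam, double k, double nidx, double emin,
                            double emax, bool clamp) {
  double eta;
  if (gam <= 0.0) {
    eta = (nidx < 1.0) ? (clamp ? emax : k) : (nidx > 1.0 ? (clamp ? emin : 0.0) : k);
  } else {
    eta = k * std::pow(gam, nidx - 1.0);
  }
  if (clamp) eta = std::min(emax, std::max(emin, eta));
  return eta;
}

// cell-centred shear rate sqrt(0.5 D:D), one-sided at walls/solids
void shear_rate(const Geom& g, const double* u, const double* w, double* gam) {
  int nx = g.nx, nz = g.nz;
  std::vector<double> uc(nx * nz, 0.0), wc(nx * nz, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      int c = g.C(i, k);
      if (g.ctype[c] != 0) { gam[c] = 0.0; continue; }
      uc[c] = 0.5 * (u[g.FX(i, k)] + u[g.FX(i + 1, k)]);
      wc[c] = 0.5 * (w[g.FZ(i, k)] + w[g.FZ(i, k + 1)]);
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      int c = g.C(i, k);
      if (g.ctype[c] != 0) continue;
      double dudx = (u[g.FX(i + 1, k)] - u[g.FX(i, k)]) / g.dx;
      double dwdz = (w[g.FZ(i, k + 1)] - w[g.FZ(i, k)]) / g.dz;
      // cross derivatives from cell-centred interpolants
      bool fE = g.fluid(i + 1, k), fW = g.fluid(i - 1, k);
      bool fN = g.fluid(i, k + 1), fS = g.fluid(i, k - 1);
      double ue = fE ? uc[g.C(i + 1, k)] : uc[c], uw2 = fW ? uc[g.C(i - 1, k)] : uc[c];
      double un = fN ? uc[g.C(i, k + 1)] : uc[c], us = fS ? uc[g.C(i, k - 1)] : uc[c];
      double we = fE ? wc[g.C(i + 1, k)] : wc[c], ww2 = fW ? wc[g.C(i - 1, k)] : wc[c];
      double hx = (fE && fW) ? 2.0 * g.dx : g.dx;
      double hz = (fN && fS) ? 2.0 * g.dz : g.dz;
      double dudz = (fN || fS) ? (un - us) / hz : 0.0;
      double dwdx = (fE || fW) ? (we - ww2) / hx : 0.0;
      gam[c] = std::sqrt(2.0 * dudx * dudx + 2.0 * dwdz * dwdz +
                         (dudz + dwdx) * (dudz + dwdx));
    }
}

inline double vanleer(double r) {
  double a = std::fabs(r);
  return (r + a) / (1.0 + a);
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_shear_rate(NumericVector u, NumericVector w, List geom) {
  Geom g = unpack_geom(geom);
  NumericVector gam(g.nx * g.nz);
  shear_rate(g, REAL(u), REAL(w), REAL(gam));
  return gam;
}

// One full time step.  Returns updated fields plus diagnostics.
// [[Rcpp::export]]
List cpp_flow_step(NumericVector u_in, NumericVector w_in, NumericVector a_in,
                   NumericVector p_in, List geom, List phys, double dt,
                   double inlet_speed, double lid_u, double tol_div,
                   int maxit) {
  Geom g = unpack_geom(geom);
  const int nx = g.nx, nz = g.nz;
  const double dx = g.dx, dz = g.dz;
  const double rho_m = as<double>(phys["rho_m"]), rho_a = as<double>(phys["rho_a"]);
  const double mu_a = as<double>(phys["mu_a"]);
  const double kcons = as<double>(phys["k"]), nidx = as<double>(phys["n"]);
  const double emin = as<double>(phys["eta_min"]), emax = as<double>(phys["eta_max"]);
  const bool clamp = as<bool>(phys["clamp"]);
  const double gz = as<double>(phys["g_z"]);

  NumericVector u = clone(u_in), w = clone(w_in), alpha = clone(a_in), p = clone(p_in);
  double* U = REAL(u); double* W = REAL(w); double* A = REAL(alpha); double* P = REAL(p);

  // ---- prescribed inlet faces -------------------------------------------
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i <= nx; ++i) {
      int f = g.FX(i, k);
      if (g.fx[f] == 1) U[f] = 0.0;
      else if (g.fx[f] == 2) U[f] = inlet_speed * g.sx[f];
    }
  for (int k = 0; k <= nz; ++k)
    for (int i = 0; i < nx; ++i) {
      int f = g.FZ(i, k);
      if (g.fz[f] == 1) W[f] = 0.0;
      else if (g.fz[f] == 2) W[f] = inlet_speed * g.sz[f];
    }

  // velocity scale for iterative-solver tolerances
  double vref = std::max(inlet_speed, std::fabs(lid_u));
  for (int f = 0; f < (nx + 1) * nz; ++f) vref = std::max(vref, std::fabs(U[f]));
  for (int f = 0; f < nx * (nz + 1); ++f) vref = std::max(vref, std::fabs(W[f]));
  if (vref <= 0) vref = 1e-6;

  // ---- mixture properties -----------------------------------------------
  std::vector<double> gam(nx * nz), mu(nx * nz, mu_a), rho(nx * nz, rho_a);
  shear_rate(g, U, W, gam.data());
  for (int c = 0; c < nx * nz; ++c) {
    if (g.ctype[c] != 0) continue;
    double a = std::min(1.0, std::max(0.0, A[c]));
    double eta = power_law_eta(gam[c], kcons, nidx, emin, emax, clamp);
    mu[c] = a * eta + (1.0 - a) * mu_a;
    rho[c] = a * rho_m + (1.0 - a) * rho_a;
  }
  auto mu_corner_u = [&](int i, int k, int kk) {
    // viscosity between u(i,k) and u(i,kk) (kk = k+-1): average of the 2..4
    // fluid cells around the shared corner
    double s = 0.0; int n = 0;
    int klo = std::min(k, kk), khi = std::max(k, kk);
    for (int ii = i - 1; ii <= i; ++ii)
      for (int kc = klo; kc <= khi; ++kc)
        if (g.fluid(ii, kc)) { s += mu[g.C(ii, kc)]; ++n; }
    return n ? s / n : mu_a;
  };
  auto mu_corner_w = [&](int i, int k, int ii) {
    double s = 0.0; int n = 0;
    int ilo = std::min(i, ii), ihi = std::max(i, ii);
    for (int ic = ilo; ic <= ihi; ++ic)
      for (int kc = k - 1; kc <= k; ++kc)
        if (g.fluid(ic, kc)) { s += mu[g.C(ic, kc)]; ++n; }
    return n ? s / n : mu_a;
  };
  auto rho_face_u = [&](int i, int k) {
    double s = 0.0; int n = 0;
    if (g.fluid(i - 1, k)) { s += rho[g.C(i - 1, k)]; ++n; }
    if (g.fluid(i, k)) { s += rho[g.C(i, k)]; ++n; }
    return n ? s / n : rho_a;
  };
  auto rho_face_w = [&](int i, int k) {
    double s = 0.0; int n = 0;
    if (g.fluid(i, k - 1)) { s += rho[g.C(i, k - 1)]; ++n; }
    if (g.fluid(i, k)) { s += rho[g.C(i, k)]; ++n; }
    return n ? s / n : rho_a;
  };

  // ---- predictor (explicit hybrid advection; gravity on w) ---------------
  std::vector<double> us((nx + 1) * nz), ws(nx * (nz + 1));
  for (int f = 0; f < (nx + 1) * nz; ++f) us[f] = U[f];
  for (int f = 0; f < nx * (nz + 1); ++f) ws[f] = W[f];

  auto uval = [&](int i, int k, double self, double wallv) {
    // tangential ghost in z handled by caller; this is plain lookup with
    // mirror ghost for out-of-range rows
    if (k < 0 || k >= nz) return 2.0 * wallv - self;
    int f = g.FX(i, k);
    if (g.fx[f] == 1) {
      // face exists but blocked: if column of cells beside it is solid this is
      // a tangential wall at half cell; mirror ghost
      return 2.0 * 0.0 - self;
    }
    return U[f];
  };
  auto wval = [&](int i, int k, double self) {
    if (i < 0 || i >= nx) return -self;
    int f = g.FZ(i, k);
    if (g.fz[f] == 1) return -self;
    return W[f];
  };

  for (int k = 0; k < nz; ++k)
    for (int i = 1; i < nx; ++i) {
      int f = g.FX(i, k);
      if (g.fx[f] != 0) continue;
      double uu = U[f];
      double ww = 0.25 * (W[g.FZ(i - 1, k)] + W[g.FZ(i, k)] +
                          W[g.FZ(i - 1, k + 1)] + W[g.FZ(i, k + 1)]);
      double uE = (g.fx[g.FX(i + 1, k)] == 1) ? 0.0 : U[g.FX(i + 1, k)];
      double uWn = (g.fx[g.FX(i - 1, k)] == 1) ? 0.0 : U[g.FX(i - 1, k)];
      double wallN = (k == nz - 1) ? lid_u : 0.0;
      double uN = uval(i, k + 1, uu, wallN);
      double uS = uval(i, k - 1, uu, 0.0);
      double muf = 0.5 * (mu[g.C(i - 1, k)] + mu[g.C(i, k)]);
      double rf = rho_face_u(i, k);
      double pex = rf * std::fabs(uu) * dx / std::max(muf, 1e-300);
      double pez = rf * std::fabs(ww) * dz / std::max(muf, 1e-300);
      double dudx = (pex < 2.0) ? (uE - uWn) / (2.0 * dx)
                                : (uu > 0 ? (uu - uWn) / dx : (uE - uu) / dx);
      double dudz = (pez < 2.0) ? (uN - uS) / (2.0 * dz)
                                : (ww > 0 ? (uu - uS) / dz : (uN - uu) / dz);
      us[f] = uu + dt * (-uu * dudx - ww * dudz);
    }
  for (int k = 1; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      int f = g.FZ(i, k);
      if (g.fz[f] != 0) continue;
      double ww = W[f];
      double uu = 0.25 * (U[g.FX(i, k - 1)] + U[g.FX(i + 1, k - 1)] +
                          U[g.FX(i, k)] + U[g.FX(i + 1, k)]);
      double wN = (g.fz[g.FZ(i, k + 1)] == 1) ? 0.0 : W[g.FZ(i, k + 1)];
      double wS = (g.fz[g.FZ(i, k - 1)] == 1) ? 0.0 : W[g.FZ(i, k - 1)];
      double wE = wval(i + 1, k, ww);
      double wWn = wval(i - 1, k, ww);
      double muf = 0.5 * (mu[g.C(i, k - 1)] + mu[g.C(i, k)]);
      double rf = rho_face_w(i, k);
      double pex = rf * std::fabs(uu) * dx / std::max(muf, 1e-300);
      double pez = rf * std::fabs(ww) * dz / std::max(muf, 1e-300);
      double dwdx = (pex < 2.0) ? (wE - wWn) / (2.0 * dx)
                                : (uu > 0 ? (ww - wWn) / dx : (wE - ww) / dx);
      double dwdz = (pez < 2.0) ? (wN - wS) / (2.0 * dz)
                                : (ww > 0 ? (ww - wS) / dz : (wN - ww) / dz);
      ws[f] = ww + dt * (-uu * dwdx - ww * dwdz + gz);
    }
  // outlet faces: zero-gradient predictor from interior neighbour
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i <= nx; ++i) {
      int f = g.FX(i, k);
      if (g.fx[f] != 3) continue;
      us[f] = (i > 0 && g.fluid(i - 1, k)) ? us[g.FX(i - 1, k)] : us[g.FX(i + 1, k)];
    }
  for (int i = 0; i < nx; ++i) {
    for (int k = 0; k <= nz; ++k) {
      int f = g.FZ(i, k);
      if (g.fz[f] != 3) continue;
      ws[f] = (k > 0 && g.fluid(i, k - 1)) ? ws[g.FZ(i, k - 1)] : ws[g.FZ(i, k + 1)];
    }
  }

  // ---- implicit viscosity -----------------------------------------------
  // u-component
  {
    std::vector<int> id((nx + 1) * nz, -1);
    std::vector<int> fi, fk;
    for (int k = 0; k < nz; ++k)
      for (int i = 1; i < nx; ++i)
        if (g.fx[g.FX(i, k)] == 0) {
          id[g.FX(i, k)] = (int)fi.size();
          fi.push_back(i); fk.push_back(k);
        }
    LinSys S; S.init((int)fi.size());
    for (int m = 0; m < S.n; ++m) {
      int i = fi[m], k = fk[m], f = g.FX(i, k);
      double rf = rho_face_u(i, k);
      double ap = rf / dt;
      double rhs = rf / dt * us[f];
      // x-neighbours (through cells i-1 / i)
      int fE = g.FX(i + 1, k), fW = g.FX(i - 1, k);
      double cE = mu[g.C(i, k)] / (dx * dx);
      double cW = mu[g.C(i - 1, k)] / (dx * dx);
      ap += cE + cW;
      if (g.fx[fE] == 0) { S.nb[4 * m] = id[fE]; S.coef[4 * m] = cE; }
      else if (g.fx[fE] == 2 || g.fx[fE] == 3) rhs += cE * us[fE];
      if (g.fx[fW] == 0) { S.nb[4 * m + 1] = id[fW]; S.coef[4 * m + 1] = cW; }
      else if (g.fx[fW] == 2 || g.fx[fW] == 3) rhs += cW * us[fW];
      // z-neighbours (tangential; wall at half-cell when neighbour missing)
      for (int s = 0; s < 2; ++s) {
        int kk = (s == 0) ? k + 1 : k - 1;
        bool have = kk >= 0 && kk < nz && g.fx[g.FX(i, kk)] == 0;
        double muc = mu_corner_u(i, k, kk < 0 ? 0 : std::min(kk, nz - 1));
        if (have) {
          double c = muc / (dz * dz);
          ap += c;
          S.nb[4 * m + 2 + s] = id[g.FX(i, kk)];
          S.coef[4 * m + 2 + s] = c;
        } else {
          // wall (or prescribed face) at dz/2 .. dz
          double uwall = 0.0;
          bool half = true;
          if (kk >= 0 && kk < nz) {
            int fn = g.FX(i, kk);
            if (g.fx[fn] == 2 || g.fx[fn] == 3) { uwall = us[fn]; half = false; }
          } else if (kk >= nz) {
            uwall = lid_u;
          }
          double c = half ? 2.0 * muc / (dz * dz) : muc / (dz * dz);
          ap += c;
          rhs += c * uwall;
        }
      }
      S.aP[m] = ap; S.b[m] = rhs; S.x[m] = us[f];
    }
    S.cg(1e-9 * vref * (rho_m / dt), maxit);
    for (int m = 0; m < S.n; ++m) us[g.FX(fi[m], fk[m])] = S.x[m];
  }
  // w-component
  {
    std::vector<int> id(nx * (nz + 1), -1);
    std::vector<int> fi, fk;
    for (int k = 1; k < nz; ++k)
      for (int i = 0; i < nx; ++i)
        if (g.fz[g.FZ(i, k)] == 0) {
          id[g.FZ(i, k)] = (int)fi.size();
          fi.push_back(i); fk.push_back(k);
        }
    LinSys S; S.init((int)fi.size());
    for (int m = 0; m < S.n; ++m) {
      int i = fi[m], k = fk[m], f = g.FZ(i, k);
      double rf = rho_face_w(i, k);
      double ap = rf / dt;
      double rhs = rf / dt * ws[f];
      int fN = g.FZ(i, k + 1), fS = g.FZ(i, k - 1);
      double cN = mu[g.C(i, k)] / (dz * dz);
      double cS = mu[g.C(i, k - 1)] / (dz * dz);
      ap += cN + cS;
      if (g.fz[fN] == 0) { S.nb[4 * m] = id[fN]; S.coef[4 * m] = cN; }
      else if (g.fz[fN] == 2 || g.fz[fN] == 3) rhs += cN * ws[fN];
      if (g.fz[fS] == 0) { S.nb[4 * m + 1] = id[fS]; S.coef[4 * m + 1] = cS; }
      else if (g.fz[fS] == 2 || g.fz[fS] == 3) rhs += cS * ws[fS];
      for (int s = 0; s < 2; ++s) {
        int ii = (s == 0) ? i + 1 : i - 1;
        bool have = ii >= 0 && ii < nx && g.fz[g.FZ(ii, k)] == 0;
        double muc = mu_corner_w(i, k, ii < 0 ? 0 : std::min(ii, nx - 1));
        if (have) {
          double c = muc / (dx * dx);
          ap += c;
          S.nb[4 * m + 2 + s] = id[g.FZ(ii, k)];
          S.coef[4 * m + 2 + s] = c;
        } else {
          double wwall = 0.0;
          bool half = true;
          if (ii >= 0 && ii < nx) {
            int fn = g.FZ(ii, k);
            if (g.fz[fn] == 2 || g.fz[fn] == 3) { wwall = ws[fn]; half = false; }
          }
          // axis of symmetry (ii < 0 with zero-area face) is a symmetry
          // plane, not a wall: no tangential stress
          if (ii < 0 && g.Ax[g.FX(0, k)] <= 0.0) continue;
          double c = half ? 2.0 * muc / (dx * dx) : muc / (dx * dx);
          ap += c;
          rhs += c * wwall;
        }
      }
      S.aP[m] = ap; S.b[m] = rhs; S.x[m] = ws[f];
    }
    S.cg(1e-9 * vref * (rho_m / dt), maxit);
    for (int m = 0; m < S.n; ++m) ws[g.FZ(fi[m], fk[m])] = S.x[m];
  }

  // ---- pressure projection ----------------------------------------------
  std::vector<int> cid(nx * nz, -1);
  std::vector<int> ci, ck;
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      if (g.ctype[g.C(i, k)] == 0) {
        cid[g.C(i, k)] = (int)ci.size();
        ci.push_back(i); ck.push_back(k);
      }
  LinSys S; S.init((int)ci.size());
  bool has_outlet = false;
  for (int m = 0; m < S.n; ++m) {
    int i = ci[m], k = ck[m], c = g.C(i, k);
    double ap = 0.0, rhs = 0.0;
    struct FaceRef { int f, type; double Aface, sgn, beta, d; int nbc; int axis; };
    // east, west, north(top), south(bottom); sgn = outward normal sign
    int fE = g.FX(i + 1, k), fW = g.FX(i, k), fN = g.FZ(i, k + 1), fS = g.FZ(i, k);
    FaceRef fr[4] = {
      {fE, g.fx[fE], g.Ax[fE], +1.0, 0.0, dx, (i + 1 < nx) ? g.C(i + 1, k) : -1, 0},
      {fW, g.fx[fW], g.Ax[fW], -1.0, 0.0, dx, (i - 1 >= 0) ? g.C(i - 1, k) : -1, 0},
      {fN, g.fz[fN], g.Az[fN], +1.0, 0.0, dz, (k + 1 < nz) ? g.C(i, k + 1) : -1, 1},
      {fS, g.fz[fS], g.Az[fS], -1.0, 0.0, dz, (k - 1 >= 0) ? g.C(i, k - 1) : -1, 1}};
    for (int q = 0; q < 4; ++q) {
      FaceRef& F = fr[q];
      double uf = (F.axis == 0) ? us[F.f] : ws[F.f];
      if (F.type == 1) continue;  // blocked: no flux, no coupling
      if (F.type == 2) {          // inlet: fixed flux
        double un = (F.axis == 0) ? U[F.f] : W[F.f];
        rhs += F.Aface * F.sgn * un;
        continue;
      }
      rhs += F.Aface * F.sgn * uf;
      double rf = (F.axis == 0) ? rho_face_u((F.sgn > 0) ? i + 1 : i, k)
                                : rho_face_w(i, (F.sgn > 0) ? k + 1 : k);
      double beta = 1.0 / rf;
      if (F.type == 3) {          // outlet: ghost p = 0 at d/2
        has_outlet = true;
        double cc = F.Aface * beta / (0.5 * F.d);
        ap += cc;
        continue;
      }
      double cc = F.Aface * beta / F.d;
      ap += cc;
      S.nb[4 * m + q] = cid[F.nbc];
      S.coef[4 * m + q] = cc;
    }
    S.aP[m] = ap > 0 ? ap : 1.0;   // isolated cell: pin
    S.b[m] = -rhs / dt;            // -div(u*)/dt in flux form
    S.scale[m] = g.vol[c];         // stop when max |div| <= tol
    S.x[m] = P[c];
  }
  if (!has_outlet) {
    // closed domain (pure Neumann, nullspace = constants): make RHS
    // compatible by removing its mean, and keep iterates mean-free
    double sb = 0.0;
    for (int m = 0; m < S.n; ++m) sb += S.b[m];
    double mb = sb / S.n;
    for (int m = 0; m < S.n; ++m) S.b[m] -= mb;
    double sx = 0.0;
    for (int m = 0; m < S.n; ++m) sx += S.x[m];
    for (int m = 0; m < S.n; ++m) S.x[m] -= sx / S.n;
  }
  int cg_it = S.cg(tol_div / dt, maxit);
  for (int m = 0; m < S.n; ++m) P[g.C(ci[m], ck[m])] = S.x[m];

  // ---- velocity correction ----------------------------------------------
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i <= nx; ++i) {
      int f = g.FX(i, k);
      if (g.fx[f] == 0) {
        double beta = 1.0 / rho_face_u(i, k);
        U[f] = us[f] - dt * beta * (P[g.C(i, k)] - P[g.C(i - 1, k)]) / dx;
      } else if (g.fx[f] == 3) {
        double beta = 1.0 / rho_face_u(i, k);
        int c = (i > 0 && g.fluid(i - 1, k)) ? g.C(i - 1, k) : g.C(i, k);
        double sgn = (i > 0 && g.fluid(i - 1, k)) ? 1.0 : -1.0;
        U[f] = us[f] - dt * beta * sgn * (0.0 - P[c]) / (0.5 * dx);
      }
    }
  for (int k = 0; k <= nz; ++k)
    for (int i = 0; i < nx; ++i) {
      int f = g.FZ(i, k);
      if (g.fz[f] == 0) {
        double beta = 1.0 / rho_face_w(i, k);
        W[f] = ws[f] - dt * beta * (P[g.C(i, k)] - P[g.C(i, k - 1)]) / dz;
      } else if (g.fz[f] == 3) {
        double beta = 1.0 / rho_face_w(i, k);
        int c = (k > 0 && g.fluid(i, k - 1)) ? g.C(i, k - 1) : g.C(i, k);
        double sgn = (k > 0 && g.fluid(i, k - 1)) ? 1.0 : -1.0;
        W[f] = ws[f] - dt * beta * sgn * (0.0 - P[c]) / (0.5 * dz);
      }
    }

  // ---- post-projection divergence & max speed ----------------------------
  double maxdiv = 0.0, umax = 0.0;
  for (int m = 0; m < S.n; ++m) {
    int i = ci[m], k = ck[m], c = g.C(i, k);
    double div = (g.Ax[g.FX(i + 1, k)] * U[g.FX(i + 1, k)] -
                  g.Ax[g.FX(i, k)] * U[g.FX(i, k)] +
                  g.Az[g.FZ(i, k + 1)] * W[g.FZ(i, k + 1)] -
                  g.Az[g.FZ(i, k)] * W[g.FZ(i, k)]) / g.vol[c];
    maxdiv = std::max(maxdiv, std::fabs(div));
  }
  for (int f = 0; f < (nx + 1) * nz; ++f) umax = std::max(umax, std::fabs(U[f]));
  for (int f = 0; f < nx * (nz + 1); ++f) umax = std::max(umax, std::fabs(W[f]));

  // ---- VOF advection (van Leer limited, conservative) --------------------
  double influx = 0.0, outflux_m = 0.0, clipped = 0.0;
  {
    std::vector<double> dA(nx * nz, 0.0);
    auto aval = [&](int i, int k, double fb) {
      return g.fluid(i, k) ? A[g.C(i, k)] : fb;
    };
    // x-faces
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i <= nx; ++i) {
        int f = g.FX(i, k);
        int ft = g.fx[f];
        if (ft == 1 || g.Ax[f] <= 0.0) continue;
        double uf = U[f];
        if (uf == 0.0) continue;
        double af;
        if (ft == 2) af = 1.0;  // marrow inflow
        else {
          int di = uf > 0 ? i - 1 : i;       // donor cell
          int ai = uf > 0 ? i : i - 1;       // acceptor
          int ui2 = uf > 0 ? i - 2 : i + 1;  // far upwind
          if (!g.fluid(di, k)) continue;
          double aD = A[g.C(di, k)];
          double aA = aval(ai, k, aD);
          double aU = aval(ui2, k, aD);
          double dDA = aA - aD;
          double psi = 0.0;
          if (std::fabs(dDA) > 1e-14) psi = vanleer((aD - aU) / dDA);
          af = aD + 0.5 * psi * dDA;
        }
        double Fl = g.Ax[f] * uf * af * dt;
        if (g.fluid(i - 1, k)) dA[g.C(i - 1, k)] -= Fl;
        if (g.fluid(i, k)) dA[g.C(i, k)] += Fl;
        if (ft == 2) influx += g.Ax[f] * uf * g.sx[f] * dt;  // signed inward
        if (ft == 3) outflux_m += ((i > 0 && g.fluid(i - 1, k)) ? 1.0 : -1.0) * Fl;
      }
    // z-faces
    for (int k = 0; k <= nz; ++k)
      for (int i = 0; i < nx; ++i) {
        int f = g.FZ(i, k);
        int ft = g.fz[f];
        if (ft == 1 || g.Az[f] <= 0.0) continue;
        double wf = W[f];
        if (wf == 0.0) continue;
        double af;
        if (ft == 2) af = 1.0;
        else {
          int dk = wf > 0 ? k - 1 : k;
          int ak = wf > 0 ? k : k - 1;
          int uk = wf > 0 ? k - 2 : k + 1;
          if (!g.fluid(i, dk)) continue;
          double aD = A[g.C(i, dk)];
          double aA = aval(i, ak, aD);
          double aU = aval(i, uk, aD);
          double dDA = aA - aD;
          double psi = 0.0;
          if (std::fabs(dDA) > 1e-14) psi = vanleer((aD - aU) / dDA);
          af = aD + 0.5 * psi * dDA;
        }
        double Fl = g.Az[f] * wf * af * dt;
        if (g.fluid(i, k - 1)) dA[g.C(i, k - 1)] -= Fl;
        if (g.fluid(i, k)) dA[g.C(i, k)] += Fl;
        if (ft == 2) influx += g.Az[f] * wf * g.sz[f] * dt;
        if (ft == 3) outflux_m += ((k > 0 && g.fluid(i, k - 1)) ? 1.0 : -1.0) * Fl;
      }
    for (int m = 0; m < (int)ci.size(); ++m) {
      int c = g.C(ci[m], ck[m]);
      double an = A[c] + dA[c] / g.vol[c];
      if (an < 0.0) { clipped += -an * g.vol[c]; an = 0.0; }
      if (an > 1.0) { clipped += (an - 1.0) * g.vol[c]; an = 1.0; }
      A[c] = an;
    }
  }

  return List::create(_["u"] = u, _["w"] = w, _["alpha"] = alpha, _["p"] = p,
                      _["max_div"] = maxdiv, _["u_max"] = umax,
                      _["cg_iters"] = cg_it, _["influx"] = influx,
                      _["outflux_marrow"] = outflux_m, _["clipped"] = clipped);
}

// ---------------------------------------------------------------------------
// Lagrangian particles
// ---------------------------------------------------------------------------

static inline double interp_u(const Geom& g, const double* U, double x, double z) {
  // u nodes at (i*dx, (k+0.5)*dz)
  double xi = x / g.dx, zk = z / g.dz - 0.5;
  int i0 = (int)std::floor(xi), k0 = (int)std::floor(zk);
  double fx = xi - i0, fz = zk - k0;
  i0 = std::max(0, std::min(g.nx - 1, i0));
  k0 = std::max(0, std::min(g.nz - 2, k0));
  fx = std::max(0.0, std::min(1.0, fx)); fz = std::max(0.0, std::min(1.0, fz));
  return (1 - fx) * (1 - fz) * U[g.FX(i0, k0)] + fx * (1 - fz) * U[g.FX(i0 + 1, k0)] +
         (1 - fx) * fz * U[g.FX(i0, k0 + 1)] + fx * fz * U[g.FX(i0 + 1, k0 + 1)];
}
static inline double interp_w(const Geom& g, const double* W, double x, double z) {
  double xi = x / g.dx - 0.5, zk = z / g.dz;
  int i0 = (int)std::floor(xi), k0 = (int)std::floor(zk);
  double fx = xi - i0, fz = zk - k0;
  i0 = std::max(0, std::min(g.nx - 2, i0));
  k0 = std::max(0, std::min(g.nz - 1, k0));
  fx = std::max(0.0, std::min(1.0, fx)); fz = std::max(0.0, std::min(1.0, fz));
  return (1 - fx) * (1 - fz) * W[g.FZ(i0, k0)] + fx * (1 - fz) * W[g.FZ(i0 + 1, k0)] +
         (1 - fx) * fz * W[g.FZ(i0, k0 + 1)] + fx * fz * W[g.FZ(i0 + 1, k0 + 1)];
}
static inline double interp_cell(const Geom& g, const std::vector<double>& F,
                                 double x, double z, double fb) {
  double xi = x / g.dx - 0.5, zk = z / g.dz - 0.5;
  int i0 = (int)std::floor(xi), k0 = (int)std::floor(zk);
  double fx = xi - i0, fz = zk - k0;
  i0 = std::max(0, std::min(g.nx - 2, i0));
  k0 = std::max(0, std::min(g.nz - 2, k0));
  fx = std::max(0.0, std::min(1.0, fx)); fz = std::max(0.0, std::min(1.0, fz));
  auto v = [&](int i, int k) {
    return g.ctype[g.C(i, k)] == 0 ? F[g.C(i, k)] : fb;
  };
  return (1 - fx) * (1 - fz) * v(i0, k0) + fx * (1 - fz) * v(i0 + 1, k0) +
         (1 - fx) * fz * v(i0, k0 + 1) + fx * fz * v(i0 + 1, k0 + 1);
}

// Drag relaxation with exponential integrator: exact for frozen carrier
// velocity and drag factor over the step.  Schiller-Naumann correction.
// [[Rcpp::export]]
List cpp_advance_cells(NumericVector px, NumericVector pz, NumericVector pvx,
                       NumericVector pvz, NumericVector u, NumericVector w,
                       NumericVector mu_c, NumericVector rho_c, List geom,
                       double rho_p, double d_p, double g_z, double dt) {
  Geom g = unpack_geom(geom);
  int n = px.size();
  NumericVector qx(n), qz(n), qvx(n), qvz(n);
  std::vector<double> MU(mu_c.begin(), mu_c.end()), RHO(rho_c.begin(), rho_c.end());
  for (int m = 0; m < n; ++m) {
    double x = px[m], z = pz[m], vx = pvx[m], vz = pvz[m];
    double uf = interp_u(g, REAL(u), x, z);
    double wf = interp_w(g, REAL(w), x, z);
    double muf = std::max(interp_cell(g, MU, x, z, 1e-3), 1e-9);
    double rhof = std::max(interp_cell(g, RHO, x, z, 1.2), 1e-3);
    double tau = rho_p * d_p * d_p / (18.0 * muf);
    double dvx = uf - vx, dvz = wf - vz;
    double re = rhof * d_p * std::sqrt(dvx * dvx + dvz * dvz) / muf;
    double cf = 1.0 + 0.15 * std::pow(re, 0.687);
    double taue = tau / cf;
    double gx_eff = 0.0;
    double gz_eff = (1.0 - rhof / rho_p) * g_z;
    double veqx = uf + taue * gx_eff, veqz = wf + taue * gz_eff;
    double dec = std::exp(-dt / taue);
    double nvx = veqx + (vx - veqx) * dec;
    double nvz = veqz + (vz - veqz) * dec;
    double nx_ = x + dt * nvx, nz_ = z + dt * nvz;
    if (nx_ < 0) { nx_ = -nx_; nvx = -nvx; }  // axis reflection
    qx[m] = nx_; qz[m] = nz_; qvx[m] = nvx; qvz[m] = nvz;
  }
  return List::create(_["x"] = qx, _["z"] = qz, _["vx"] = qvx, _["vz"] = qvz);
}

// Impingement detection between old and proposed positions.
// Event kinds: 1 scaffold, 2 wall, 3 outlet (escape), 4 inlet face contact.
// An event is raised when the segment enters a non-fluid cell / leaves the
// domain, or (touch capture) when the end position lies within `capture` of a
// solid surface probed along the axes.
// [[Rcpp::export]]
List cpp_detect_impingement(NumericVector x0, NumericVector z0, NumericVector x1,
                            NumericVector z1, NumericVector vx, NumericVector vz,
                            List geom, double capture) {
  Geom g = unpack_geom(geom);
  int n = x0.size();
  std::vector<int> idx, kind;
  std::vector<double> nxv, nzv, vn, ix, iz;
  auto cellkind = [&](int i, int k) -> int {
    // 0 fluid, >0 solid-ish: map cell types / boundaries to event kinds
    if (i < 0) return 0;                       // axis: handled by reflection
    if (i >= g.nx) return 2;                   // outer radius: wall/inlet side
    if (k < 0) return 2;                       // below bottom
    if (k >= g.nz) return 3;                   // above top: outlet or wall (checked later)
    int ct = g.ctype[g.C(i, k)];
    if (ct == 1) return 1;
    if (ct != 0) return 2;
    return 0;
  };
  const double INF = std::numeric_limits<double>::infinity();
  for (int m = 0; m < n; ++m) {
    double ax = x0[m], az = z0[m], bx = x1[m], bz = z1[m];
    double segx = bx - ax, segz = bz - az;
    // exact grid traversal (Amanatides-Woo): visit every cell the segment
    // crosses, in order, and stop at the first non-fluid one
    int i = (int)std::floor(ax / g.dx), k = (int)std::floor(az / g.dz);
    int stepi = (segx > 0) - (segx < 0), stepk = (segz > 0) - (segz < 0);
    double tmaxx = stepi ? (((i + (stepi > 0)) * g.dx) - ax) / segx : INF;
    double tmaxz = stepk ? (((k + (stepk > 0)) * g.dz) - az) / segz : INF;
    double tdx = stepi ? g.dx / std::fabs(segx) : INF;
    double tdz = stepk ? g.dz / std::fabs(segz) : INF;
    bool hit = false;
    while (!hit) {
      int axis;
      double t;
      if (tmaxx < tmaxz) { t = tmaxx; tmaxx += tdx; i += stepi; axis = 0; }
      else if (std::isfinite(tmaxz)) { t = tmaxz; tmaxz += tdz; k += stepk; axis = 1; }
      else break;
      if (t > 1.0) break;
      int ck = cellkind(i, k);
      if (ck == 0) continue;
      double nxe = 0.0, nze = 0.0;
      double px_ = ax + t * segx, pz_ = az + t * segz;
      if (axis == 0) nxe = -stepi; else nze = -stepk;
      int kk = ck;
      if (ck == 3) {
        // crossing top boundary: outlet only if the top face there is outlet
        int ii = std::max(0, std::min(g.nx - 1, i));
        kk = (g.fz[g.FZ(ii, g.nz)] == 3) ? 3 : 2;
      } else if (ck == 2) {
        // wall cell: if the crossed face is an inlet, tag inlet contact
        // (resolution decides whether inlets capture)
        int pi2 = std::max(0, std::min(g.nx - 1, i - (axis == 0 ? stepi : 0)));
        int pk2 = std::max(0, std::min(g.nz - 1, k - (axis == 1 ? stepk : 0)));
        if (axis == 0) {
          int fcol = (stepi > 0) ? pi2 + 1 : pi2;
          if (g.fx[g.FX(std::max(0, std::min(g.nx, fcol)), pk2)] == 2) kk = 4;
        } else {
          int frow = (stepk > 0) ? pk2 + 1 : pk2;
          if (g.fz[g.FZ(pi2, std::max(0, std::min(g.nz, frow)))] == 2) kk = 4;
        }
      }
      idx.push_back(m + 1);
      kind.push_back(kk);
      nxv.push_back(nxe); nzv.push_back(nze);
      vn.push_back(std::max(0.0, -(vx[m] * nxe + vz[m] * nze)));
      ix.push_back(std::max(px_, 0.0)); iz.push_back(pz_);
      hit = true;
    }
    if (hit) continue;
    // touch capture at end position
    struct Probe { double dx_, dz_; } pr[4] = {
        {capture, 0.0}, {-capture, 0.0}, {0.0, capture}, {0.0, -capture}};
    for (int q = 0; q < 4; ++q) {
      double cx = bx + pr[q].dx_, cz = bz + pr[q].dz_;
      if (cx < 0) continue;  // axis
      int i = (int)std::floor(cx / g.dx), k = (int)std::floor(cz / g.dz);
      int ck = cellkind(i, k);
      if (ck == 0) continue;
      double nxe = (pr[q].dx_ != 0.0) ? (pr[q].dx_ > 0 ? -1.0 : 1.0) : 0.0;
      double nze = (pr[q].dz_ != 0.0) ? (pr[q].dz_ > 0 ? -1.0 : 1.0) : 0.0;
      int kk = ck;
      if (ck == 3) {
        int ii = std::max(0, std::min(g.nx - 1, i));
        kk = (g.fz[g.FZ(ii, g.nz)] == 3) ? 3 : 2;
      }
      if (kk == 2) {
        int ii = (int)std::floor(bx / g.dx), ik = (int)std::floor(bz / g.dz);
        ii = std::max(0, std::min(g.nx - 1, ii));
        ik = std::max(0, std::min(g.nz - 1, ik));
        if (nxe < 0 && g.fx[g.FX(std::min(ii + 1, g.nx), ik)] == 2) kk = 4;
        if (nxe > 0 && g.fx[g.FX(ii, ik)] == 2) kk = 4;
        if (nze < 0 && g.fz[g.FZ(ii, std::min(ik + 1, g.nz))] == 2) kk = 4;
        if (nze > 0 && g.fz[g.FZ(ii, ik)] == 2) kk = 4;
      }
      idx.push_back(m + 1);
      kind.push_back(kk);
      nxv.push_back(nxe); nzv.push_back(nze);
      vn.push_back(std::max(0.0, -(vx[m] * nxe + vz[m] * nze)));
      ix.push_back(bx); iz.push_back(bz);
      break;
    }
  }
  return List::create(_["idx"] = wrap(idx), _["kind"] = wrap(kind),
                      _["nx"] = wrap(nxv), _["nz"] = wrap(nzv),
                      _["vn"] = wrap(vn), _["x"] = wrap(ix), _["z"] = wrap(iz));
}
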