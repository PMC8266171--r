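// Monolithic three-field FEM kernel: bilinear quad / trilinear hex elements
// with nodal dofs [u (dim), c, phi] and a Gauss-point growth variable alpha.
//
// Element residuals are templated on the scalar type; the consistent tangent
// is obtained by complex-step differentiation of the residual (exact to
// machine precision, including the follower-pressure and finite-strain
// geometric terms).  Lagged quantities (Heaviside gates, the nutrient
// gradient direction in the phase-field source, alpha) enter as plain data
// and therefore contribute no tangent blocks.
#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cdouble;

static inline double Re(double x) { return x; }
static inline double Re(const cdouble& x) { return x.real(); }

template <typename T> static inline T mac(const T& x) {
  return Re(x) >= 0.0 ? x : T(0.0);
}

// ---------- small dense 3x3 helpers (row-major T[9]) ----------
template <typename T> static inline T det3(const T* A) {
  return A[0] * (A[4] * A[8] - A[5] * A[7])
       - A[1] * (A[3] * A[8] - A[5] * A[6])
       + A[2] * (A[3] * A[7] - A[4] * A[6]);
}
template <typename T> static inline void inv3(const T* A, T* B, const T& d) {
  T id = T(1.0) / d;
  B[0] =  (A[4] * A[8] - A[5] * A[7]) * id;
  B[1] = -(A[1] * A[8] - A[2] * A[7]) * id;
  B[2] =  (A[1] * A[5] - A[2] * A[4]) * id;
  B[3] = -(A[3] * A[8] - A[5] * A[6]) * id;
  B[4] =  (A[0] * A[8] - A[2] * A[6]) * id;
  B[5] = -(A[0] * A[5] - A[2] * A[3]) * id;
  B[6] =  (A[3] * A[7] - A[4] * A[6]) * id;
  B[7] = -(A[0] * A[7] - A[1] * A[6]) * id;
  B[8] =  (A[0] * A[4] - A[1] * A[3]) * id;
}
template <typename T> static inline void mul3(const T* A, const T* B, T* C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      T s(0.0);
      for (int k = 0; k < 3; ++k) s += A[3 * i + k] * B[3 * k + j];
      C[3 * i + j] = s;
    }
}

struct MatPar {
  double mu, nu, eta, beta, rho, theta_el, exp_clip;
  bool vol_literal, iso_matrix;
};

struct Pars {
  int dim;
  MatPar mat;
  double Kc, Dmax, Dmin, Rc;
  double Kphi, eps2, M, Rs, Kp;
  double dt;
  bool transient;
  double kg, alpha_cri; // used by the staggered alpha update only
};

static MatPar mat_from_list(const List& m) {
  MatPar p;
  p.mu = as<double>(m["mu"]);       p.nu = as<double>(m["nu"]);
  p.eta = as<double>(m["eta"]);     p.beta = as<double>(m["beta"]);
  p.rho = as<double>(m["rho"]);     p.theta_el = as<double>(m["theta_el"]);
  p.exp_clip = as<double>(m["exp_clip"]);
  p.vol_literal = as<bool>(m["vol_coeff_literal"]);
  p.iso_matrix = as<bool>(m["isochoric_matrix"]);
  return p;
}

// ---------- HGO free energy and its analytic first Piola derivative ----------
// Psi(Fe) = mu/2 (I1 - 3)                      [full I1 by default]
//         + (eta/beta) exp(beta [rho<I4b-1>^2 + (1-rho)(I1b-3)^2])
//         + kvol (Je - 1)^2 - mu log Je
// with isochoric invariants I1b = Je^{-2/3} tr(Ce), I4b = Je^{-2/3} n.Ce.n
// and kvol = mu nu/(1-2nu) (or the literal nu/(mu(1-2nu)) behind a flag).
template <typename T>
static T psi_hgo_T(const T* Fe, const double* nfib, const MatPar& mp) {
  T J = det3(Fe);
  T I1(0.0);
  for (int k = 0; k < 9; ++k) I1 += Fe[k] * Fe[k];
  T Fn[3];
  for (int i = 0; i < 3; ++i)
    Fn[i] = Fe[3 * i + 0] * nfib[0] + Fe[3 * i + 1] * nfib[1] +
            Fe[3 * i + 2] * nfib[2];
  T I4 = Fn[0] * Fn[0] + Fn[1] * Fn[1] + Fn[2] * Fn[2];
  T Jm23 = exp(T(-2.0 / 3.0) * log(J));
  T I1b = Jm23 * I1, I4b = Jm23 * I4;
  T psi(0.0);
  psi += mp.iso_matrix ? T(0.5 * mp.mu) * (I1b - T(3.0))
                       : T(0.5 * mp.mu) * (I1 - T(3.0));
  if (mp.eta > 0.0) {
    T q4 = mac(I4b - T(1.0));
    T Q = T(mp.rho) * q4 * q4 +
          T(1.0 - mp.rho) * (I1b - T(3.0)) * (I1b - T(3.0));
    T arg = T(mp.beta) * Q;
    if (Re(arg) > mp.exp_clip) arg = T(mp.exp_clip); // overflow guard
    psi += T(mp.eta / mp.beta) * exp(arg);
  }
  double kvol = mp.vol_literal ? mp.nu / (mp.mu * (1.0 - 2.0 * mp.nu))
                               : mp.mu * mp.nu / (1.0 - 2.0 * mp.nu);
  psi += T(kvol) * (J - T(1.0)) * (J - T(1.0)) - T(mp.mu) * log(J);
  return psi;
}

// dPsi/dFe (3x3, row-major) — hand-derived closed form.
template <typename T>
static void dpsi_dF_T(const T* Fe, const double* nfib, const MatPar& mp,
                      T* P) {
  T J = det3(Fe);
  T Finv[9], FinvT[9];
  inv3(Fe, Finv, J);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) FinvT[3 * i + j] = Finv[3 * j + i];
  T I1(0.0);
  for (int k = 0; k < 9; ++k) I1 += Fe[k] * Fe[k];
  T Fn[3];
  for (int i = 0; i < 3; ++i)
    Fn[i] = Fe[3 * i + 0] * nfib[0] + Fe[3 * i + 1] * nfib[1] +
            Fe[3 * i + 2] * nfib[2];
  T I4 = Fn[0] * Fn[0] + Fn[1] * Fn[1] + Fn[2] * Fn[2];
  T Jm23 = exp(T(-2.0 / 3.0) * log(J));
  T I1b = Jm23 * I1, I4b = Jm23 * I4;

  // d(I1b)/dF = 2 J^{-2/3} F - (2/3) I1b F^{-T}; similarly for I4b with Fn on.
  T dI1b[9], dI4b[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      int k = 3 * i + j;
      dI1b[k] = T(2.0) * Jm23 * Fe[k] - T(2.0 / 3.0) * I1b * FinvT[k];
      dI4b[k] = T(2.0) * Jm23 * Fn[i] * nfib[j] -
                T(2.0 / 3.0) * I4b * FinvT[k];
    }

  double kvol = mp.vol_literal ? mp.nu / (mp.mu * (1.0 - 2.0 * mp.nu))
                               : mp.mu * mp.nu / (1.0 - 2.0 * mp.nu);
  for (int k = 0; k < 9; ++k) {
    T v = (T(2.0) * T(kvol) * (J - T(1.0)) * J - T(mp.mu)) * FinvT[k];
    v += mp.iso_matrix ? T(0.5 * mp.mu) * dI1b[k] : T(mp.mu) * Fe[k];
    P[k] = v;
  }
  if (mp.eta > 0.0) {
    T q4 = mac(I4b - T(1.0));
    T Q = T(mp.rho) * q4 * q4 +
          T(1.0 - mp.rho) * (I1b - T(3.0)) * (I1b - T(3.0));
    T arg = T(mp.beta) * Q;
    if (Re(arg) <= mp.exp_clip) { // beyond the clip the fiber stress is frozen
      T fac = T(mp.eta) * exp(arg);
      for (int k = 0; k < 9; ++k)
        P[k] += fac * (T(2.0 * mp.rho) * q4 * dI4b[k] +
                       T(2.0 * (1.0 - mp.rho)) * (I1b - T(3.0)) * dI1b[k]);
    }
  }
}

// Cauchy stress sigma = (1/Je) dPsi/dFe Fe^T
template <typename T>
static void cauchy_T(const T* Fe, const double* nfib, const MatPar& mp,
                     T* sig) {
  T P[9];
  dpsi_dF_T(Fe, nfib, mp, P);
  T J = det3(Fe);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      T s(0.0);
      for (int k = 0; k < 3; ++k) s += P[3 * i + k] * Fe[3 * j + k];
      sig[3 * i + j] = s / J;
    }
}

// ---------- shape functions ----------
static const double GP = 0.5773502691896258; // 1/sqrt(3)

static void shape2d(double xi, double eta, double* N, double* dN) {
  const double xa[4] = {-1, 1, 1, -1}, ya[4] = {-1, -1, 1, 1};
  for (int a = 0; a < 4; ++a) {
    N[a] = 0.25 * (1 + xa[a] * xi) * (1 + ya[a] * eta);
    dN[2 * a + 0] = 0.25 * xa[a] * (1 + ya[a] * eta);
    dN[2 * a + 1] = 0.25 * ya[a] * (1 + xa[a] * xi);
  }
}
static void shape3d(double xi, double eta, double ze, double* N, double* dN) {
  const double xa[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double ya[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double za[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int a = 0; a < 8; ++a) {
    N[a] = 0.125 * (1 + xa[a] * xi) * (1 + ya[a] * eta) * (1 + za[a] * ze);
    dN[3 * a + 0] = 0.125 * xa[a] * (1 + ya[a] * eta) * (1 + za[a] * ze);
    dN[3 * a + 1] = 0.125 * ya[a] * (1 + xa[a] * xi) * (1 + za[a] * ze);
    dN[3 * a + 2] = 0.125 * za[a] * (1 + xa[a] * xi) * (1 + ya[a] * eta);
  }
}

static void gauss_point(int dim, int g, double* xi) {
  if (dim == 2) {
    const double x[4] = {-GP, GP, GP, -GP}, y[4] = {-GP, -GP, GP, GP};
    xi[0] = x[g]; xi[1] = y[g];
  } else {
    xi[0] = (g & 1) ? GP : -GP;
    xi[1] = (g & 2) ? GP : -GP;
    xi[2] = (g & 4) ? GP : -GP;
  }
}

static void shape_at(int dim, const double* xi, double* N, double* dN) {
  if (dim == 2) shape2d(xi[0], xi[1], N, dN);
  else shape3d(xi[0], xi[1], xi[2], N, dN);
}

// fiber direction from azimuth/elevation:
// n = [-cos(el) sin(az), cos(el) cos(az), sin(el)]
static void fiber_dir(double x, double y, double theta_el, double* n) {
  double r = std::sqrt(x * x + y * y);
  double caz = x / r, saz = y / r;
  n[0] = -std::cos(theta_el) * saz;
  n[1] =  std::cos(theta_el) * caz;
  n[2] =  std::sin(theta_el);
}

// ---------- element residual ----------
// Xe: nen x dim reference coords (row-major [a*dim+i]); de: nen x ndpn dofs;
// re accumulates nen*ndpn entries.  Returns false if an element is inverted.
// skip_mech: omit the stress block (valid when differentiating w.r.t. c/phi
// dofs, which do not enter the mechanical residual).
template <typename T>
static bool elem_residual(int dim, const double* Xe, const T* de,
                          const double* phi_prev, const double* alpha_gp,
                          const double* Hlag, const double* ghat,
                          const Pars& P, T* re, bool skip_mech = false) {
  int nen = (dim == 2) ? 4 : 8, ngp = nen, ndpn = dim + 2;
  for (int k = 0; k < nen * ndpn; ++k) re[k] = T(0.0);
  double N[8], dNxi[24], xi[3];
  T dNx[24];
  for (int g = 0; g < ngp; ++g) {
    gauss_point(dim, g, xi);
    shape_at(dim, xi, N, dNxi);
    // deformed jacobian dx/dxi from xe = Xe + u
    T Jx[9], Jinv[9];
    for (int i = 0; i < dim; ++i)
      for (int j = 0; j < dim; ++j) {
        T s(0.0);
        for (int a = 0; a < nen; ++a)
          s += (T(Xe[a * dim + i]) + de[a * ndpn + i]) * T(dNxi[a * dim + j]);
        Jx[3 * i + j] = s;
      }
    if (dim == 2) { Jx[2] = Jx[5] = Jx[6] = Jx[7] = T(0.0); Jx[8] = T(1.0); }
    T detJ = det3(Jx);
    if (Re(detJ) <= 0.0) return false;
    inv3(Jx, Jinv, detJ);
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < dim; ++i) {
        T s(0.0);
        for (int j = 0; j < dim; ++j)
          s += T(dNxi[a * dim + j]) * Jinv[3 * j + i];
        dNx[a * dim + i] = s;
      }
    T wdv = detJ; // unit Gauss weights

    // --- mechanics ---
    if (!skip_mech) {
    T gradu[9] = {T(0)};
    for (int i = 0; i < dim; ++i)
      for (int j = 0; j < dim; ++j) {
        T s(0.0);
        for (int a = 0; a < nen; ++a) s += de[a * ndpn + i] * dNx[a * dim + j];
        gradu[3 * i + j] = s;
      }
    T A[9] = {T(1), T(0), T(0), T(0), T(1), T(0), T(0), T(0), T(1)};
    for (int i = 0; i < dim; ++i)
      for (int j = 0; j < dim; ++j) A[3 * i + j] -= gradu[3 * i + j];
    if (dim == 2) A[8] = T(1.0);
    T dA = det3(A);
    if (Re(dA) <= 0.0) return false;
    T F[9];
    inv3(A, F, dA);
    // growth split: in-plane in 2D (plane strain, unit out-of-plane growth)
    double ia = 1.0 / (1.0 + alpha_gp[g]);
    T Fe[9];
    for (int k = 0; k < 9; ++k) Fe[k] = F[k] * T(ia);
    if (dim == 2) Fe[8] = T(1.0);
    double Xgp[2] = {0, 0};
    for (int a = 0; a < nen; ++a) {
      Xgp[0] += N[a] * Xe[a * dim + 0];
      Xgp[1] += N[a] * Xe[a * dim + 1];
    }
    double nfib[3];
    fiber_dir(Xgp[0], Xgp[1], P.mat.theta_el, nfib);
    T sig[9];
    cauchy_T(Fe, nfib, P.mat, sig);
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < dim; ++i) {
        T s(0.0);
        for (int j = 0; j < dim; ++j) s += sig[3 * i + j] * dNx[a * dim + j];
        re[a * ndpn + i] += s * wdv;
      }
    }

    // --- nutrient (steady diffusion-reaction) ---
    T c_gp(0.0), gradc[3] = {T(0), T(0), T(0)};
    T phi_gp(0.0), gradphi[3] = {T(0), T(0), T(0)};
    double phiprev_gp = 0.0;
    for (int a = 0; a < nen; ++a) {
      c_gp += T(N[a]) * de[a * ndpn + dim];
      phi_gp += T(N[a]) * de[a * ndpn + dim + 1];
      phiprev_gp += N[a] * phi_prev[a];
      for (int i = 0; i < dim; ++i) {
        gradc[i] += de[a * ndpn + dim] * dNx[a * dim + i];
        gradphi[i] += de[a * ndpn + dim + 1] * dNx[a * dim + i];
      }
    }
    T phic = phi_gp; // clamped to [0,1] inside constitutive evaluations
    if (Re(phic) < 0.0) phic = T(0.0);
    else if (Re(phic) > 1.0) phic = T(1.0);
    T D = phic * T(P.Dmin) + (T(1.0) - phic) * T(P.Dmax);
    for (int a = 0; a < nen; ++a) {
      T s(0.0);
      for (int i = 0; i < dim; ++i) s += gradc[i] * dNx[a * dim + i];
      re[a * ndpn + dim] += T(P.Kc) * (D * s + T(P.Rc * N[a])) * wdv;
    }

    // --- phase field (Allen-Cahn with lagged advective source) ---
    T fp = T(32.0 * P.M) * phi_gp * (T(1.0) - phi_gp) *
           (T(1.0) - T(2.0) * phi_gp);
    T Pp = T(2.0) * mac(phi_gp - T(1.0)) - T(2.0) * mac(-phi_gp);
    T S(0.0);
    if (P.Rs > 0.0 && Hlag[g] > 0.0) {
      T adv(0.0);
      for (int i = 0; i < dim; ++i) adv += gradphi[i] * T(ghat[g * dim + i]);
      S = T(P.Rs * Hlag[g]) * adv;
    }
    for (int a = 0; a < nen; ++a) {
      T s(0.0);
      for (int i = 0; i < dim; ++i) s += gradphi[i] * dNx[a * dim + i];
      T bulk = T(P.eps2) * s +
               (T(P.M) * fp + T(P.Kp) * Pp - S) * T(N[a]);
      if (P.transient)
        bulk += (phi_gp - T(phiprev_gp)) / T(P.dt) * T(N[a]);
      re[a * ndpn + dim + 1] += T(P.Kphi) * bulk * wdv;
    }
  }
  return true;
}

static Pars pars_from_list(int dim, const List& par) {
  Pars P;
  P.dim = dim;
  P.mat = mat_from_list(par["material"]);
  List nu = par["nutrient"], ph = par["phasefield"], so = par["solver"];
  P.Kc = as<double>(so["K_c"]);   P.Kphi = as<double>(so["K_phi"]);
  P.Dmax = as<double>(nu["D_max"]); P.Dmin = as<double>(nu["D_min"]);
  P.Rc = as<double>(nu["R_c"]);
  double eps = as<double>(ph["eps"]);
  P.eps2 = eps * eps;
  P.M = as<double>(ph["M"]); P.Rs = as<double>(ph["R_s"]);
  P.Kp = as<double>(ph["K_p"]);
  P.dt = as<double>(so["dt"]);
  P.transient = P.dt > 0.0;
  List gr = par["growth"];
  P.kg = as<double>(gr["k_g"]); P.alpha_cri = as<double>(gr["alpha_cri"]);
  return P;
}

// ---------- exported: monolithic assembly ----------
// [[Rcpp::export]]
List fem_assemble(NumericMatrix coords, IntegerMatrix elems0, int dim,
                  NumericVector dofs, NumericVector phi_prev_nodal,
                  NumericMatrix alpha_gp, NumericMatrix Hlag,
                  NumericMatrix ghat, List par, bool want_tangent) {
  int m = elems0.nrow(), nen = elems0.ncol(), ndpn = dim + 2;
  int nde = nen * ndpn, n = coords.nrow();
  Pars P = pars_from_list(dim, par);
  NumericVector res(n * ndpn);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve((size_t)m * nde * nde);
    tj.reserve((size_t)m * nde * nde);
    tx.reserve((size_t)m * nde * nde);
  }
  double Xe[24];
  double de[40], phip[8], agp[8], Hl[8], gh[24];
  double reD[40];
  cdouble deC[40], reC[40];
  const double hstep = 1e-30;
  bool ok = true;
  int ngp = nen;
  for (int e = 0; e < m && ok; ++e) {
    for (int a = 0; a < nen; ++a) {
      int nd = elems0(e, a);
      for (int i = 0; i < dim; ++i) Xe[a * dim + i] = coords(nd, i);
      for (int k = 0; k < ndpn; ++k) de[a * ndpn + k] = dofs[nd * ndpn + k];
      phip[a] = phi_prev_nodal[nd];
    }
    for (int g = 0; g < ngp; ++g) {
      agp[g] = alpha_gp(e, g);
      Hl[g] = Hlag(e, g);
      for (int i = 0; i < dim; ++i) gh[g * dim + i] = ghat(e, g * dim + i);
    }
    if (!elem_residual<double>(dim, Xe, de, phip, agp, Hl, gh, P, reD)) {
      ok = false;
      break;
    }
    for (int a = 0; a < nen; ++a) {
      int nd = elems0(e, a);
      for (int k = 0; k < ndpn; ++k) res[nd * ndpn + k] += reD[a * ndpn + k];
    }
    if (want_tangent) {
      for (int k = 0; k < nde; ++k) deC[k] = cdouble(de[k], 0.0);
      for (int kcol = 0; kcol < nde; ++kcol) {
        deC[kcol] = cdouble(de[kcol], hstep);
        bool is_scalar_dof = (kcol % ndpn) >= dim;
        elem_residual<cdouble>(dim, Xe, deC, phip, agp, Hl, gh, P, reC,
                               is_scalar_dof);
        deC[kcol] = cdouble(de[kcol], 0.0);
        int ac = kcol / ndpn, kc = kcol % ndpn;
        int jglob = elems0(e, ac) * ndpn + kc;
        for (int krow = 0; krow < nde; ++krow) {
          double v = reC[krow].imag() / hstep;
          if (v != 0.0) {
            int ar = krow / ndpn, kr = krow % ndpn;
            ti.push_back(elems0(e, ar) * ndpn + kr);
            tj.push_back(jglob);
            tx.push_back(v);
          }
        }
      }
    }
  }
  return List::create(_["res"] = res, _["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx), _["ok"] = ok);
}

// ---------- exported: follower pressure on boundary facets ----------
// Residual contribution - int t . delta_u ds with t = -p n on the deformed
// facet; n is the outward normal (orientation sign supplied per facet).
template <typename T>
static void facet_residual(int dim, const double* Xf, const T* uf,
                           double orient, double p, T* rf) {
  if (dim == 2) {
    // straight segment, exact with 2-point rule on a linear integrand
    T y0[2], y1[2];
    for (int i = 0; i < 2; ++i) {
      y0[i] = T(Xf[i]) + uf[i];
      y1[i] = T(Xf[2 + i]) + uf[2 + i];
    }
    T tau[2] = {y1[0] - y0[0], y1[1] - y0[1]};
    T nds[2] = {tau[1] * T(orient), -tau[0] * T(orient)}; // n |tau|, unnormed
    for (int a = 0; a < 2; ++a)
      for (int i = 0; i < 2; ++i)
        rf[a * 2 + i] = T(0.5 * p) * nds[i]; // int N_a ds = |tau|/2 each
  } else {
    for (int k = 0; k < 12; ++k) rf[k] = T(0.0);
    double N[4], dN[8];
    const double gp2[2] = {-GP, GP};
    for (int gx = 0; gx < 2; ++gx)
      for (int gy = 0; gy < 2; ++gy) {
        shape2d(gp2[gx], gp2[gy], N, dN);
        T t1[3] = {T(0), T(0), T(0)}, t2[3] = {T(0), T(0), T(0)};
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i) {
            T y = T(Xf[a * 3 + i]) + uf[a * 3 + i];
            t1[i] += y * T(dN[2 * a + 0]);
            t2[i] += y * T(dN[2 * a + 1]);
          }
        T nds[3] = {t1[1] * t2[2] - t1[2] * t2[1],
                    t1[2] * t2[0] - t1[0] * t2[2],
                    t1[0] * t2[1] - t1[1] * t2[0]};
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i)
            rf[a * 3 + i] += T(p * orient * N[a]) * nds[i];
      }
  }
}

// [[Rcpp::export]]
List fem_assemble_pressure(NumericMatrix coords, int dim, NumericVector dofs,
                           IntegerMatrix facet_nodes0, NumericVector orient,
                           double p, bool want_tangent) {
  int nf = facet_nodes0.nrow(), nfn = facet_nodes0.ncol(), ndpn = dim + 2;
  int n = coords.nrow(), ndf = nfn * dim;
  NumericVector res(n * ndpn);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  double Xf[12], uf[12], rfD[12];
  cdouble ufC[12], rfC[12];
  const double hstep = 1e-30;
  for (int f = 0; f < nf; ++f) {
    for (int a = 0; a < nfn; ++a) {
      int nd = facet_nodes0(f, a);
      for (int i = 0; i < dim; ++i) {
        Xf[a * dim + i] = coords(nd, i);
        uf[a * dim + i] = dofs[nd * ndpn + i];
      }
    }
    facet_residual<double>(dim, Xf, uf, orient[f], p, rfD);
    for (int a = 0; a < nfn; ++a) {
      int nd = facet_nodes0(f, a);
      for (int i = 0; i < dim; ++i) res[nd * ndpn + i] += rfD[a * dim + i];
    }
    if (want_tangent) {
      for (int k = 0; k < ndf; ++k) ufC[k] = cdouble(uf[k], 0.0);
      for (int kcol = 0; kcol < ndf; ++kcol) {
        ufC[kcol] = cdouble(uf[kcol], hstep);
        facet_residual<cdouble>(dim, Xf, ufC, orient[f], p, rfC);
        ufC[kcol] = cdouble(uf[kcol], 0.0);
        int ac = kcol / dim, ic = kcol % dim;
        int jglob = facet_nodes0(f, ac) * ndpn + ic;
        for (int krow = 0; krow < ndf; ++krow) {
          double v = rfC[krow].imag() / hstep;
          if (v != 0.0) {
            int ar = krow / dim, ir = krow % dim;
            ti.push_back(facet_nodes0(f, ar) * ndpn + ir);
            tj.push_back(jglob);
            tx.push_back(v);
          }
        }
      }
    }
  }
  return List::create(_["res"] = res, _["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx));
}

// ---------- exported: Gauss-point field evaluation (deformed config) ----------
// Returns per Gauss point: nutrient value and gradient, phase-field value,
// integration weight (det J x unit weight) — used for the lagged source
// quantities, the staggered alpha update and volume integrals.
// [[Rcpp::export]]
List fem_gp_fields(NumericMatrix coords, IntegerMatrix elems0, int dim,
                   NumericVector dofs) {
  int m = elems0.nrow(), nen = elems0.ncol(), ndpn = dim + 2, ngp = nen;
  NumericMatrix c_gp(m, ngp), phi_gp(m, ngp), detJw(m, ngp);
  NumericMatrix gradc(m, ngp * dim), gradphi(m, ngp * dim);
  double N[8], dNxi[24], xi[3];
  for (int e = 0; e < m; ++e) {
    double xe[24], ce[8], fe[8];
    for (int a = 0; a < nen; ++a) {
      int nd = elems0(e, a);
      for (int i = 0; i < dim; ++i)
        xe[a * dim + i] = coords(nd, i) + dofs[nd * ndpn + i];
      ce[a] = dofs[nd * ndpn + dim];
      fe[a] = dofs[nd * ndpn + dim + 1];
    }
    for (int g = 0; g < ngp; ++g) {
      gauss_point(dim, g, xi);
      shape_at(dim, xi, N, dNxi);
      double Jx[9] = {0, 0, 0, 0, 0, 0, 0, 0, 1};
      for (int i = 0; i < dim; ++i)
        for (int j = 0; j < dim; ++j) {
          double s = 0;
          for (int a = 0; a < nen; ++a)
            s += xe[a * dim + i] * dNxi[a * dim + j];
          Jx[3 * i + j] = s;
        }
      double dJ = det3(Jx), Jinv[9];
      inv3(Jx, Jinv, dJ);
      detJw(e, g) = dJ;
      double cg = 0, fg = 0, gc[3] = {0, 0, 0}, gf[3] = {0, 0, 0};
      for (int a = 0; a < nen; ++a) {
        cg += N[a] * ce[a];
        fg += N[a] * fe[a];
        for (int i = 0; i < dim; ++i) {
          double dNa = 0;
          for (int j = 0; j < dim; ++j)
            dNa += dNxi[a * dim + j] * Jinv[3 * j + i];
          gc[i] += dNa * ce[a];
          gf[i] += dNa * fe[a];
        }
      }
      c_gp(e, g) = cg;
      phi_gp(e, g) = fg;
      for (int i = 0; i < dim; ++i) {
        gradc(e, g * dim + i) = gc[i];
        gradphi(e, g * dim + i) = gf[i];
      }
    }
  }
  return List::create(_["c_gp"] = c_gp, _["phi_gp"] = phi_gp,
                      _["gradc"] = gradc, _["gradphi"] = gradphi,
                      _["detJw"] = detJw);
}

// ---------- exported: per-element averaged Cauchy stress ----------
// [[Rcpp::export]]
NumericMatrix fem_gp_stress(NumericMatrix coords, IntegerMatrix elems0,
                            int dim, NumericVector dofs,
                            NumericMatrix alpha_gp, List material) {
  int m = elems0.nrow(), nen = elems0.ncol(), ndpn = dim + 2, ngp = nen;
  MatPar mp = mat_from_list(material);
  NumericMatrix out(m, 9);
  double N[8], dNxi[24], xi[3];
  for (int e = 0; e < m; ++e) {
    double Xe[24], xe[24];
    for (int a = 0; a < nen; ++a) {
      int nd = elems0(e, a);
      for (int i = 0; i < dim; ++i) {
        Xe[a * dim + i] = coords(nd, i);
        xe[a * dim + i] = coords(nd, i) + dofs[nd * ndpn + i];
      }
    }
    double acc[9] = {0};
    for (int g = 0; g < ngp; ++g) {
      gauss_point(dim, g, xi);
      shape_at(dim, xi, N, dNxi);
      double Jx[9] = {0, 0, 0, 0, 0, 0, 0, 0, 1};
      for (int i = 0; i < dim; ++i)
        for (int j = 0; j < dim; ++j) {
          double s = 0;
          for (int a = 0; a < nen; ++a)
            s += xe[a * dim + i] * dNxi[a * dim + j];
          Jx[3 * i + j] = s;
        }
      double dJ = det3(Jx), Jinv[9];
      inv3(Jx, Jinv, dJ);
      double gradu[9] = {0};
      for (int i = 0; i < dim; ++i)
        for (int j = 0; j < dim; ++j) {
          double s = 0;
          for (int a = 0; a < nen; ++a) {
            double dNa = 0;
            for (int k = 0; k < dim; ++k)
              dNa += dNxi[a * dim + k] * Jinv[3 * k + j];
            s += (xe[a * dim + i] - Xe[a * dim + i]) * dNa;
          }
          gradu[3 * i + j] = s;
        }
      double A[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
      for (int i = 0; i < dim; ++i)
        for (int j = 0; j < dim; ++j) A[3 * i + j] -= gradu[3 * i + j];
      double dA = det3(A), F[9];
      inv3(A, F, dA);
      double ia = 1.0 / (1.0 + alpha_gp(e, g));
      double Fe[9];
      for (int k = 0; k < 9; ++k) Fe[k] = F[k] * ia;
      if (dim == 2) Fe[8] = 1.0;
      double Xgp[2] = {0, 0};
      for (int a = 0; a < nen; ++a) {
        Xgp[0] += N[a] * Xe[a * dim + 0];
        Xgp[1] += N[a] * Xe[a * dim + 1];
      }
      double nfib[3], sig[9];
      fiber_dir(Xgp[0], Xgp[1], mp.theta_el, nfib);
      cauchy_T<double>(Fe, nfib, mp, sig);
      for (int k = 0; k < 9; ++k) acc[k] += sig[k] / ngp;
    }
    for (int k = 0; k < 9; ++k) out(e, k) = acc[k];
  }
  return out;
}

// ---------- exported: pointwise material law (used by R wrappers) ----------
// [[Rcpp::export]]
double psi_hgo_cpp(NumericMatrix Fe, NumericVector nfib, List material) {
  MatPar mp = mat_from_list(material);
  double F[9], n[3];
  for (int i = 0; i < 3; ++i) {
    n[i] = nfib[i];
    for (int j = 0; j < 3; ++j) F[3 * i + j] = Fe(i, j);
  }
  return psi_hgo_T<double>(F, n, mp);
}

// [[Rcpp::export]]
NumericMatrix stress_hgo_cpp(NumericMatrix Fe, NumericVector nfib,
                             List material) {
  MatPar mp = mat_from_list(material);
  double F[9], n[3], sig[9];
  for (int i = 0; i < 3; ++i) {
    n[i] = nfib[i];
    for (int j = 0; j < 3; ++j) F[3 * i + j] = Fe(i, j);
  }
  cauchy_T<double>(F, n, mp, sig);
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = sig[3 * i + j];
  return out;
}

// ---------- exported: mesh utilities ----------
// [[Rcpp::export]]
NumericVector fem_element_volumes(NumericMatrix coords, IntegerMatrix elems0,
                                  int dim) {
  int m = elems0.nrow(), nen = elems0.ncol(), ngp = nen;
  NumericVector vol(m);
  double N[8], dNxi[24], xi[3];
  for (int e = 0; e < m; ++e) {
    double v = 0;
    for (int g = 0; g < ngp; ++g) {
      gauss_point(dim, g, xi);
      shape_at(dim, xi, N, dNxi);
      double Jx[9] = {0, 0, 0, 0, 0, 0, 0, 0, 1};
      for (int i = 0; i < dim; ++i)
        for (int j = 0; j < dim; ++j) {
          double s = 0;
          for (int a = 0; a < nen; ++a)
            s += coords(elems0(e, a), i) * dNxi[a * dim + j];
          Jx[3 * i + j] = s;
        }
      v += det3(Jx);
    }
    vol[e] = v;
  }
  return vol;
}

// [[Rcpp::export]]
double fem_min_jacobian(NumericMatrix coords, IntegerMatrix elems0, int dim) {
  int m = elems0.nrow(), nen = elems0.ncol(), ngp = nen;
  double mn = R_PosInf;
  double N[8], dNxi[24], xi[3];
  for (int e = 0; e < m; ++e)
    for (int g = 0; g < ngp; ++g) {
      gauss_point(dim, g, xi);
      shape_at(dim, xi, N, dNxi);
      double Jx[9] = {0, 0, 0, 0, 0, 0, 0, 0, 1};
      for (int i = 0; i < dim; ++i)
        for (int j = 0; j < dim; ++j) {
          double s = 0;
          for (int a = 0; a < nen; ++a)
            s += coords(elems0(e, a), i) * dNxi[a * dim + j];
          Jx[3 * i + j] = s;
        }
      mn = std::min(mn, det3(Jx));
    }
  return mn;
}

// ---------- exported: segment / convex-element intersection tagging ----------
// Clips each segment's parameter interval against the half-space of every
// element face (inward normals); a non-empty interval within [0,1] means the
// closed element is cut.  Endpoint- and boundary-inclusive via tol.
// [[Rcpp::export]]
IntegerVector fem_segment_cut_elements(NumericMatrix coords,
                                       IntegerMatrix elems0, int dim,
                                       NumericMatrix A, NumericMatrix B,
                                       double tol) {
  int m = elems0.nrow();
  int nseg = A.nrow();
  std::vector<int> hits;
  // element bounding boxes
  std::vector<double> lo(m * dim), hi(m * dim);
  int nen = elems0.ncol();
  for (int e = 0; e < m; ++e)
    for (int i = 0; i < dim; ++i) {
      double l = R_PosInf, h = R_NegInf;
      for (int a = 0; a < nen; ++a) {
        double v = coords(elems0(e, a), i);
        l = std::min(l, v);
        h = std::max(h, v);
      }
      lo[e * dim + i] = l - tol;
      hi[e * dim + i] = h + tol;
    }
  const int qface[4][2] = {{0, 1}, {1, 2}, {2, 3}, {3, 0}};
  const int hface[6][4] = {{0, 1, 2, 3}, {4, 5, 6, 7}, {0, 1, 5, 4},
                           {1, 2, 6, 5}, {2, 3, 7, 6}, {3, 0, 4, 7}};
  for (int e = 0; e < m; ++e) {
    // element centroid (for inward orientation of face normals)
    double ec[3] = {0, 0, 0};
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < dim; ++i) ec[i] += coords(elems0(e, a), i) / nen;
    bool cut = false;
    for (int s = 0; s < nseg && !cut; ++s) {
      // bbox prefilter
      bool out = false;
      for (int i = 0; i < dim; ++i) {
        double a = A(s, i), b = B(s, i);
        if (std::max(a, b) < lo[e * dim + i] ||
            std::min(a, b) > hi[e * dim + i]) {
          out = true;
          break;
        }
      }
      if (out) continue;
      double tlo = 0.0, thi = 1.0;
      bool rej = false;
      int nfaces = (dim == 2) ? 4 : 6;
      for (int f = 0; f < nfaces && !rej; ++f) {
        double nrm[3] = {0, 0, 0}, fc[3] = {0, 0, 0};
        if (dim == 2) {
          int i0 = elems0(e, qface[f][0]), i1 = elems0(e, qface[f][1]);
          double tx = coords(i1, 0) - coords(i0, 0);
          double ty = coords(i1, 1) - coords(i0, 1);
          nrm[0] = -ty; nrm[1] = tx; // inward for CCW polygons
          fc[0] = 0.5 * (coords(i0, 0) + coords(i1, 0));
          fc[1] = 0.5 * (coords(i0, 1) + coords(i1, 1));
        } else {
          double p[4][3];
          for (int k = 0; k < 4; ++k) {
            int nd = elems0(e, hface[f][k]);
            for (int i = 0; i < 3; ++i) {
              p[k][i] = coords(nd, i);
              fc[i] += coords(nd, i) / 4.0;
            }
          }
          double d1[3], d2[3];
          for (int i = 0; i < 3; ++i) {
            d1[i] = p[2][i] - p[0][i];
            d2[i] = p[3][i] - p[1][i];
          }
          nrm[0] = d1[1] * d2[2] - d1[2] * d2[1];
          nrm[1] = d1[2] * d2[0] - d1[0] * d2[2];
          nrm[2] = d1[0] * d2[1] - d1[1] * d2[0];
          double dot = 0;
          for (int i = 0; i < 3; ++i) dot += nrm[i] * (ec[i] - fc[i]);
          if (dot < 0)
            for (int i = 0; i < 3; ++i) nrm[i] = -nrm[i];
        }
        double nn = 0;
        for (int i = 0; i < dim; ++i) nn += nrm[i] * nrm[i];
        nn = std::sqrt(nn);
        double a0 = 0, b0 = 0;
        for (int i = 0; i < dim; ++i) {
          a0 += nrm[i] / nn * (A(s, i) - fc[i]);
          b0 += nrm[i] / nn * (B(s, i) - A(s, i));
        }
        if (std::fabs(b0) < 1e-14) {
          if (a0 < -tol) rej = true;
        } else {
          double tc = (-tol - a0) / b0;
          if (b0 > 0) tlo = std::max(tlo, tc);
          else thi = std::min(thi, tc);
          if (tlo > thi) rej = true;
        }
      }
      if (!rej) cut = true;
    }
    if (cut) hits.push_back(e);
  }
  return wrap(hits);
}
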