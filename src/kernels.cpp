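// Numerical kernels for the cross-scale tumour model:
//  - right-hand side of the nine-species intracellular network
//  - L-stable adaptive backward-Euler advance of many cells over a macro step
//    (the network mixes rates from ~5e-3 to ~2e5 s^-1, far too stiff for an
//    explicit scheme over hour-long horizons)
//  - explicit FTCS diffusion substeps with occupancy factor and reflecting
//    boundaries.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NSPEC = 9;

// parameter vector layout (matches .gs_param_names on the R side)
enum {
  K1, K1_I, K2, K3, K4, K5, K6, K7, K8, K9, K10,
  K11_M1, K11_C1, K11_M2, K11_C2, K12_I, K12,
  K13_M1, K13_C1, K13_M2, K13_C2, K14, K15_I, K15, K16,
  K17_M1, K17_C1, K17_M2, K17_C2, K18_M, K18_C,
  R_CONS, C1W, C2W, NPAR
};
// constants layout: A_tot, T_tot, R_tot, M_tot, S_tot, kappa, g_ref
enum { CA, CT, CR, CM, CS, CKAPPA, CGREF, NCONST };

static inline void rhs_core(const double* x, double glucose,
                            const double* p, const double* c, double* dx) {
  const double gt = glucose * c[CKAPPA];   // pmol/L
  const double gh = glucose / c[CGREF];    // dimensionless
  const double bind = p[K2] * x[0] * x[1];
  dx[0] = p[K1] * gt / (1.0 + x[0] / p[K1_I]) - bind + p[K3] * x[2]
          - p[K6] * x[0];
  dx[1] = p[K4] - bind + p[K3] * x[2] - p[K7] * x[1];
  dx[2] = bind - p[K3] * x[2] - p[K5] * x[2];
  const double assoc = p[K9] * x[3] * (c[CS] - x[4]);
  dx[3] = p[K8] * x[1] - assoc + p[K10] * x[4];
  dx[4] = assoc - p[K10] * x[4];
  dx[5] = p[K11_C1] * x[4] * (c[CA] - x[5]) / (p[K11_M1] + c[CA] - x[5])
          - p[K11_C2] * x[5] / (p[K11_M2] + x[5])
          - p[K12] * x[5] * gh / (p[K12_I] + gh);
  dx[6] = p[K13_C1] * x[5] * (c[CT] - x[6]) / (p[K13_M1] + c[CT] - x[6])
          - p[K13_C2] * x[6] / (p[K13_M2] + x[6]);
  dx[7] = p[K14] * (c[CR] - x[7])
          - p[K15] * x[7] * x[6] / (p[K15_I] + x[6]);
  dx[8] = p[K17_C1] * x[7] * (c[CM] - x[8]) / (p[K17_M1] + c[CM] - x[8])
          - p[K17_C2] * x[8] / (p[K17_M2] + x[8])
          - p[K18_C] * x[5] * x[8] / (p[K18_M] + x[8])
          - p[K16] * x[8];
}

// [[Rcpp::export]]
NumericVector gs_rhs_cpp(NumericVector state, double glucose,
                         NumericVector params, NumericVector consts) {
  if (state.size() != NSPEC) stop("state must have 9 components");
  NumericVector out(NSPEC);
  rhs_core(state.begin(), glucose, params.begin(), consts.begin(),
           out.begin());
  return out;
}

// solve A y = b in place by Gaussian elimination with partial pivoting
static bool solve9(double A[NSPEC][NSPEC], double* b) {
  for (int k = 0; k < NSPEC; ++k) {
    int imax = k;
    double amax = std::fabs(A[k][k]);
    for (int i = k + 1; i < NSPEC; ++i) {
      double a = std::fabs(A[i][k]);
      if (a > amax) { amax = a; imax = i; }
    }
    if (amax < 1e-300) return false;
    if (imax != k) {
      for (int j = 0; j < NSPEC; ++j) std::swap(A[k][j], A[imax][j]);
      std::swap(b[k], b[imax]);
    }
    for (int i = k + 1; i < NSPEC; ++i) {
      double f = A[i][k] / A[k][k];
      A[i][k] = 0.0;
      for (int j = k + 1; j < NSPEC; ++j) A[i][j] -= f * A[k][j];
      b[i] -= f * b[k];
    }
  }
  for (int i = NSPEC - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < NSPEC; ++j) s -= A[i][j] * b[j];
    b[i] = s / A[i][i];
  }
  return true;
}

// clamp to [0, pool]; returns number of clamped components
static int clamp_state(double* x, const double* c) {
  int n = 0;
  const double pool[NSPEC] = {
    1e300, 1e300, 1e300, 1e300, c[CS], c[CA], c[CT], c[CR], c[CM] };
  for (int i = 0; i < NSPEC; ++i) {
    if (x[i] < 0.0) { x[i] = 0.0; ++n; }
    else if (x[i] > pool[i]) { x[i] = pool[i]; ++n; }
  }
  return n;
}

// one backward-Euler step x -> y solving y = x + h f(y) by damped Newton
static bool be_step(const double* x, double h, double glucose,
                    const double* p, const double* c, double* y) {
  double f[NSPEC], F[NSPEC], fp[NSPEC], yp[NSPEC];
  double J[NSPEC][NSPEC];
  for (int i = 0; i < NSPEC; ++i) y[i] = x[i];
  for (int it = 0; it < 12; ++it) {
    rhs_core(y, glucose, p, c, f);
    double fnorm = 0.0;
    for (int i = 0; i < NSPEC; ++i) {
      F[i] = y[i] - x[i] - h * f[i];
      double s = std::fabs(F[i]) / (1.0 + std::fabs(y[i]));
      if (s > fnorm) fnorm = s;
    }
    if (fnorm < 1e-10) return true;
    // numeric Jacobian of F: I - h df/dy (forward differences)
    for (int j = 0; j < NSPEC; ++j) {
      double eps = 1e-7 * (1.0 + std::fabs(y[j]));
      for (int i = 0; i < NSPEC; ++i) yp[i] = y[i];
      yp[j] += eps;
      rhs_core(yp, glucose, p, c, fp);
      for (int i = 0; i < NSPEC; ++i)
        J[i][j] = (i == j ? 1.0 : 0.0) - h * (fp[i] - f[i]) / eps;
    }
    double dy[NSPEC];
    for (int i = 0; i < NSPEC; ++i) dy[i] = -F[i];
    if (!solve9(J, dy)) return false;
    for (int i = 0; i < NSPEC; ++i) {
      y[i] += dy[i];
      if (!std::isfinite(y[i])) return false;
    }
  }
  return false;
}

// advance one cell state over dt using adaptive backward Euler
static int advance_one(double* x, double glucose, double dt,
                       const double* p, const double* c,
                       double h0, double hmax) {
  double t = 0.0, h = h0;
  int clamped = 0, fails = 0;
  double y[NSPEC];
  while (t < dt) {
    if (h > dt - t) h = dt - t;
    if (be_step(x, h, glucose, p, c, y)) {
      for (int i = 0; i < NSPEC; ++i) x[i] = y[i];
      clamped += clamp_state(x, c);
      t += h;
      fails = 0;
      h = std::min(h * 2.0, hmax);
    } else {
      h *= 0.25;
      if (++fails > 60 || h < 1e-14)
        stop("implicit step failed to converge at t=%f (h=%g)", t, h);
    }
  }
  return clamped;
}

// [[Rcpp::export]]
List gs_advance_cpp(NumericMatrix states, NumericVector glucose,
                    NumericVector params, NumericVector consts,
                    double dt, double h0, double hmax) {
  const int n = states.nrow();
  if (states.ncol() != NSPEC) stop("states must have 9 columns");
  if (glucose.size() != n) stop("glucose must have one value per cell");
  NumericMatrix out = clone(states);
  const double* p = params.begin();
  const double* c = consts.begin();
  int clamped = 0;
  double x[NSPEC];
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < NSPEC; ++i) x[i] = out(k, i);
    double g = glucose[k];
    if (g < 0.0 || !std::isfinite(g)) stop("non-finite or negative glucose");
    clamped += advance_one(x, g, dt, p, c, h0, hmax);
    for (int i = 0; i < NSPEC; ++i) out(k, i) = x[i];
  }
  return List::create(_["states"] = out, _["clamped"] = clamped);
}

// [[Rcpp::export]]
NumericMatrix gs_diffuse_cpp(NumericMatrix field, LogicalMatrix occ,
                             double D, double alpha, double dx, double dt,
                             int nsteps) {
  const int nr = field.nrow(), nc = field.ncol();
  if (occ.nrow() != nr || occ.ncol() != nc)
    stop("occupancy shape must match the field");
  NumericMatrix a = clone(field), b(nr, nc);
  const double coef = D * dt / (dx * dx);
  // harmonic-mean interface diffusivity: flux between two sites is damped
  // by occupancy on either side, and every flux is antisymmetric, so the
  // scheme conserves mass exactly for any occupancy pattern
  std::vector<double> fac(static_cast<size_t>(nr) * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      fac[static_cast<size_t>(j) * nr + i] = occ(i, j) ? alpha : 1.0;
  auto iface = [&](int i1, int j1, int i2, int j2) {
    const double f1 = fac[static_cast<size_t>(j1) * nr + i1];
    const double f2 = fac[static_cast<size_t>(j2) * nr + i2];
    return 2.0 * f1 * f2 / (f1 + f2);
  };
  for (int s = 0; s < nsteps; ++s) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const double cij = a(i, j);
        // reflecting (zero-flux) boundary: missing neighbours carry no flux
        double flux = 0.0;
        if (i > 0)      flux += iface(i, j, i - 1, j) * (a(i - 1, j) - cij);
        if (i < nr - 1) flux += iface(i, j, i + 1, j) * (a(i + 1, j) - cij);
        if (j > 0)      flux += iface(i, j, i, j - 1) * (a(i, j - 1) - cij);
        if (j < nc - 1) flux += iface(i, j, i, j + 1) * (a(i, j + 1) - cij);
        b(i, j) = cij + coef * flux;
      }
    }
    std::swap(a, b);
  }
  return a;
}
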