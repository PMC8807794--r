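#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deterministic forward model for a DCM of fMRI: bilinear/nonlinear neuronal
// state equation
//   xdot = (A + sum_j u_j B^(j) + sum_d x_d D^(d)) x + C u
// coupled to the balloon-windkessel haemodynamic model per region
//   sdot = x - kappa s - gamma (f - 1)
//   fdot = s
//   tau vdot = f - v^(1/alpha)
//   tau qdot = f E(f, rho)/rho - v^(1/alpha) q / v,  E(f,rho) = 1-(1-rho)^(1/f)
// and the BOLD output equation (percent signal change)
//   y = 100 V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)).
//
// The haemodynamic states f, v, q are integrated on the log scale so they
// remain positive for every parameter draw (the standard robust
// parameterization). Log-states are read through a clamp at +/- LNCLAMP
// (e^10 ~ 2.2e4-fold change, far outside the physiological range), which
// keeps the derivative evaluation finite for arbitrarily extreme
// connectivity draws: such draws produce finite, astronomically poor
// likelihoods rather than NaN, so prior-tempered chains can still explore.
// The only divergence mode left is neuronal blow-up.
//
// Inputs are piecewise constant over bins of width dt; integration uses a
// fixed-step scheme (Euler or classical RK4) with `substeps` steps per input
// bin. The BOLD signal is sampled at the end of each repetition time.

static const double LNCLAMP = 10.0;
static inline double clamp_ln(double x) {
  if (x > LNCLAMP) return LNCLAMP;
  if (x < -LNCLAMP) return -LNCLAMP;
  return x;
}

struct DcmSystem {
  int R, nu;
  const double *A, *B, *C, *D; // B: R x R x nu, D: R x R x R (col-major)
  bool has_B, has_D;
  double kappa, gamma, tau, inv_alpha, rho_eff, log1mrho;

  // state layout: x[R], s[R], lnf[R], lnv[R], lnq[R]
  void deriv(const double *st, const double *u, double *out) const {
    const double *x = st, *s = st + R, *lnf = st + 2 * R, *lnv = st + 3 * R,
                 *lnq = st + 4 * R;
    double *dx = out, *ds = out + R, *dlnf = out + 2 * R, *dlnv = out + 3 * R,
           *dlnq = out + 4 * R;
    for (int i = 0; i < R; ++i) {
      double acc = 0.0;
      for (int k = 0; k < R; ++k) acc += A[i + R * k] * x[k];
      if (has_B)
        for (int j = 0; j < nu; ++j) {
          if (u[j] == 0.0) continue;
          const double *Bj = B + (size_t)R * R * j;
          double bx = 0.0;
          for (int k = 0; k < R; ++k) bx += Bj[i + R * k] * x[k];
          acc += u[j] * bx;
        }
      if (has_D)
        for (int d = 0; d < R; ++d) {
          if (x[d] == 0.0) continue;
          const double *Dd = D + (size_t)R * R * d;
          double dxk = 0.0;
          for (int k = 0; k < R; ++k) dxk += Dd[i + R * k] * x[k];
          acc += x[d] * dxk;
        }
      for (int j = 0; j < nu; ++j) acc += C[i + R * j] * u[j];
      dx[i] = acc;
    }
    for (int i = 0; i < R; ++i) {
      double clf = clamp_ln(lnf[i]), clv = clamp_ln(lnv[i]),
             clq = clamp_ln(lnq[i]);
      double f = std::exp(clf);
      double v = std::exp(clv);
      double q = std::exp(clq);
      double va = std::exp(inv_alpha * clv); // v^(1/alpha)
      ds[i] = x[i] - kappa * s[i] - gamma * (f - 1.0);
      dlnf[i] = s[i] / f;
      dlnv[i] = (f - va) / (tau * v);
      double E = 1.0 - std::exp(log1mrho / f);
      // rho_eff = 1 - exp(log(1 - rho)) so the resting point (x = s = 0,
      // f = v = q = 1) is an exact fixed point in floating point
      dlnq[i] = (f * E / (rho_eff * q) - va / v) / tau;
    }
  }
};

// [[Rcpp::export(name = ".dcm_integrate_cpp")]]
List dcm_integrate_cpp(NumericMatrix A, NumericVector B, NumericMatrix C,
                       NumericVector D, NumericMatrix inputs, double dt,
                       int substeps, int n_scans, double TR,
                       NumericVector hemo, bool rk4, double bound,
                       bool return_states) {
  const int R = A.nrow();
  const int nu = C.ncol();
  DcmSystem sys;
  sys.R = R; sys.nu = nu;
  sys.A = A.begin(); sys.B = B.begin(); sys.C = C.begin(); sys.D = D.begin();
  sys.has_B = false;
  for (R_xlen_t i = 0; i < B.size(); ++i) if (B[i] != 0.0) { sys.has_B = true; break; }
  sys.has_D = false;
  for (R_xlen_t i = 0; i < D.size(); ++i) if (D[i] != 0.0) { sys.has_D = true; break; }
  sys.kappa = hemo[0]; sys.gamma = hemo[1]; sys.tau = hemo[2];
  sys.inv_alpha = 1.0 / hemo[3];
  sys.log1mrho = std::log(1.0 - hemo[4]);
  sys.rho_eff = 1.0 - std::exp(sys.log1mrho);
  const double V0 = hemo[5], k1 = hemo[6], k2 = hemo[7], k3 = hemo[8];

  const int nstate = 5 * R;
  std::vector<double> st(nstate, 0.0), k1v(nstate), k2v(nstate), k3v(nstate),
      k4v(nstate), tmp(nstate);
  // x = s = 0, ln f = ln v = ln q = 0 (baseline)

  const double steps_per_scan_d = TR / dt;
  const int steps_per_scan = (int)std::lround(steps_per_scan_d);
  if (std::fabs(steps_per_scan_d - steps_per_scan) > 1e-8 || steps_per_scan < 1)
    stop("TR must be an integer multiple of the input sampling interval");
  const int n_bins = n_scans * steps_per_scan;
  if (inputs.nrow() < n_bins)
    stop("inputs do not cover the acquisition window");

  const double h = dt / substeps;
  NumericMatrix signal(n_scans, R);
  NumericMatrix states;
  if (return_states) states = NumericMatrix(n_bins + 1, R);

  bool ok = true;
  std::vector<double> u(nu);
  int scan = 0;
  for (int b = 0; b < n_bins && ok; ++b) {
    for (int j = 0; j < nu; ++j) u[j] = inputs(b, j);
    for (int ss = 0; ss < substeps && ok; ++ss) {
      if (rk4) {
        sys.deriv(st.data(), u.data(), k1v.data());
        for (int i = 0; i < nstate; ++i) tmp[i] = st[i] + 0.5 * h * k1v[i];
        sys.deriv(tmp.data(), u.data(), k2v.data());
        for (int i = 0; i < nstate; ++i) tmp[i] = st[i] + 0.5 * h * k2v[i];
        sys.deriv(tmp.data(), u.data(), k3v.data());
        for (int i = 0; i < nstate; ++i) tmp[i] = st[i] + h * k3v[i];
        sys.deriv(tmp.data(), u.data(), k4v.data());
        for (int i = 0; i < nstate; ++i)
          st[i] += h / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
      } else {
        sys.deriv(st.data(), u.data(), k1v.data());
        for (int i = 0; i < nstate; ++i) st[i] += h * k1v[i];
      }
      for (int i = 0; i < nstate; ++i)
        if (!std::isfinite(st[i])) { ok = false; break; }
      if (ok)
        for (int i = 0; i < R; ++i)
          if (std::fabs(st[i]) > bound) { ok = false; break; }
    }
    if (!ok) break;
    if (return_states)
      for (int i = 0; i < R; ++i) states(b + 1, i) = st[i];
    if ((b + 1) % steps_per_scan == 0) {
      for (int i = 0; i < R; ++i) {
        double v = std::exp(clamp_ln(st[3 * R + i])),
               q = std::exp(clamp_ln(st[4 * R + i]));
        double y =
            100.0 * V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
        // Saturate at +/-100 percent signal change: physically meaningless
        // beyond that, and bounding the output keeps the likelihood of
        // degenerate haemodynamic excursions finite and well-scaled. Never
        // active on trajectories of physiological magnitude.
        if (y > 100.0) y = 100.0;
        else if (y < -100.0) y = -100.0;
        signal(scan, i) = y;
      }
      ++scan;
    }
  }

  if (return_states)
    return List::create(_["signal"] = signal, _["ok"] = ok,
                        _["states"] = states);
  return List::create(_["signal"] = signal, _["ok"] = ok);
}
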