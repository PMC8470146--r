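#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled neural + balloon/windkessel integrator.
//
// States per region: z (neural), s (vasoactive signal), and the LOGS of
// inflow f, venous volume v and deoxyhaemoglobin q. Integrating the
// haemodynamic states in log space keeps f, v, q strictly positive along
// any trajectory, so the observation equation never sees a non-positive
// volume. The resting fixed point is z = s = 0, ln f = ln v = ln q = 0.
//
// At      : R x R, transpose of the full connectivity matrix (so the rate
//           of change of region j is sum_i At[j,i] * z[i]).
// drive   : T x R, precomputed driving input U %*% t(C), one row per
//           microtime bin.
// The integration step is dt per bin; inputs are held constant within a bin.

struct DcmSys {
  int R;
  const double *At;      // column-major R x R
  double kappa, gam, alpha, E0;
  const double *tau;     // length R
};

static inline void dcm_deriv(const DcmSys &sys, const double *x,
                             const double *u, double *dx) {
  const int R = sys.R;
  const double *z  = x;
  const double *s  = x + R;
  const double *lf = x + 2 * R;
  const double *lv = x + 3 * R;
  const double *lq = x + 4 * R;
  double *dz  = dx;
  double *ds  = dx + R;
  double *dlf = dx + 2 * R;
  double *dlv = dx + 3 * R;
  double *dlq = dx + 4 * R;
  const double ia = 1.0 / sys.alpha;
  for (int j = 0; j < R; ++j) {
    double a = 0.0;
    for (int i = 0; i < R; ++i) a += sys.At[j + i * R] * z[i];
    dz[j] = a + u[j];
    const double f = std::exp(lf[j]);
    const double v = std::exp(lv[j]);
    const double q = std::exp(lq[j]);
    ds[j]  = z[j] - sys.kappa * s[j] - sys.gam * (f - 1.0);
    dlf[j] = s[j] / f;
    const double fv = std::pow(v, ia);              // outflow v^(1/alpha)
    const double ef = 1.0 - std::pow(1.0 - sys.E0, 1.0 / f);  // O2 extraction
    dlv[j] = (f - fv) / (sys.tau[j] * v);
    dlq[j] = (f * ef / sys.E0 - fv * q / v) / (sys.tau[j] * q);
  }
}

// [[Rcpp::export]]
List dcm_integrate_cpp(NumericMatrix At, NumericMatrix drive,
                       double kappa, NumericVector tau,
                       double gam, double alpha, double E0,
                       double dt,
                       double k1, double k2, double k3, double V0,
                       IntegerVector sample_bins,
                       int method, double state_bound) {
  const int R = At.nrow();
  const int T = drive.nrow();
  const int S = sample_bins.size();
  const int n = 5 * R;
  NumericMatrix y(S, R);
  std::fill(y.begin(), y.end(), NA_REAL);

  DcmSys sys;
  sys.R = R;
  sys.At = At.begin();
  sys.kappa = kappa;
  sys.gam = gam;
  sys.alpha = alpha;
  sys.E0 = E0;
  sys.tau = tau.begin();

  std::vector<double> x(n, 0.0), dx(n), xt(n), u(R);
  std::vector<double> kk1(n), kk2(n), kk3(n), kk4(n);
  // map: which sample index (if any) is recorded at each bin
  std::vector<int> rec(T, -1);
  for (int s = 0; s < S; ++s) {
    int b = sample_bins[s] - 1;
    if (b >= 0 && b < T) rec[b] = s;
  }
  const double lbound = std::log(state_bound);

  bool ok = true;
  int bad_bin = -1;
  for (int t = 0; t < T && ok; ++t) {
    for (int j = 0; j < R; ++j) u[j] = drive(t, j);
    if (method == 1) {                       // RK4
      dcm_deriv(sys, x.data(), u.data(), kk1.data());
      for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * kk1[i];
      dcm_deriv(sys, xt.data(), u.data(), kk2.data());
      for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * kk2[i];
      dcm_deriv(sys, xt.data(), u.data(), kk3.data());
      for (int i = 0; i < n; ++i) xt[i] = x[i] + dt * kk3[i];
      dcm_deriv(sys, xt.data(), u.data(), kk4.data());
      for (int i = 0; i < n; ++i)
        x[i] += dt / 6.0 * (kk1[i] + 2.0 * kk2[i] + 2.0 * kk3[i] + kk4[i]);
    } else {                                 // forward Euler
      dcm_deriv(sys, x.data(), u.data(), dx.data());
      for (int i = 0; i < n; ++i) x[i] += dt * dx[i];
    }
    for (int i = 0; i < n; ++i) {
      const double b = (i < 2 * R) ? state_bound : lbound;
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > b) {
        ok = false;
        bad_bin = t + 1;
        break;
      }
    }
    if (ok && rec[t] >= 0) {
      const int s = rec[t];
      for (int j = 0; j < R; ++j) {
        const double v = std::exp(x[3 * R + j]);
        const double q = std::exp(x[4 * R + j]);
        y(s, j) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
      }
    }
  }
  return List::create(_["y"] = y, _["ok"] = ok, _["bad_bin"] = bad_bin);
}
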