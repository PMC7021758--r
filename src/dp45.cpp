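// Adaptive Dormand-Prince 5(4) integrator specialized to the coupled
// strategy-environment vector field
//   dx/dt = x (1-x) g(x, n)
//   dn/dt = environment drift
// with g bilinear in (x, n).  The state is confined to the unit square;
// accepted steps are clipped back to [0,1] when the overshoot is below a
// hard violation threshold, and integration aborts otherwise.
//
// Environment codes:
//   0 renewing  : eps * (r - q*(eL*n + eH*(1-n))) * (x - n)
//   1 decaying  : eps * alpha * (x - n)
//   2 tipping, uniform threshold CDF : eps * n*(1-n) * (x - a*n + a/2 - mu)
//   3 tipping, Heaviside (Weitz limit): eps_tilde * n*(1-n) * (theta*x - (1-x))
//     (for code 3 the `eps` slot carries eps_tilde)

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct SysPar {
  double dL1, dH1, dl0, dh0;   // incentive parameters
  int env;
  double eps;
  double r, k, q, eL, eH;      // renewing
  double alpha;                // decaying
  double mu, a, theta;         // tipping
};

static inline double gain_of(const SysPar &s, double x, double n) {
  return (1.0 - n) * (x * s.dl0 + (1.0 - x) * s.dh0)
       - n * (x * s.dL1 + (1.0 - x) * s.dH1);
}

static inline void field_of(const SysPar &s, double x, double n,
                            double &dx, double &dn) {
  dx = x * (1.0 - x) * gain_of(s, x, n);
  switch (s.env) {
  case 0:
    dn = s.eps * (s.r - s.q * (s.eL * n + s.eH * (1.0 - n))) * (x - n);
    break;
  case 1:
    dn = s.eps * s.alpha * (x - n);
    break;
  case 2:
    dn = s.eps * n * (1.0 - n) * (x - s.a * n + s.a / 2.0 - s.mu);
    break;
  default:
    dn = s.eps * n * (1.0 - n) * (s.theta * x - (1.0 - x));
    break;
  }
}

// Dormand-Prince tableau
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order embedded weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

// status: 0 reached t_end, 1 converged (field norm below conv_tol for a
// sustained window), 2 containment violation, 3 max steps exceeded,
// 4 step-size underflow
// [[Rcpp::export(name = ".dp45_integrate")]]
List dp45_integrate(NumericVector par, double x0, double n0, double t_end,
                    double rtol, double atol,
                    Nullable<NumericVector> t_eval_ = R_NilValue,
                    double conv_tol = 1e-10, double conv_window = 5.0,
                    double clip_tol = 1e-8, double max_steps = 2e7) {
  SysPar s;
  s.dL1 = par[0]; s.dH1 = par[1]; s.dl0 = par[2]; s.dh0 = par[3];
  s.env = (int) par[4]; s.eps = par[5];
  s.r = par[6]; s.k = par[7]; s.q = par[8]; s.eL = par[9]; s.eH = par[10];
  s.alpha = par[11]; s.mu = par[12]; s.a = par[13]; s.theta = par[14];

  std::vector<double> Ts, Xs, Ns;
  bool have_eval = t_eval_.isNotNull();
  NumericVector t_eval;
  R_xlen_t n_eval = 0, i_eval = 0;
  std::vector<double> Ex, En;
  if (have_eval) {
    t_eval = t_eval_.get();
    n_eval = t_eval.size();
    Ex.assign(n_eval, NA_REAL);
    En.assign(n_eval, NA_REAL);
  }

  double t = 0.0, x = x0, n = n0;
  double k1x, k1n;
  field_of(s, x, n, k1x, k1n);
  Ts.push_back(t); Xs.push_back(x); Ns.push_back(n);
  if (have_eval) {
    while (i_eval < n_eval && t_eval[i_eval] <= 0.0) {
      Ex[i_eval] = x; En[i_eval] = n; ++i_eval;
    }
  }

  double h = std::min(1e-3, t_end / 10.0);
  int status = 0;
  double quiet_since = -1.0;  // start of the current low-field-norm stretch
  double steps = 0.0;

  while (t < t_end) {
    if (steps > max_steps) { status = 3; break; }
    if (h < 1e-14 * std::max(1.0, std::fabs(t))) { status = 4; break; }
    if (t + h > t_end) h = t_end - t;

    double k2x, k2n, k3x, k3n, k4x, k4n, k5x, k5n, k6x, k6n, k7x, k7n;
    double xs, ns;
    xs = x + h * a21 * k1x;                 ns = n + h * a21 * k1n;
    field_of(s, xs, ns, k2x, k2n);
    xs = x + h * (a31 * k1x + a32 * k2x);   ns = n + h * (a31 * k1n + a32 * k2n);
    field_of(s, xs, ns, k3x, k3n);
    xs = x + h * (a41 * k1x + a42 * k2x + a43 * k3x);
    ns = n + h * (a41 * k1n + a42 * k2n + a43 * k3n);
    field_of(s, xs, ns, k4x, k4n);
    xs = x + h * (a51 * k1x + a52 * k2x + a53 * k3x + a54 * k4x);
    ns = n + h * (a51 * k1n + a52 * k2n + a53 * k3n + a54 * k4n);
    field_of(s, xs, ns, k5x, k5n);
    xs = x + h * (a61 * k1x + a62 * k2x + a63 * k3x + a64 * k4x + a65 * k5x);
    ns = n + h * (a61 * k1n + a62 * k2n + a63 * k3n + a64 * k4n + a65 * k5n);
    field_of(s, xs, ns, k6x, k6n);
    double x5 = x + h * (b1 * k1x + b3 * k3x + b4 * k4x + b5 * k5x + b6 * k6x);
    double n5 = n + h * (b1 * k1n + b3 * k3n + b4 * k4n + b5 * k5n + b6 * k6n);
    field_of(s, x5, n5, k7x, k7n);
    double x4 = x + h * (e1 * k1x + e3 * k3x + e4 * k4x + e5 * k5x
                         + e6 * k6x + e7 * k7x);
    double n4 = n + h * (e1 * k1n + e3 * k3n + e4 * k4n + e5 * k5n
                         + e6 * k6n + e7 * k7n);

    double scx = atol + rtol * std::max(std::fabs(x), std::fabs(x5));
    double scn = atol + rtol * std::max(std::fabs(n), std::fabs(n5));
    double ex = (x5 - x4) / scx, en = (n5 - n4) / scn;
    double err = std::sqrt(0.5 * (ex * ex + en * en));
    steps += 1.0;

    if (err <= 1.0 || h <= 1e-13) {
      // dense output: cubic Hermite on [t, t+h] using endpoint derivatives
      if (have_eval) {
        while (i_eval < n_eval && t_eval[i_eval] <= t + h) {
          double th = (t_eval[i_eval] - t) / h;
          double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
          double h10 = th * (1 - th) * (1 - th);
          double h01 = th * th * (3 - 2 * th);
          double h11 = th * th * (th - 1);
          Ex[i_eval] = h00 * x + h10 * h * k1x + h01 * x5 + h11 * h * k7x;
          En[i_eval] = h00 * n + h10 * h * k1n + h01 * n5 + h11 * h * k7n;
          ++i_eval;
        }
      }
      t += h; x = x5; n = n5; k1x = k7x; k1n = k7n;
      // containment
      double viol = std::max(std::max(-x, x - 1.0), std::max(-n, n - 1.0));
      if (viol > clip_tol) { status = 2; Ts.push_back(t); Xs.push_back(x);
        Ns.push_back(n); break; }
      if (x < 0) x = 0; else if (x > 1) x = 1;
      if (n < 0) n = 0; else if (n > 1) n = 1;
      Ts.push_back(t); Xs.push_back(x); Ns.push_back(n);
      // convergence window on the vector-field norm
      field_of(s, x, n, k1x, k1n);
      double fn = std::sqrt(k1x * k1x + k1n * k1n);
      if (fn < conv_tol) {
        if (quiet_since < 0) quiet_since = t;
        else if (t - quiet_since >= conv_window) { status = 1; break; }
      } else quiet_since = -1.0;
    }
    double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2; else if (fac > 5.0) fac = 5.0;
    h *= fac;
  }

  List out = List::create(
    _["t"] = wrap(Ts), _["x"] = wrap(Xs), _["n"] = wrap(Ns),
    _["status"] = status, _["nsteps"] = steps);
  if (have_eval) {
    out["t_eval"] = t_eval;
    out["x_eval"] = wrap(Ex);
    out["n_eval"] = wrap(En);
    out["n_eval_filled"] = (double) i_eval;
  }
  return out;
}
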