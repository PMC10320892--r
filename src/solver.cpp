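#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

// The severity ODE  dDep/dt = r * (1 - I(t)) - r * Dep  with
// I(t) = TRT(t) / (TRT(t) + s50), where TRT is the combined latent treatment
// mass: unit boluses per session, first-order decay per service compartment.
// Between events TRT(t) = sum_s M_s(t0) * exp(-k_s * (t - t0)), so the
// integration carries the three per-service masses at the segment origin and
// restarts at every bolus (derivative discontinuity).
struct Model {
  std::vector<double> et;   // event times, sorted
  std::vector<int> esvc;    // 0 = coaching, 1 = therapy, 2 = psychiatry
  double k[3];              // per-service elimination rate constants
  double s50, r;
  int hook;                 // 0 none, 1 constant inhibition, 2 constant mass
  double hookval;

  double rhs(double t0, const double* M0, double t, double D) const {
    double I;
    if (hook == 1) {
      I = hookval;
    } else {
      double m;
      if (hook == 2) {
        m = hookval;
      } else {
        double dt = t - t0;
        m = M0[0] * std::exp(-k[0] * dt) + M0[1] * std::exp(-k[1] * dt) +
            M0[2] * std::exp(-k[2] * dt);
      }
      I = m / (m + s50);
    }
    return r * (1.0 - I) - r * D;
  }
};

// Adaptive Cash-Karp RK45 over one smooth segment [a, b] (no events inside;
// M0 holds the per-service masses at a). The step size h is carried across
// segments by reference as a warm start.
static double integrate_segment(const Model& M, const double* M0, double a,
                                double b, double D, double rtol, double atol,
                                double& h) {
  static const double a2 = 0.2, a3 = 0.3, a4 = 0.6, a5 = 1.0, a6 = 0.875;
  static const double b21 = 0.2,
    b31 = 3.0 / 40.0,       b32 = 9.0 / 40.0,
    b41 = 0.3,              b42 = -0.9,            b43 = 1.2,
    b51 = -11.0 / 54.0,     b52 = 2.5,             b53 = -70.0 / 27.0,
    b54 = 35.0 / 27.0,
    b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,   b63 = 575.0 / 13824.0,
    b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
    c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
    dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0, dc6 = c6 - 0.25;

  if (b <= a) return D;
  double t = a;
  long iter = 0;
  while (t < b) {
    if (++iter > 2000000L)
      stop("ODE solver failed to converge: step limit exceeded");
    double hs = h;
    if (t + hs > b) hs = b - t;
    double k1 = M.rhs(a, M0, t, D);
    double k2 = M.rhs(a, M0, t + a2 * hs, D + hs * b21 * k1);
    double k3 = M.rhs(a, M0, t + a3 * hs, D + hs * (b31 * k1 + b32 * k2));
    double k4 = M.rhs(a, M0, t + a4 * hs,
                      D + hs * (b41 * k1 + b42 * k2 + b43 * k3));
    double k5 = M.rhs(a, M0, t + a5 * hs,
                      D + hs * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4));
    double k6 = M.rhs(a, M0, t + a6 * hs,
                      D + hs * (b61 * k1 + b62 * k2 + b63 * k3 + b64 * k4 +
                                b65 * k5));
    double D5 = D + hs * (c1 * k1 + c3 * k3 + c4 * k4 + c6 * k6);
    double err = std::fabs(hs * (dc1 * k1 + dc3 * k3 + dc4 * k4 + dc5 * k5 +
                                 dc6 * k6));
    if (!std::isfinite(D5))
      stop("ODE solver produced a non-finite state");
    double tol = atol + rtol * std::max(std::fabs(D), std::fabs(D5));
    if (err <= tol) {
      t += hs;
      D = D5;
      double fac = (err > 0.0) ? 0.9 * std::pow(tol / err, 0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      if (fac < 1.0) fac = 1.0;
      h = hs * fac;
    } else {
      double fac = 0.9 * std::pow(tol / err, 0.25);
      if (fac < 0.1) fac = 0.1;
      h = hs * fac;
      if (h < 1e-13 * (b - a + 1.0))
        stop("ODE solver step size underflow");
    }
  }
  return D;
}

// March across a sorted grid, restarting at every event time.
static void solve_grid(const Model& M, const std::vector<double>& grid,
                       double dep0, double rtol, double atol, double* out) {
  double t = 0.0, D = dep0, h = 1.0;
  double mass[3] = {0.0, 0.0, 0.0};
  size_t ei = 0;
  // events at time 0 contribute from the start
  while (ei < M.et.size() && M.et[ei] <= 0.0) mass[M.esvc[ei++]] += 1.0;
  for (size_t gi = 0; gi < grid.size(); ++gi) {
    double g = grid[gi];
    while (ei < M.et.size() && M.et[ei] < g) {
      double te = M.et[ei];
      if (te > t) {
        D = integrate_segment(M, mass, t, te, D, rtol, atol, h);
        for (int s = 0; s < 3; ++s) mass[s] *= std::exp(-M.k[s] * (te - t));
        t = te;
      }
      mass[M.esvc[ei]] += 1.0;
      ++ei;
    }
    if (g > t) {
      D = integrate_segment(M, mass, t, g, D, rtol, atol, h);
      for (int s = 0; s < 3; ++s) mass[s] *= std::exp(-M.k[s] * (g - t));
      t = g;
    }
    out[gi] = D;
  }
}

// [[Rcpp::export]]
NumericVector dep_solve_cpp(NumericVector grid, NumericVector event_time,
                            IntegerVector event_svc, NumericVector kout,
                            double s50, double r, double dep0, int hook,
                            double hookval, double rtol, double atol) {
  Model M;
  M.et.assign(event_time.begin(), event_time.end());
  M.esvc.assign(event_svc.begin(), event_svc.end());
  for (int s = 0; s < 3; ++s) M.k[s] = kout[s];
  M.s50 = s50;
  M.r = r;
  M.hook = hook;
  M.hookval = hookval;
  std::vector<double> g(grid.begin(), grid.end());
  NumericVector out(g.size());
  if (g.size() == 0) return out;
  solve_grid(M, g, dep0, rtol, atol, REAL(out));
  return out;
}

// Gaussian log-likelihood of one patient's post-baseline observations given
// individual log-parameters phi = log(k_c, k_t, k_p, s50, r).
static double patient_ll(const double* phi, const NumericVector& obs_t,
                         const NumericVector& obs_y, const NumericVector& ev_t,
                         const IntegerVector& ev_svc, double sigma,
                         double dep0, double rtol, double atol, double& ss) {
  Model M;
  M.et.assign(ev_t.begin(), ev_t.end());
  M.esvc.assign(ev_svc.begin(), ev_svc.end());
  for (int s = 0; s < 3; ++s) M.k[s] = std::exp(phi[s]);
  M.s50 = std::exp(phi[3]);
  M.r = std::exp(phi[4]);
  M.hook = 0;
  M.hookval = 0.0;
  int m = obs_t.size();
  ss = 0.0;
  if (m > 0) {
    std::vector<double> grid(obs_t.begin(), obs_t.end());
    std::vector<double> pred((size_t)m);
    solve_grid(M, grid, dep0, rtol, atol, pred.data());
    for (int i = 0; i < m; ++i) {
      double res = obs_y[i] - pred[i];
      ss += res * res;
    }
  }
  return -0.5 * ss / (sigma * sigma) - m * std::log(sigma) - 0.5 * m * LOG2PI;
}

static double log_prior(const double* phi, const NumericVector& logmu,
                        const NumericVector& omega) {
  double lp = 0.0;
  for (int p = 0; p < logmu.size(); ++p) {
    if (omega[p] > 0.0) {
      double z = (phi[p] - logmu[p]) / omega[p];
      lp += -0.5 * z * z - std::log(omega[p]) - 0.5 * LOG2PI;
    }
  }
  return lp;
}

// One SAEM E-step update for one patient: n_mh Metropolis transitions on
// each chain of individual log-parameters, with multivariate random-walk
// proposals prop = cur + L z (L a lower-triangular Cholesky factor of the
// adaptive proposal covariance; rows of fixed parameters are zero). Uses
// R's RNG so seeding from R makes the draw stream reproducible and
// order-invariant.
// [[Rcpp::export]]
List mh_update_cpp(NumericMatrix phi, NumericVector obs_t, NumericVector obs_y,
                   NumericVector ev_t, IntegerVector ev_svc,
                   NumericVector logmu, NumericVector omega, double sigma,
                   int n_mh, NumericMatrix prop_L, double dep0,
                   double rtol, double atol, NumericVector ss_cache) {
  int C = phi.nrow(), P = phi.ncol();
  NumericMatrix phinew(clone(phi));
  NumericVector ssout(C);
  int nacc = 0, nprop = 0;
  bool any_fixed = false;
  for (int p = 0; p < P; ++p)
    if (omega[p] <= 0.0) any_fixed = true;
  std::vector<double> cur((size_t)P), prop((size_t)P), z((size_t)P);
  int m = obs_t.size();
  for (int c = 0; c < C; ++c) {
    for (int p = 0; p < P; ++p)
      cur[p] = (omega[p] > 0.0) ? phinew(c, p) : logmu[p];
    double curss;
    double lp;
    // the residual sum of squares depends on phi only, so a cached value
    // from the previous iteration skips one solve per chain; with fixed
    // (omega = 0) parameters phi tracks the moving logmu, so recompute
    if (!any_fixed && c < ss_cache.size() &&
        NumericVector::is_na(ss_cache[c]) == false) {
      curss = ss_cache[c];
      lp = -0.5 * curss / (sigma * sigma) - m * std::log(sigma) -
           0.5 * m * LOG2PI + log_prior(cur.data(), logmu, omega);
    } else {
      lp = patient_ll(cur.data(), obs_t, obs_y, ev_t, ev_svc, sigma,
                      dep0, rtol, atol, curss) +
           log_prior(cur.data(), logmu, omega);
    }
    for (int it = 0; it < n_mh; ++it) {
      prop = cur;
      for (int p = 0; p < P; ++p) z[p] = norm_rand();
      for (int p = 0; p < P; ++p) {
        if (omega[p] <= 0.0) continue;
        double step = 0.0;
        for (int q = 0; q <= p; ++q) step += prop_L(p, q) * z[q];
        prop[p] += step;
      }
      double pss;
      double plp = patient_ll(prop.data(), obs_t, obs_y, ev_t, ev_svc, sigma,
                              dep0, rtol, atol, pss) +
                   log_prior(prop.data(), logmu, omega);
      ++nprop;
      if (std::log(unif_rand()) < plp - lp) {
        cur = prop;
        lp = plp;
        curss = pss;
        ++nacc;
      }
    }
    for (int p = 0; p < P; ++p) phinew(c, p) = cur[p];
    ssout[c] = curss;
  }
  double arate = nprop > 0 ? (double)nacc / (double)nprop : NA_REAL;
  return List::create(_["phi"] = phinew, _["ss"] = ssout,
                      _["accept"] = arate);
}
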