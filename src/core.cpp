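// Fixed-step RK4 integrator for the two-population neurogenesis ODE
//   dP/dt = rho(t) * P * (1 - alpha(t) - 2 beta(t))
//   dN/dt = rho(t) * P * (alpha(t) + 2 beta(t))
// The right-hand side is piecewise-smooth: kinks occur at the strategy
// switch time tS and at cell-cycle anchor days.  Segment boundaries are
// aligned exactly with the step grid so the integrator never straddles a
// kink, which keeps the solution deterministic and 4th-order accurate.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct CycleSpec {
  int mode;                     // 0 = constant, 1 = age-dependent
  double tc_const;              // hours
  std::vector<double> day, tc;  // anchors (embryonic day, hours)
  double scale;                 // multiplier on T_C
  int extrap;                   // 0 = continue last segment, 1 = hold value
  double floor_h;               // lower bound on scaled T_C, hours
};

double tc_at(const CycleSpec &c, double t) {
  double v;
  if (c.mode == 0) {
    v = c.tc_const;
  } else {
    const std::vector<double> &d = c.day;
    const int n = (int)d.size();
    if (n == 1) {
      v = c.tc[0];
    } else if (c.extrap == 1 && t <= d[0]) {
      v = c.tc[0];
    } else if (c.extrap == 1 && t >= d[n - 1]) {
      v = c.tc[n - 1];
    } else {
      int j = 0;
      if (t >= d[n - 1]) j = n - 2;
      else { while (j < n - 2 && t > d[j + 1]) ++j; }
      v = c.tc[j] + (c.tc[j + 1] - c.tc[j]) * (t - d[j]) / (d[j + 1] - d[j]);
    }
  }
  v *= c.scale;
  if (v < c.floor_h) v = c.floor_h;
  return v;
}

// rho in day^-1: T_C is in hours, ln(2) doubles P once per cycle
inline double rho_at(const CycleSpec &c, double t) {
  return M_LN2 * 24.0 / tc_at(c, t);
}

struct ProbSpec {
  int mode;                       // 0 = two-phase strategy, 1 = constant
  double a0, aS, bF, tS, aF;      // strategy parameters
  double ca, cb;                  // constant-mode alpha, beta
  double t0, tF;
};

inline void ab_at(const ProbSpec &p, double t, double &a, double &b) {
  if (p.mode == 1) { a = p.ca; b = p.cb; return; }
  if (t <= p.tS) {
    const double u = (p.tS > p.t0) ? (t - p.t0) / (p.tS - p.t0) : 1.0;
    a = p.a0 + (p.aS - p.a0) * u;
    b = 0.0;
  } else {
    const double u = (p.tF > p.tS) ? (t - p.tS) / (p.tF - p.tS) : 1.0;
    b = p.bF * u;
    a = p.aS + (p.aF - p.aS) * u;
  }
}

inline void deriv(const ProbSpec &pr, const CycleSpec &cy, double t, double P,
                  double &dP, double &dN) {
  double a, b;
  ab_at(pr, t, a, b);
  const double r = rho_at(cy, t);
  dP = r * P * (1.0 - a - 2.0 * b);
  dN = r * P * (a + 2.0 * b);
}

// breakpoints: sorted, unique, interior to (t0, tF)
std::vector<double> make_breaks(const ProbSpec &pr, const CycleSpec &cy,
                                double t0, double tF,
                                const std::vector<double> &extra) {
  std::vector<double> b;
  if (pr.mode == 0 && pr.tS > t0 && pr.tS < tF) b.push_back(pr.tS);
  if (cy.mode == 1)
    for (double d : cy.day)
      if (d > t0 && d < tF) b.push_back(d);
  for (double d : extra)
    if (d > t0 && d < tF) b.push_back(d);
  std::sort(b.begin(), b.end());
  std::vector<double> out;
  double last = t0;
  for (double d : b) {
    if (d - last > 1e-9) { out.push_back(d); last = d; }
  }
  return out;
}

// Integrate over [t0, tF]; if times/Ps/Ns non-null, record every grid point.
// Returns (P, N) at tF.
void integrate(const ProbSpec &pr, const CycleSpec &cy, double t0, double tF,
               double step, double P0,
               const std::vector<double> &extra_breaks,
               std::vector<double> *times, std::vector<double> *Ps,
               std::vector<double> *Ns, double &P_end, double &N_end,
               const std::vector<double> *query = nullptr,
               std::vector<double> *query_N = nullptr) {
  std::vector<double> brk = make_breaks(pr, cy, t0, tF, extra_breaks);
  brk.push_back(tF);

  double t = t0, P = P0, N = 0.0;
  if (times) { times->push_back(t); Ps->push_back(P); Ns->push_back(N); }
  size_t qi = 0;
  if (query) {
    while (qi < query->size() && (*query)[qi] <= t0 + 1e-9) {
      query_N->push_back(N);
      ++qi;
    }
  }

  for (double b : brk) {
    const double len = b - t;
    if (len <= 1e-12) { t = b; continue; }
    const int nsub = std::max(1, (int)std::ceil(len / step - 1e-9));
    const double h = len / nsub;
    for (int i = 0; i < nsub; ++i) {
      const double ti = t + i * h;
      double k1P, k1N, k2P, k2N, k3P, k3N, k4P, k4N;
      deriv(pr, cy, ti, P, k1P, k1N);
      deriv(pr, cy, ti + 0.5 * h, P + 0.5 * h * k1P, k2P, k2N);
      deriv(pr, cy, ti + 0.5 * h, P + 0.5 * h * k2P, k3P, k3N);
      deriv(pr, cy, ti + h, P + h * k3P, k4P, k4N);
      P += h / 6.0 * (k1P + 2.0 * k2P + 2.0 * k3P + k4P);
      N += h / 6.0 * (k1N + 2.0 * k2N + 2.0 * k3N + k4N);
      const double tnext = (i == nsub - 1) ? b : ti + h;
      if (!std::isfinite(P) || !std::isfinite(N))
        stop("non-finite state at t = %f", tnext);
      if (times) { times->push_back(tnext); Ps->push_back(P); Ns->push_back(N); }
      if (query) {
        while (qi < query->size() && (*query)[qi] <= tnext + 1e-9) {
          query_N->push_back(N);
          ++qi;
        }
      }
    }
    t = b;
  }
  P_end = P;
  N_end = N;
}

CycleSpec cycle_from_args(int cycle_mode, double tc_const,
                          NumericVector anchor_day, NumericVector anchor_tc,
                          double scale, int extrap, double floor_h) {
  CycleSpec cy;
  cy.mode = cycle_mode;
  cy.tc_const = tc_const;
  cy.day = as<std::vector<double>>(anchor_day);
  cy.tc = as<std::vector<double>>(anchor_tc);
  cy.scale = scale;
  cy.extrap = extrap;
  cy.floor_h = floor_h;
  return cy;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix sim_trajectory_cpp(double t0, double tF, double step,
                                 int prob_mode, double a0, double aS,
                                 double bF, double tS, double aF,
                                 double const_alpha, double const_beta,
                                 int cycle_mode, double tc_const,
                                 NumericVector anchor_day,
                                 NumericVector anchor_tc, double scale,
                                 int extrap, double floor_h, double P0) {
  ProbSpec pr;
  pr.mode = prob_mode;
  pr.a0 = a0; pr.aS = aS; pr.bF = bF; pr.tS = tS; pr.aF = aF;
  pr.ca = const_alpha; pr.cb = const_beta;
  pr.t0 = t0; pr.tF = tF;
  CycleSpec cy = cycle_from_args(cycle_mode, tc_const, anchor_day, anchor_tc,
                                 scale, extrap, floor_h);
  std::vector<double> times, Ps, Ns, extra;
  double Pe, Ne;
  integrate(pr, cy, t0, tF, step, P0, extra, &times, &Ps, &Ns, Pe, Ne);
  NumericMatrix out((int)times.size(), 3);
  for (int i = 0; i < (int)times.size(); ++i) {
    out(i, 0) = times[i];
    out(i, 1) = Ps[i];
    out(i, 2) = Ns[i];
  }
  colnames(out) = CharacterVector::create("time", "P", "N");
  return out;
}

// Per-founder N at tM and tF for a batch of strategy candidates.
// cand columns: alpha0, alphaS, betaF, tS.  aF_mode: 0 -> alphaF = 0,
// 1 -> alphaF = 1 - betaF.
// [[Rcpp::export]]
NumericMatrix grid_endpoints_cpp(NumericMatrix cand, double t0, double tF,
                                 double tM, double step, int aF_mode,
                                 int cycle_mode, double tc_const,
                                 NumericVector anchor_day,
                                 NumericVector anchor_tc, double scale,
                                 int extrap, double floor_h) {
  const int n = cand.nrow();
  NumericMatrix out(n, 2);
  CycleSpec cy = cycle_from_args(cycle_mode, tc_const, anchor_day, anchor_tc,
                                 scale, extrap, floor_h);
  std::vector<double> extra(1, tM);
  std::vector<double> query(1, tM), qN;
  for (int i = 0; i < n; ++i) {
    ProbSpec pr;
    pr.mode = 0;
    pr.a0 = cand(i, 0); pr.aS = cand(i, 1); pr.bF = cand(i, 2);
    pr.tS = cand(i, 3);
    pr.aF = (aF_mode == 0) ? 0.0 : 1.0 - pr.bF;
    pr.ca = pr.cb = 0.0;
    pr.t0 = t0; pr.tF = tF;
    double Pe, Ne;
    qN.clear();
    integrate(pr, cy, t0, tF, step, 1.0, extra, nullptr, nullptr, nullptr,
              Pe, Ne, &query, &qN);
    out(i, 0) = qN.empty() ? NA_REAL : qN[0];
    out(i, 1) = Ne;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(out) = CharacterVector::create("N_tM", "N_tF");
  return out;
}
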