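// Exact survival/hazard of the two-stage clonal expansion (TSCE) process
// under piecewise-constant rates, plus the left-truncated cohort
// log-likelihood, conditional event-time sampling and a branching-process
// Monte Carlo check.
//
// Notation per interval (rates constant): initiation intensity nu = X*mu0,
// initiated-cell division rate a (alpha), death rate b (beta), malignant
// conversion rate m (mu1).  The clone extinction probability
// Gamma(u; t) = P(no malignant cell by t | one initiated cell at u)
// obeys the backward Riccati equation
//   dGamma/du = (a+b+m) Gamma - a Gamma^2 - b,  Gamma(t; t) = 1,
// which factors through the roots y+- of a y^2 - (a+b+m) y + b = 0.
// Survival: S(t) = exp(-Int_0^t nu (1 - Gamma) du).  The hazard uses
// B(u; t) = -dGamma/dt, with dB/du = [(a+b+m) - 2 a Gamma] B, B(t;t) = m,
// and h(t) = Int_0^t nu B du.
//
// To avoid catastrophic cancellation all propagation is done in terms of
// Gd = Gamma - 1 and e1p = 1 - y+, e1m = 1 - y- computed stably:
//   s    = sqrt((a-b)^2 + 2 m (a+b) + m^2)   (= sqrt((a+b+m)^2 - 4ab))
//   e1p  = (a - b - m - s) / (2a)  (<= 0),  e1m = (a - b - m + s) / (2a).
// With w = (Gamma - y+)/(Gamma - y-), w propagates as w(u) = w(r) e^{s (r-u)}
// and the per-interval survival integral reduces to
//   Int (1 - Gamma) du = e1p * d + log((1 - w_l)/(1 - w_r)) / a.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rates {
  double nu, a, m, s, e1p, e1m;
  bool degen;  // m == 0 and a == b (double root at 1)
};

// Build per-interval solver constants from raw process rates.
// Returns false when the rate set is invalid (negative rates).
inline bool make_rates(double nu, double a, double b, double m, Rates &rc) {
  if (!(a > 0.0) || !(b >= 0.0) || !(m >= 0.0) || !(nu >= 0.0)) return false;
  if (!R_finite(a) || !R_finite(b) || !R_finite(m) || !R_finite(nu))
    return false;
  const double g0 = a - b - m;              // a + b + m - 2b - 2m
  const double disc = (a - b) * (a - b) + 2.0 * m * (a + b) + m * m;
  const double s = std::sqrt(disc);
  rc.nu = nu;
  rc.a = a;
  rc.m = m;
  rc.s = s;
  rc.e1p = (g0 - s) / (2.0 * a);
  rc.e1m = (g0 + s) / (2.0 * a);
  rc.degen = (s <= 1e-13 * (a + b + m));
  return true;
}

struct SolveOut {
  double logS, h;
  bool ok;
};

// Backward propagation from age t to 0 across intervals with left edges
// L[0] = 0 < L[1] < ... < L[K-1]; interval k is [L[k], L[k+1]).
inline SolveOut solve_at(const double *L, const Rates *R, int K, double t) {
  SolveOut o;
  o.logS = 0.0;
  o.h = 0.0;
  o.ok = true;
  if (!(t > 0.0)) return o;
  int kt = K - 1;
  while (kt > 0 && L[kt] >= t) --kt;
  double Gd = 0.0;             // Gamma - 1 at current right edge
  double B = R[kt].m;          // B at current right edge
  double right = t;
  for (int k = kt; k >= 0; --k) {
    const Rates &rc = R[k];
    const double left = L[k];
    const double d = right - left;
    if (d > 0.0) {
      double Gld;
      if (rc.degen) {
        // m = 0, a = b: dGd/du = -a Gd^2, B proportional to Gd^2.
        if (Gd == 0.0) {
          Gld = 0.0;  // Gamma stays 1; survival contribution 0, B stays B
        } else {
          const double invr = 1.0 / Gd;
          Gld = 1.0 / (invr - rc.a * d);
          o.logS -= rc.nu * (-std::log1p(-rc.a * d * Gd) / rc.a);
          if (B != 0.0) {
            const double C = B / (Gd * Gd);
            o.h += rc.nu * C * (Gld - Gd) / rc.a;
            B = C * Gld * Gld;
          }
        }
      } else {
        if (rc.s * d > 500.0) {  // e^{s d} overflows; outside supported domain
          o.ok = false;
          return o;
        }
        const double np = Gd + rc.e1p;   // Gamma - y+
        const double dn = Gd + rc.e1m;   // Gamma - y-
        const double wr = np / dn;
        const double wl = wr * std::exp(rc.s * d);
        const double lg = std::log((1.0 - wl) / (1.0 - wr));
        o.logS -= rc.nu * (rc.e1p * d + lg / rc.a);
        Gld = (wl * rc.e1m - rc.e1p) / (1.0 - wl);
        if (B != 0.0) {
          const double C = B / (np * dn);
          o.h += rc.nu * C * (Gld - Gd) / rc.a;
          B = C * (Gld + rc.e1p) * (Gld + rc.e1m);
        }
      }
      Gd = Gld;
      if (!R_finite(Gd) || !R_finite(o.logS) || !R_finite(o.h)) {
        o.ok = false;
        return o;
      }
    }
    right = left;
  }
  return o;
}

// Dose-response: theta * (1 + theta_c * dose^theta_p); exact identity at 0.
inline double dresp(double th, double thc, double thp, double dose) {
  if (dose <= 0.0 || thc == 0.0) return th;
  return th * (1.0 + thc * std::pow(dose, thp));
}

// Column layout of the per-group parameter matrix (see R/likelihood.R).
enum ParCol {
  P_X = 0, P_ALPHA, P_MU0, P_MU1, P_G, P_GC, P_GP,
  P_M1C, P_M1P, P_M0C, P_M0P, P_LAG, P_NCOL
};

// Per (group, dose) rate cache for one parameter evaluation.  Rates live in
// a deque so pointers handed out stay valid as the cache grows.
struct RateCache {
  std::deque<Rates> pool;
  std::vector<std::vector<std::pair<double, int> > > memo;
  const NumericMatrix &par;
  bool ok;
  explicit RateCache(const NumericMatrix &p) : memo(p.nrow()), par(p), ok(true) {}
  const Rates *get(int g, double dose) {
    std::vector<std::pair<double, int> > &v = memo[g];
    for (size_t i = 0; i < v.size(); ++i)
      if (v[i].first == dose) return &pool[v[i].second];
    const double alpha = par(g, P_ALPHA);
    const double geff = dresp(par(g, P_G), par(g, P_GC), par(g, P_GP), dose);
    const double meff = dresp(par(g, P_MU1), par(g, P_M1C), par(g, P_M1P), dose);
    const double i0 = dresp(par(g, P_MU0), par(g, P_M0C), par(g, P_M0P), dose);
    const double beta = alpha - geff - meff;
    Rates rc;
    if (beta < 0.0 || !make_rates(par(g, P_X) * i0, alpha, beta, meff, rc)) {
      ok = false;
      return NULL;
    }
    pool.push_back(rc);
    v.push_back(std::make_pair(dose, (int)pool.size() - 1));
    return &pool.back();
  }
};

// Variant operating on per-interval rate pointers (no copying).
inline SolveOut solve_at_p(const double *L, const Rates *const *R, int K,
                           double t) {
  SolveOut o;
  o.logS = 0.0;
  o.h = 0.0;
  o.ok = true;
  if (!(t > 0.0)) return o;
  int kt = K - 1;
  while (kt > 0 && L[kt] >= t) --kt;
  double Gd = 0.0;
  double B = R[kt]->m;
  double right = t;
  for (int k = kt; k >= 0; --k) {
    const Rates &rc = *R[k];
    const double left = L[k];
    const double d = right - left;
    if (d > 0.0) {
      double Gld;
      if (rc.degen) {
        if (Gd == 0.0) {
          Gld = 0.0;
        } else {
          Gld = 1.0 / (1.0 / Gd - rc.a * d);
          o.logS -= rc.nu * (-std::log1p(-rc.a * d * Gd) / rc.a);
          if (B != 0.0) {
            const double C = B / (Gd * Gd);
            o.h += rc.nu * C * (Gld - Gd) / rc.a;
            B = C * Gld * Gld;
          }
        }
      } else {
        if (rc.s * d > 500.0) {
          o.ok = false;
          return o;
        }
        const double np = Gd + rc.e1p;
        const double dn = Gd + rc.e1m;
        const double wr = np / dn;
        const double wl = wr * std::exp(rc.s * d);
        const double lg = std::log((1.0 - wl) / (1.0 - wr));
        o.logS -= rc.nu * (rc.e1p * d + lg / rc.a);
        Gld = (wl * rc.e1m - rc.e1p) / (1.0 - wl);
        if (B != 0.0) {
          const double C = B / (np * dn);
          o.h += rc.nu * C * (Gld - Gd) / rc.a;
          B = C * (Gld + rc.e1p) * (Gld + rc.e1m);
        }
      }
      Gd = Gld;
      if (!R_finite(Gd) || !R_finite(o.logS) || !R_finite(o.h)) {
        o.ok = false;
        return o;
      }
    }
    right = left;
  }
  return o;
}

enum { MAX_IVALS = 64 };

// Resolve the per-interval rate pointers for one individual.
inline bool lookup_ind(const int *off, const double *ds, int i, int g,
                       RateCache &cache, const Rates **Rp, int &K) {
  const int k0 = off[i], k1 = off[i + 1];
  K = k1 - k0;
  if (K > MAX_IVALS) stop("too many dose intervals for one individual");
  for (int k = 0; k < K; ++k) {
    const Rates *rc = cache.get(g, ds[k0 + k]);
    if (rc == NULL) return false;
    Rp[k] = rc;
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".solve_schedule_cpp")]]
NumericMatrix solve_schedule_cpp(NumericVector breaks, NumericVector nu,
                                 NumericVector alpha, NumericVector beta,
                                 NumericVector mu1, NumericVector tvec,
                                 double lag) {
  const int K = breaks.size();
  std::vector<double> L(K);
  std::vector<Rates> R(K);
  for (int k = 0; k < K; ++k) {
    L[k] = breaks[k];
    if (!make_rates(nu[k], alpha[k], beta[k], mu1[k], R[k]))
      stop("invalid (negative or non-finite) rates in interval %d", k + 1);
  }
  const int n = tvec.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    const double te = tvec[i] - lag;
    SolveOut o = solve_at(&L[0], &R[0], K, te);
    if (!o.ok)
      stop("TSCE propagation failed at t = %g (rates outside supported range)",
           tvec[i]);
    out(i, 0) = o.logS;
    out(i, 1) = o.h;
  }
  return out;
}

// [[Rcpp::export(name = ".cohort_loglik_cpp")]]
NumericVector cohort_loglik_cpp(IntegerVector off, NumericVector ibk,
                                NumericVector ids, IntegerVector grp,
                                NumericVector entry, NumericVector exitage,
                                IntegerVector iscase, NumericMatrix par,
                                bool aggregate) {
  const int n = entry.size();
  RateCache cache(par);
  const Rates *Rp[MAX_IVALS];
  int K = 0;
  const int *offp = INTEGER(off);
  const double *bkp = REAL(ibk);
  const double *dsp = REAL(ids);
  double total = 0.0;
  NumericVector out(aggregate ? 1 : n);
  for (int i = 0; i < n; ++i) {
    const int g = grp[i];
    const double lag = par(g, P_LAG);
    if (!lookup_ind(offp, dsp, i, g, cache, Rp, K)) {
      if (aggregate) { out[0] = R_NegInf; return out; }
      out[i] = R_NegInf; continue;
    }
    const double *L = bkp + offp[i];
    SolveOut se = solve_at_p(L, Rp, K, exitage[i] - lag);
    SolveOut sa = solve_at_p(L, Rp, K, entry[i] - lag);
    if (!se.ok || !sa.ok) {
      if (aggregate) { out[0] = R_NegInf; return out; }
      out[i] = R_NegInf; continue;
    }
    double ll = se.logS - sa.logS;
    if (iscase[i]) {
      if (se.h > 0.0) ll += std::log(se.h);
      else ll = R_NegInf;
    }
    if (aggregate) {
      total += ll;
      if (!R_finite(total)) { out[0] = R_NegInf; return out; }
    } else out[i] = ll;
  }
  if (aggregate) out[0] = total;
  return out;
}

// Draw event ages conditional on no event by entry: solve S(T)/S(ae) = u by
// bisection on log S; returns +Inf when no event occurs by maxage.
// [[Rcpp::export(name = ".sample_event_cpp")]]
NumericVector sample_event_cpp(IntegerVector off, NumericVector ibk,
                               NumericVector ids, IntegerVector grp,
                               NumericVector entry, NumericVector maxage,
                               NumericVector u, NumericMatrix par) {
  const int n = entry.size();
  RateCache cache(par);
  const Rates *Rp[MAX_IVALS];
  int K = 0;
  const int *offp = INTEGER(off);
  const double *bkp = REAL(ibk);
  const double *dsp = REAL(ids);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int g = grp[i];
    const double lag = par(g, P_LAG);
    if (!lookup_ind(offp, dsp, i, g, cache, Rp, K))
      stop("invalid generating parameters");
    const double *L = bkp + offp[i];
    SolveOut sa = solve_at_p(L, Rp, K, entry[i] - lag);
    SolveOut sx = solve_at_p(L, Rp, K, maxage[i] - lag);
    if (!sa.ok || !sx.ok)
      stop("TSCE propagation failed during event sampling");
    const double target = std::log(u[i]) + sa.logS;
    if (sx.logS >= target) {
      out[i] = R_PosInf;
      continue;
    }
    double lo = entry[i], hi = maxage[i];
    for (int it = 0; it < 80 && (hi - lo) > 1e-10; ++it) {
      const double mid = 0.5 * (lo + hi);
      SolveOut sm = solve_at_p(L, Rp, K, mid - lag);
      if (sm.logS >= target) lo = mid; else hi = mid;
    }
    out[i] = 0.5 * (lo + hi);
  }
  return out;
}

// Direct branching-process simulation of the cell model with constant rates:
// X*mu0 initiations as a Poisson process on [0, t]; each initiated cell starts
// a birth(a)-death(b)-conversion(m) clone; a run "survives" when no clone
// produces a malignant cell by t.  Returns the fraction of surviving runs.
// [[Rcpp::export(name = ".branching_surv_cpp")]]
double branching_surv_cpp(double nu, double a, double b, double m, double t,
                          int nrep) {
  if (!(nu >= 0 && a > 0 && b >= 0 && m >= 0 && t >= 0))
    stop("invalid rates for branching simulation");
  const double tot = a + b + m;
  long surv = 0;
  for (int r = 0; r < nrep; ++r) {
    const int ninit = (int)R::rpois(nu * t);
    bool cancer = false;
    for (int j = 0; j < ninit && !cancer; ++j) {
      double time = t * R::unif_rand();  // initiation age (uniform given count)
      long ncell = 1;
      while (ncell > 0) {
        time += R::exp_rand() / (ncell * tot);
        if (time >= t) break;
        const double e = tot * R::unif_rand();
        if (e < m) { cancer = true; break; }
        else if (e < m + a) ++ncell;
        else --ncell;
      }
    }
    if (!cancer) ++surv;
  }
  return (double)surv / (double)nrep;
}
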