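// Core numerical engine: extended model-free spectral density, weighted
// least-squares fitting of the nested models by multi-start Nelder-Mead,
// AICc selection with the single-timescale (Model 2/3) split, and the
// enumerated block-bootstrap ensemble loop.
//
// All times here are in ns, angular frequencies in rad/ns, spectral
// densities in ns/rad.  The R wrappers convert from SI units; working in
// ns keeps all optimized parameters within a few orders of magnitude of 1.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double BIG = 1e30;

static inline double lorentz(double tau, double w) {
  if (tau <= 0.0) return 0.0;
  return tau / (1.0 + w * w * tau * tau);
}

// p = {tau_m, Sf2, Ss2, tau_f, tau_s}; a Lorentzian with tau = 0
// contributes exactly 0 (limit convention for removed internal modes).
static inline double mf_J(double w, const double* p) {
  const double tm = p[0], sf = p[1], ss = p[2], tf = p[3], ts = p[4];
  const double t1 = (ts > 0.0) ? 1.0 / (1.0 / tm + 1.0 / ts) : 0.0;
  const double t2 = (tf > 0.0) ? 1.0 / (1.0 / tm + 1.0 / tf) : 0.0;
  const double t3 = (tf > 0.0 && ts > 0.0)
                      ? 1.0 / (1.0 / tm + 1.0 / ts + 1.0 / tf) : 0.0;
  double J = sf * ss * lorentz(tm, w)
           + sf * (1.0 - ss) * lorentz(t1, w)
           + (1.0 - sf) * ss * lorentz(t2, w)
           + (1.0 - sf) * (1.0 - ss) * lorentz(t3, w);
  return 0.4 * J;
}

// [[Rcpp::export]]
NumericVector cpp_model_free_J(NumericVector omega, NumericVector par5) {
  if (par5.size() != 5) stop("par5 must have length 5");
  double p[5];
  for (int k = 0; k < 5; ++k) p[k] = par5[k];
  NumericVector out(omega.size());
  for (R_xlen_t i = 0; i < omega.size(); ++i) out[i] = mf_J(omega[i], p);
  return out;
}

// ---------------------------------------------------------------------------
// Model embeddings.  Internally four functional forms are fitted:
//   form 0: Model 1        free = {Sf2}
//   form 1: Models 2/3     free = {S2, tau}    (single internal timescale)
//   form 2: Model 4        free = {Sf2, Ss2, tau_s}
//   form 3: Model 5        free = {Sf2, Ss2, tau_f, tau_s}
// When tau_m is locally fitted it is prepended as the first free parameter.

struct Problem {
  const double* y;
  const double* sig;
  const double* w;
  const double* mult; // per-point multiplicity (bootstrap counter weights)
  int n;
  int form;        // 0..3
  bool tm_free;
  double tm_fixed; // used when !tm_free
  double tm_hi;    // upper bound on tau_s via tau_s <= tau_m
};

static inline void fill_par5(const Problem& pb, const double* x, double* p) {
  int o = pb.tm_free ? 1 : 0;
  p[0] = pb.tm_free ? x[0] : pb.tm_fixed;
  switch (pb.form) {
  case 0: p[1] = x[o];     p[2] = 1.0;      p[3] = 0.0;      p[4] = 0.0;      break;
  case 1: p[1] = x[o];     p[2] = 1.0;      p[3] = x[o + 1]; p[4] = 0.0;      break;
  case 2: p[1] = x[o];     p[2] = x[o + 1]; p[3] = 0.0;      p[4] = x[o + 2]; break;
  default:p[1] = x[o];     p[2] = x[o + 1]; p[3] = x[o + 2]; p[4] = x[o + 3]; break;
  }
}

static double obj_chi2(const Problem& pb, const double* x) {
  double p[5];
  fill_par5(pb, x, p);
  // keep the slow internal timescale below the overall tumbling time
  if (pb.form >= 2 && p[4] > p[0]) return BIG * (1.0 + p[4] - p[0]);
  if (pb.form == 1 && p[3] > p[0]) return BIG * (1.0 + p[3] - p[0]);
  double s = 0.0;
  for (int j = 0; j < pb.n; ++j) {
    if (pb.mult[j] == 0.0) continue;
    double r = (pb.y[j] - mf_J(pb.w[j], p)) / pb.sig[j];
    s += pb.mult[j] * r * r;
  }
  return s;
}

// ---------------------------------------------------------------------------
// Box-constrained Nelder-Mead (projection onto the box).  Dimensions are
// small (<= 5) and the objective is cheap, so plain simplex search with a
// couple of restarts is robust enough at the 1e-10 chi2 tolerance.

static inline void clampv(std::vector<double>& x,
                          const std::vector<double>& lo,
                          const std::vector<double>& hi) {
  for (size_t k = 0; k < x.size(); ++k) {
    if (x[k] < lo[k]) x[k] = lo[k];
    if (x[k] > hi[k]) x[k] = hi[k];
  }
}

static double nelder_mead(const Problem& pb, std::vector<double>& x,
                          const std::vector<double>& lo,
                          const std::vector<double>& hi,
                          double tol, int maxit) {
  const int d = (int)x.size();
  const int np = d + 1;
  std::vector<std::vector<double> > S(np, x);
  std::vector<double> f(np);
  clampv(S[0], lo, hi);
  for (int k = 0; k < d; ++k) {
    double step = 0.10 * (hi[k] - lo[k]);
    if (step <= 0.0) step = 1e-8;
    S[k + 1] = S[0];
    S[k + 1][k] += (S[0][k] + step > hi[k]) ? -step : step;
    clampv(S[k + 1], lo, hi);
  }
  for (int v = 0; v < np; ++v) f[v] = obj_chi2(pb, S[v].data());

  std::vector<double> cen(d), xr(d), xe(d), xc(d);
  for (int it = 0; it < maxit * np; ++it) {
    // order: find best, worst, second-worst
    int ib = 0, iw = 0;
    for (int v = 1; v < np; ++v) {
      if (f[v] < f[ib]) ib = v;
      if (f[v] > f[iw]) iw = v;
    }
    int is = ib;
    for (int v = 0; v < np; ++v) if (v != iw && f[v] > f[is]) is = v;
    if (std::fabs(f[iw] - f[ib]) <= tol * (1.0 + std::fabs(f[ib]))) break;

    for (int k = 0; k < d; ++k) {
      double s = 0.0;
      for (int v = 0; v < np; ++v) if (v != iw) s += S[v][k];
      cen[k] = s / d;
    }
    for (int k = 0; k < d; ++k) xr[k] = cen[k] + (cen[k] - S[iw][k]);
    clampv(xr, lo, hi);
    double fr = obj_chi2(pb, xr.data());
    if (fr < f[ib]) {
      for (int k = 0; k < d; ++k) xe[k] = cen[k] + 2.0 * (cen[k] - S[iw][k]);
      clampv(xe, lo, hi);
      double fe = obj_chi2(pb, xe.data());
      if (fe < fr) { S[iw] = xe; f[iw] = fe; }
      else         { S[iw] = xr; f[iw] = fr; }
    } else if (fr < f[is]) {
      S[iw] = xr; f[iw] = fr;
    } else {
      for (int k = 0; k < d; ++k) xc[k] = cen[k] + 0.5 * (S[iw][k] - cen[k]);
      clampv(xc, lo, hi);
      double fc = obj_chi2(pb, xc.data());
      if (fc < f[iw]) { S[iw] = xc; f[iw] = fc; }
      else {
        for (int v = 0; v < np; ++v) {
          if (v == ib) continue;
          for (int k = 0; k < d; ++k)
            S[v][k] = S[ib][k] + 0.5 * (S[v][k] - S[ib][k]);
          clampv(S[v], lo, hi);
          f[v] = obj_chi2(pb, S[v].data());
        }
      }
    }
  }
  int ib = 0;
  for (int v = 1; v < np; ++v) if (f[v] < f[ib]) ib = v;
  x = S[ib];
  return f[ib];
}

// ---------------------------------------------------------------------------
// Fitting one functional form from a set of starts.

struct FitOut {
  double chi2;
  double par5[5];
  std::vector<double> xfree; // best free vector (incl. tau_m if free)
  bool ok;
};

struct Bounds {
  double tm_lo, tm_hi;   // tau_m box (ns)
  double thr;            // fast/slow split (ns)
  double ts_hi;          // upper box for internal times
};

static void form_bounds(const Problem& pb, const Bounds& bd,
                        std::vector<double>& lo, std::vector<double>& hi) {
  lo.clear(); hi.clear();
  if (pb.tm_free) { lo.push_back(bd.tm_lo); hi.push_back(bd.tm_hi); }
  switch (pb.form) {
  case 0:
    lo.push_back(0.0); hi.push_back(1.0);
    break;
  case 1: // single timescale: tau free over the full internal range
    lo.push_back(0.0); hi.push_back(1.0);
    lo.push_back(0.0); hi.push_back(bd.ts_hi);
    break;
  case 2:
    lo.push_back(0.0); hi.push_back(1.0);
    lo.push_back(0.0); hi.push_back(1.0);
    lo.push_back(bd.thr); hi.push_back(bd.ts_hi);
    break;
  default:
    lo.push_back(0.0); hi.push_back(1.0);
    lo.push_back(0.0); hi.push_back(1.0);
    lo.push_back(0.0); hi.push_back(bd.thr);
    lo.push_back(bd.thr); hi.push_back(bd.ts_hi);
    break;
  }
}

static FitOut fit_form(Problem pb, const Bounds& bd,
                       const std::vector<std::vector<double> >& starts,
                       double tol, int maxit) {
  std::vector<double> lo, hi;
  form_bounds(pb, bd, lo, hi);
  FitOut out;
  out.chi2 = std::numeric_limits<double>::infinity();
  out.ok = false;
  for (size_t s = 0; s < starts.size(); ++s) {
    std::vector<double> x = starts[s];
    if (x.size() != lo.size()) continue;
    clampv(x, lo, hi);
    double f = nelder_mead(pb, x, lo, hi, tol, maxit);
    if (f < out.chi2) {
      out.chi2 = f;
      out.xfree = x;
      out.ok = true;
    }
  }
  if (out.ok) fill_par5(pb, out.xfree.data(), out.par5);
  return out;
}

// coarse 1-D scan of tau_m with the closed-form optimal Sf2 of Model 1
// (J is linear in Sf2 for Model 1, so weighted LS has an explicit solution)
static double tm_scan(const double* y, const double* sig, const double* w,
                      const double* mult, int n,
                      double tm_lo, double tm_hi) {
  const int NG = 40;
  double best_tm = 0.5 * (tm_lo + tm_hi);
  double best_f = std::numeric_limits<double>::infinity();
  for (int g = 0; g < NG; ++g) {
    double tm = tm_lo * std::pow(tm_hi / tm_lo, (double)g / (NG - 1));
    double num = 0.0, den = 0.0;
    for (int j = 0; j < n; ++j) {
      double b = 0.4 * lorentz(tm, w[j]);
      num += mult[j] * y[j] * b / (sig[j] * sig[j]);
      den += mult[j] * b * b / (sig[j] * sig[j]);
    }
    double sf = (den > 0.0) ? num / den : 1.0;
    if (sf < 0.0) sf = 0.0;
    if (sf > 1.0) sf = 1.0;
    double f = 0.0;
    for (int j = 0; j < n; ++j) {
      double r = (y[j] - sf * 0.4 * lorentz(tm, w[j])) / sig[j];
      f += mult[j] * r * r;
    }
    if (f < best_f) { best_f = f; best_tm = tm; }
  }
  return best_tm;
}

// ---------------------------------------------------------------------------
// Start-list plumbing: starts for each form come from R as a matrix whose
// rows are free-parameter vectors in the form's layout (tau_m first when
// locally fitted; a negative tau_m entry means "use the per-sample scan").

static void collect_starts(const NumericMatrix& m, bool tm_free, double tm0,
                           std::vector<std::vector<double> >& out) {
  for (int i = 0; i < m.nrow(); ++i) {
    std::vector<double> x(m.ncol());
    for (int j = 0; j < m.ncol(); ++j) x[j] = m(i, j);
    if (tm_free && x.size() > 0 && x[0] < 0.0) x[0] = tm0;
    out.push_back(x);
  }
}

struct SelCfg {
  Bounds bd;
  bool tm_free;
  double tm_fixed;
  double tol;
  int maxit;
  bool j0_combined; // add propagated error to the jackknife SE in quadrature
  int n;        // number of fitted points
};

struct SelOut {
  // per form: chi2, converged; par5 per form
  double chi2[4];
  double par5[4][5];
  double aicc[5];   // indexed by model id - 1 (Model 2/3 share the form-1 fit)
  int k5[5];
  int label23;      // 2 or 3
  int best;         // model id 1..5
  double best_par5[5];
  double best_chi2;
};

static double aicc_val(double chi2, int k, int n) {
  if (n - k - 1 <= 0) return NA_REAL;
  return chi2 + 2.0 * k + 2.0 * k * (k + 1.0) / (n - k - 1.0);
}

static void select_one(const double* y, const double* sig, const double* w,
                       const double* mult, const SelCfg& cfg,
                       const std::vector<std::vector<double> > starts0[4],
                       SelOut& so) {
  const int n = cfg.n;
  const int o = cfg.tm_free ? 1 : 0;
  double tm0 = cfg.tm_fixed;
  if (cfg.tm_free)
    tm0 = tm_scan(y, sig, w, mult, n, cfg.bd.tm_lo, cfg.bd.tm_hi);

  Problem pb; pb.y = y; pb.sig = sig; pb.w = w; pb.mult = mult; pb.n = n;
  pb.tm_free = cfg.tm_free; pb.tm_fixed = cfg.tm_fixed; pb.tm_hi = cfg.bd.tm_hi;

  // --- Model 1
  pb.form = 0;
  std::vector<std::vector<double> > st = starts0[0];
  for (size_t s = 0; s < st.size(); ++s)
    if (cfg.tm_free && st[s].size() && st[s][0] < 0) st[s][0] = tm0;
  FitOut f1 = fit_form(pb, cfg.bd, st, cfg.tol, cfg.maxit);

  // --- Models 2/3 (single internal timescale), cascaded from Model 1
  pb.form = 1;
  st = starts0[1];
  for (size_t s = 0; s < st.size(); ++s)
    if (cfg.tm_free && st[s].size() && st[s][0] < 0) st[s][0] = tm0;
  if (f1.ok) {
    std::vector<double> x;
    if (cfg.tm_free) x.push_back(f1.xfree[0]);
    x.push_back(f1.xfree[o]); // S2
    x.push_back(0.0);         // tau -> reproduces Model 1 exactly
    st.push_back(x);
  }
  FitOut f23 = fit_form(pb, cfg.bd, st, cfg.tol, cfg.maxit);

  // --- Model 4, cascaded from Models 1 and 2/3
  pb.form = 2;
  st = starts0[2];
  for (size_t s = 0; s < st.size(); ++s)
    if (cfg.tm_free && st[s].size() && st[s][0] < 0) st[s][0] = tm0;
  if (f1.ok) {
    std::vector<double> x;
    if (cfg.tm_free) x.push_back(f1.xfree[0]);
    x.push_back(f1.xfree[o]); x.push_back(1.0); x.push_back(cfg.bd.thr);
    st.push_back(x); // Ss2 = 1 makes tau_s inert -> chi2 equals Model 1
  }
  if (f23.ok) {
    double S2 = f23.xfree[o], tau = f23.xfree[o + 1];
    std::vector<double> x;
    if (cfg.tm_free) x.push_back(f23.xfree[0]);
    if (tau >= cfg.bd.thr) { // Model-3-like: Sf2 = 1, Ss2 = S2, tau_s = tau
      x.push_back(1.0); x.push_back(S2); x.push_back(tau);
    } else {                 // Model-2-like: Ss2 = 1 leaves tau_s inert
      x.push_back(S2); x.push_back(1.0); x.push_back(cfg.bd.thr);
    }
    st.push_back(x);
  }
  FitOut f4 = fit_form(pb, cfg.bd, st, cfg.tol, cfg.maxit);

  // --- Model 5, cascaded from Model 4 and the Model-2 branch
  pb.form = 3;
  st = starts0[3];
  for (size_t s = 0; s < st.size(); ++s)
    if (cfg.tm_free && st[s].size() && st[s][0] < 0) st[s][0] = tm0;
  if (f4.ok) {
    std::vector<double> x;
    if (cfg.tm_free) x.push_back(f4.xfree[0]);
    x.push_back(f4.xfree[o]); x.push_back(f4.xfree[o + 1]);
    x.push_back(0.0); x.push_back(f4.xfree[o + 2]);
    st.push_back(x); // tau_f = 0 reproduces Model 4 exactly
  }
  if (f23.ok) {
    double S2 = f23.xfree[o], tau = f23.xfree[o + 1];
    if (tau < cfg.bd.thr) {
      std::vector<double> x;
      if (cfg.tm_free) x.push_back(f23.xfree[0]);
      x.push_back(S2); x.push_back(1.0); x.push_back(tau); x.push_back(cfg.bd.thr);
      st.push_back(x); // Ss2 = 1 leaves tau_s inert -> chi2 equals Model 2
    }
  }
  FitOut f5 = fit_form(pb, cfg.bd, st, cfg.tol, cfg.maxit);

  // --- bookkeeping
  const FitOut* ff[4] = { &f1, &f23, &f4, &f5 };
  for (int q = 0; q < 4; ++q) {
    so.chi2[q] = ff[q]->ok ? ff[q]->chi2 : NA_REAL;
    for (int k = 0; k < 5; ++k)
      so.par5[q][k] = ff[q]->ok ? ff[q]->par5[k] : NA_REAL;
  }
  // Model 2/3 label from the single-timescale fit
  so.label23 = 0;
  if (f23.ok) so.label23 = (f23.xfree[o + 1] < cfg.bd.thr) ? 2 : 3;

  int kbase = cfg.tm_free ? 1 : 0;
  int kf[4] = { kbase + 1, kbase + 2, kbase + 3, kbase + 4 };
  for (int m = 0; m < 5; ++m) { so.aicc[m] = NA_REAL; so.k5[m] = NA_INTEGER; }
  if (f1.ok)  { so.k5[0] = kf[0]; so.aicc[0] = aicc_val(f1.chi2,  kf[0], n); }
  if (f23.ok && so.label23 > 0) {
    so.k5[so.label23 - 1] = kf[1];
    so.aicc[so.label23 - 1] = aicc_val(f23.chi2, kf[1], n);
  }
  if (f4.ok)  { so.k5[3] = kf[2]; so.aicc[3] = aicc_val(f4.chi2,  kf[2], n); }
  if (f5.ok)  { so.k5[4] = kf[3]; so.aicc[4] = aicc_val(f5.chi2,  kf[3], n); }

  // argmin AICc; ties broken toward fewer free parameters (smaller k);
  // model ids are ordered by k here so scanning in id order suffices
  so.best = 0;
  double ba = std::numeric_limits<double>::infinity();
  for (int m = 0; m < 5; ++m) {
    if (ISNA(so.aicc[m])) continue;
    if (so.aicc[m] < ba - 0.0) { ba = so.aicc[m]; so.best = m + 1; }
  }
  for (int k = 0; k < 5; ++k) so.best_par5[k] = NA_REAL;
  so.best_chi2 = NA_REAL;
  if (so.best >= 1) {
    int q = (so.best == 1) ? 0 : (so.best <= 3 ? 1 : so.best - 2);
    so.best_chi2 = so.chi2[q];
    for (int k = 0; k < 5; ++k) so.best_par5[k] = so.par5[q][k];
    if (so.best == 3) {
      // relabel the single-timescale fit with Model 3 conventions:
      // {tau_m, 1, S2, 0, tau_s}
      double S2 = so.par5[1][1], tau = so.par5[1][3];
      so.best_par5[1] = 1.0; so.best_par5[2] = S2;
      so.best_par5[3] = 0.0; so.best_par5[4] = tau;
    }
  }
}

static SelCfg parse_cfg(List cfg, int n) {
  SelCfg c;
  c.bd.tm_lo = as<double>(cfg["tau_m_lo"]);
  c.bd.tm_hi = as<double>(cfg["tau_m_hi"]);
  c.bd.thr   = as<double>(cfg["threshold"]);
  c.bd.ts_hi = as<double>(cfg["tau_s_hi"]);
  c.tm_free  = as<bool>(cfg["tau_m_free"]);
  c.tm_fixed = as<double>(cfg["tau_m_fixed"]);
  c.tol      = as<double>(cfg["tol"]);
  c.maxit    = as<int>(cfg["maxit"]);
  c.j0_combined = as<bool>(cfg["j0_combined"]);
  c.n = n;
  return c;
}

static void parse_starts(List starts, bool tm_free,
                         std::vector<std::vector<double> > st[4]) {
  for (int q = 0; q < 4; ++q) {
    NumericMatrix m = as<NumericMatrix>(starts[q]);
    collect_starts(m, tm_free, -1.0, st[q]); // scan substitution done later
  }
}

// Fit all models to one fit vector and select by AICc.
// y, sig in ns/rad; omega in rad/ns.  Returns the full per-model table.
// [[Rcpp::export]]
List cpp_select_model(NumericVector y, NumericVector sig, NumericVector omega,
                      List cfg, List starts) {
  int n = y.size();
  SelCfg c = parse_cfg(cfg, n);
  std::vector<std::vector<double> > st[4];
  parse_starts(starts, c.tm_free, st);
  std::vector<double> ones(n, 1.0);
  SelOut so;
  select_one(REAL(y), REAL(sig), REAL(omega), ones.data(), c, st, so);

  NumericMatrix par(4, 5);
  NumericVector chi2(4);
  for (int q = 0; q < 4; ++q) {
    chi2[q] = so.chi2[q];
    for (int k = 0; k < 5; ++k) par(q, k) = so.par5[q][k];
  }
  return List::create(
    _["chi2_form"] = chi2,             // M1, M2/3, M4, M5
    _["par_form"] = par,
    _["aicc"] = NumericVector(so.aicc, so.aicc + 5),
    _["k"] = IntegerVector(so.k5, so.k5 + 5),
    _["label23"] = so.label23,
    _["best"] = so.best,
    _["best_par5"] = NumericVector(so.best_par5, so.best_par5 + 5),
    _["best_chi2"] = so.best_chi2);
}

// Fit a single fixed model (1..5).  Models 2 and 3 constrain the internal
// timescale to their side of the threshold.
// [[Rcpp::export]]
List cpp_fit_model(NumericVector y, NumericVector sig, NumericVector omega,
                   int model_id, List cfg, NumericMatrix starts) {
  int n = y.size();
  SelCfg c = parse_cfg(cfg, n);
  std::vector<double> ones(n, 1.0);
  Problem pb;
  pb.y = REAL(y); pb.sig = REAL(sig); pb.w = REAL(omega);
  pb.mult = ones.data(); pb.n = n;
  pb.tm_free = c.tm_free; pb.tm_fixed = c.tm_fixed; pb.tm_hi = c.bd.tm_hi;

  Bounds bd = c.bd;
  int form;
  switch (model_id) {
  case 1: form = 0; break;
  case 2: form = 1; bd.ts_hi = c.bd.thr; break;         // tau in [0, thr)
  case 3: form = 1; break;                               // handled below
  case 4: form = 2; break;
  case 5: form = 3; break;
  default: stop("model_id must be 1..5");
  }
  pb.form = form;

  double tm0 = c.tm_fixed;
  if (c.tm_free)
    tm0 = tm_scan(pb.y, pb.sig, pb.w, pb.mult, n, bd.tm_lo, bd.tm_hi);
  std::vector<std::vector<double> > st;
  collect_starts(starts, c.tm_free, tm0, st);

  FitOut fo;
  if (model_id == 3) {
    // single-timescale form with tau restricted to [thr, ts_hi]
    std::vector<double> lo, hi;
    form_bounds(pb, bd, lo, hi);
    lo[lo.size() - 1] = bd.thr;
    fo.chi2 = std::numeric_limits<double>::infinity(); fo.ok = false;
    for (size_t s = 0; s < st.size(); ++s) {
      std::vector<double> x = st[s];
      if (x.size() != lo.size()) continue;
      clampv(x, lo, hi);
      double f = nelder_mead(pb, x, lo, hi, c.tol, c.maxit);
      if (f < fo.chi2) { fo.chi2 = f; fo.xfree = x; fo.ok = true; }
    }
    if (fo.ok) fill_par5(pb, fo.xfree.data(), fo.par5);
  } else {
    fo = fit_form(pb, bd, st, c.tol, c.maxit);
  }
  if (!fo.ok)
    return List::create(_["converged"] = false);

  double par5[5];
  for (int k = 0; k < 5; ++k) par5[k] = fo.par5[k];
  if (model_id == 3) { // Model 3 conventions {tau_m, 1, S2, 0, tau_s}
    par5[2] = fo.par5[1]; par5[4] = fo.par5[3];
    par5[1] = 1.0; par5[3] = 0.0;
  }
  int kbase = c.tm_free ? 1 : 0;
  int kf = kbase + ((form == 0) ? 1 : (form == 1) ? 2 : (form == 2) ? 3 : 4);
  return List::create(
    _["converged"] = true,
    _["chi2"] = fo.chi2,
    _["par5"] = NumericVector(par5, par5 + 5),
    _["xfree"] = NumericVector(fo.xfree.begin(), fo.xfree.end()),
    _["k"] = kf,
    _["aicc"] = aicc_val(fo.chi2, kf, n));
}

// ---------------------------------------------------------------------------
// Enumerated bootstrap ensemble.
//
// Blocks are resampled independently for J(0), J(omegaN), J(0.87 omegaH)
// using the pointer table; the block index triple (l, m, n) for sample i is
// the mixed-radix decomposition of i-1 with the most significant digit
// assigned to the J(0) block.  For each sample the J(0) block is collapsed
// to its inverse-variance weighted mean with delete-one jackknife SE before
// fitting, exactly as for the original data.

static void wmean_jack(const std::vector<double>& v,
                       const std::vector<double>& e,
                       double& mean, double& se, double& prop) {
  int g = (int)v.size();
  double sw = 0.0, swx = 0.0;
  for (int j = 0; j < g; ++j) {
    double wj = 1.0 / (e[j] * e[j]);
    sw += wj; swx += wj * v[j];
  }
  mean = swx / sw;
  prop = std::sqrt(1.0 / sw);
  if (g < 2) { se = e[0]; return; }
  std::vector<double> th(g);
  double tbar = 0.0;
  for (int j = 0; j < g; ++j) {
    double wj = 1.0 / (e[j] * e[j]);
    th[j] = (swx - wj * v[j]) / (sw - wj);
    tbar += th[j];
  }
  tbar /= g;
  double s = 0.0;
  for (int j = 0; j < g; ++j) s += (th[j] - tbar) * (th[j] - tbar);
  se = std::sqrt((g - 1.0) / g * s);
}

// [[Rcpp::export]]
List cpp_ensemble(NumericVector j0v, NumericVector j0e,
                  NumericVector jnv, NumericVector jne,
                  NumericVector jhv, NumericVector jhe,
                  NumericVector wN, NumericVector wH,
                  IntegerMatrix pointers, List cfg, List starts,
                  bool do_select, int fixed_model) {
  const int G = j0v.size();
  const int narr = pointers.nrow();
  const int B = narr * narr * narr;
  const int N = 3 * G;
  const int nfit = 1 + 2 * G;

  SelCfg c = parse_cfg(cfg, nfit);
  std::vector<std::vector<double> > st[4];
  if (do_select) parse_starts(starts, c.tm_free, st);

  NumericMatrix par(B, 5);
  IntegerVector model(B);
  NumericVector chi2(B);
  LogicalVector conv(B);
  IntegerMatrix Y(B, N);

  // A bootstrap sample resamples data points (value, frequency) pairs, so
  // the high-frequency blocks keep their original values and frequencies;
  // the counter vector enters the objective as per-point multiplicities.
  // Only the averaged J(0) slot changes between samples.
  std::vector<double> y(nfit), sig(nfit), w(nfit), mult(nfit);
  w[0] = 0.0; mult[0] = 1.0;
  for (int g = 0; g < G; ++g) {
    w[1 + g] = wN[g];     y[1 + g] = jnv[g];     sig[1 + g] = jne[g];
    w[1 + G + g] = wH[g]; y[1 + G + g] = jhv[g]; sig[1 + G + g] = jhe[g];
  }

  std::vector<double> v0(G), e0(G);

  for (int i = 0; i < B; ++i) {
    int l = i / (narr * narr);
    int m = (i / narr) % narr;
    int n = i % narr;
    // counters derived from the pointers of each block
    for (int j = 0; j < N; ++j) Y(i, j) = 0;
    for (int g = 0; g < G; ++g) {
      int pl = pointers(l, g) - 1;
      int pm = pointers(m, g) - 1;
      int pn = pointers(n, g) - 1;
      Y(i, pl) += 1;
      Y(i, G + pm) += 1;
      Y(i, 2 * G + pn) += 1;
      v0[g] = j0v[pl]; e0[g] = j0e[pl];
    }
    for (int g = 0; g < G; ++g) {
      mult[1 + g] = Y(i, G + g);
      mult[1 + G + g] = Y(i, 2 * G + g);
    }
    double mu, se, prop;
    wmean_jack(v0, e0, mu, se, prop);
    // degenerate jackknife (identical resampled values): propagated fallback
    if (se <= 1e-12 * std::fabs(mu)) se = e0[0];
    else if (c.j0_combined) se = std::sqrt(se * se + prop * prop);
    y[0] = mu; sig[0] = se;

    if (do_select) {
      SelOut so;
      select_one(y.data(), sig.data(), w.data(), mult.data(), c, st, so);
      model[i] = so.best;
      conv[i] = (so.best >= 1);
      chi2[i] = so.best_chi2;
      for (int k = 0; k < 5; ++k) par(i, k) = so.best_par5[k];
    } else {
      // fixed-model refit (conventional bootstrap)
      Problem pb;
      pb.y = y.data(); pb.sig = sig.data(); pb.w = w.data();
      pb.mult = mult.data(); pb.n = nfit;
      pb.tm_free = c.tm_free; pb.tm_fixed = c.tm_fixed; pb.tm_hi = c.bd.tm_hi;
      int form = (fixed_model == 1) ? 0 : (fixed_model <= 3) ? 1
                 : (fixed_model == 4) ? 2 : 3;
      pb.form = form;
      std::vector<std::vector<double> > stf;
      NumericMatrix sm = as<NumericMatrix>(starts[0]);
      double tm0 = c.tm_fixed;
      if (c.tm_free)
        tm0 = tm_scan(pb.y, pb.sig, pb.w, pb.mult, nfit,
                      c.bd.tm_lo, c.bd.tm_hi);
      collect_starts(sm, c.tm_free, tm0, stf);
      FitOut fo = fit_form(pb, c.bd, stf, c.tol, c.maxit);
      conv[i] = fo.ok;
      model[i] = fixed_model;
      chi2[i] = fo.ok ? fo.chi2 : NA_REAL;
      if (fo.ok) {
        double p5[5];
        for (int k = 0; k < 5; ++k) p5[k] = fo.par5[k];
        if (fixed_model == 3) {
          p5[2] = fo.par5[1]; p5[4] = fo.par5[3]; p5[1] = 1.0; p5[3] = 0.0;
        }
        for (int k = 0; k < 5; ++k) par(i, k) = p5[k];
      } else {
        for (int k = 0; k < 5; ++k) par(i, k) = NA_REAL;
      }
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["par"] = par, _["model"] = model, _["chi2"] = chi2,
    _["converged"] = conv, _["Y"] = Y, _["B"] = B);
}
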