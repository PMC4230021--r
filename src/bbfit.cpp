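// Per-site beta-binomial regression fitting by maximum likelihood.
//
// The genome-wide scan fits two models (full and reduced) at every site, so
// the inner loop lives here. Optimisation uses R's own vmmin (BFGS with a
// numerical central-difference gradient) and falls back to nmmin
// (Nelder-Mead) when BFGS fails; both are deterministic.

#include <RcppArmadillo.h>
#include <R_ext/Applic.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double GAMMA_MIN = 1e-6;
static const double GAMMA_MAX = 1.0 - 1e-6;
static const double BIG_PENALTY = 1e30;

// log Pr(M = m | n, pi, gamma) WITHOUT the log-choose term (constant in the
// parameters; added back once per site). gamma must lie in (0, 1).
//
// log B(m+a, n-m+b) - log B(a, b) for integer m, n telescopes to
//   sum_{k<m} log(a+k) + sum_{k<n-m} log(b+k) - sum_{k<n} log(a+b+k),
// which is much cheaper than six lgamma calls at the low coverages typical
// of WGBS; large n falls back to lbeta.
static double bb_logpmf_core(int m, int n, double pi, double gamma) {
  double s = 1.0 / gamma - 1.0;
  double a = pi * s, b = (1.0 - pi) * s;
  if (n <= 400) {
    double acc = 0.0;
    for (int k = 0; k < m; ++k)     acc += std::log(a + k);
    for (int k = 0; k < n - m; ++k) acc += std::log(b + k);
    for (int k = 0; k < n; ++k)     acc -= std::log(a + b + k);
    return acc;
  }
  return R::lbeta(m + a, n - m + b) - R::lbeta(a, b);
}

struct SiteEx {
  int s;                     // covered samples
  int t;                     // regression parameters (columns of X)
  const int* n;
  const int* m;
  const arma::mat* X;        // s x t
};

// negative log-likelihood; par = (eta_1..eta_t, theta) with gamma = plogis(theta)
static double negll(int npar, double* par, void* ex_) {
  SiteEx* ex = static_cast<SiteEx*>(ex_);
  int t = ex->t;
  double theta = par[t];
  if (theta > 30.0) theta = 30.0;
  if (theta < -30.0) theta = -30.0;
  double gamma = 1.0 / (1.0 + std::exp(-theta));
  if (gamma < GAMMA_MIN) gamma = GAMMA_MIN;
  if (gamma > GAMMA_MAX) gamma = GAMMA_MAX;
  double ll = 0.0;
  for (int i = 0; i < ex->s; ++i) {
    double lp = 0.0;
    for (int j = 0; j < t; ++j) lp += (*ex->X)(i, j) * par[j];
    double pi = 1.0 / (1.0 + std::exp(-lp));
    if (pi < 1e-12) pi = 1e-12;
    if (pi > 1.0 - 1e-12) pi = 1.0 - 1e-12;
    ll += bb_logpmf_core(ex->m[i], ex->n[i], pi, gamma);
  }
  if (!std::isfinite(ll)) return BIG_PENALTY;
  return -ll;
}

static void negll_gr(int npar, double* par, double* gr, void* ex) {
  std::vector<double> p(par, par + npar);
  for (int j = 0; j < npar; ++j) {
    double h = 1e-6 * (1.0 + std::fabs(par[j]));
    p[j] = par[j] + h;
    double f1 = negll(npar, p.data(), ex);
    p[j] = par[j] - h;
    double f2 = negll(npar, p.data(), ex);
    p[j] = par[j];
    gr[j] = (f1 - f2) / (2.0 * h);
  }
}

// One ML fit from a given start. Returns true when the optimizer reported
// convergence; par is overwritten with the optimum, fmin with the minimum.
static bool fit_model(SiteEx& ex, std::vector<double>& par, double& fmin) {
  int npar = static_cast<int>(par.size());
  std::vector<int> mask(npar, 1);
  std::vector<double> pb = par;
  double fb = BIG_PENALTY;
  int fail = 1, fncount = 0, grcount = 0;
  vmmin(npar, pb.data(), &fb, negll, negll_gr, 500, 0, mask.data(),
        R_NegInf, 1e-8, 10, &ex, &fncount, &grcount, &fail);
  bool ok = (fail == 0) && std::isfinite(fb);

  // Nelder-Mead pass: a fallback when BFGS fails, otherwise a polish from
  // the BFGS solution (derivative-free, so the finite-difference gradient
  // noise cannot bias the final optimum)
  std::vector<double> start = ok ? pb : par;
  std::vector<double> pn(npar);
  double fn = BIG_PENALTY;
  int fail2 = 1, fc = 0;
  nmmin(npar, start.data(), pn.data(), &fn, negll, &fail2,
        R_NegInf, 1e-12, &ex, 1.0, 0.5, 2.0, 0, &fc, 1000);
  if (std::isfinite(fn) && (fn <= fb || !std::isfinite(fb))) {
    pb = pn;
    fb = fn;
    ok = ok || (fail2 == 0);
  }
  par = pb;
  fmin = fb;
  return ok;
}

// deterministic start for eta: a few IRLS steps of the pooled binomial
// logistic fit (fallback: zeros), per-element clamped to +-8
static arma::vec irls_start(const arma::mat& X, const arma::vec& n,
                            const arma::vec& m) {
  int t = X.n_cols;
  arma::vec y = (m + 0.5) / (n + 1.0);
  arma::vec lp = arma::log(y / (1.0 - y));
  arma::vec beta(t, arma::fill::zeros);
  for (int it = 0; it < 8; ++it) {
    if (it > 0) lp = X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-lp));
    arma::vec w = n % mu % (1.0 - mu) + 1e-8;
    arma::vec z = lp + (m - n % mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::vec nb;
    if (!arma::solve(nb, X.t() * Xw, X.t() * (w % z)) || !nb.is_finite())
      return arma::vec(t, arma::fill::zeros);
    beta = nb;
  }
  beta.transform([](double v) {
    if (v > 8.0) return 8.0;
    if (v < -8.0) return -8.0;
    return v;
  });
  return beta;
}

static double clamp_gamma(double theta) {
  double g = 1.0 / (1.0 + std::exp(-theta));
  if (g < GAMMA_MIN) g = GAMMA_MIN;
  if (g > GAMMA_MAX) g = GAMMA_MAX;
  return g;
}

// Batch fitter. total, meth: sites x samples; X: samples x t model matrix;
// dropCols: 1-based columns of X removed in the reduced model (may be empty,
// in which case only the full model is fitted). A site is untestable when,
// after removing zero-coverage samples, fewer than t samples remain, X loses
// full column rank, or (when testing) some level of the test factor has no
// coverage left.
// [[Rcpp::export(name = ".fitSitesCpp")]]
List fitSitesCpp(IntegerMatrix total, IntegerMatrix meth, arma::mat X,
                 IntegerVector dropCols) {
  int nsite = total.nrow(), s = total.ncol();
  int t = X.n_cols;
  bool doReduced = dropCols.size() > 0;
  int tr = t - dropCols.size();

  std::vector<int> keepIdx;  // columns kept in the reduced model
  std::vector<bool> isDrop(t, false);
  for (int k = 0; k < dropCols.size(); ++k) isDrop[dropCols[k] - 1] = true;
  for (int j = 0; j < t; ++j) if (!isDrop[j]) keepIdx.push_back(j);

  NumericMatrix etaFull(nsite, t), etaRed(nsite, std::max(tr, 1));
  NumericVector gammaFull(nsite, NA_REAL), gammaRed(nsite, NA_REAL);
  NumericVector llFull(nsite, NA_REAL), llRed(nsite, NA_REAL);
  LogicalVector convFull(nsite, NA_LOGICAL), convRed(nsite, NA_LOGICAL);
  IntegerVector nUsed(nsite);
  LogicalVector testable(nsite);
  std::fill(etaFull.begin(), etaFull.end(), NA_REAL);
  std::fill(etaRed.begin(), etaRed.end(), NA_REAL);

  const double theta0 = std::log(0.05 / 0.95);  // gamma start 0.05

  for (int r = 0; r < nsite; ++r) {
    std::vector<int> cov;
    for (int i = 0; i < s; ++i) if (total(r, i) > 0) cov.push_back(i);
    int sc = static_cast<int>(cov.size());
    nUsed[r] = sc;
    testable[r] = false;
    if (sc < t) continue;

    arma::mat Xc(sc, t);
    arma::vec nv(sc), mv(sc);
    std::vector<int> ni(sc), mi(sc);
    for (int i = 0; i < sc; ++i) {
      for (int j = 0; j < t; ++j) Xc(i, j) = X(cov[i], j);
      ni[i] = total(r, cov[i]);
      mi[i] = meth(r, cov[i]);
      nv[i] = ni[i];
      mv[i] = mi[i];
    }
    if (arma::rank(Xc) < (unsigned)t) continue;

    if (doReduced) {
      // every level of the test factor must retain coverage: each dropped
      // column needs a covered sample with a 1, and the reference level
      // (all dropped columns 0) needs one too
      bool ok = true;
      for (int k = 0; k < dropCols.size(); ++k) {
        int j = dropCols[k] - 1;
        bool any1 = false;
        for (int i = 0; i < sc; ++i) if (Xc(i, j) != 0.0) { any1 = true; break; }
        if (!any1) { ok = false; break; }
      }
      if (ok) {
        bool anyRef = false;
        for (int i = 0; i < sc; ++i) {
          bool ref = true;
          for (int k = 0; k < dropCols.size(); ++k)
            if (Xc(i, dropCols[k] - 1) != 0.0) { ref = false; break; }
          if (ref) { anyRef = true; break; }
        }
        if (!anyRef) ok = false;
      }
      if (!ok) continue;
    }
    testable[r] = true;

    // the log-choose constant, shared by full and reduced models
    double lcc = 0.0;
    for (int i = 0; i < sc; ++i) lcc += R::lchoose(ni[i], mi[i]);

    SiteEx exF = {sc, t, ni.data(), mi.data(), &Xc};

    // reduced model first: its solution seeds a second start for the full fit
    double fR = NA_REAL;
    std::vector<double> parR;
    arma::mat Xr;
    if (doReduced) {
      Xr = arma::mat(sc, std::max(tr, 1));
      if (tr > 0)
        for (int i = 0; i < sc; ++i)
          for (size_t j = 0; j < keepIdx.size(); ++j)
            Xr(i, j) = Xc(i, keepIdx[j]);
      SiteEx exR = {sc, std::max(tr, 1), ni.data(), mi.data(), &Xr};
      if (tr == 0) {
        // reduced model with no regression columns cannot occur (intercept
        // is never the test factor); guard anyway
        exR.t = 0;
      }
      arma::vec b0 = irls_start(Xr, nv, mv);
      parR.assign(tr + 1, 0.0);
      for (int j = 0; j < tr; ++j) parR[j] = b0[j];
      parR[tr] = theta0;
      bool cR = fit_model(exR, parR, fR);
      convRed[r] = cR;
      llRed[r] = -fR + lcc;
      gammaRed[r] = clamp_gamma(parR[tr]);
      for (int j = 0; j < tr; ++j) etaRed(r, j) = parR[j];
    }

    // full model
    arma::vec bF = irls_start(Xc, nv, mv);
    std::vector<double> parF(t + 1, 0.0);
    for (int j = 0; j < t; ++j) parF[j] = bF[j];
    parF[t] = theta0;
    double fF = NA_REAL;
    bool cF = fit_model(exF, parF, fF);

    if (doReduced && std::isfinite(fR)) {
      // candidate start at the reduced optimum (dropped effects = 0):
      // guarantees llFull >= llRed up to optimizer tolerance
      std::vector<double> parF2(t + 1, 0.0);
      for (size_t j = 0; j < keepIdx.size(); ++j) parF2[keepIdx[j]] = parR[j];
      parF2[t] = parR[tr];
      double fF2 = NA_REAL;
      bool cF2 = fit_model(exF, parF2, fF2);
      if (std::isfinite(fF2) && (!std::isfinite(fF) || fF2 < fF)) {
        parF = parF2;
        fF = fF2;
        cF = cF2;
      }
    }
    convFull[r] = cF;
    llFull[r] = -fF + lcc;
    gammaFull[r] = clamp_gamma(parF[t]);
    for (int j = 0; j < t; ++j) etaFull(r, j) = parF[j];
  }

  return List::create(
      _["etaFull"] = etaFull, _["gammaFull"] = gammaFull,
      _["llFull"] = llFull, _["convFull"] = convFull,
      _["etaRed"] = etaRed, _["gammaRed"] = gammaRed,
      _["llRed"] = llRed, _["convRed"] = convRed,
      _["nUsed"] = nUsed, _["testable"] = testable);
}
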