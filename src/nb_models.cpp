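// Negative binomial GLM and random-intercept GLMM fitters used per gene.
//
// The GLM path is iteratively reweighted least squares alternated with
// Newton maximization of the profile likelihood in log(theta).  The GLMM
// path maximizes the Laplace-approximate marginal likelihood over
// (beta0, beta1, log theta, log sigma2): an inner Newton solve finds the
// conditional mode of each group's random intercept, the outer problem is
// handled by Nelder-Mead followed by Newton polish on finite-difference
// derivatives, which also supplies the observed-information standard errors.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 0  // singular solves are handled explicitly
#include <RcppArmadillo.h>
#include <functional>
#include <vector>

using namespace Rcpp;

static const double ETA_MAX = 30.0;
static const double LT_LO = -9.0;   // log theta bounds
static const double LT_HI = 16.0;
static const double LS_LO = -18.420680743952367; // log(1e-8)
static const double LS_HI = 9.2103403719761836;  // log(1e4)

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// NB2 log-likelihood of one observation; safe for y = 0 and continuous y.
static inline double nb_ll1(double y, double mu, double theta) {
  double ll = R::lgammafn(y + theta) - R::lgammafn(theta) - R::lgammafn(y + 1.0)
            + theta * (std::log(theta) - std::log(theta + mu));
  if (y > 0.0) ll += y * (std::log(mu) - std::log(theta + mu));
  return ll;
}

// Poisson IRLS for intercept + indicator, with offset; used to initialize.
static arma::vec poisson_irls(const arma::vec& y, const arma::vec& x,
                              const arma::vec& off) {
  const arma::uword n = y.n_elem;
  arma::mat X(n, 2);
  X.col(0).ones();
  X.col(1) = x;
  arma::vec beta(2);
  beta[0] = std::log(arma::mean(y) + 0.1) - arma::mean(off);
  beta[1] = 0.0;
  for (int it = 0; it < 50; ++it) {
    arma::vec eta = arma::clamp(X * beta + off, -ETA_MAX, ETA_MAX);
    arma::vec mu = arma::exp(eta);
    arma::vec w = arma::clamp(mu, 1e-8, arma::datum::inf);
    arma::vec z = (eta - off) + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::vec bnew;
    if (!arma::solve(bnew, X.t() * Xw, Xw.t() * z)) break;
    bnew = arma::clamp(bnew, -50.0, 50.0);
    double d = arma::norm(bnew - beta, "inf");
    beta = bnew;
    if (d < 1e-10) break;
  }
  return beta;
}

// Method-of-moments dispersion given fitted means; returns theta = 1/phi.
static double theta_moments(const arma::vec& y, const arma::vec& mu) {
  double num = arma::accu(arma::square(y - mu) - mu);
  double den = arma::accu(arma::square(mu));
  double phi = (den > 0.0) ? num / den : 1.0;
  phi = clampd(phi, 1e-3, 100.0);
  return 1.0 / phi;
}

// ---------------------------------------------------------------------------
// NB GLM: IRLS for beta inside a 1-D profile search over log(theta).
// The dispersion profile is optionally Cox-Reid adjusted
// (ll - 0.5 log det X'WX), which removes the upward small-sample bias of the
// ML dispersion that would otherwise deflate the Wald standard errors.
// ---------------------------------------------------------------------------

struct GlmProfile {
  const arma::vec& y;
  const arma::mat& X;
  const arma::vec& off;
  bool adjust;
  mutable arma::vec beta;  // warm-started across profile evaluations
  mutable bool solve_failed = false;

  void irls(double theta) const {
    const arma::uword n = y.n_elem;
    for (int k = 0; k < 50; ++k) {
      arma::vec eta = arma::clamp(X * beta + off, -ETA_MAX, ETA_MAX);
      arma::vec mu = arma::exp(eta);
      arma::vec w = arma::clamp(mu * theta / (mu + theta), 1e-10,
                                arma::datum::inf);
      arma::vec z = (eta - off) + (y - mu) / arma::clamp(mu, 1e-8,
                                                         arma::datum::inf);
      arma::mat Xw = X.each_col() % w;
      arma::vec bnew;
      if (!arma::solve(bnew, X.t() * Xw, Xw.t() * z)) {
        solve_failed = true;
        break;
      }
      bnew = arma::clamp(bnew, -50.0, 50.0);
      double d = arma::norm(bnew - beta, "inf");
      beta = bnew;
      if (d < 1e-12) break;
    }
  }

  double loglik(double theta) const {
    arma::vec mu = arma::exp(arma::clamp(X * beta + off, -ETA_MAX, ETA_MAX));
    double ll = 0.0;
    for (arma::uword j = 0; j < y.n_elem; ++j) ll += nb_ll1(y[j], mu[j], theta);
    return ll;
  }

  // negative (adjusted) profile log-likelihood in log(theta)
  double operator()(double lt) const {
    double theta = std::exp(lt);
    irls(theta);
    double ll = loglik(theta);
    if (adjust) {
      arma::vec mu = arma::exp(arma::clamp(X * beta + off, -ETA_MAX, ETA_MAX));
      arma::vec w = mu * theta / (mu + theta);
      arma::mat info = X.t() * (X.each_col() % w);
      double ldet, sign;
      arma::log_det(ldet, sign, info);
      if (sign > 0) ll -= 0.5 * ldet;
    }
    return std::isfinite(ll) ? -ll : 1e10;
  }
};

// golden-section minimization of a 1-D function on [lo, hi]
template <typename F>
static double golden_min(const F& f, double lo, double hi, double tol) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = f(c), fd = f(d);
  while (std::fabs(b - a) > tol) {
    if (fc < fd) { b = d; d = c; fd = fc; c = b - gr * (b - a); fc = f(c); }
    else { a = c; c = d; fc = fd; d = a + gr * (b - a); fd = f(d); }
  }
  return 0.5 * (a + b);
}

// [[Rcpp::export]]
List cpp_fit_nb_glm(arma::vec y, arma::vec x, arma::vec off,
                    bool cox_reid = true) {
  const arma::uword n = y.n_elem;
  arma::mat X(n, 2);
  X.col(0).ones();
  X.col(1) = x;

  if (arma::accu(y) <= 0.0) {
    return List::create(_["beta"] = NumericVector::create(NA_REAL, NA_REAL),
                        _["se"] = NumericVector::create(NA_REAL, NA_REAL),
                        _["theta"] = NA_REAL, _["loglik"] = NA_REAL,
                        _["converged"] = false, _["n_iter"] = 0);
  }

  GlmProfile prof{y, X, off, cox_reid, poisson_irls(y, x, off)};
  double ltheta = golden_min(prof, LT_LO, LT_HI, 1e-8);
  double theta = std::exp(ltheta);
  prof.irls(theta);
  arma::vec beta = prof.beta;
  double ll = prof.loglik(theta);

  // expected information at fixed theta (glm.nb convention)
  arma::vec mu = arma::exp(arma::clamp(X * beta + off, -ETA_MAX, ETA_MAX));
  arma::vec w = mu * theta / (mu + theta);
  arma::mat Xw = X.each_col() % w;
  arma::mat info = X.t() * Xw;
  arma::vec se(2);
  se.fill(NA_REAL);
  arma::mat cov;
  if (arma::inv_sympd(cov, info) || arma::inv(cov, info)) {
    if (cov(0, 0) > 0) se[0] = std::sqrt(cov(0, 0));
    if (cov(1, 1) > 0) se[1] = std::sqrt(cov(1, 1));
  }
  bool converged = !prof.solve_failed && std::isfinite(ll) &&
    std::max(std::fabs(beta[0]), std::fabs(beta[1])) < 49.0 &&
    std::isfinite(se[1]);

  return List::create(_["beta"] = NumericVector::create(beta[0], beta[1]),
                      _["se"] = NumericVector::create(se[0], se[1]),
                      _["theta"] = theta, _["loglik"] = ll,
                      _["converged"] = converged, _["n_iter"] = 1);
}

// ---------------------------------------------------------------------------
// Laplace NB GLMM with a single random intercept term.
// ---------------------------------------------------------------------------

struct GlmmObj {
  const arma::vec& y;
  const arma::vec& x;
  const arma::vec& off;
  const std::vector<std::vector<arma::uword>>& gidx;
  bool fix_sigma0;

  // Newton solve for one group's conditional mode; h(b) is strictly concave.
  double bhat(const std::vector<arma::uword>& idx, const arma::vec& eta0,
              double theta, double sigma2, double& negH, double& llmode) const {
    double b = 0.0;
    for (int it = 0; it < 80; ++it) {
      double g = -b / sigma2, H = -1.0 / sigma2;
      for (arma::uword j : idx) {
        double eta = clampd(eta0[j] + b, -ETA_MAX, ETA_MAX);
        double mu = std::exp(eta);
        double tm = theta + mu;
        g += y[j] - mu * (y[j] + theta) / tm;
        H -= mu * theta * (y[j] + theta) / (tm * tm);
      }
      double step = clampd(-g / H, -4.0, 4.0);
      b += step;
      if (std::fabs(g) < 1e-11 || std::fabs(step) < 1e-13) break;
    }
    double H = -1.0 / sigma2;
    llmode = 0.0;
    for (arma::uword j : idx) {
      double eta = clampd(eta0[j] + b, -ETA_MAX, ETA_MAX);
      double mu = std::exp(eta);
      double tm = theta + mu;
      H -= mu * theta * (y[j] + theta) / (tm * tm);
      llmode += nb_ll1(y[j], mu, theta);
    }
    negH = -H;
    return b;
  }

  // negative Laplace marginal log-likelihood (plus a soft box penalty)
  double operator()(const arma::vec& p) const {
    if (!p.is_finite()) return 1e10;
    double b0 = p[0], b1 = p[1];
    if (std::fabs(b0) > 45.0 || std::fabs(b1) > 45.0) return 1e10;
    double lt = p[2];
    double ltc = clampd(lt, LT_LO, LT_HI);
    double pen = 1e-2 * (lt - ltc) * (lt - ltc);
    double theta = std::exp(ltc);
    arma::vec eta0 = b0 + b1 * x + off;
    double ll = 0.0;
    if (fix_sigma0) {
      for (arma::uword j = 0; j < y.n_elem; ++j) {
        double mu = std::exp(clampd(eta0[j], -ETA_MAX, ETA_MAX));
        ll += nb_ll1(y[j], mu, theta);
      }
    } else {
      double ls = p[3];
      double lsc = clampd(ls, LS_LO, LS_HI);
      pen += 1e-2 * (ls - lsc) * (ls - lsc);
      double s2 = std::exp(lsc);
      for (const auto& idx : gidx) {
        double negH, llm;
        double b = bhat(idx, eta0, theta, s2, negH, llm);
        ll += llm - b * b / (2.0 * s2) - 0.5 * std::log(s2) - 0.5 * std::log(negH);
      }
    }
    if (!std::isfinite(ll)) return 1e10;
    return -ll + pen;
  }
};

typedef std::function<double(const arma::vec&)> ObjFun;

static arma::vec nelder_mead(const ObjFun& f, arma::vec p0, double step,
                             int maxeval, double tol, double& fbest, int& neval) {
  const int n = p0.n_elem;
  std::vector<arma::vec> S(n + 1, p0);
  arma::vec fv(n + 1);
  for (int i = 1; i <= n; ++i) S[i][i - 1] += step;
  neval = 0;
  for (int i = 0; i <= n; ++i) { fv[i] = f(S[i]); ++neval; }

  while (neval < maxeval) {
    // sort simplex by function value
    arma::uvec ord = arma::sort_index(fv);
    std::vector<arma::vec> S2(n + 1);
    arma::vec fv2(n + 1);
    for (int i = 0; i <= n; ++i) { S2[i] = S[ord[i]]; fv2[i] = fv[ord[i]]; }
    S = S2; fv = fv2;
    if (fv[n] - fv[0] < tol * (1.0 + std::fabs(fv[0]))) break;

    arma::vec cen = arma::zeros<arma::vec>(n);
    for (int i = 0; i < n; ++i) cen += S[i];
    cen /= n;

    arma::vec xr = cen + (cen - S[n]);       // reflection
    double fr = f(xr); ++neval;
    if (fr < fv[0]) {
      arma::vec xe = cen + 2.0 * (cen - S[n]);  // expansion
      double fe = f(xe); ++neval;
      if (fe < fr) { S[n] = xe; fv[n] = fe; } else { S[n] = xr; fv[n] = fr; }
    } else if (fr < fv[n - 1]) {
      S[n] = xr; fv[n] = fr;
    } else {
      arma::vec xc = cen + 0.5 * (S[n] - cen);  // contraction
      double fc = f(xc); ++neval;
      if (fc < fv[n]) {
        S[n] = xc; fv[n] = fc;
      } else {
        for (int i = 1; i <= n; ++i) {          // shrink
          S[i] = S[0] + 0.5 * (S[i] - S[0]);
          fv[i] = f(S[i]); ++neval;
        }
      }
    }
  }
  arma::uword ib = fv.index_min();
  fbest = fv[ib];
  return S[ib];
}

static arma::vec fd_grad(const ObjFun& f, const arma::vec& p, int& neval) {
  const int n = p.n_elem;
  arma::vec g(n);
  for (int i = 0; i < n; ++i) {
    double h = 3e-5 * std::max(1.0, std::fabs(p[i]));
    arma::vec pp = p, pm = p;
    pp[i] += h; pm[i] -= h;
    g[i] = (f(pp) - f(pm)) / (2.0 * h);
    neval += 2;
  }
  return g;
}

static arma::mat fd_hess(const ObjFun& f, const arma::vec& p, int& neval) {
  const int n = p.n_elem;
  arma::mat H(n, n);
  arma::vec h(n);
  for (int i = 0; i < n; ++i) h[i] = 1e-3 * std::max(1.0, std::fabs(p[i]));
  double f0 = f(p); ++neval;
  for (int i = 0; i < n; ++i) {
    arma::vec pp = p, pm = p;
    pp[i] += h[i]; pm[i] -= h[i];
    double fp = f(pp), fm = f(pm);
    neval += 2;
    H(i, i) = (fp - 2.0 * f0 + fm) / (h[i] * h[i]);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      arma::vec a = p, b = p, c = p, d = p;
      a[i] += h[i]; a[j] += h[j];
      b[i] += h[i]; b[j] -= h[j];
      c[i] -= h[i]; c[j] += h[j];
      d[i] -= h[i]; d[j] -= h[j];
      H(i, j) = H(j, i) = (f(a) - f(b) - f(c) + f(d)) / (4.0 * h[i] * h[j]);
      neval += 4;
    }
  }
  return H;
}

// [[Rcpp::export]]
List cpp_fit_nb_glmm(arma::vec y, arma::vec x, arma::vec off, arma::uvec grp,
                     bool fix_sigma0, double sigma2_init = 0.1,
                     int max_outer = 200, int nm_maxeval = 400) {
  const arma::uword n = y.n_elem;

  std::vector<std::vector<arma::uword>> gidx;
  if (!fix_sigma0) {
    arma::uword K = grp.max() + 1;
    gidx.resize(K);
    for (arma::uword j = 0; j < n; ++j) gidx[grp[j]].push_back(j);
  }
  GlmmObj obj{y, x, off, gidx, fix_sigma0};
  ObjFun f = [&obj](const arma::vec& p) { return obj(p); };

  // deterministic initialization: Poisson GLM beta, moment theta, sigma2_init
  arma::vec beta0 = poisson_irls(y, x, off);
  arma::mat X(n, 2);
  X.col(0).ones();
  X.col(1) = x;
  arma::vec mu0 = arma::exp(arma::clamp(X * beta0 + off, -ETA_MAX, ETA_MAX));
  double lt0 = clampd(std::log(theta_moments(y, mu0)), LT_LO, LT_HI);

  const int np = fix_sigma0 ? 3 : 4;
  arma::vec p(np);
  p[0] = beta0[0]; p[1] = beta0[1]; p[2] = lt0;
  if (!fix_sigma0) p[3] = std::log(sigma2_init);

  double fbest;
  int neval = 0;
  p = nelder_mead(f, p, 0.3, nm_maxeval, 1e-12, fbest, neval);

  // Newton polish on finite-difference derivatives
  bool converged = false;
  int it = 0;
  double f0 = f(p);
  for (; it < max_outer; ++it) {
    arma::vec g = fd_grad(f, p, neval);
    if (!g.is_finite()) break;
    if (arma::norm(g, 2) < 1e-6 * std::max(1.0, std::fabs(f0))) {
      converged = true;
      break;
    }
    arma::mat H = fd_hess(f, p, neval);
    arma::vec d;
    if (!arma::solve(d, H, -g) || !d.is_finite()) d = -g;
    if (arma::dot(d, g) > 0) d = -g;  // ensure descent direction
    double t = 1.0;
    bool improved = false;
    for (int ls = 0; ls < 30; ++ls) {
      arma::vec pn = p + t * d;
      double fn = f(pn);
      if (std::isfinite(fn) && fn < f0 - 1e-13) {
        p = pn; f0 = fn; improved = true;
        break;
      }
      t *= 0.5;
    }
    if (!improved) {
      converged = arma::norm(g, 2) < 1e-5 * std::max(1.0, std::fabs(f0));
      break;
    }
  }

  double theta = std::exp(clampd(p[2], LT_LO, LT_HI));
  double sigma2 = fix_sigma0 ? 0.0 : std::exp(clampd(p[3], LS_LO, LS_HI));
  bool boundary = (!fix_sigma0) && (sigma2 <= 1.2e-8);

  // observed-information standard errors
  arma::vec se(2);
  se.fill(NA_REAL);
  if (!boundary) {
    arma::mat H = fd_hess(f, p, neval);
    arma::mat cov;
    bool ok = arma::inv_sympd(cov, H);
    if (!ok) ok = arma::pinv(cov, H);
    if (ok) {
      if (cov(0, 0) > 0) se[0] = std::sqrt(cov(0, 0));
      if (cov(1, 1) > 0) se[1] = std::sqrt(cov(1, 1));
    }
    if (!std::isfinite(se[1])) converged = false;
  }

  return List::create(_["beta"] = NumericVector::create(p[0], p[1]),
                      _["se"] = NumericVector::create(se[0], se[1]),
                      _["theta"] = theta, _["sigma2"] = sigma2,
                      _["loglik"] = -f0, _["converged"] = converged,
                      _["n_iter"] = neval, _["boundary"] = boundary);
}
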