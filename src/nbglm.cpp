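// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Per-taxon negative-binomial GLM (log link, fixed offset) sharing one design
// matrix, as in multivariate community models: IRLS for the coefficients
// alternating with Newton maximum-likelihood updates of the dispersion, with
// a method-of-moments fallback when the ML update fails. theta is the NB
// size; the reported dispersion is 1/theta (0 in the Poisson limit).

static const double TH_MIN = 1e-3, TH_MAX = 1e5;

static double nb_loglik(const arma::vec &y, const arma::vec &mu, double th) {
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double m = std::max(mu[i], 1e-12);
    ll += R::lgammafn(y[i] + th) - R::lgammafn(th) - R::lgammafn(y[i] + 1.0)
        + th * std::log(th / (th + m));
    if (y[i] > 0) ll += y[i] * std::log(m / (th + m));
  }
  return ll;
}

static double theta_mom(const arma::vec &y, const arma::vec &mu) {
  double num = arma::accu(arma::square(mu));
  double den = arma::accu(arma::square(y - mu) - mu);
  if (den <= 1e-10 || num <= 0) return TH_MAX;
  return std::min(std::max(num / den, TH_MIN), TH_MAX);
}

static double theta_ml(const arma::vec &y, const arma::vec &mu,
                       double th0, bool &ok) {
  double th = std::min(std::max(th0, TH_MIN), TH_MAX);
  ok = true;
  for (int it = 0; it < 30; ++it) {
    const double dg_th = R::digamma(th), tg_th = R::trigamma(th);
    const double log_th = std::log(th), inv_th = 1.0 / th;
    double sc = 0.0, info = 0.0;
    for (arma::uword i = 0; i < y.n_elem; ++i) {
      double m = std::max(mu[i], 1e-12);
      sc += R::digamma(y[i] + th) - dg_th + log_th + 1.0
          - std::log(th + m) - (y[i] + th) / (th + m);
      info += -R::trigamma(y[i] + th) + tg_th - inv_th
            + 2.0 / (th + m) - (y[i] + th) / ((th + m) * (th + m));
    }
    if (!std::isfinite(sc) || !std::isfinite(info) || info <= 0) {
      ok = false; return th;
    }
    double step = sc / info;
    double thn = th + step;
    if (!std::isfinite(thn)) { ok = false; return th; }
    thn = std::min(std::max(thn, TH_MIN), TH_MAX);
    if (std::fabs(thn - th) < 1e-8 * (th + 1e-8)) return thn;
    th = thn;
  }
  return th;
}

static double theta_score(const arma::vec &y, const arma::vec &mu,
                          double th) {
  const double dg_th = R::digamma(th), log_th = std::log(th);
  double sc = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double m = std::max(mu[i], 1e-12);
    sc += R::digamma(y[i] + th) - dg_th + log_th + 1.0
        - std::log(th + m) - (y[i] + th) / (th + m);
  }
  return sc;
}

// bracketed bisection on the profile score in log-theta, for the cases where
// the Newton step runs into non-positive observed information
static double theta_bisect(const arma::vec &y, const arma::vec &mu) {
  double lo = std::log(TH_MIN), hi = std::log(TH_MAX);
  double slo = theta_score(y, mu, std::exp(lo));
  double shi = theta_score(y, mu, std::exp(hi));
  if (slo <= 0) return TH_MIN;   // score negative everywhere: boundary
  if (shi >= 0) return TH_MAX;   // score positive everywhere: Poisson limit
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    double smid = theta_score(y, mu, std::exp(mid));
    if (smid > 0) lo = mid; else hi = mid;
    if (hi - lo < 1e-10) break;
  }
  return std::exp(0.5 * (lo + hi));
}

struct NbFit {
  arma::vec beta, se;
  double theta, loglik;
  bool fallback, zero, converged;
};

static NbFit nb_fit_one(const arma::vec &y, const arma::mat &X,
                        const arma::vec &offset) {
  const arma::uword n = y.n_elem, p = X.n_cols;
  NbFit fit; fit.beta.zeros(p); fit.se.zeros(p);
  fit.theta = TH_MAX; fit.loglik = 0.0;
  fit.fallback = false; fit.zero = false; fit.converged = true;
  if (arma::accu(y) <= 0) { fit.zero = true; return fit; }

  arma::vec mu = y + arma::mean(y) * 0.5 + 0.1;
  arma::vec eta = arma::log(mu) - offset;
  arma::vec beta(p, arma::fill::zeros);
  double th = 10.0, ll_old = -1e300;

  for (int outer = 0; outer < 40; ++outer) {
    // IRLS step for beta given theta
    for (int inner = 0; inner < 3; ++inner) {
      arma::vec w = mu / (1.0 + mu / th);
      arma::vec z = eta + (y - mu) / mu;
      arma::mat Xw = X.each_col() % w;
      arma::mat A = X.t() * Xw;
      arma::vec b = X.t() * (w % z);
      arma::vec bn;
      if (!arma::solve(bn, A, b, arma::solve_opts::no_approx)) {
        bn = arma::pinv(A) * b;
      }
      beta = bn;
      eta = X * beta;
      eta = arma::clamp(eta + offset, -30.0, 30.0) - offset;
      mu = arma::exp(eta + offset);
      mu = arma::clamp(mu, 1e-10, 1e10);
    }
    if (outer == 0) th = theta_mom(y, mu);
    bool ok = true;
    double th_new = theta_ml(y, mu, th, ok);
    if (!ok) {
      double th_bis = theta_bisect(y, mu);
      double th_mom = theta_mom(y, mu);
      // keep whichever estimate profiles best; flag when moments win
      double cand[3] = {th_new, th_bis, th_mom};
      double best_ll = -1e300; int best = 0;
      for (int c = 0; c < 3; ++c) {
        double ll_c = nb_loglik(y, mu, cand[c]);
        if (ll_c > best_ll) { best_ll = ll_c; best = c; }
      }
      th_new = cand[best];
      if (best == 2) fit.fallback = true;
    }
    th = th_new;
    double ll = nb_loglik(y, mu, th);
    if (std::fabs(ll - ll_old) < 1e-7 * (std::fabs(ll) + 1e-7)) {
      ll_old = ll; break;
    }
    ll_old = ll;
    if (outer == 39) fit.converged = false;
  }
  arma::vec w = mu / (1.0 + mu / th);
  arma::mat A = X.t() * (X.each_col() % w);
  arma::mat Ai;
  if (!arma::inv_sympd(Ai, A)) Ai = arma::pinv(A);
  fit.beta = beta;
  fit.se = arma::sqrt(arma::clamp(Ai.diag(), 0.0, arma::datum::inf));
  fit.theta = th;
  fit.loglik = ll_old;
  return fit;
}

// [[Rcpp::export]]
List nb_glm_fit_cpp(const arma::mat &Y, const arma::mat &X,
                    const arma::vec &offset) {
  const arma::uword K = Y.n_cols, p = X.n_cols;
  arma::mat beta(p, K, arma::fill::zeros), se(p, K, arma::fill::zeros);
  arma::vec theta(K), loglik(K);
  LogicalVector fallback(K), zero(K), converged(K);
  for (arma::uword k = 0; k < K; ++k) {
    NbFit f = nb_fit_one(Y.col(k), X, offset);
    beta.col(k) = f.beta; se.col(k) = f.se;
    theta[k] = f.theta; loglik[k] = f.loglik;
    fallback[k] = f.fallback; zero[k] = f.zero; converged[k] = f.converged;
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["theta"] = theta,
                      _["loglik"] = loglik, _["fallback"] = fallback,
                      _["zero"] = zero, _["converged"] = converged);
}

// Parametric-bootstrap likelihood-ratio test: observed per-taxon LR of full
// vs reduced, plus B resampled multivariate LR statistics drawn from the
// fitted reduced model (NB with its theta). Uses R's RNG.
// [[Rcpp::export]]
List nb_lrt_boot_cpp(const arma::mat &Y, const arma::mat &Xf,
                     const arma::mat &Xr, const arma::vec &offset, int B) {
  const arma::uword n = Y.n_rows, K = Y.n_cols;
  arma::vec lr_obs(K, arma::fill::zeros);
  arma::mat mu_red(n, K, arma::fill::zeros);
  arma::vec th_red(K, arma::fill::ones);
  for (arma::uword k = 0; k < K; ++k) {
    NbFit ff = nb_fit_one(Y.col(k), Xf, offset);
    NbFit fr = nb_fit_one(Y.col(k), Xr, offset);
    if (ff.zero || fr.zero) continue;
    lr_obs[k] = std::max(0.0, 2.0 * (ff.loglik - fr.loglik));
    mu_red.col(k) = arma::exp(arma::clamp(Xr * fr.beta + offset, -30.0, 30.0));
    th_red[k] = fr.theta;
  }
  arma::vec lr_boot(B, arma::fill::zeros);
  arma::vec ysim(n);
  for (int b = 0; b < B; ++b) {
    double tot = 0.0;
    for (arma::uword k = 0; k < K; ++k) {
      if (arma::accu(mu_red.col(k)) <= 0) continue;
      for (arma::uword i = 0; i < n; ++i) {
        // NB(mu, theta) as a gamma-Poisson mixture
        double lam = R::rgamma(th_red[k], mu_red(i, k) / th_red[k]);
        ysim[i] = R::rpois(lam);
      }
      if (arma::accu(ysim) <= 0) continue;
      NbFit ff = nb_fit_one(ysim, Xf, offset);
      NbFit fr = nb_fit_one(ysim, Xr, offset);
      tot += std::max(0.0, 2.0 * (ff.loglik - fr.loglik));
    }
    lr_boot[b] = tot;
    if (b % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["lr_obs"] = lr_obs, _["lr_boot"] = lr_boot,
                      _["theta_red"] = th_red);
}
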