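#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double plogis_(double x) {
  if (x > 35.0) return 1.0;
  if (x < -35.0) return std::exp(x);
  return 1.0 / (1.0 + std::exp(-x));
}

// Weighted Bernoulli log-likelihood of one cluster at random intercept u.
static double cluster_ll_at(const double* eta, const double* y, const double* w,
                            int len, double u) {
  double ll = 0.0;
  for (int i = 0; i < len; i++) {
    double e = eta[i] + u;
    ll += w[i] * (y[i] * e - log1pexp_(e));
  }
  return ll;
}

// Marginal log-likelihood contribution of one cluster, integrating the
// random intercept u ~ N(0, sigma^2) by adaptive Gauss-Hermite quadrature
// centred at the conditional mode (Newton steps) and scaled by the
// conditional curvature.
static double cluster_marginal_ll(const double* eta, const double* y,
                                  const double* w, int len, double sigma,
                                  const double* ghx, const double* ghlw,
                                  int ngh) {
  if (sigma < 1e-10) return cluster_ll_at(eta, y, w, len, 0.0);
  const double inv_s2 = 1.0 / (sigma * sigma);
  // Newton search for the mode of f(u) = sum_i w_i ll_i(u) - u^2/(2 sigma^2)
  double u = 0.0;
  for (int it = 0; it < 30; it++) {
    double g = -u * inv_s2, h = -inv_s2;
    for (int i = 0; i < len; i++) {
      double p = plogis_(eta[i] + u);
      g += w[i] * (y[i] - p);
      h -= w[i] * p * (1.0 - p);
    }
    double step = g / h;
    u -= step;
    if (std::fabs(step) < 1e-10) break;
  }
  double h = -inv_s2;
  for (int i = 0; i < len; i++) {
    double p = plogis_(eta[i] + u);
    h -= w[i] * p * (1.0 - p);
  }
  double tau = 1.0 / std::sqrt(-h);
  const double SQRT2 = 1.4142135623730951;
  const double LOG_SQRT_2PI = 0.9189385332046727;
  // log integrand includes the N(0, sigma^2) density of u
  double m = R_NegInf;
  std::vector<double> terms(ngh);
  for (int k = 0; k < ngh; k++) {
    double uk = u + SQRT2 * tau * ghx[k];
    double f = cluster_ll_at(eta, y, w, len, uk)
      - 0.5 * uk * uk * inv_s2 - std::log(sigma) - LOG_SQRT_2PI;
    terms[k] = ghlw[k] + ghx[k] * ghx[k] + f;
    if (terms[k] > m) m = terms[k];
  }
  double s = 0.0;
  for (int k = 0; k < ngh; k++) s += std::exp(terms[k] - m);
  return std::log(SQRT2 * tau) + m + std::log(s);
}

// [[Rcpp::export]]
double agq_loglik_cpp(NumericVector eta, NumericVector y, NumericVector w,
                      IntegerVector cl_start, IntegerVector cl_len,
                      double sigma, NumericVector gh_x, NumericVector gh_logw) {
  int m = cl_start.size();
  double ll = 0.0;
  for (int j = 0; j < m; j++) {
    ll += cluster_marginal_ll(&eta[cl_start[j]], &y[cl_start[j]],
                              &w[cl_start[j]], cl_len[j], sigma,
                              &gh_x[0], &gh_logw[0], gh_x.size());
  }
  return ll;
}

struct PostArgs {
  const NumericMatrix& X;
  const NumericVector& y;
  const NumericVector& w;
  const IntegerVector& cl_start;
  const IntegerVector& cl_len;
  const NumericVector& prior_mean;
  const NumericVector& prior_var;
  double sigma_prior_scale;
  bool sample_sigma;
  const NumericVector& gh_x;
  const NumericVector& gh_logw;
};

// Log posterior (weighted pseudo-likelihood x prior) at theta = (beta, log sigma_u).
static double log_post(const std::vector<double>& theta, const PostArgs& a) {
  int n = a.X.nrow(), p = a.X.ncol();
  std::vector<double> eta(n, 0.0);
  for (int k = 0; k < p; k++) {
    double b = theta[k];
    if (b == 0.0) continue;
    const double* col = &a.X(0, k);
    for (int i = 0; i < n; i++) eta[i] += col[i] * b;
  }
  double ll = 0.0;
  int m = a.cl_start.size();
  double sigma = a.sample_sigma ? std::exp(theta[p]) : 0.0;
  for (int j = 0; j < m; j++) {
    ll += cluster_marginal_ll(&eta[a.cl_start[j]], &a.y[a.cl_start[j]],
                              &a.w[a.cl_start[j]], a.cl_len[j], sigma,
                              &a.gh_x[0], &a.gh_logw[0], a.gh_x.size());
  }
  double lp = 0.0;
  for (int k = 0; k < p; k++) {
    double d = theta[k] - a.prior_mean[k];
    lp += -0.5 * d * d / a.prior_var[k] - 0.5 * std::log(a.prior_var[k]);
  }
  if (a.sample_sigma) {
    // Half-Normal(0, scale^2) on sigma, plus the log-scale Jacobian
    double sc = a.sigma_prior_scale;
    lp += -0.5 * sigma * sigma / (sc * sc) + std::log(sigma);
  }
  return ll + lp;
}

// Random-walk Metropolis with a fixed (pre-estimated) proposal shape and a
// global step scale adapted during burn-in only (Robbins-Monro toward a
// 0.234 acceptance rate), frozen afterwards so the kept chain is Markov.
// [[Rcpp::export]]
List rwm_sample_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                    IntegerVector cl_start, IntegerVector cl_len,
                    NumericVector prior_mean, NumericVector prior_var,
                    double sigma_prior_scale, NumericVector init,
                    NumericMatrix prop_chol, int n_burnin, int n_keep,
                    int thin, bool sample_sigma,
                    NumericVector gh_x, NumericVector gh_logw) {
  PostArgs a{X, y, w, cl_start, cl_len, prior_mean, prior_var,
             sigma_prior_scale, sample_sigma, gh_x, gh_logw};
  int d = init.size();
  std::vector<double> theta(init.begin(), init.end());
  double lp = log_post(theta, a);
  if (!R_finite(lp)) stop("log posterior is not finite at the initial value");
  double log_scale = 0.0;
  const double target = (d > 1) ? 0.234 : 0.44;
  NumericMatrix draws(n_keep, d);
  std::vector<double> prop(d), z(d);
  int n_total = n_burnin + n_keep * thin;
  long accepted = 0, counted = 0;
  GetRNGstate();
  for (int it = 0; it < n_total; it++) {
    double s = std::exp(log_scale);
    for (int k = 0; k < d; k++) z[k] = norm_rand();
    // prop = theta + s * L z  (L lower-triangular)
    for (int k = 0; k < d; k++) {
      double acc = 0.0;
      for (int l = 0; l <= k; l++) acc += prop_chol(k, l) * z[l];
      prop[k] = theta[k] + s * acc;
    }
    double lp_new = log_post(prop, a);
    bool acc_move = R_finite(lp_new) &&
      (lp_new - lp > std::log(unif_rand()));
    if (acc_move) { theta = prop; lp = lp_new; }
    if (it < n_burnin) {
      double gamma = 1.0 / std::sqrt((double)(it + 1));
      log_scale += gamma * ((acc_move ? 1.0 : 0.0) - target);
      if (log_scale < -8) log_scale = -8;
      if (log_scale > 4) log_scale = 4;
    } else {
      counted++;
      if (acc_move) accepted++;
      int post = it - n_burnin;
      if ((post + 1) % thin == 0) {
        int row = post / thin;
        for (int k = 0; k < d; k++) draws(row, k) = theta[k];
      }
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  if (sample_sigma) {
    for (int r = 0; r < n_keep; r++) draws(r, d - 1) = std::exp(draws(r, d - 1));
  }
  return List::create(_["draws"] = draws,
                      _["accept_rate"] = counted ? (double)accepted / counted : NA_REAL,
                      _["step_scale"] = std::exp(log_scale));
}
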