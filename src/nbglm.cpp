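// Negative binomial GLM engine: per-gene IRLS with log link and offsets,
// Cox-Reid adjusted profile likelihood for the dispersion, Wald contrasts.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double ETA_MAX = 30.0;

// NB log-likelihood with dispersion alpha (size = 1/alpha), means mu.
static double nb_loglik(const vec &y, const vec &mu, double alpha) {
  const double k = 1.0 / alpha;
  double ll = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    const double m = mu[i];
    ll += R::lgammafn(y[i] + k) - R::lgammafn(k) - R::lgammafn(y[i] + 1.0) +
          k * std::log(k / (k + m)) + y[i] * std::log(m / (k + m));
  }
  return ll;
}

// Ridge-stabilised IRLS; on return XtWX holds X'WX + ridge*I at the optimum.
static bool irls_fit(const mat &X, const vec &y, const vec &off, double alpha,
                     double ridge, vec &beta, vec &mu, mat &XtWX,
                     int maxit = 50, double tol = 1e-9) {
  vec eta = clamp(X * beta + off, -ETA_MAX, ETA_MAX);
  mu = exp(eta);
  for (int it = 0; it < maxit; ++it) {
    vec w = mu / (1.0 + alpha * mu);
    vec z = (eta - off) + (y - mu) / mu;
    mat A = X.t() * (X.each_col() % w);
    A.diag() += ridge;
    vec b = X.t() * (w % z);
    vec beta_new;
    if (!solve(beta_new, A, b, solve_opts::no_approx)) return false;
    if (!beta_new.is_finite()) return false;
    const double delta = max(abs(beta_new - beta));
    beta = beta_new;
    eta = clamp(X * beta + off, -ETA_MAX, ETA_MAX);
    mu = exp(eta);
    if (delta < tol) break;
  }
  vec w = mu / (1.0 + alpha * mu);
  XtWX = X.t() * (X.each_col() % w);
  XtWX.diag() += ridge;
  return beta.is_finite();
}

// Cox-Reid adjusted profile log-likelihood at log-dispersion lalpha.
// beta is used as a warm start and updated in place.
static double cr_profile(const mat &X, const vec &y, const vec &off,
                         double lalpha, double ridge, vec &beta) {
  const double alpha = std::exp(lalpha);
  vec mu;
  mat XtWX;
  vec b = beta;
  if (!irls_fit(X, y, off, alpha, ridge, b, mu, XtWX, 25, 1e-8))
    return -datum::inf;
  beta = b;
  double ldet, sign;
  if (!log_det(ldet, sign, XtWX) || sign <= 0) return -datum::inf;
  return nb_loglik(y, mu, alpha) - 0.5 * ldet;
}

// Golden-section maximisation of the CR profile over log alpha.
static double golden_max(const mat &X, const vec &y, const vec &off,
                         double lo, double hi, double ridge, vec &beta,
                         bool &ok) {
  const double phi = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double x1 = b - phi * (b - a), x2 = a + phi * (b - a);
  double f1 = cr_profile(X, y, off, x1, ridge, beta);
  double f2 = cr_profile(X, y, off, x2, ridge, beta);
  double flo = cr_profile(X, y, off, lo, ridge, beta);
  double fhi = cr_profile(X, y, off, hi, ridge, beta);
  ok = std::isfinite(f1) || std::isfinite(f2) || std::isfinite(flo) ||
       std::isfinite(fhi);
  if (!ok) return lo;
  for (int it = 0; it < 35; ++it) {
    if (f1 >= f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - phi * (b - a);
      f1 = cr_profile(X, y, off, x1, ridge, beta);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + phi * (b - a);
      f2 = cr_profile(X, y, off, x2, ridge, beta);
    }
  }
  double best = (f1 >= f2) ? x1 : x2, fbest = std::max(f1, f2);
  if (flo > fbest) { best = lo; fbest = flo; }
  if (fhi > fbest) { best = hi; }
  return best;
}

// Method-of-moments dispersion from size-factor-normalised counts.
static double mom_alpha(const vec &y, const vec &sf, double amin, double amax) {
  vec q = y / sf;
  const double m = mean(q);
  if (m <= 0) return amin;
  const double v = var(q);
  double a = (v - m) / (m * m);
  if (!std::isfinite(a)) a = amin;
  return std::min(std::max(a, amin), amax);
}

// counts: genes x samples; X: design; logsf: per-sample log size factors;
// Cmat: design-width x n_contrast matrix of contrast coefficients;
// alpha_fixed: per-gene dispersion (NA => estimate by CR-adjusted MLE).
// Estimates and SEs are returned in log2 units; Wald stat is scale-free.
// [[Rcpp::export]]
Rcpp::List nbglm_fit_cpp(const arma::mat &counts, const arma::mat &X,
                         const arma::vec &logsf, const arma::mat &Cmat,
                         double ridge, double alpha_min, double alpha_max,
                         Rcpp::NumericVector alpha_fixed) {
  const uword G = counts.n_rows, p = X.n_cols, nc = Cmat.n_cols;
  const double L2 = std::log(2.0);
  vec alpha_out(G, fill::value(datum::nan));
  mat beta_out(G, p, fill::value(datum::nan));
  mat est(G, nc, fill::value(datum::nan)), se(G, nc, fill::value(datum::nan)),
      stat(G, nc, fill::value(datum::nan));
  Rcpp::LogicalVector disp_ok(G, true), fit_ok(G, true);
  const vec sf = exp(logsf);
  const double la_min = std::log(alpha_min), la_max = std::log(alpha_max);

  for (uword g = 0; g < G; ++g) {
    const vec y = counts.row(g).t();
    vec beta(p, fill::zeros);
    beta[0] = std::log(mean(y / sf) + 0.1);

    double ah;
    if (!Rcpp::NumericVector::is_na(alpha_fixed[g])) {
      ah = alpha_fixed[g];
    } else {
      bool ok = false;
      const double lbest = golden_max(X, y, logsf, la_min, la_max, ridge,
                                      beta, ok);
      if (ok) {
        ah = std::exp(lbest);
      } else {
        ah = mom_alpha(y, sf, alpha_min, alpha_max);
        disp_ok[g] = false;
      }
    }
    alpha_out[g] = ah;

    vec mu;
    mat XtWX;
    if (!irls_fit(X, y, logsf, ah, ridge, beta, mu, XtWX, 100, 1e-10)) {
      fit_ok[g] = false;
      continue;
    }
    mat cov;
    if (!inv_sympd(cov, XtWX)) {
      if (!inv(cov, XtWX)) { fit_ok[g] = false; continue; }
    }
    beta_out.row(g) = beta.t();
    for (uword c = 0; c < nc; ++c) {
      const vec cc = Cmat.col(c);
      const double e = dot(cc, beta);
      const double v = as_scalar(cc.t() * cov * cc);
      if (v <= 0 || !std::isfinite(v)) { fit_ok[g] = false; continue; }
      est(g, c) = e / L2;
      se(g, c) = std::sqrt(v) / L2;
      stat(g, c) = e / std::sqrt(v);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("alpha") = alpha_out, Rcpp::Named("beta") = beta_out,
      Rcpp::Named("est") = est, Rcpp::Named("se") = se,
      Rcpp::Named("stat") = stat, Rcpp::Named("disp_ok") = disp_ok,
      Rcpp::Named("fit_ok") = fit_ok);
}
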