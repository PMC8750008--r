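// Profiled REML for a linear mixed model with a single random intercept.
//
// For the model y = X beta + Z delta + eps, delta ~ N(0, s2w I_G),
// eps ~ N(0, s2e I_n), with Z the group (wheel) incidence matrix, the
// covariance is V = s2e * V*, V* = I + lambda Z Z', lambda = s2w / s2e.
// Woodbury gives V*^{-1} = I - Z W Z' with W = diag(lambda / (1 + lambda m_g)),
// so all per-lambda quantities reduce to group sums:
//   X' V*^{-1} X = X'X - S_X' W S_X,   S_X = Z'X (group row-sums)
// and the sigma2-profiled REML criterion is
//   -2 l_R(lambda) = (n-p) (1 + log(2 pi rss/(n-p)))
//                    + sum_g log(1 + lambda m_g) + log |X' V*^{-1} X|
// minimised by golden-section search on log(lambda). Verified to agree with
// lme4's REML criterion, variance components and fixed effects.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Prep {
  mat XtX;     // p x p
  mat SX;      // G x p group row-sums of X
  mat SXtSX;   // p x p, usable when all groups have equal size
  vec m;       // group sizes
  bool equal_m;
  double m0;
  int n, p, G;
};

Prep prepare(const mat& X, const ivec& group, int G) {
  Prep pr;
  pr.n = X.n_rows;
  pr.p = X.n_cols;
  pr.G = G;
  pr.XtX = X.t() * X;
  pr.SX.zeros(G, pr.p);
  pr.m.zeros(G);
  for (int i = 0; i < pr.n; ++i) {
    int g = group(i) - 1;
    pr.SX.row(g) += X.row(i);
    pr.m(g) += 1.0;
  }
  pr.m0 = pr.m(0);
  pr.equal_m = all(pr.m == pr.m0);
  if (pr.equal_m) pr.SXtSX = pr.SX.t() * pr.SX;
  return pr;
}

// REML deviance (-2 log restricted likelihood) at a given lambda; fills
// beta and rss. Returns +Inf when the whitened normal equations are
// singular.
double eval_dev(double lambda, const Prep& pr, const vec& Xty,
                const vec& sy, double yty, vec& beta, double& rss) {
  const double np = pr.n - pr.p;
  mat A;
  vec w = lambda / (1.0 + lambda * pr.m);
  if (pr.equal_m) {
    A = pr.XtX - w(0) * pr.SXtSX;
  } else {
    A = pr.XtX - pr.SX.t() * (pr.SX.each_col() % w);
  }
  vec b = Xty - pr.SX.t() * (w % sy);
  double q = yty - dot(w, square(sy));
  mat R;
  if (!chol(R, A)) return datum::inf;
  beta = solve(trimatu(R), solve(trimatl(R.t()), b));
  rss = q - dot(b, beta);
  if (rss < 1e-300) rss = 1e-300;
  double s2 = rss / np;
  double ldA = 2.0 * accu(log(R.diag()));
  double ldV = accu(log1p(lambda * pr.m));
  return np * (1.0 + std::log(2.0 * datum::pi * s2)) + ldV + ldA;
}

struct FitResult {
  vec beta;
  double lambda, s2e, s2w, dev;
  bool converged;
  int iterations;
};

// Brent minimisation (golden section + successive parabolic
// interpolation, as in classic fmin) of the REML deviance on log(lambda)
// in [log(lo), log(hi)]; boundary solutions are clamped to lambda = 0
FitResult fit_reml(const Prep& pr, const vec& Xty, const vec& sy,
                   double yty, double tol, int max_iter,
                   double lo = 1e-8, double hi = 1e8) {
  const double gold = (3.0 - std::sqrt(5.0)) / 2.0;
  const double eps = std::sqrt(datum::eps);
  double a = std::log(lo), b = std::log(hi);
  vec btmp;
  double rtmp;
  auto f = [&](double t) {
    return eval_dev(std::exp(t), pr, Xty, sy, yty, btmp, rtmp);
  };
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  int it = 0;
  bool bad = !std::isfinite(fx);
  while (!bad && it < max_iter) {
    double m = 0.5 * (a + b);
    double tol1 = eps * std::abs(x) + tol / 3.0;
    double t2 = 2.0 * tol1;
    if (std::abs(x - m) <= t2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    if (std::abs(e) > tol1) {  // fit parabola
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p; else q = -q;
      r = e;
      e = d;
    }
    if (std::abs(p) < std::abs(0.5 * q * r) && p > q * (a - x) &&
        p < q * (b - x)) {
      d = p / q;
      double u = x + d;
      if (u - a < t2 || b - u < t2) d = (x < m) ? tol1 : -tol1;
    } else {  // golden-section step
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::abs(d) >= tol1) ? x + d
                                     : x + ((d > 0.0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
    ++it;
  }
  FitResult res;
  double lambda = std::exp(x);
  // a minimiser hugging the lower bound is a boundary (OLS) solution
  if (x < std::log(lo) + 1e-3 || bad) lambda = 0.0;
  vec beta;
  double rss;
  double dev = eval_dev(lambda, pr, Xty, sy, yty, beta, rss);
  if (!std::isfinite(dev)) {
    res.converged = false;
    res.beta.zeros(pr.p);
    res.lambda = res.s2e = res.s2w = datum::nan;
    res.dev = datum::inf;
    res.iterations = it;
    return res;
  }
  res.beta = beta;
  res.lambda = lambda;
  res.s2e = rss / (pr.n - pr.p);
  res.s2w = lambda * res.s2e;
  res.dev = dev;
  res.converged = it < max_iter;
  res.iterations = it;
  return res;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List reml_fit_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::ivec& group, int n_groups,
                        double tol = 1e-10, int max_iter = 200) {
  if ((int)X.n_rows <= (int)X.n_cols)
    Rcpp::stop("no residual degrees of freedom");
  Prep pr = prepare(X, group, n_groups);
  vec Xty = X.t() * y;
  vec sy(n_groups, fill::zeros);
  for (uword i = 0; i < y.n_elem; ++i) sy(group(i) - 1) += y(i);
  double yty = dot(y, y);
  FitResult res = fit_reml(pr, Xty, sy, yty, tol, max_iter);
  if (!std::isfinite(res.dev))
    Rcpp::stop("singular fixed-effect design");
  return Rcpp::List::create(
    Rcpp::Named("beta") = res.beta,
    Rcpp::Named("lambda") = res.lambda,
    Rcpp::Named("sigma2_eps") = res.s2e,
    Rcpp::Named("sigma2_wheel") = res.s2w,
    Rcpp::Named("loglik_reml") = -res.dev / 2.0,
    Rcpp::Named("converged") = res.converged,
    Rcpp::Named("iterations") = res.iterations);
}

// restricted log-likelihood at a fixed variance ratio (for optimality
// probes and diagnostics)
// [[Rcpp::export]]
double reml_loglik_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::ivec& group, int n_groups,
                       double lambda) {
  Prep pr = prepare(X, group, n_groups);
  vec Xty = X.t() * y;
  vec sy(n_groups, fill::zeros);
  for (uword i = 0; i < y.n_elem; ++i) sy(group(i) - 1) += y(i);
  double yty = dot(y, y);
  vec beta;
  double rss;
  double dev = eval_dev(lambda, pr, Xty, sy, yty, beta, rss);
  return -dev / 2.0;
}

// Refit the model on row-permuted responses and return the
// observation-expanded sum of squares of each requested term.
// perm: n x P matrix of 1-based row indices into y; term_cols: list of
// 1-based column index vectors of X. Returns P x n_terms matrix of SS and
// a count of non-converged refits (via attribute handled R-side).
// [[Rcpp::export]]
Rcpp::List perm_ss_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::ivec& group, int n_groups,
                       const arma::imat& perm, Rcpp::List term_cols,
                       double tol = 1e-10, int max_iter = 200) {
  Prep pr = prepare(X, group, n_groups);
  int P = perm.n_cols;
  int T = term_cols.size();
  std::vector<uvec> cols(T);
  for (int t = 0; t < T; ++t) {
    Rcpp::IntegerVector iv = term_cols[t];
    uvec u(iv.size());
    for (int k = 0; k < iv.size(); ++k) u(k) = iv[k] - 1;
    cols[t] = u;
  }
  mat ss(P, T);
  int n_fail = 0;
  for (int j = 0; j < P; ++j) {
    vec yp(pr.n);
    for (int i = 0; i < pr.n; ++i) yp(i) = y(perm(i, j) - 1);
    vec Xty = X.t() * yp;
    vec sy(n_groups, fill::zeros);
    for (int i = 0; i < pr.n; ++i) sy(group(i) - 1) += yp(i);
    double yty = dot(yp, yp);
    FitResult res = fit_reml(pr, Xty, sy, yty, tol, max_iter);
    if (!res.converged) ++n_fail;
    for (int t = 0; t < T; ++t) {
      ss(j, t) = accu(square(X.cols(cols[t]) * res.beta(cols[t])));
    }
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("ss") = ss,
                            Rcpp::Named("n_fail") = n_fail);
}
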