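// Core numerics for the proportional-odds (cumulative logit) model:
//   - exact log-likelihood / gradient / Hessian
//   - Newton-Raphson maximum likelihood with step halving
//   - cyclic coordinate descent for the elastic net penalized objective
//       f(theta) = -(1/N) logL + lambda [ w * sum|b| + (1-w)/2 * sum b^2 ]
//     with soft-thresholded proximal Newton steps on the slopes,
//     warm-started along a descending lambda path.
//
// Parameterization: logit P(Y <= j | x) = gamma_j + x' beta, gamma increasing.
// Outcomes are coded 1..K with every category observed (callers collapse
// empty categories first).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sigmoid(double z) {
  if (z >= 0.0) {
    double e = std::exp(-z);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

// minimum admissible category probability: keeps log finite while leaving
// the optimum (where probabilities are bounded away from 0) untouched
static const double PMIN = 1e-12;

static double loglik(const arma::ivec& y, const arma::mat& X,
                     const arma::vec& gamma, const arma::vec& beta) {
  const int n = y.n_elem;
  const int K = gamma.n_elem + 1;
  arma::vec eta(n, arma::fill::zeros);
  if (beta.n_elem > 0) eta = X * beta;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = y[i];
    double A = (k < K) ? sigmoid(gamma[k - 1] + eta[i]) : 1.0;
    double B = (k > 1) ? sigmoid(gamma[k - 2] + eta[i]) : 0.0;
    double p = A - B;
    if (p < PMIN) p = PMIN;
    ll += std::log(p);
  }
  return ll;
}

// gradient and Hessian of logL at (gamma, beta), packed (gamma first)
static void grad_hess(const arma::ivec& y, const arma::mat& X,
                      const arma::vec& gamma, const arma::vec& beta,
                      arma::vec& grad, arma::mat& hess) {
  const int n = y.n_elem;
  const int K = gamma.n_elem + 1;
  const int p = beta.n_elem;
  const int m = (K - 1) + p;
  grad.zeros(m);
  hess.zeros(m, m);
  arma::vec eta(n, arma::fill::zeros);
  if (p > 0) eta = X * beta;
  for (int i = 0; i < n; ++i) {
    int k = y[i];
    double A = (k < K) ? sigmoid(gamma[k - 1] + eta[i]) : 1.0;
    double B = (k > 1) ? sigmoid(gamma[k - 2] + eta[i]) : 0.0;
    double pr = A - B;
    if (pr < PMIN) pr = PMIN;
    double u = A * (1.0 - A);            // sigma'(z1), 0 when k == K
    double v = B * (1.0 - B);            // sigma'(z2), 0 when k == 1
    double up = u * (1.0 - 2.0 * A);
    double vp = v * (1.0 - 2.0 * B);
    double g1 = u / pr;
    double g2 = -v / pr;
    double h11 = up / pr - (u * u) / (pr * pr);
    double h22 = -vp / pr - (v * v) / (pr * pr);
    double h12 = (u * v) / (pr * pr);
    int i1 = (k < K) ? (k - 1) : -1;     // index of gamma_k
    int i2 = (k > 1) ? (k - 2) : -1;     // index of gamma_{k-1}
    if (i1 >= 0) {
      grad[i1] += g1;
      hess(i1, i1) += h11;
    }
    if (i2 >= 0) {
      grad[i2] += g2;
      hess(i2, i2) += h22;
    }
    if (i1 >= 0 && i2 >= 0) {
      hess(i1, i2) += h12;
      hess(i2, i1) += h12;
    }
    if (p > 0) {
      double geta = g1 + g2;
      double heta = h11 + 2.0 * h12 + h22;
      for (int a = 0; a < p; ++a) {
        double xa = X(i, a);
        grad[K - 1 + a] += geta * xa;
        double hg1 = (h11 + h12) * xa;   // d2 l / d gamma_k d beta_a
        double hg2 = (h22 + h12) * xa;   // d2 l / d gamma_{k-1} d beta_a
        if (i1 >= 0) {
          hess(i1, K - 1 + a) += hg1;
          hess(K - 1 + a, i1) += hg1;
        }
        if (i2 >= 0) {
          hess(i2, K - 1 + a) += hg2;
          hess(K - 1 + a, i2) += hg2;
        }
        for (int b = 0; b <= a; ++b) {
          double hab = heta * xa * X(i, b);
          hess(K - 1 + a, K - 1 + b) += hab;
          if (b != a) hess(K - 1 + b, K - 1 + a) += hab;
        }
      }
    }
  }
}

static bool increasing(const arma::vec& g) {
  for (arma::uword j = 1; j < g.n_elem; ++j)
    if (g[j] <= g[j - 1]) return false;
  return true;
}

// intercepts of the intercept-only ML fit: logits of cumulative proportions
static arma::vec start_gamma(const arma::ivec& y, int K) {
  arma::vec cnt(K, arma::fill::zeros);
  for (arma::uword i = 0; i < y.n_elem; ++i) cnt[y[i] - 1] += 1.0;
  double n = (double)y.n_elem;
  arma::vec g(K - 1);
  double cum = 0.0;
  for (int j = 0; j < K - 1; ++j) {
    cum += cnt[j];
    double pj = cum / n;
    // guard: collapsing upstream should prevent 0/1, but stay finite
    pj = std::min(std::max(pj, 1e-10), 1.0 - 1e-10);
    g[j] = std::log(pj / (1.0 - pj));
  }
  // enforce strict increase under extreme ties
  for (int j = 1; j < K - 1; ++j)
    if (g[j] <= g[j - 1]) g[j] = g[j - 1] + 1e-9;
  return g;
}

// [[Rcpp::export(name = ".olr_loglik_cpp")]]
double olr_loglik_cpp(IntegerVector y, NumericMatrix X,
                      NumericVector gamma, NumericVector beta) {
  arma::ivec yy(y.begin(), y.size());
  arma::mat XX(X.begin(), X.nrow(), X.ncol());
  arma::vec gg(gamma.begin(), gamma.size());
  arma::vec bb(beta.begin(), beta.size());
  return loglik(yy, XX, gg, bb);
}

// [[Rcpp::export(name = ".olr_newton_cpp")]]
List olr_newton_cpp(IntegerVector y, NumericMatrix X, int n_cat,
                    double tol, int max_iter) {
  arma::ivec yy(y.begin(), y.size());
  arma::mat XX(X.begin(), X.nrow(), X.ncol());
  const int K = n_cat;
  const int p = XX.n_cols;
  arma::vec gamma = start_gamma(yy, K);
  arma::vec beta(p, arma::fill::zeros);
  double ll = loglik(yy, XX, gamma, beta);
  arma::vec grad;
  arma::mat hess;
  bool converged = false;
  int iter = 0;
  double maxgrad = NA_REAL;
  for (iter = 0; iter < max_iter; ++iter) {
    grad_hess(yy, XX, gamma, beta, grad, hess);
    maxgrad = arma::abs(grad).max();
    if (maxgrad < tol) { converged = true; break; }
    arma::mat nh = -hess;
    arma::vec step;
    bool ok = arma::solve(step, nh, grad, arma::solve_opts::no_approx);
    if (!ok) {
      nh.diag() += 1e-8 * (1.0 + arma::abs(nh.diag()).max());
      arma::solve(step, nh, grad);
    }
    double t = 1.0;
    bool moved = false;
    for (int h = 0; h < 40; ++h) {
      arma::vec g_new = gamma + t * step.head(K - 1);
      arma::vec b_new = beta + t * step.tail(p);
      if (increasing(g_new)) {
        double ll_new = loglik(yy, XX, g_new, b_new);
        if (ll_new >= ll - 1e-12) {
          bool improved = (ll_new > ll + 1e-13);
          gamma = g_new; beta = b_new;
          double rel = std::fabs(ll_new - ll) / (std::fabs(ll) + 1.0);
          ll = ll_new;
          moved = true;
          if (!improved || rel < 1e-13) {
            grad_hess(yy, XX, gamma, beta, grad, hess);
            maxgrad = arma::abs(grad).max();
            converged = (maxgrad < tol) || rel < 1e-13;
          }
          break;
        }
      }
      t *= 0.5;
    }
    if (!moved) { // cannot improve: accept as converged-by-stall if grad small-ish
      grad_hess(yy, XX, gamma, beta, grad, hess);
      maxgrad = arma::abs(grad).max();
      converged = maxgrad < std::sqrt(tol);
      break;
    }
    if (converged) break;
  }
  if (!converged) { // final check after the loop
    grad_hess(yy, XX, gamma, beta, grad, hess);
    maxgrad = arma::abs(grad).max();
    converged = maxgrad < tol;
  }
  return List::create(_["gamma"] = NumericVector(gamma.begin(), gamma.end()),
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["loglik"] = ll,
                      _["converged"] = converged,
                      _["n_iter"] = iter,
                      _["max_grad"] = maxgrad);
}

// elastic net penalty (excludes intercepts)
static double penalty(const arma::vec& beta, double lambda, double w) {
  double l1 = arma::accu(arma::abs(beta));
  double l2 = arma::dot(beta, beta);
  return lambda * (w * l1 + 0.5 * (1.0 - w) * l2);
}

// first/second derivative of -(1/N) logL wrt one packed coordinate
static void coord_deriv(const arma::ivec& y, const arma::mat& X,
                        const arma::vec& gamma, const arma::vec& eta,
                        int coord, int K, double& d1, double& d2) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  d1 = 0.0; d2 = 0.0;
  const bool is_slope = coord >= K - 1;
  const int a = is_slope ? coord - (K - 1) : -1;
  const int j = is_slope ? -1 : coord; // gamma index (0-based)
  for (int i = 0; i < n; ++i) {
    int k = y[i];
    int i1 = (k < K) ? (k - 1) : -1;
    int i2 = (k > 1) ? (k - 2) : -1;
    if (!is_slope && j != i1 && j != i2) continue;
    double A = (i1 >= 0) ? sigmoid(gamma[i1] + eta[i]) : 1.0;
    double B = (i2 >= 0) ? sigmoid(gamma[i2] + eta[i]) : 0.0;
    double pr = A - B;
    if (pr < PMIN) pr = PMIN;
    double u = (i1 >= 0) ? A * (1.0 - A) : 0.0;
    double v = (i2 >= 0) ? B * (1.0 - B) : 0.0;
    double up = u * (1.0 - 2.0 * A);
    double vp = v * (1.0 - 2.0 * B);
    double g1 = u / pr;
    double g2 = -v / pr;
    double h11 = up / pr - (u * u) / (pr * pr);
    double h22 = -vp / pr - (v * v) / (pr * pr);
    double h12 = (u * v) / (pr * pr);
    if (is_slope) {
      double xa = X(i, a);
      d1 += (g1 + g2) * xa;
      d2 += (h11 + 2.0 * h12 + h22) * xa * xa;
    } else {
      if (j == i1) { d1 += g1; d2 += h11; }
      if (j == i2) { d1 += g2; d2 += h22; }
    }
  }
  double N = (double)n;
  d1 = -d1 / N;            // derivative of -(1/N) logL
  d2 = -d2 / N;            // concave logL => d2 >= 0
}

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Proximal Newton solver: at each outer iteration form the exact quadratic
// model of -(1/N) logL, minimize (quadratic + penalty) by cyclic coordinate
// descent (closed-form soft-thresholded updates; cost independent of n),
// and take the resulting direction with a step-halving line search on the
// true penalized objective, keeping the intercepts strictly increasing.
// Warm-started along the descending lambda path.
// [[Rcpp::export(name = ".olr_cd_path_cpp")]]
List olr_cd_path_cpp(IntegerVector y, NumericMatrix X, int n_cat,
                     NumericVector lambdas, double w,
                     double tol, int max_iter) {
  arma::ivec yy(y.begin(), y.size());
  arma::mat XX(X.begin(), X.nrow(), X.ncol());
  const int K = n_cat;
  const int p = XX.n_cols;
  const int n = XX.n_rows;
  const double N = (double)n;
  const int L = lambdas.size();
  const int m = (K - 1) + p;

  arma::vec gamma = start_gamma(yy, K);
  arma::vec beta(p, arma::fill::zeros);

  arma::mat gamma_out(K - 1, L);
  arma::mat beta_out(p, L);
  arma::vec ll_out(L), obj_out(L);
  arma::ivec conv_out(L), iter_out(L);

  arma::vec grad_l;   // gradient of logL (note sign)
  arma::mat hess_l;   // Hessian of logL

  for (int li = 0; li < L; ++li) {
    const double lambda = lambdas[li];
    double ll = loglik(yy, XX, gamma, beta);
    double f = -ll / N + penalty(beta, lambda, w);
    bool converged = false;
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
      grad_hess(yy, XX, gamma, beta, grad_l, hess_l);
      arma::vec g = -grad_l / N;          // gradient of -(1/N) logL
      arma::mat H = -hess_l / N;          // psd by concavity
      H.diag() += 1e-9;
      // inner CD on: q(d) = g'd + 0.5 d'Hd + pen(beta_slopes + d_slopes)
      arma::vec d(m, arma::fill::zeros);
      arma::vec hd(m, arma::fill::zeros); // H * d, updated incrementally
      for (int cyc = 0; cyc < 100; ++cyc) {
        double inner_max = 0.0;
        for (int c = 0; c < m; ++c) {
          double hcc = H(c, c);
          double gc = g[c] + hd[c] - hcc * d[c];
          double d_new;
          if (c < K - 1) {
            d_new = -gc / hcc;
          } else {
            double bc = beta[c - (K - 1)];
            double u = soft(hcc * bc - gc, lambda * w) /
                       (hcc + lambda * (1.0 - w));
            d_new = u - bc;
          }
          double delta = d_new - d[c];
          if (delta != 0.0) {
            d[c] = d_new;
            hd += H.col(c) * delta;
            inner_max = std::max(inner_max, std::fabs(delta));
          }
        }
        if (inner_max < 1e-10) break;
      }
      double step_max = arma::abs(d).max();
      if (step_max < tol) { converged = true; break; }
      // line search on the true objective with intercept-order guard
      double t = 1.0;
      bool moved = false;
      for (int h = 0; h < 30; ++h) {
        arma::vec g_new = gamma + t * d.head(K - 1);
        arma::vec b_new = beta + t * d.tail(p);
        if (increasing(g_new)) {
          double ll_new = loglik(yy, XX, g_new, b_new);
          double f_new = -ll_new / N + penalty(b_new, lambda, w);
          if (f_new <= f + 1e-13) {
            gamma = g_new; beta = b_new;
            double df = f - f_new;
            f = f_new; ll = ll_new;
            moved = true;
            if (t == 1.0 && (step_max < tol || df < 1e-13))
              converged = true;
            break;
          }
        }
        t *= 0.5;
      }
      if (!moved) { converged = step_max < 1e-4; break; }
      if (converged) break;
    }
    gamma_out.col(li) = gamma;
    beta_out.col(li) = beta;
    ll_out[li] = ll;
    obj_out[li] = f;
    conv_out[li] = converged ? 1 : 0;
    iter_out[li] = it;
  }
  return List::create(_["gamma"] = gamma_out,
                      _["beta"] = beta_out,
                      _["loglik"] = NumericVector(ll_out.begin(), ll_out.end()),
                      _["objective"] = NumericVector(obj_out.begin(), obj_out.end()),
                      _["converged"] = IntegerVector(conv_out.begin(), conv_out.end()),
                      _["n_iter"] = IntegerVector(iter_out.begin(), iter_out.end()));
}

// score of -(1/N) logL wrt each slope at the intercept-only fit; used for
// the lambda_max of the automatically generated path
// [[Rcpp::export(name = ".olr_null_score_cpp")]]
NumericVector olr_null_score_cpp(IntegerVector y, NumericMatrix X, int n_cat) {
  arma::ivec yy(y.begin(), y.size());
  arma::mat XX(X.begin(), X.nrow(), X.ncol());
  const int K = n_cat;
  const int p = XX.n_cols;
  arma::vec gamma = start_gamma(yy, K);
  arma::vec eta(XX.n_rows, arma::fill::zeros);
  NumericVector out(p);
  for (int a = 0; a < p; ++a) {
    double d1, d2;
    coord_deriv(yy, XX, gamma, eta, K - 1 + a, K, d1, d2);
    out[a] = d1;
  }
  return out;
}
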