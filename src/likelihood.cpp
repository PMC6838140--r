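#include <Rcpp.h>
using namespace Rcpp;

// Condition codes (match cond_levels() in R): 1 = go_gain, 2 = nogo_gain,
// 3 = go_avoid, 4 = nogo_avoid.  Domain is gain for codes 1-2, loss for 3-4.
// Action: 1 = go, 0 = nogo.  Outcome r in {-1, 0, 1}.
//
// Full parameter block p8 (natural scale):
//   [0] eps_GP  [1] eps_GN  [2] eps_LP  [3] eps_LN
//   [4] rho_G   [5] rho_L   [6] bias    [7] pav

static inline double log1pexp_(double x) {
  // stable log(1 + exp(x))
  if (x <= -37.0) return std::exp(x);
  if (x <= 18.0)  return std::log1p(std::exp(x));
  if (x <= 33.3)  return x + std::exp(-x);
  return x;
}

// eps index for (domain, PE sign); ties (delta == 0) take the positive rate
static inline int eps_index(int loss, double delta) {
  int pos = (delta >= 0.0) ? 0 : 1;
  return 2 * loss + pos;
}

static double ll_core(const int* cond, const int* act, const int* out, int n,
                      const double* p, bool has_pav) {
  double Q[4][2] = {{0.0, 0.0}, {0.0, 0.0}, {0.0, 0.0}, {0.0, 0.0}};
  double V[4] = {0.0, 0.0, 0.0, 0.0};
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int s = cond[t] - 1;          // 0-based stimulus
    int loss = (s >= 2) ? 1 : 0;
    int a = act[t];               // 1 go, 0 nogo
    double r = (double)out[t];

    double w_go = Q[s][1] + p[6];
    if (has_pav) w_go += p[7] * V[s];
    double w_nogo = Q[s][0];
    double dw = w_go - w_nogo;
    // log softmax over two actions
    ll += (a == 1) ? -log1pexp_(-dw) : -log1pexp_(dw);

    double rho = p[4 + loss];
    double delta = rho * r - Q[s][a];
    Q[s][a] += p[eps_index(loss, delta)] * delta;

    if (has_pav) {
      double dv = rho * r - V[s];
      V[s] += p[eps_index(loss, dv)] * dv;
    }
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_session_loglik(IntegerVector cond, IntegerVector act,
                          IntegerVector out, NumericVector p8, bool has_pav) {
  return ll_core(cond.begin(), act.begin(), out.begin(), cond.size(),
                 p8.begin(), has_pav);
}

// Expand a free transformed-scale vector into the natural-scale p8 block.
// lr_split in {1,2,4}; rho_split in {1,2}; has_bias, has_pav in {0,1}.
static void expand_theta(const double* theta, int lr_split, int rho_split,
                         int has_bias, int has_pav, double* p8) {
  int k = 0;
  double e[4];
  if (lr_split == 1) {
    double v = 1.0 / (1.0 + std::exp(-theta[k++]));
    e[0] = e[1] = e[2] = e[3] = v;
  } else if (lr_split == 2) {
    double ep = 1.0 / (1.0 + std::exp(-theta[k++]));
    double en = 1.0 / (1.0 + std::exp(-theta[k++]));
    e[0] = ep; e[1] = en; e[2] = ep; e[3] = en;
  } else {
    for (int i = 0; i < 4; ++i) e[i] = 1.0 / (1.0 + std::exp(-theta[k++]));
  }
  for (int i = 0; i < 4; ++i) p8[i] = e[i];
  if (rho_split == 1) {
    double rv = std::exp(theta[k++]);
    p8[4] = rv; p8[5] = rv;
  } else {
    p8[4] = std::exp(theta[k++]);
    p8[5] = std::exp(theta[k++]);
  }
  p8[6] = has_bias ? theta[k++] : 0.0;
  p8[7] = has_pav ? theta[k++] : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_expand_theta(NumericVector theta, int lr_split,
                               int rho_split, int has_bias, int has_pav) {
  NumericVector p8(8);
  expand_theta(theta.begin(), lr_split, rho_split, has_bias, has_pav,
               p8.begin());
  return p8;
}

// Negative log posterior of one session on the transformed scale:
// -(loglik + sum dnorm(theta, mu, sqrt(sigma2), log)).  Used by optim().
// [[Rcpp::export]]
double cpp_neg_logpost(NumericVector theta, IntegerVector cond,
                       IntegerVector act, IntegerVector out, int lr_split,
                       int rho_split, int has_bias, int has_pav,
                       NumericVector mu, NumericVector sigma2) {
  double p8[8];
  expand_theta(theta.begin(), lr_split, rho_split, has_bias, has_pav, p8);
  double ll = ll_core(cond.begin(), act.begin(), out.begin(), cond.size(),
                      p8, has_pav != 0);
  double lp = 0.0;
  for (int i = 0; i < theta.size(); ++i) {
    double d = theta[i] - mu[i];
    lp += -0.5 * std::log(2.0 * M_PI * sigma2[i]) - 0.5 * d * d / sigma2[i];
  }
  return -(ll + lp);
}

// Central-difference gradient of cpp_neg_logpost (used by BFGS).
// [[Rcpp::export]]
NumericVector cpp_neg_logpost_grad(NumericVector theta, IntegerVector cond,
                                   IntegerVector act, IntegerVector out,
                                   int lr_split, int rho_split, int has_bias,
                                   int has_pav, NumericVector mu,
                                   NumericVector sigma2) {
  const double h = 1e-6;
  int k = theta.size();
  NumericVector g(k);
  std::vector<double> th(theta.begin(), theta.end());
  double p8[8];
  for (int i = 0; i < k; ++i) {
    double orig = th[i];
    double f[2];
    for (int s = 0; s < 2; ++s) {
      th[i] = orig + (s == 0 ? h : -h);
      expand_theta(th.data(), lr_split, rho_split, has_bias, has_pav, p8);
      double ll = ll_core(cond.begin(), act.begin(), out.begin(),
                          cond.size(), p8, has_pav != 0);
      double lp = 0.0;
      for (int j = 0; j < k; ++j) {
        double d = th[j] - mu[j];
        lp += -0.5 * std::log(2.0 * M_PI * sigma2[j]) -
              0.5 * d * d / sigma2[j];
      }
      f[s] = -(ll + lp);
    }
    th[i] = orig;
    g[i] = (f[0] - f[1]) / (2.0 * h);
  }
  return g;
}

// Session log-likelihood for each row of a k x 8 natural-scale parameter
// matrix (Monte-Carlo draws for the integrated BIC).
// [[Rcpp::export]]
NumericVector cpp_loglik_draws(IntegerVector cond, IntegerVector act,
                               IntegerVector out, NumericMatrix par,
                               bool has_pav) {
  int k = par.nrow(), n = cond.size();
  NumericVector res(k);
  double p8[8];
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < 8; ++c) p8[c] = par(j, c);
    res[j] = ll_core(cond.begin(), act.begin(), out.begin(), n, p8,
                     has_pav);
  }
  return res;
}
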