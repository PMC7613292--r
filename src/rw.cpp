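#include <Rcpp.h>
using namespace Rcpp;

// Belief recursion shared by simulation and likelihood. Beliefs are the
// prediction held *before* the outcome of each trial; element n + 1 is the
// belief after the final outcome. kappa (post-failure decrement) and lambda
// (decay toward the scale midpoint) are zero in the plain valence-split
// model; the latent state is clipped to the 1-7 rating scale only when those
// extensions can push it outside (the plain update is convex and cannot).
static inline double step_belief(double cur, int outcome, double alpha_pos,
                                 double alpha_neg, double kappa, double lambda,
                                 int failure) {
  double delta = (double)outcome - cur;
  if (delta > 0.0)
    cur += alpha_pos * delta;
  else if (delta < 0.0)
    cur += alpha_neg * delta;
  if (kappa != 0.0 && failure == 1)
    cur -= kappa;
  if (lambda != 0.0)
    cur += lambda * (4.0 - cur);
  if (cur < 1.0) cur = 1.0;
  if (cur > 7.0) cur = 7.0;
  return cur;
}

// [[Rcpp::export]]
NumericVector latent_beliefs_cpp(double mu0, double alpha_pos, double alpha_neg,
                                 double kappa, double lambda,
                                 IntegerVector outcomes,
                                 IntegerVector failures) {
  int n = outcomes.size();
  NumericVector b(n + 1);
  double cur = mu0;
  for (int t = 0; t < n; ++t) {
    b[t] = cur;
    cur = step_belief(cur, outcomes[t], alpha_pos, alpha_neg, kappa, lambda,
                      failures[t]);
  }
  b[n] = cur;
  return b;
}

// Negative log-likelihood of reported beliefs under a Gaussian centred on
// the latent prediction with scale xi, truncated to [1, 7].
// [[Rcpp::export]]
double nll_truncnorm_cpp(double mu0, double alpha_pos, double alpha_neg,
                         double kappa, double lambda, double xi,
                         IntegerVector outcomes, IntegerVector failures,
                         NumericVector reports) {
  int n = outcomes.size();
  double cur = mu0;
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    double z = (reports[t] - cur) / xi;
    double log_num = R::dnorm(z, 0.0, 1.0, 1) - std::log(xi);
    double denom = R::pnorm((7.0 - cur) / xi, 0.0, 1.0, 1, 0) -
                   R::pnorm((1.0 - cur) / xi, 0.0, 1.0, 1, 0);
    if (denom < 1e-300) denom = 1e-300;
    nll -= log_num - std::log(denom);
    cur = step_belief(cur, outcomes[t], alpha_pos, alpha_neg, kappa, lambda,
                      failures[t]);
  }
  return nll;
}

// ---- multi-start L-BFGS-B driver -------------------------------------------
// Runs R's own L-BFGS-B (R_ext/Applic.h) over the free parameters from each
// start, with the NLL objective evaluated natively; gradients are central
// finite differences. Free-parameter codes: 0 mu0, 1 alpha (tied), 2
// alpha_pos, 3 alpha_neg, 4 xi, 5 kappa, 6 lambda.

#include <R_ext/Applic.h>

struct FitCtx {
  int n_free;
  const int *codes;
  double fixed_mu0;
  const int *outcomes;
  const int *failures;
  const double *reports;
  int n_obs;
};

static double nll_for_theta(const double *theta, const FitCtx *ctx) {
  double mu0 = ctx->fixed_mu0, ap = 0.3, an = 0.3, xi = 0.5, kappa = 0.0,
         lambda = 0.0;
  for (int j = 0; j < ctx->n_free; ++j) {
    switch (ctx->codes[j]) {
    case 0: mu0 = theta[j]; break;
    case 1: ap = an = theta[j]; break;
    case 2: ap = theta[j]; break;
    case 3: an = theta[j]; break;
    case 4: xi = theta[j]; break;
    case 5: kappa = theta[j]; break;
    case 6: lambda = theta[j]; break;
    }
  }
  double cur = mu0, nll = 0.0;
  for (int t = 0; t < ctx->n_obs; ++t) {
    double z = (ctx->reports[t] - cur) / xi;
    double log_num = R::dnorm(z, 0.0, 1.0, 1) - std::log(xi);
    double denom = R::pnorm((7.0 - cur) / xi, 0.0, 1.0, 1, 0) -
                   R::pnorm((1.0 - cur) / xi, 0.0, 1.0, 1, 0);
    if (denom < 1e-300) denom = 1e-300;
    nll -= log_num - std::log(denom);
    cur = step_belief(cur, ctx->outcomes[t], ap, an, kappa, lambda,
                      ctx->failures[t]);
  }
  return nll;
}

static double fit_objfn(int n, double *par, void *ex) {
  (void)n;
  return nll_for_theta(par, (FitCtx *)ex);
}

static void fit_objgr(int n, double *par, double *gr, void *ex) {
  FitCtx *ctx = (FitCtx *)ex;
  std::vector<double> th(par, par + n);
  for (int j = 0; j < n; ++j) {
    double h = 1e-6 * std::max(1.0, std::fabs(par[j]));
    th[j] = par[j] + h;
    double up = nll_for_theta(th.data(), ctx);
    th[j] = par[j] - h;
    double dn = nll_for_theta(th.data(), ctx);
    th[j] = par[j];
    gr[j] = (up - dn) / (2.0 * h);
  }
}

// [[Rcpp::export]]
List fit_rw_cpp(NumericMatrix starts, NumericVector lower, NumericVector upper,
                IntegerVector free_codes, double fixed_mu0,
                IntegerVector outcomes, IntegerVector failures,
                NumericVector reports, double factr, int maxit) {
  int n_free = starts.ncol();
  FitCtx ctx = {n_free, INTEGER(free_codes), fixed_mu0, INTEGER(outcomes),
                INTEGER(failures), REAL(reports),
                (int)outcomes.size()};
  std::vector<int> nbd(n_free, 2);  // both bounds
  std::vector<double> x(n_free), lo(lower.begin(), lower.end()),
      hi(upper.begin(), upper.end());
  double best_val = R_PosInf;
  std::vector<double> best_par(n_free);
  int best_conv = -1, n_ok = 0;
  char msg[1024];
  for (int s = 0; s < starts.nrow(); ++s) {
    for (int j = 0; j < n_free; ++j) x[j] = starts(s, j);
    double fmin = 0.0;
    int fail = 0, fncount = 0, grcount = 0;
    lbfgsb(n_free, 5, x.data(), lo.data(), hi.data(), nbd.data(), &fmin,
           fit_objfn, fit_objgr, &fail, (void *)&ctx, factr, 1e-8, &fncount,
           &grcount, maxit, msg, 0, 100);
    if (!R_finite(fmin)) continue;
    ++n_ok;
    if (fmin < best_val) {
      best_val = fmin;
      best_par.assign(x.begin(), x.end());
      best_conv = fail;
    }
  }
  return List::create(_["par"] = NumericVector(best_par.begin(),
                                               best_par.end()),
                      _["value"] = best_val,
                      _["convergence"] = best_conv,
                      _["n_ok"] = n_ok);
}
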