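#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the L1-penalized binomial logistic path.
// Loss convention: (1/n) * negative log-likelihood + lambda * sum |beta_j|,
// intercept unpenalized. Outer IRLS rebuilds the quadratic approximation;
// the inner loop iterates the active set to convergence, then sweeps the
// inactive genes for KKT violations. Warm starts along the decreasing grid.
// The path stops early once the fit saturates (fraction of null deviance
// explained exceeds devmax); remaining grid points repeat that solution.
// [[Rcpp::export]]
List l1_logistic_core_cpp(NumericMatrix X, NumericVector y,
                          NumericVector lambdas, double tol, double maxit,
                          double devmax = 0.95) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  const double wmin = 1e-5;

  std::vector<double> beta(p, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double b0 = std::log(ybar / (1.0 - ybar));

  NumericVector a0_out(L);
  NumericMatrix beta_out(p, L);
  std::vector<double> eta(n), w(n), s(n), vj(p), beta_old(p);
  std::vector<int> active;

  const double nulldev = -2.0 * (ybar * std::log(ybar) +
                                 (1.0 - ybar) * std::log(1.0 - ybar));
  NumericVector dev_ratio(L);
  NumericVector outers_out(L), iters_out(L);
  int k_stop = L;

  for (int k = 0; k < L; ++k) {
    const double lam = lambdas[k];
    double it = 0.0;
    int outer_used = 0;
    for (int outer = 0; outer < 50; ++outer) {
      outer_used = outer + 1;
      // linear predictor from current coefficients
      for (int i = 0; i < n; ++i) eta[i] = b0;
      for (int j = 0; j < p; ++j) {
        if (beta[j] != 0.0) {
          const double bj = beta[j];
          const double *xj = &X(0, j);
          for (int i = 0; i < n; ++i) eta[i] += bj * xj[i];
        }
      }
      double sw = 0.0;
      for (int i = 0; i < n; ++i) {
        const double pr = 1.0 / (1.0 + std::exp(-eta[i]));
        double wi = pr * (1.0 - pr);
        if (wi < wmin) wi = wmin;
        w[i] = wi;
        sw += wi;
        s[i] = y[i] - pr; // working weighted residual w*(z - eta)
      }
      for (int j = 0; j < p; ++j) {
        const double *xj = &X(0, j);
        double v = 0.0;
        for (int i = 0; i < n; ++i) v += w[i] * xj[i] * xj[i];
        vj[j] = v / n;
      }
      const double b0_start = b0;
      std::copy(beta.begin(), beta.end(), beta_old.begin());

      active.clear();
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
      for (;;) {
        // iterate the active set (plus intercept) to convergence
        for (;;) {
          double delta = 0.0;
          for (size_t a = 0; a < active.size(); ++a) {
            const int j = active[a];
            const double *xj = &X(0, j);
            double gj = 0.0;
            for (int i = 0; i < n; ++i) gj += xj[i] * s[i];
            gj /= n;
            const double bnew = soft(gj + beta[j] * vj[j], lam) / vj[j];
            const double d = bnew - beta[j];
            if (d != 0.0) {
              for (int i = 0; i < n; ++i) s[i] -= d * w[i] * xj[i];
              beta[j] = bnew;
              const double ad = vj[j] * d * d; // weighted squared change
              if (ad > delta) delta = ad;
            }
          }
          double d0 = 0.0;
          for (int i = 0; i < n; ++i) d0 += s[i];
          d0 /= sw;
          if (d0 != 0.0) {
            b0 += d0;
            for (int i = 0; i < n; ++i) s[i] -= d0 * w[i];
            const double ad = (sw / n) * d0 * d0;
            if (ad > delta) delta = ad;
          }
          it += active.size() + 1;
          if (delta < tol || it > maxit) break;
        }
        // admission sweep over inactive genes (KKT violations enter)
        bool grown = false;
        for (int j = 0; j < p; ++j) {
          if (beta[j] != 0.0) continue;
          const double *xj = &X(0, j);
          double gj = 0.0;
          for (int i = 0; i < n; ++i) gj += xj[i] * s[i];
          gj /= n;
          const double bnew = soft(gj, lam) / vj[j];
          // dust guard: a gradient numerically at the penalty boundary
          // otherwise flip-flops between admission and shrinkage forever
          if (std::fabs(bnew) >= 1e-10) {
            for (int i = 0; i < n; ++i) s[i] -= bnew * w[i] * xj[i];
            beta[j] = bnew;
            grown = true;
          }
        }
        it += p;
        if (!grown || it > maxit) break;
        active.clear();
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
      }

      double maxchange = (sw / n) * (b0 - b0_start) * (b0 - b0_start);
      for (int j = 0; j < p; ++j) {
        const double d = beta[j] - beta_old[j];
        const double ad = vj[j] * d * d;
        if (ad > maxchange) maxchange = ad;
      }
      if (maxchange < tol || it > maxit) break;
    }
    for (int j = 0; j < p; ++j) {
      // soft-threshold floating-point dust is not a real support member
      beta_out(j, k) = (std::fabs(beta[j]) < 1e-10) ? 0.0 : beta[j];
    }
    a0_out[k] = b0;
    outers_out[k] = outer_used;
    iters_out[k] = it;

    // deviance at this solution (eta refreshed from stored coefficients)
    double dev = 0.0;
    for (int i = 0; i < n; ++i) eta[i] = b0;
    for (int j = 0; j < p; ++j) {
      if (beta_out(j, k) != 0.0) {
        const double bj = beta_out(j, k);
        const double *xj = &X(0, j);
        for (int i = 0; i < n; ++i) eta[i] += bj * xj[i];
      }
    }
    for (int i = 0; i < n; ++i) {
      // -2*loglik with numerically safe log1p(exp(.))
      const double e = eta[i];
      const double lse = (e > 0) ? e + std::log1p(std::exp(-e))
                                 : std::log1p(std::exp(e));
      dev += -2.0 * (y[i] * e - lse);
    }
    dev /= n;
    dev_ratio[k] = 1.0 - dev / nulldev;
    if (dev_ratio[k] > devmax) { k_stop = k + 1; break; }
  }
  // flat tail: repeat the saturated solution over the remaining grid
  for (int k = k_stop; k < L; ++k) {
    a0_out[k] = a0_out[k_stop - 1];
    for (int j = 0; j < p; ++j) beta_out(j, k) = beta_out(j, k_stop - 1);
    dev_ratio[k] = dev_ratio[k_stop - 1];
  }
  return List::create(_["a0"] = a0_out, _["beta"] = beta_out,
                      _["dev_ratio"] = dev_ratio, _["outers"] = outers_out,
                      _["iters"] = iters_out);
}
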