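#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// L1-penalized maximum-entropy fit over background cells by cyclic
// coordinate descent with soft-thresholded prox-Newton steps and a halving
// line search on the exact penalized log-likelihood
//   obj(lambda) = pbar . lambda - log Z(lambda) - sum_j beta_j |lambda_j|,
//   Z = sum_i exp(eta_i),  eta_i = sum_j lambda_j F_ij.
// Convergence: penalized log-likelihood improvement per sweep < tol.
// [[Rcpp::export]]
List maxent_cd(NumericMatrix Fb, NumericVector pbar, NumericVector beta,
               double tol, int max_sweeps) {
  const int n = Fb.nrow(), p = Fb.ncol();
  if (pbar.size() != p || beta.size() != p)
    stop("pbar/beta length must equal the number of features");
  std::vector<double> eta(n, 0.0), lambda(p, 0.0), q(n);
  double logZ = std::log((double)n);

  auto full_logZ = [&]() {
    double mx = eta[0];
    for (int i = 1; i < n; ++i) if (eta[i] > mx) mx = eta[i];
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += std::exp(eta[i] - mx);
    return mx + std::log(s);
  };
  auto objective = [&]() {
    double o = -logZ;
    for (int j = 0; j < p; ++j)
      o += pbar[j] * lambda[j] - beta[j] * std::fabs(lambda[j]);
    return o;
  };

  double obj = objective();
  bool converged = false;
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double obj_start = obj;
    for (int j = 0; j < p; ++j) {
      const double *f = &Fb(0, j);
      double E = 0.0, E2 = 0.0;
      for (int i = 0; i < n; ++i) {
        q[i] = std::exp(eta[i] - logZ);
        E += q[i] * f[i];
        E2 += q[i] * f[i] * f[i];
      }
      double g = pbar[j] - E;
      double h = E2 - E * E;
      if (h < 1e-12) h = 1e-12;
      double u = lambda[j] + g / h, thr = beta[j] / h;
      double lnew = (u > thr) ? (u - thr) : ((u < -thr) ? (u + thr) : 0.0);
      double delta = lnew - lambda[j];
      if (std::fabs(delta) < 1e-12) continue;
      for (int ls = 0; ls < 40; ++ls) {
        double cand = lambda[j] + delta;
        double mx = -1e300;
        for (int i = 0; i < n; ++i) {
          double e = eta[i] + delta * f[i];
          if (e > mx) mx = e;
        }
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += std::exp(eta[i] + delta * f[i] - mx);
        double logZc = mx + std::log(s);
        double dobj = pbar[j] * delta - (logZc - logZ) -
          beta[j] * (std::fabs(cand) - std::fabs(lambda[j]));
        if (dobj >= -1e-14) {
          for (int i = 0; i < n; ++i) eta[i] += delta * f[i];
          logZ = logZc;
          lambda[j] = cand;
          obj += dobj;
          break;
        }
        delta *= 0.5;
        if (std::fabs(delta) < 1e-13) break;
      }
    }
    logZ = full_logZ();       // numerical hygiene once per sweep
    obj = objective();
    if (obj - obj_start < tol && obj - obj_start >= 0) {
      converged = true;
      ++sweep;
      break;
    }
    if (obj - obj_start < 0 && std::fabs(obj - obj_start) < tol) {
      converged = true;
      ++sweep;
      break;
    }
  }
  return List::create(_["lambda"] = NumericVector(lambda.begin(), lambda.end()),
                      _["eta"] = NumericVector(eta.begin(), eta.end()),
                      _["logZ"] = logZ,
                      _["objective"] = obj,
                      _["converged"] = converged,
                      _["sweeps"] = sweep);
}
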