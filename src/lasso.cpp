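#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for L1-penalized regression paths, with
// sequential strong-rule screening and active-set iteration.
//
// All routines expect X already standardized column-wise (mean 0, variance 1
// computed with 1/n) and work on that scale; the R wrappers translate
// coefficients back to the original scale.  Convergence is declared when a
// full pass over the screened set changes no coefficient by more than `tol`
// (standardized scale) AND the KKT conditions hold over all columns (the
// strong rule is a heuristic screen; every solution is verified).  Warm
// starts along a decreasing lambda sequence.  The path is truncated early
// when the deviance stops improving, the fit saturates, the Cox degrees of
// freedom exceed the event count, or a lambda fails to converge within its
// cycle budget (unconverged solutions are never returned).

static inline double soft(double z, double g) {
  // the relative guard absorbs last-bit rounding so that lambda >= lambda_max
  // yields an exactly zero coefficient vector
  if (z > g + 1e-12 * g) return z - g;
  if (z < -g - 1e-12 * g) return z + g;
  return 0.0;
}

// One coordinate-descent pass over `cols` for the weighted quadratic
// (1/2n) sum_i w_i (z_i - b0 - x'b)^2 + lam ||b||_1, r = z - b0 - Xb.
static double cd_pass(const NumericMatrix& X, const std::vector<double>& w,
                      const std::vector<double>& wxx, double wsum,
                      std::vector<double>& r, std::vector<double>& b,
                      double& b0, bool intercept, double lam,
                      const std::vector<int>& cols) {
  int n = X.nrow();
  double dmax = 0.0;
  for (size_t c = 0; c < cols.size(); ++c) {
    int j = cols[c];
    if (wxx[j] <= 0) continue;
    double bj = b[j];
    double rho = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) rho += w[i] * xj[i] * r[i];
    rho = rho / n + wxx[j] * bj;
    double bn = soft(rho, lam) / wxx[j];
    if (bn != bj) {
      double d = bn - bj;
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      b[j] = bn;
      double ad = std::abs(d);
      if (ad > dmax) dmax = ad;
    }
  }
  if (intercept && wsum > 0) {
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += w[i] * r[i];
    double d0 = num / wsum;
    if (d0 != 0.0) {
      b0 += d0;
      for (int i = 0; i < n; ++i) r[i] -= d0;
      double ad = std::abs(d0);
      if (ad > dmax) dmax = ad;
    }
  }
  return dmax;
}

// Active-set solve of the weighted quadratic restricted to `cols`.
// Returns true if a pass over `cols` moved nothing beyond tol in budget.
static bool wls_solve(const NumericMatrix& X, const std::vector<double>& w,
                      std::vector<double>& r, std::vector<double>& b,
                      double& b0, bool intercept, double lam, double tol,
                      int budget, int& used, const std::vector<int>& cols) {
  int n = X.nrow(), p = X.ncol();
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += w[i];
  std::vector<double> wxx(p, 0.0);
  for (size_t c = 0; c < cols.size(); ++c) {
    int j = cols[c];
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
    wxx[j] = s / n;
  }
  int start = used;
  while (used - start < budget) {
    ++used;
    double dmax = cd_pass(X, w, wxx, wsum, r, b, b0, intercept, lam, cols);
    if (dmax < tol) return true;
    std::vector<int> act;
    for (size_t c = 0; c < cols.size(); ++c)
      if (b[cols[c]] != 0.0) act.push_back(cols[c]);
    while (used - start < budget) {
      ++used;
      double da = cd_pass(X, w, wxx, wsum, r, b, b0, intercept, lam, act);
      if (da < tol) break;
    }
  }
  return false;
}

// Sequential strong-rule screen: |grad_j| >= 2 lam - lam_prev, plus the
// current active set.
static std::vector<int> strong_set(const std::vector<double>& grad,
                                   const std::vector<double>& b,
                                   double lam, double lam_prev) {
  int p = grad.size();
  double thr = 2.0 * lam - lam_prev;
  std::vector<int> s;
  for (int j = 0; j < p; ++j)
    if (b[j] != 0.0 || std::abs(grad[j]) >= thr) s.push_back(j);
  return s;
}

// KKT check outside `inset`; returns violating columns (|grad_j| > lam).
static std::vector<int> kkt_violations(const std::vector<double>& grad,
                                       const std::vector<bool>& inset,
                                       double lam) {
  std::vector<int> v;
  for (size_t j = 0; j < grad.size(); ++j)
    if (!inset[j] && std::abs(grad[j]) > lam * (1.0 + 1e-9))
      v.push_back(j);
  return v;
}

// Full gradient of the smooth loss w.r.t. standardized beta given the
// per-observation gradient geta (d loss / d eta_i): grad_j = sum_i x_ij geta_i.
static void xt_grad(const NumericMatrix& X, const std::vector<double>& geta,
                    std::vector<double>& grad) {
  int n = X.nrow(), p = X.ncol();
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * geta[i];
    grad[j] = s;
  }
}

// Gaussian: minimize (1/2n)||y - X b||^2 + lambda ||b||_1, y centered.
// [[Rcpp::export(name = ".cd_gaussian")]]
List cd_gaussian(NumericMatrix X, NumericVector y, NumericVector lambdas,
                 double tol, int max_cycles) {
  int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  NumericMatrix beta(p, nl);
  IntegerVector cycles(nl);
  std::vector<double> b(p, 0.0), r(y.begin(), y.end());
  std::vector<double> w(n, 1.0), grad(p), geta(n);
  double b0 = 0.0;
  double nulldev = 0.0;
  for (int i = 0; i < n; ++i) nulldev += y[i] * y[i];
  double devr_prev = 0.0;
  int nused = nl;
  double lam_prev = lambdas[0];
  for (int l = 0; l < nl; ++l) {
    double lam = lambdas[l];
    int used = 0;
    for (int i = 0; i < n; ++i) geta[i] = -r[i] / n;
    xt_grad(X, geta, grad);
    std::vector<int> scr = strong_set(grad, b, lam, lam_prev);
    bool conv = false;
    for (int round = 0; round < 20; ++round) {
      conv = wls_solve(X, w, r, b, b0, false, lam, tol,
                       max_cycles - used, used, scr);
      if (!conv) break;
      for (int i = 0; i < n; ++i) geta[i] = -r[i] / n;
      xt_grad(X, geta, grad);
      std::vector<bool> inset(p, false);
      for (size_t c = 0; c < scr.size(); ++c) inset[scr[c]] = true;
      std::vector<int> viol = kkt_violations(grad, inset, lam);
      if (viol.empty()) break;
      scr.insert(scr.end(), viol.begin(), viol.end());
    }
    cycles[l] = used;
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
    lam_prev = lam;
    if (!conv && l > 0) { nused = l; break; }
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    double devr = nulldev > 0 ? 1.0 - rss / nulldev : 0.0;
    if (l > 0 && (devr - devr_prev < 1e-5 * devr || devr > 0.999)) {
      nused = l + 1;
      break;
    }
    devr_prev = devr;
  }
  return List::create(_["beta"] = beta, _["cycles"] = cycles,
                      _["nused"] = nused);
}

// Binomial: minimize -(1/n) loglik + lambda ||b||_1, unpenalized intercept.
// [[Rcpp::export(name = ".cd_binomial")]]
List cd_binomial(NumericMatrix X, NumericVector y, NumericVector lambdas,
                 double tol, int max_cycles) {
  int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  NumericMatrix beta(p, nl);
  NumericVector b0v(nl);
  IntegerVector cycles(nl);
  std::vector<double> b(p, 0.0), eta(n, 0.0), w(n), z(n), r(n);
  std::vector<double> grad(p), geta(n);
  double ybar = mean(y);
  double b0 = std::log(ybar / (1.0 - ybar));
  for (int i = 0; i < n; ++i) eta[i] = b0;
  const double pmin = 1e-5;
  double nulldev = -2.0 * n * (ybar * std::log(ybar) +
                               (1.0 - ybar) * std::log(1.0 - ybar));
  double devr_prev = 0.0;
  int nused = nl;
  double lam_prev = lambdas[0];

  // d loss / d eta at current eta
  auto comp_geta = [&](void) {
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-eta[i]));
      geta[i] = (pi - y[i]) / n;
    }
  };

  for (int l = 0; l < nl; ++l) {
    double lam = lambdas[l];
    int used = 0;
    comp_geta();
    xt_grad(X, geta, grad);
    std::vector<int> scr = strong_set(grad, b, lam, lam_prev);
    bool conv = false, saturated = false;
    for (int round = 0; round < 20; ++round) {
      conv = false;
      double ll_prev = R_NegInf;
      for (int outer = 0; outer < 50 && used < max_cycles; ++outer) {
        std::vector<double> bprev(b);
        double b0prev = b0;
        double emax = 0.0;
        for (int i = 0; i < n; ++i) emax = std::max(emax, std::abs(eta[i]));
        if (emax > 30.0) { saturated = true; break; }
        double ll_cur = 0.0;
        for (int i = 0; i < n; ++i) {
          double pc = 1.0 / (1.0 + std::exp(-eta[i]));
          pc = std::min(std::max(pc, 1e-10), 1.0 - 1e-10);
          ll_cur += y[i] * std::log(pc) + (1.0 - y[i]) * std::log(1.0 - pc);
        }
        if (outer > 0 && std::abs(ll_cur - ll_prev) <
              1e-9 * std::max(nulldev, 1.0)) { conv = true; break; }
        ll_prev = ll_cur;
        for (int i = 0; i < n; ++i) {
          double pi = 1.0 / (1.0 + std::exp(-eta[i]));
          if (pi < pmin) pi = pmin;
          if (pi > 1.0 - pmin) pi = 1.0 - pmin;
          w[i] = pi * (1.0 - pi);
          z[i] = eta[i] + (y[i] - pi) / w[i];
          r[i] = z[i] - eta[i];
        }
        wls_solve(X, w, r, b, b0, true, lam, tol, max_cycles - used, used,
                  scr);
        for (int i = 0; i < n; ++i) eta[i] = z[i] - r[i];
        double odmax = std::abs(b0 - b0prev);
        for (size_t c = 0; c < scr.size(); ++c)
          odmax = std::max(odmax, std::abs(b[scr[c]] - bprev[scr[c]]));
        if (odmax < tol) { conv = true; break; }
      }
      if (!conv || saturated) break;
      comp_geta();
      xt_grad(X, geta, grad);
      std::vector<bool> inset(p, false);
      for (size_t c = 0; c < scr.size(); ++c) inset[scr[c]] = true;
      std::vector<int> viol = kkt_violations(grad, inset, lam);
      if (viol.empty()) break;
      scr.insert(scr.end(), viol.begin(), viol.end());
    }
    cycles[l] = used;
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
    b0v[l] = b0;
    lam_prev = lam;
    if ((!conv || saturated) && l > 0) {
      nused = saturated ? l + 1 : l;
      break;
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-eta[i]));
      pi = std::min(std::max(pi, 1e-10), 1.0 - 1e-10);
      ll += y[i] * std::log(pi) + (1.0 - y[i]) * std::log(1.0 - pi);
    }
    double devr = nulldev > 0 ? 1.0 - (-2.0 * ll) / nulldev : 0.0;
    if (l > 0 && (devr - devr_prev < 1e-5 * devr || devr > 0.999)) {
      nused = l + 1;
      break;
    }
    devr_prev = devr;
  }
  return List::create(_["beta"] = beta, _["b0"] = b0v, _["cycles"] = cycles,
                      _["nused"] = nused);
}

// Breslow partial-likelihood derivatives.  Subjects must arrive sorted by
// increasing time; `grp` maps each position to its tie-group (0-based,
// increasing with time) and `gstart` gives the first position of each group;
// `gd` is the number of events in each group.  Returns the per-subject
// gradient and (diagonal) Hessian of -(2/n) * logPL with respect to eta.
static void cox_derivs(const std::vector<double>& eta, const IntegerVector& grp,
                       const IntegerVector& gstart, const NumericVector& gd,
                       const NumericVector& d, int n, int ng,
                       std::vector<double>& g, std::vector<double>& h,
                       double* pll) {
  std::vector<double> ex(n), S0(ng), A(ng), B(ng);
  double emax = eta[0];
  for (int i = 1; i < n; ++i) if (eta[i] > emax) emax = eta[i];
  for (int i = 0; i < n; ++i) ex[i] = std::exp(eta[i] - emax);
  // reverse cumulative sum of ex at group starts = risk-set sums
  std::vector<double> rc(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) rc[i] = rc[i + 1] + ex[i];
  for (int k = 0; k < ng; ++k) S0[k] = rc[gstart[k]];
  double cumA = 0.0, cumB = 0.0, ll = 0.0;
  for (int k = 0; k < ng; ++k) {
    if (gd[k] > 0) {
      cumA += gd[k] / S0[k];
      cumB += gd[k] / (S0[k] * S0[k]);
      ll -= gd[k] * (std::log(S0[k]) + emax);
    }
    A[k] = cumA;
    B[k] = cumB;
  }
  for (int i = 0; i < n; ++i) {
    if (d[i] > 0) ll += eta[i];
    double mu = ex[i] * A[grp[i]];
    double v = mu - ex[i] * ex[i] * B[grp[i]];
    if (v < 1e-9) v = 1e-9;
    g[i] = -2.0 / n * (d[i] - mu);
    h[i] = 2.0 / n * v;
  }
  if (pll) *pll = ll;
}

// Cox: minimize -(2/n) * Breslow logPL + lambda ||b||_1 (no intercept).
// The path additionally stops once the number of nonzero coefficients
// exceeds the event count (the partial likelihood cannot support more).
// [[Rcpp::export(name = ".cd_cox")]]
List cd_cox(NumericMatrix X, NumericVector d, IntegerVector grp,
            IntegerVector gstart, NumericVector gd, NumericVector lambdas,
            double tol, int max_cycles) {
  int n = X.nrow(), p = X.ncol(), nl = lambdas.size(), ng = gstart.size();
  NumericMatrix beta(p, nl);
  IntegerVector cycles(nl);
  std::vector<double> b(p, 0.0), eta(n, 0.0), g(n), h(n), w(n), r(n);
  std::vector<double> grad(p);
  double b0 = 0.0;  // unused (no intercept)
  double ll0, llsat = 0.0;
  cox_derivs(eta, grp, gstart, gd, d, n, ng, g, h, &ll0);
  double nev = 0.0;
  for (int k = 0; k < ng; ++k)
    if (gd[k] > 0) { llsat -= gd[k] * std::log(gd[k]); nev += gd[k]; }
  double nulldev = 2.0 * (llsat - ll0);
  double devr_prev = 0.0;
  int nused = nl;
  double lam_prev = lambdas[0];
  for (int l = 0; l < nl; ++l) {
    double lam = lambdas[l];
    int used = 0;
    cox_derivs(eta, grp, gstart, gd, d, n, ng, g, h, NULL);
    xt_grad(X, g, grad);
    std::vector<int> scr = strong_set(grad, b, lam, lam_prev);
    bool conv = false, saturated = false;
    for (int round = 0; round < 20; ++round) {
      conv = false;
      double ll_prev = R_NegInf;
      for (int outer = 0; outer < 50 && used < max_cycles; ++outer) {
        std::vector<double> bprev(b);
        double emax = 0.0;
        for (int i = 0; i < n; ++i) emax = std::max(emax, std::abs(eta[i]));
        if (emax > 30.0) { saturated = true; break; }
        double ll_cur;
        cox_derivs(eta, grp, gstart, gd, d, n, ng, g, h, &ll_cur);
        // once the partial likelihood stops moving the remaining coefficient
        // drift is in a flat direction the data cannot determine
        if (outer > 0 && std::abs(ll_cur - ll_prev) <
              1e-9 * std::max(nulldev, 1.0)) { conv = true; break; }
        ll_prev = ll_cur;
        // quadratic: (1/2) sum h_i (z_i - x'b)^2 => weights n*h in cd_pass
        for (int i = 0; i < n; ++i) {
          w[i] = n * h[i];
          r[i] = -g[i] / h[i];
        }
        wls_solve(X, w, r, b, b0, false, lam, tol, max_cycles - used, used,
                  scr);
        std::fill(eta.begin(), eta.end(), 0.0);
        for (size_t c = 0; c < scr.size(); ++c) {
          int j = scr[c];
          double bj = b[j];
          if (bj == 0.0) continue;
          const double* xj = &X(0, j);
          for (int i = 0; i < n; ++i) eta[i] += xj[i] * bj;
        }
        double odmax = 0.0;
        for (size_t c = 0; c < scr.size(); ++c)
          odmax = std::max(odmax, std::abs(b[scr[c]] - bprev[scr[c]]));
        if (odmax < tol) { conv = true; break; }
      }
      if (!conv || saturated) break;
      cox_derivs(eta, grp, gstart, gd, d, n, ng, g, h, NULL);
      xt_grad(X, g, grad);
      std::vector<bool> inset(p, false);
      for (size_t c = 0; c < scr.size(); ++c) inset[scr[c]] = true;
      std::vector<int> viol = kkt_violations(grad, inset, lam);
      if (viol.empty()) break;
      scr.insert(scr.end(), viol.begin(), viol.end());
    }
    cycles[l] = used;
    int df = 0;
    for (int j = 0; j < p; ++j) { beta(j, l) = b[j]; if (b[j] != 0.0) ++df; }
    lam_prev = lam;
    if ((!conv || saturated) && l > 0) {
      nused = saturated ? l + 1 : l;
      break;
    }
    if (df > nev && l > 0) { nused = l + 1; break; }
    double ll;
    cox_derivs(eta, grp, gstart, gd, d, n, ng, g, h, &ll);
    double devr = nulldev > 0 ? (ll - ll0) * 2.0 / nulldev : 0.0;
    if (l > 0 && (devr - devr_prev < 1e-5 * devr || devr > 0.999)) {
      nused = l + 1;
      break;
    }
    devr_prev = devr;
  }
  return List::create(_["beta"] = beta, _["cycles"] = cycles,
                      _["nused"] = nused);
}

// Breslow log partial likelihood at a given eta (sorted order, tie groups).
// [[Rcpp::export(name = ".cox_pll")]]
double cox_pll(NumericVector eta, NumericVector d, IntegerVector grp,
               IntegerVector gstart, NumericVector gd) {
  int n = eta.size(), ng = gstart.size();
  std::vector<double> e(eta.begin(), eta.end()), g(n), h(n);
  double ll = 0.0;
  cox_derivs(e, grp, gstart, gd, d, n, ng, g, h, &ll);
  return ll;
}
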