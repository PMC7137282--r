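#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Scaled-probability forward/backward for a discrete-emission HMM.
// loge: T x k matrix of per-position emission log-likelihoods (finite or -Inf),
// trans: k x k row-stochastic transition matrix (structural zeros are exact 0),
// init: length-k initial distribution.
// Returns total log-likelihood, posterior state probabilities (gamma, T x k),
// summed pairwise-transition expectations (xi_sum, k x k) and gamma at t = 1 —
// the sufficient statistics Baum-Welch needs.
// Internally everything is laid out k x T so the per-position state vectors
// are contiguous (the T x k layout thrashes the cache for large T).
// [[Rcpp::export]]
List fb_kernel(NumericMatrix loge, NumericMatrix trans, NumericVector init) {
  const int T = loge.nrow(), k = loge.ncol();
  const double *A = trans.begin();           // column-major k x k
  std::vector<double> b((size_t)k * T);      // scaled emission likelihoods, k x T
  std::vector<double> mshift(T);
  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int s = 0; s < k; ++s) {
      const double v = loge(t, s);
      if (v > m) m = v;
    }
    if (m == R_NegInf)
      stop("all emission likelihoods are zero at bin %d", t + 1);
    mshift[t] = m;
    double *bt = &b[(size_t)t * k];
    for (int s = 0; s < k; ++s) bt[s] = std::exp(loge(t, s) - m);
  }

  std::vector<double> alpha((size_t)k * T), beta((size_t)k * T);
  std::vector<double> cscale(T);
  double c = 0.0;
  for (int s = 0; s < k; ++s) { alpha[s] = init[s] * b[s]; c += alpha[s]; }
  if (c <= 0.0) stop("observation sequence impossible under model at bin 1");
  cscale[0] = c;
  for (int s = 0; s < k; ++s) alpha[s] /= c;

  for (int t = 1; t < T; ++t) {
    const double *ap = &alpha[(size_t)(t - 1) * k];
    const double *bt = &b[(size_t)t * k];
    double *at = &alpha[(size_t)t * k];
    c = 0.0;
    for (int s = 0; s < k; ++s) {
      const double *Acol = A + (size_t)s * k;  // column s = transitions into s
      double a = 0.0;
      for (int r = 0; r < k; ++r) a += ap[r] * Acol[r];
      a *= bt[s];
      at[s] = a;
      c += a;
    }
    if (c <= 0.0) stop("observation sequence impossible under model at bin %d", t + 1);
    cscale[t] = c;
    for (int s = 0; s < k; ++s) at[s] /= c;
  }

  double *bT = &beta[(size_t)(T - 1) * k];
  for (int s = 0; s < k; ++s) bT[s] = 1.0;
  std::vector<double> tmp(k);
  for (int t = T - 2; t >= 0; --t) {
    const double *bn = &b[(size_t)(t + 1) * k];
    const double *be = &beta[(size_t)(t + 1) * k];
    double *bt_ = &beta[(size_t)t * k];
    const double cn = cscale[t + 1];
    for (int r = 0; r < k; ++r) tmp[r] = bn[r] * be[r] / cn;
    for (int s = 0; s < k; ++s) {
      double v = 0.0;
      for (int r = 0; r < k; ++r) v += A[s + (size_t)r * k] * tmp[r];  // A(s, r)
      bt_[s] = v;
    }
  }

  NumericMatrix gamma(T, k);
  NumericMatrix xi_sum(k, k);
  double *X = xi_sum.begin();
  for (int t = 0; t < T; ++t) {
    const double *at = &alpha[(size_t)t * k];
    const double *bt_ = &beta[(size_t)t * k];
    double g = 0.0;
    for (int s = 0; s < k; ++s) { tmp[s] = at[s] * bt_[s]; g += tmp[s]; }
    for (int s = 0; s < k; ++s) gamma(t, s) = tmp[s] / g;  // guard rounding drift
  }
  for (int t = 0; t < T - 1; ++t) {
    const double *at = &alpha[(size_t)t * k];
    const double *bn = &b[(size_t)(t + 1) * k];
    const double *be = &beta[(size_t)(t + 1) * k];
    const double cn = cscale[t + 1];
    for (int s = 0; s < k; ++s) tmp[s] = bn[s] * be[s] / cn;
    for (int s = 0; s < k; ++s) {
      const double w = tmp[s];
      if (w == 0.0) continue;
      double *Xcol = X + (size_t)s * k;
      const double *Acol = A + (size_t)s * k;
      for (int r = 0; r < k; ++r) Xcol[r] += at[r] * Acol[r] * w;
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(cscale[t]) + mshift[t];
  NumericVector gamma1(k);
  for (int s = 0; s < k; ++s) gamma1[s] = gamma(0, s);

  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum, _["gamma1"] = gamma1);
}

// Log-space Viterbi. Ties broken toward the lowest state index.
// Returns the 1-based argmax state path and its log joint probability.
// [[Rcpp::export]]
List viterbi_kernel(NumericMatrix loge, NumericMatrix trans, NumericVector init) {
  const int T = loge.nrow(), k = loge.ncol();
  std::vector<double> lt((size_t)k * k);   // lt[r + s*k] = log trans(r, s)
  std::vector<double> li(k);
  for (int r = 0; r < k; ++r) {
    li[r] = init[r] > 0.0 ? std::log(init[r]) : R_NegInf;
    for (int s = 0; s < k; ++s)
      lt[r + (size_t)s * k] = trans(r, s) > 0.0 ? std::log(trans(r, s)) : R_NegInf;
  }

  std::vector<double> dprev(k), dcur(k);
  std::vector<int> psi((size_t)k * T);
  bool any_finite = false;
  for (int s = 0; s < k; ++s) {
    dprev[s] = li[s] + loge(0, s);
    if (R_FINITE(dprev[s])) any_finite = true;
  }
  if (!any_finite) stop("no feasible state at bin 1");

  for (int t = 1; t < T; ++t) {
    any_finite = false;
    int *pt = &psi[(size_t)t * k];
    for (int s = 0; s < k; ++s) {
      const double *ls = &lt[(size_t)s * k];
      double best = R_NegInf;
      int arg = 0;
      for (int r = 0; r < k; ++r) {
        const double v = dprev[r] + ls[r];
        if (v > best) { best = v; arg = r; }
      }
      dcur[s] = best + loge(t, s);
      pt[s] = arg;
      if (R_FINITE(dcur[s])) any_finite = true;
    }
    if (!any_finite) stop("no feasible state path through bin %d", t + 1);
    dprev.swap(dcur);
  }

  double best = R_NegInf;
  int arg = 0;
  for (int s = 0; s < k; ++s)
    if (dprev[s] > best) { best = dprev[s]; arg = s; }

  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi[(size_t)t * k + path[t]];
  for (int t = 0; t < T; ++t) path[t] += 1;

  return List::create(_["path"] = path, _["logprob"] = best);
}

// Ancestral sampling of a state path; uniform variates supplied by the caller
// so all randomness stays under R's RNG.
// [[Rcpp::export]]
IntegerVector sample_path_kernel(NumericMatrix trans, NumericVector init,
                                 NumericVector u) {
  const int T = u.size(), k = init.size();
  IntegerVector path(T);
  double acc = 0.0;
  int s = k - 1;
  for (int j = 0; j < k; ++j) { acc += init[j]; if (u[0] <= acc) { s = j; break; } }
  path[0] = s + 1;
  for (int t = 1; t < T; ++t) {
    acc = 0.0;
    int nxt = k - 1;
    for (int j = 0; j < k; ++j) {
      acc += trans(s, j);
      if (u[t] <= acc) { nxt = j; break; }
    }
    s = nxt;
    path[t] = s + 1;
  }
  return path;
}
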