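#include <Rcpp.h>
using namespace Rcpp;

// composite log-likelihood sum_s log sum_m k_m A[s,m]
static double ll_of(const double *a0, const double *a1, const double *a2,
                    int n, const double *k) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i)
    acc += std::log(k[0] * a0[i] + k[1] * a1[i] + k[2] * a2[i]);
  return acc;
}

// one EM step k_in -> k_out; returns the log-likelihood at k_in
static double em_step(const double *a0, const double *a1, const double *a2,
                      int n, const double *k, double *k_out) {
  double acc = 0.0, w0 = 0.0, w1 = 0.0, w2 = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = k[0] * a0[i] + k[1] * a1[i] + k[2] * a2[i];
    acc += std::log(d);
    double inv = 1.0 / d;
    w0 += a0[i] * inv;
    w1 += a1[i] * inv;
    w2 += a2[i] * inv;
  }
  k_out[0] = k[0] * w0 / n;
  k_out[1] = k[1] * w1 / n;
  k_out[2] = k[2] * w2 / n;
  double s = k_out[0] + k_out[1] + k_out[2];
  for (int m = 0; m < 3; ++m) k_out[m] /= s;
  return acc;
}

static void clamp_simplex(double *k) {
  double s = 0.0;
  for (int m = 0; m < 3; ++m) {
    if (k[m] < 0.0) k[m] = 0.0;
    s += k[m];
  }
  for (int m = 0; m < 3; ++m) k[m] /= s;
}

// Monotone EM ascent over the (k0,k1,k2) simplex with a SQUAREM-style
// acceleration step, accepted only when it does not lower the
// log-likelihood, so ascent stays monotone (asserted each cycle).
// [[Rcpp::export(name = ".em_simplex_cpp")]]
List em_simplex_cpp(NumericMatrix A, NumericVector k_init,
                    double tol, int max_iter) {
  const int n = A.nrow();
  const double *a0 = &A(0, 0), *a1 = &A(0, 1), *a2 = &A(0, 2);
  double k[3] = { k_init[0], k_init[1], k_init[2] };
  clamp_simplex(k);
  double ll = ll_of(a0, a1, a2, n, k), ll_prev = R_NegInf;
  bool converged = false;
  double k1[3], k2[3], kc[3];
  for (int it = 0; it < max_iter; ++it) {
    double ll0 = em_step(a0, a1, a2, n, k, k1);
    double ll1 = em_step(a0, a1, a2, n, k1, k2);
    if (ll1 < ll0 - 1e-8) stop("EM log-likelihood decreased");
    // extrapolate k -> k2 along the step direction (SQUAREM S1)
    double r[3], v[3], rn = 0.0, vn = 0.0;
    for (int m = 0; m < 3; ++m) {
      r[m] = k1[m] - k[m];
      v[m] = k2[m] - k1[m] - r[m];
      rn += r[m] * r[m];
      vn += v[m] * v[m];
    }
    double ll_new;
    if (vn > 1e-30) {
      double alpha = -std::sqrt(rn) / std::sqrt(vn);
      if (alpha > -1.0) alpha = -1.0;
      for (int m = 0; m < 3; ++m)
        kc[m] = k[m] - 2.0 * alpha * r[m] + alpha * alpha * v[m];
      clamp_simplex(kc);
      double llc = ll_of(a0, a1, a2, n, kc);
      double ll2 = ll_of(a0, a1, a2, n, k2);
      if (llc >= ll2) {
        for (int m = 0; m < 3; ++m) k[m] = kc[m];
        ll_new = llc;
      } else {
        for (int m = 0; m < 3; ++m) k[m] = k2[m];
        ll_new = ll2;
      }
    } else {
      for (int m = 0; m < 3; ++m) k[m] = k2[m];
      ll_new = ll_of(a0, a1, a2, n, k2);
    }
    if (ll_new < ll - 1e-8) stop("EM log-likelihood decreased");
    ll_prev = ll;
    ll = ll_new;
    if (ll - ll_prev < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["k"] = NumericVector::create(k[0], k[1], k[2]),
                      _["loglik"] = ll, _["converged"] = converged);
}
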