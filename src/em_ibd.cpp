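#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// one EM sweep: input k, output k_new and the log-likelihood at the INPUT k
inline double em_sweep(const double *l0, const double *l1, const double *l2,
                       int S, double &k0, double &k1, double &k2) {
  double a0 = 0.0, a1 = 0.0, a2 = 0.0, ll = 0.0;
  for (int s = 0; s < S; ++s) {
    const double w0 = k0 * l0[s], w1 = k1 * l1[s], w2 = k2 * l2[s];
    const double t = w0 + w1 + w2;
    ll += std::log(t);
    a0 += w0 / t; a1 += w1 / t; a2 += w2 / t;
  }
  k0 = a0 / S; k1 = a1 / S; k2 = a2 / S;
  return ll;
}

inline double loglik_at(const double *l0, const double *l1, const double *l2,
                        int S, double k0, double k1, double k2) {
  double ll = 0.0;
  for (int s = 0; s < S; ++s)
    ll += std::log(k0 * l0[s] + k1 * l1[s] + k2 * l2[s]);
  return ll;
}

// clip to the simplex (non-negative, sum 1), keeping a tiny interior margin
inline void project_simplex(double &k0, double &k1, double &k2) {
  const double eps = 1e-12;
  if (k0 < eps) k0 = eps;
  if (k1 < eps) k1 = eps;
  if (k2 < eps) k2 = eps;
  const double t = k0 + k1 + k2;
  k0 /= t; k1 /= t; k2 /= t;
}

} // namespace

// EM maximization of the non-inbred pair IBD likelihood
//   L(k) = prod_s sum_d k_d P(g_i^s, g_j^s | IBD = d, p_s)
// over the 2-simplex, one pair per row of `pairs` (1-based sample indices),
// from the uniform start. A SQUAREM-style extrapolation is attempted each
// cycle and accepted only when it improves the log-likelihood, so the EM
// ascent property is preserved while boundary convergence (k at a simplex
// vertex, e.g. unrelated pairs) is accelerated. Iteration counts report EM
// sweeps. G is samples x markers with entries 0/1/2 (alt-allele dosage) or
// NA; markers missing in either member of a pair are skipped.
// Returns one row per pair: k0 k1 k2 loglik n_iter converged n_markers.
// [[Rcpp::export]]
NumericMatrix em_ibd_cpp(IntegerMatrix G, NumericVector p, IntegerMatrix pairs,
                         double tol, int max_iter) {
  const int S = G.ncol();
  const int m = pairs.nrow();

  // per-marker genotype-pair likelihood tables, indexed gi*3+gj
  std::vector<double> T0(S * 9), T1(S * 9), T2(S * 9);
  for (int s = 0; s < S; ++s) {
    const double ps = p[s], qs = 1.0 - ps;
    const double gp[3] = {qs * qs, 2.0 * ps * qs, ps * ps};
    double *t0 = &T0[s * 9], *t1 = &T1[s * 9], *t2 = &T2[s * 9];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        t0[a * 3 + b] = gp[a] * gp[b];
        t2[a * 3 + b] = (a == b) ? gp[a] : 0.0;
        t1[a * 3 + b] = 0.0;
      }
    t1[0 * 3 + 0] = qs * qs * qs;
    t1[2 * 3 + 2] = ps * ps * ps;
    t1[0 * 3 + 1] = t1[1 * 3 + 0] = ps * qs * qs;
    t1[2 * 3 + 1] = t1[1 * 3 + 2] = ps * ps * qs;
    t1[1 * 3 + 1] = ps * qs;
  }

  NumericMatrix out(m, 7);
  colnames(out) = CharacterVector::create("k0", "k1", "k2", "loglik",
                                          "n_iter", "converged", "n_markers");
  std::vector<double> l0, l1, l2;
  l0.reserve(S); l1.reserve(S); l2.reserve(S);

  for (int r = 0; r < m; ++r) {
    const int i = pairs(r, 0) - 1, j = pairs(r, 1) - 1;
    l0.clear(); l1.clear(); l2.clear();
    for (int s = 0; s < S; ++s) {
      const int gi = G(i, s), gj = G(j, s);
      if (gi == NA_INTEGER || gj == NA_INTEGER) continue;
      const int idx = gi * 3 + gj;
      l0.push_back(T0[s * 9 + idx]);
      l1.push_back(T1[s * 9 + idx]);
      l2.push_back(T2[s * 9 + idx]);
    }
    const int Su = (int)l0.size();
    if (Su == 0) {
      out(r, 0) = out(r, 1) = out(r, 2) = NA_REAL;
      out(r, 3) = NA_REAL; out(r, 4) = 0; out(r, 5) = 0; out(r, 6) = 0;
      continue;
    }
    const double *pl0 = l0.data(), *pl1 = l1.data(), *pl2 = l2.data();
    double k0 = 1.0 / 3.0, k1 = 1.0 / 3.0, k2 = 1.0 / 3.0;
    double ll_prev = -INFINITY, ll = 0.0;
    int sweeps = 0; bool conv = false;
    while (sweeps < max_iter) {
      // two plain EM sweeps
      double a0 = k0, a1 = k1, a2 = k2;
      ll = em_sweep(pl0, pl1, pl2, Su, a0, a1, a2);   // ll at current k
      double b0 = a0, b1 = a1, b2 = a2;
      em_sweep(pl0, pl1, pl2, Su, b0, b1, b2);
      sweeps += 2;
      if (ll - ll_prev < tol && sweeps > 2) { k0 = a0; k1 = a1; k2 = a2;
                                              conv = true; break; }
      ll_prev = ll;
      // SQUAREM extrapolation, accepted only if it does not lose likelihood
      const double r0 = a0 - k0, r1 = a1 - k1, r2 = a2 - k2;
      const double v0 = b0 - a0 - r0, v1 = b1 - a1 - r1, v2 = b2 - a2 - r2;
      const double nv = v0 * v0 + v1 * v1 + v2 * v2;
      double c0 = b0, c1 = b1, c2 = b2;
      if (nv > 1e-30) {
        const double alpha = -std::sqrt((r0 * r0 + r1 * r1 + r2 * r2) / nv);
        double s0 = k0 - 2.0 * alpha * r0 + alpha * alpha * v0;
        double s1 = k1 - 2.0 * alpha * r1 + alpha * alpha * v1;
        double s2 = k2 - 2.0 * alpha * r2 + alpha * alpha * v2;
        project_simplex(s0, s1, s2);
        const double ll_s = loglik_at(pl0, pl1, pl2, Su, s0, s1, s2);
        const double ll_b = loglik_at(pl0, pl1, pl2, Su, b0, b1, b2);
        if (ll_s >= ll_b) { c0 = s0; c1 = s1; c2 = s2; }
      }
      k0 = c0; k1 = c1; k2 = c2;
    }
    if (!conv) ll = loglik_at(pl0, pl1, pl2, Su, k0, k1, k2);
    out(r, 0) = k0; out(r, 1) = k1; out(r, 2) = k2;
    out(r, 3) = ll; out(r, 4) = sweeps; out(r, 5) = conv ? 1.0 : 0.0;
    out(r, 6) = Su;
  }
  return out;
}
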