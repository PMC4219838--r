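#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// RNG consumption contract (shared with the pure-R elementary_step):
//   1. one uniform -> target = floor(u * N)
//   2. situation variant only: one uniform -> independence branch (u < p)
//   3. independence branch: one uniform -> flip (u < f)
//   4. conformity branch: q uniforms -> partial Fisher-Yates positions
//      j = k + floor(u * (deg - k)), k = 0..q-1, over a copy of the
//      target's neighbour list; the first q entries form the group.
// All draws come from R's global stream (unif_rand), so set.seed() at the
// R level makes compiled and interpreted paths bit-identical.

// [[Rcpp::export]]
List cpp_run_steps(IntegerVector adj_ptr, IntegerVector adj_flat,
                   IntegerVector states0, LogicalVector indep,
                   int variant, double p, double f, int q,
                   double n_steps_d, int record_every, bool raster) {
  const int n = states0.size();
  const long n_steps = (long)n_steps_d;
  std::vector<int> st(states0.begin(), states0.end());
  long n_up = 0;
  for (int i = 0; i < n; ++i) n_up += st[i];

  const long n_rec = record_every > 0 ? n_steps / record_every : 0;
  NumericVector c_series(n_rec);
  IntegerMatrix ras = raster ? IntegerMatrix(n, (int)n_steps)
                             : IntegerMatrix(0, 0);

  // Sparse partial Fisher-Yates scratch: semantically identical to
  // shuffling a copy of the neighbour list, but touching only O(q)
  // positions (the copy would cost O(deg) per step on dense graphs).
  std::vector<int> mpos(2 * q + 2), mval(2 * q + 2), group(q);

  // action counts: independent_flip, independent_stay,
  //                conform_adopt_group_state, no_unanimity
  double cnt_if = 0, cnt_is = 0, cnt_cf = 0, cnt_nu = 0;
  double n_changed = 0;
  long rec_i = 0;

  for (long step = 0; step < n_steps; ++step) {
    int t = (int)(unif_rand() * n);
    if (t >= n) t = n - 1;
    bool independent = (variant == 0) ? (bool)indep[t] : (unif_rand() < p);
    if (independent) {
      if (unif_rand() < f) {
        st[t] = 1 - st[t];
        n_up += st[t] ? 1 : -1;
        cnt_if += 1; n_changed += 1;
      } else {
        cnt_is += 1;
      }
    } else {
      const int a = adj_ptr[t];
      const int deg = adj_ptr[t + 1] - a;
      if (deg < q)
        stop("insufficient degree: node %d has degree %d < q = %d",
             t + 1, deg, q);
      int mn = 0;  // displaced positions from earlier virtual swaps
      for (int k = 0; k < q; ++k) {
        int j = k + (int)(unif_rand() * (deg - k));
        if (j >= deg) j = deg - 1;
        int vj = adj_flat[a + j], vk = adj_flat[a + k];
        for (int i = 0; i < mn; ++i) {
          if (mpos[i] == j) vj = mval[i];
          if (mpos[i] == k) vk = mval[i];
        }
        group[k] = vj;
        // position j now holds the value displaced from position k
        bool found = false;
        for (int i = 0; i < mn; ++i)
          if (mpos[i] == j) { mval[i] = vk; found = true; break; }
        if (!found) { mpos[mn] = j; mval[mn] = vk; ++mn; }
      }
      const int s0 = st[group[0]];
      bool unanimous = true;
      for (int k = 1; k < q; ++k)
        if (st[group[k]] != s0) { unanimous = false; break; }
      if (unanimous) {
        cnt_cf += 1;
        if (st[t] != s0) {
          st[t] = s0;
          n_up += s0 ? 1 : -1;
          n_changed += 1;
        }
      } else {
        cnt_nu += 1;
      }
    }
    if (raster)
      for (int i = 0; i < n; ++i) ras(i, (int)step) = st[i];
    if (record_every > 0 && (step + 1) % record_every == 0)
      c_series[rec_i++] = (double)n_up / n;
  }

  List out = List::create(
    _["states"] = IntegerVector(st.begin(), st.end()),
    _["c_series"] = c_series,
    _["counts"] = NumericVector::create(
      _["independent_flip"] = cnt_if,
      _["independent_stay"] = cnt_is,
      _["conform_adopt_group_state"] = cnt_cf,
      _["no_unanimity"] = cnt_nu),
    _["n_changed"] = n_changed);
  if (raster) out["raster"] = ras;
  return out;
}

static inline double ipow(double x, int k) {
  double r = 1.0;
  for (int i = 0; i < k; ++i) r *= x;
  return r;
}

// Fixed-point iteration of the mean-field recursions with elementary-step
// scale inv_n = 1/N.  variant 0 = person (state (c_I, c_C)), 1 = situation
// (scalar c carried in cI).  Stops when every drift component (per unit
// time, i.e. N * per-step change) falls below tol; tol <= 0 runs exactly
// max_iter iterations (used by the bifurcation-scan stability oracle).
// [[Rcpp::export]]
List cpp_mf_iterate(int variant, double p, double f, int q,
                    double cI0, double cC0, double inv_n,
                    double tol, double max_iter) {
  double cI = cI0, cC = cC0;
  long it = 0;
  const long itmax = (long)max_iter;
  bool converged = false;
  while (it < itmax) {
    if (variant == 0) {
      const double c = cI + cC;
      const double dI = f * ((p - cI) - cI);
      const double dC = (1.0 - p - cC) * ipow(c, q)
                      - cC * ipow(1.0 - c, q);
      if (tol > 0 && std::fabs(dI) < tol && std::fabs(dC) < tol) {
        converged = true; break;
      }
      cI += inv_n * dI;
      cC += inv_n * dC;
    } else {
      const double c = cI;
      const double d = p * f * (1.0 - 2.0 * c)
        + (1.0 - p) * ((1.0 - c) * ipow(c, q) - c * ipow(1.0 - c, q));
      if (tol > 0 && std::fabs(d) < tol) { converged = true; break; }
      cI += inv_n * d;
    }
    ++it;
  }
  return List::create(_["c_I"] = cI, _["c_C"] = cC,
                      _["iterations"] = (double)it,
                      _["converged"] = converged);
}
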