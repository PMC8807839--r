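#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median of the first n elements of buf (buf is scratch, order destroyed).
static double med_n(std::vector<double> &buf, int n) {
  int h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + n);
  double hi = buf[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + h);
  return (lo + hi) / 2.0;
}

// SI = 100 * (1 - med_trained / med_naive); a zero naive median maps to the
// maximal-suppression sentinel 100 so permutation replicates are never
// discarded and n_perm stays fixed.
static double si_value(double med_t, double med_n_) {
  if (med_n_ == 0.0) return 100.0;
  return 100.0 * (1.0 - med_t / med_n_);
}

// In-place Fisher-Yates shuffle driven by R's RNG (deterministic under
// set.seed).
static void shuffle_pool(std::vector<double> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// Null SIs for H0: SI = 0. The pooled CI values are reassigned at random to
// simulated trained (first n_trained) and naive groups of the original sizes.
// [[Rcpp::export]]
NumericVector perm_si_pool(NumericVector pool, int n_trained, int n_perm) {
  int n = pool.size();
  if (n_trained <= 0 || n_trained >= n)
    stop("n_trained must be in (0, length(pool))");
  std::vector<double> v(pool.begin(), pool.end());
  int n_naive = n - n_trained;
  std::vector<double> buf_t(n_trained), buf_n(n_naive);
  NumericVector out(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    shuffle_pool(v);
    std::copy(v.begin(), v.begin() + n_trained, buf_t.begin());
    std::copy(v.begin() + n_trained, v.end(), buf_n.begin());
    out[p] = si_value(med_n(buf_t, n_trained), med_n(buf_n, n_naive));
  }
  return out;
}

// Null SI differences for H0: SI_exp = SI_ctrl. Arm labels (exp/ctrl) are
// permuted independently within the trained pool and within the naive pool,
// preserving group sizes; the trained/naive structure is not under test and
// is never shuffled.
// [[Rcpp::export]]
NumericVector perm_si_diff(NumericVector trained_pool, int n_exp_trained,
                           NumericVector naive_pool, int n_exp_naive,
                           int n_perm) {
  int nt = trained_pool.size(), nn = naive_pool.size();
  if (n_exp_trained <= 0 || n_exp_trained >= nt)
    stop("n_exp_trained must be in (0, length(trained_pool))");
  if (n_exp_naive <= 0 || n_exp_naive >= nn)
    stop("n_exp_naive must be in (0, length(naive_pool))");
  std::vector<double> vt(trained_pool.begin(), trained_pool.end());
  std::vector<double> vn(naive_pool.begin(), naive_pool.end());
  int nct = nt - n_exp_trained, ncn = nn - n_exp_naive;
  std::vector<double> b1(std::max(nt, nn));
  NumericVector out(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    shuffle_pool(vt);
    shuffle_pool(vn);
    std::copy(vt.begin(), vt.begin() + n_exp_trained, b1.begin());
    double met = med_n(b1, n_exp_trained);
    std::copy(vt.begin() + n_exp_trained, vt.end(), b1.begin());
    double mct = med_n(b1, nct);
    std::copy(vn.begin(), vn.begin() + n_exp_naive, b1.begin());
    double men = med_n(b1, n_exp_naive);
    std::copy(vn.begin() + n_exp_naive, vn.end(), b1.begin());
    double mcn = med_n(b1, ncn);
    out[p] = si_value(met, men) - si_value(mct, mcn);
  }
  return out;
}
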