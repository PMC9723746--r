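#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted sampling without replacement by exponential keys
// (Efraimidis-Spirakis): taking the k items with the smallest Exp(1)/w keys
// is equal in law to k successive draws with probability proportional to the
// remaining weights. Uses R's RNG so results are governed by set.seed().
static void weighted_subset(const NumericVector& w, int k,
                            std::vector<int>& idx, std::vector<double>& key,
                            std::vector<int>& out) {
  const int n = w.size();
  for (int t = 0; t < n; ++t) {
    key[t] = R::exp_rand() / w[t];
    idx[t] = t;
  }
  std::nth_element(idx.begin(), idx.begin() + k, idx.end(),
                   [&](int a, int b) { return key[a] < key[b]; });
  out.assign(idx.begin(), idx.begin() + k);
}

// Null distribution of the shared-species count between two communities of
// fixed richness alpha_i and alpha_j drawn from a weighted regional pool.
// [[Rcpp::export]]
IntegerVector rc_null_shared(NumericVector w, int alpha_i, int alpha_j,
                             int nrand) {
  const int n = w.size();
  if (alpha_i < 1 || alpha_j < 1 || alpha_i > n || alpha_j > n)
    stop("richness out of range for pool of size %d", n);
  for (int t = 0; t < n; ++t)
    if (!(w[t] > 0)) stop("pool weights must be positive");
  IntegerVector ss(nrand);
  std::vector<int> idx(n), a, b;
  std::vector<double> key(n);
  std::vector<char> flag(n, 0);
  for (int r = 0; r < nrand; ++r) {
    weighted_subset(w, alpha_i, idx, key, a);
    weighted_subset(w, alpha_j, idx, key, b);
    for (int t : a) flag[t] = 1;
    int shared = 0;
    for (int t : b) shared += flag[t];
    for (int t : a) flag[t] = 0;
    ss[r] = shared;
  }
  return ss;
}

// Zero-sum neutral drift: each update kills one uniformly chosen individual
// and replaces it from the metacommunity (probability m, cumulative shares
// meta_cum) or from the post-death local community.
// [[Rcpp::export]]
IntegerVector neutral_drift_cpp(IntegerVector counts0, NumericVector meta_cum,
                                double m, int n_updates) {
  IntegerVector counts = clone(counts0);
  const int S = counts.size();
  long J = 0;
  for (int t = 0; t < S; ++t) J += counts[t];
  if (J <= 0) stop("empty local community");
  for (int u = 0; u < n_updates; ++u) {
    // death
    double r = unif_rand() * J;
    double acc = 0.0;
    int dead = S - 1;
    for (int t = 0; t < S; ++t) {
      acc += counts[t];
      if (r < acc) { dead = t; break; }
    }
    counts[dead]--;
    // birth
    int born;
    if (unif_rand() < m) {
      double v = unif_rand();
      born = std::lower_bound(meta_cum.begin(), meta_cum.end(), v) -
             meta_cum.begin();
      if (born >= S) born = S - 1;
    } else {
      double r2 = unif_rand() * (J - 1);
      double acc2 = 0.0;
      born = S - 1;
      for (int t = 0; t < S; ++t) {
        acc2 += counts[t];
        if (r2 < acc2) { born = t; break; }
      }
    }
    counts[born]++;
  }
  return counts;
}
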