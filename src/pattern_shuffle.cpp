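#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Monte-Carlo null for per-gene cluster patterns.
//
// Each shuffle draws, without replacement, k positions uniformly from the
// gene's eligible (non-A 3'UTR) positions, partitions them into clusters at
// the given maximal gap, and compares the resulting size histogram with the
// observed one. Uses R's RNG, so results are reproducible under set.seed().
//
// observed_hist[s-1] = number of observed clusters of size s, s = 1..k.
// Returns the match count and the accumulated null size frequencies.

// [[Rcpp::export]]
List cpp_pattern_shuffle(IntegerVector eligible, int k, int n_shuffles,
                         int max_gap, IntegerVector observed_hist) {
  const int m = eligible.size();
  if (k < 1) stop("need at least one isoform");
  if (k > m) stop("more isoforms than eligible positions");
  if (observed_hist.size() != k) stop("observed_hist must have length k");

  std::vector<int> elig(eligible.begin(), eligible.end());
  std::sort(elig.begin(), elig.end());

  std::vector<int> idx(m), pick(k), hist(k + 1);
  std::vector<double> size_tot(k + 1, 0.0);
  double matches = 0;

  for (int s = 0; s < n_shuffles; ++s) {
    for (int i = 0; i < m; ++i) idx[i] = i;
    for (int i = 0; i < k; ++i) {  // partial Fisher-Yates
      int j = i + static_cast<int>(unif_rand() * (m - i));
      if (j >= m) j = m - 1;
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < k; ++i) pick[i] = elig[idx[i]];
    std::sort(pick.begin(), pick.end());

    std::fill(hist.begin(), hist.end(), 0);
    int run = 1;
    for (int i = 1; i < k; ++i) {
      if (pick[i] - pick[i - 1] <= max_gap) {
        ++run;
      } else {
        ++hist[run];
        run = 1;
      }
    }
    ++hist[run];

    bool match = true;
    for (int sz = 1; sz <= k; ++sz) {
      size_tot[sz] += hist[sz];
      if (hist[sz] != observed_hist[sz - 1]) match = false;
    }
    if (match) ++matches;
  }

  NumericVector null_sizes(k);
  for (int sz = 1; sz <= k; ++sz) null_sizes[sz - 1] = size_tot[sz];
  return List::create(_["matches"] = matches, _["null_size_counts"] = null_sizes);
}
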