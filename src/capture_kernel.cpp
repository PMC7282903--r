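#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo allele-capture curve kernel.
//
// Each replicate draws one uniform random permutation of the N wild
// individuals (Fisher-Yates on R's RNG stream, so results are reproducible
// via set.seed in R). The size-n prefix of a uniform permutation is exactly
// a simple random sample of n individuals without replacement, so reading
// every grid size off prefixes gives the correct per-size distribution while
// costing one permutation per replicate instead of N samples.
//
// carriers:   list of 0-based integer vectors; carriers[a] = indices of the
//             individuals carrying allele a (each vector non-empty).
// categories: list of 0-based integer vectors of allele indices.
// n_ind:      N, the number of wild individuals.
// replicates: number of Monte-Carlo permutations.
//
// Returns per (size, category) the running sum and sum of squares of the
// percent of the category's alleles captured, for sizes 1..N.
// [[Rcpp::export]]
List capture_curve_kernel(List carriers, List categories, int n_ind,
                          int replicates) {
  const int m = carriers.size();
  const int k = categories.size();

  std::vector<std::vector<int>> carr(m);
  for (int a = 0; a < m; ++a) {
    IntegerVector v = carriers[a];
    if (v.size() == 0) stop("allele with no carriers");
    carr[a].assign(v.begin(), v.end());
  }
  std::vector<std::vector<int>> cats(k);
  for (int c = 0; c < k; ++c) {
    IntegerVector v = categories[c];
    cats[c].assign(v.begin(), v.end());
  }

  NumericMatrix sum(n_ind, k), sumsq(n_ind, k);
  std::vector<int> idx(n_ind), pos(n_ind), firstcap(m);
  std::vector<int> cnt(n_ind + 1);

  for (int r = 0; r < replicates; ++r) {
    for (int i = 0; i < n_ind; ++i) idx[i] = i;
    for (int i = n_ind - 1; i > 0; --i) {
      int j = (int) R_unif_index(i + 1);
      std::swap(idx[i], idx[j]);
    }
    // pos[ind] = 1-based position of individual ind in the permutation
    for (int p = 0; p < n_ind; ++p) pos[idx[p]] = p + 1;
    for (int a = 0; a < m; ++a) {
      int best = n_ind + 1;
      for (int ci : carr[a]) {
        int p = pos[ci];
        if (p < best) best = p;
      }
      firstcap[a] = best;  // allele a is captured by prefixes of size >= best
    }
    for (int c = 0; c < k; ++c) {
      const std::vector<int>& al = cats[c];
      if (al.empty()) continue;
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int a : al) cnt[firstcap[a]] += 1;
      double cum = 0.0, denom = (double) al.size();
      for (int n = 1; n <= n_ind; ++n) {
        cum += cnt[n];
        double pct = 100.0 * cum / denom;
        sum(n - 1, c) += pct;
        sumsq(n - 1, c) += pct * pct;
      }
    }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq);
}
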