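#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov-like running-sum enrichment score over a ranked
// gene list. Hits are weighted by the ranking weight (exponent 1, hit weights
// normalized to sum 1), misses decrement by 1/(N - |S|); the score is the
// maximum deviation from zero of the running sum (signed). Shared by the
// per-cell and per-voxel GSEA front ends.

namespace {

// positions: 0-based hit positions in ranked order, strictly increasing
double es_from_hits(const std::vector<int>& pos, const NumericVector& w, int N) {
  int k = (int)pos.size();
  if (k == 0 || k >= N) return NA_REAL;
  double sumw = 0.0;
  for (int j = 0; j < k; ++j) sumw += w[pos[j]];
  double miss = 1.0 / (double)(N - k);
  double cum = 0.0, mx = 0.0, mn = 0.0;
  for (int j = 0; j < k; ++j) {
    double frac_before = sumw > 0 ? cum / sumw : (double)j / k;
    double run_before = frac_before - (double)(pos[j] - j) * miss;
    if (run_before < mn) mn = run_before;
    cum += w[pos[j]];
    double frac_after = sumw > 0 ? cum / sumw : (double)(j + 1) / k;
    double run_after = frac_after - (double)(pos[j] - j) * miss;
    if (run_after > mx) mx = run_after;
  }
  return (mx >= -mn) ? mx : mn;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".gsea_es_cpp")]]
double gsea_es_cpp(NumericVector weights, IntegerVector hit_pos1) {
  int N = weights.size();
  std::vector<int> pos(hit_pos1.size());
  for (int i = 0; i < hit_pos1.size(); ++i) pos[i] = hit_pos1[i] - 1;
  std::sort(pos.begin(), pos.end());
  return es_from_hits(pos, weights, N);
}

// Observed ES plus gene-label permutation null: each permutation redraws the
// |S| hit positions uniformly without replacement. Uses R's RNG so results
// are reproducible under set.seed().
//' @noRd
// [[Rcpp::export(name = ".gsea_es_perm_cpp")]]
List gsea_es_perm_cpp(NumericVector weights, IntegerVector hit_pos1, int n_perm) {
  int N = weights.size();
  int k = hit_pos1.size();
  std::vector<int> pos(k);
  for (int i = 0; i < k; ++i) pos[i] = hit_pos1[i] - 1;
  std::sort(pos.begin(), pos.end());
  double obs = es_from_hits(pos, weights, N);

  NumericVector perm(n_perm);
  int n_ge = 0;
  std::vector<int> draw(k);
  for (int p = 0; p < n_perm; ++p) {
    IntegerVector s = Rcpp::sample(N, k); // 1-based, without replacement
    for (int i = 0; i < k; ++i) draw[i] = s[i] - 1;
    std::sort(draw.begin(), draw.end());
    double e = es_from_hits(draw, weights, N);
    perm[p] = e;
    if (e >= obs) ++n_ge;
  }
  return List::create(_["es"] = obs, _["perm_es"] = perm, _["n_ge"] = n_ge);
}
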