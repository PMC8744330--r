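#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Null counts for the ligand-receptor permutation test: each permutation
// replaces the source/target marker sets by uniform draws (without
// replacement, matching sizes) from the expressed-gene pool and counts the
// database pairs falling inside both. Uses R's RNG.
//' @noRd
// [[Rcpp::export(name = ".lr_null_counts_cpp")]]
IntegerVector lr_null_counts_cpp(IntegerVector lig_idx, IntegerVector rec_idx,
                                 int n_src, int n_tgt, int n_genes, int n_perm) {
  int m = lig_idx.size();
  IntegerVector out(n_perm);
  std::vector<char> in_s(n_genes + 1), in_t(n_genes + 1);
  for (int p = 0; p < n_perm; ++p) {
    IntegerVector s = Rcpp::sample(n_genes, n_src);
    IntegerVector t = Rcpp::sample(n_genes, n_tgt);
    std::fill(in_s.begin(), in_s.end(), 0);
    std::fill(in_t.begin(), in_t.end(), 0);
    for (int i = 0; i < n_src; ++i) in_s[s[i]] = 1;
    for (int i = 0; i < n_tgt; ++i) in_t[t[i]] = 1;
    int cnt = 0;
    for (int i = 0; i < m; ++i) {
      if (in_s[lig_idx[i]] && in_t[rec_idx[i]]) ++cnt;
    }
    out[p] = cnt;
  }
  return out;
}
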