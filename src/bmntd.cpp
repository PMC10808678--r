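#include <Rcpp.h>
using namespace Rcpp;

// Pairwise beta mean nearest taxon distance for all sample pairs.
//
// relab: samples x taxa relative abundances (rows may sum to anything > 0;
//        they are renormalised over taxa present). D: taxa x taxa patristic
//        distances in the same column order. A taxon shared by both samples
//        contributes its self-distance (0). Called once per null permutation
//        with a row/column-permuted D, so the inner loops stay allocation-free.
// [[Rcpp::export(name = ".bmntd_pairs_cpp")]]
NumericMatrix bmntd_pairs_cpp(NumericMatrix relab, NumericMatrix D,
                              bool abundance_weighted) {
  int S = relab.nrow(), T = relab.ncol();
  if (D.nrow() != T || D.ncol() != T)
    stop("distance matrix does not match taxon count");
  NumericMatrix out(S, S);
  std::vector< std::vector<int> > present(S);
  std::vector< std::vector<double> > weight(S);
  for (int s = 0; s < S; ++s) {
    double tot = 0.0;
    for (int t = 0; t < T; ++t) tot += relab(s, t);
    for (int t = 0; t < T; ++t) {
      if (relab(s, t) > 0.0) {
        present[s].push_back(t);
        weight[s].push_back(relab(s, t) / tot);
      }
    }
  }
  for (int a = 0; a < S; ++a) {
    for (int b = a + 1; b < S; ++b) {
      const std::vector<int> &ta = present[a], &tb = present[b];
      if (ta.empty() || tb.empty()) {
        out(a, b) = out(b, a) = NA_REAL;
        continue;
      }
      double acc_a = 0.0, wsum_a = 0.0;
      for (size_t i = 0; i < ta.size(); ++i) {
        double mn = R_PosInf;
        for (size_t j = 0; j < tb.size(); ++j) {
          double d = D(ta[i], tb[j]);
          if (d < mn) mn = d;
        }
        double w = abundance_weighted ? weight[a][i] : 1.0 / ta.size();
        acc_a += w * mn;
        wsum_a += w;
      }
      double acc_b = 0.0, wsum_b = 0.0;
      for (size_t j = 0; j < tb.size(); ++j) {
        double mn = R_PosInf;
        for (size_t i = 0; i < ta.size(); ++i) {
          double d = D(ta[i], tb[j]);
          if (d < mn) mn = d;
        }
        double w = abundance_weighted ? weight[b][j] : 1.0 / tb.size();
        acc_b += w * mn;
        wsum_b += w;
      }
      out(a, b) = out(b, a) = 0.5 * (acc_a / wsum_a + acc_b / wsum_b);
    }
  }
  return out;
}
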