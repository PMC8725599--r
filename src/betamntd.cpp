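#include <Rcpp.h>
using namespace Rcpp;

// Beta mean-nearest-taxon distance between all sample pairs.
//
// D: taxa x taxa patristic distance matrix.
// W: taxa x samples abundance matrix (relative abundances when weighted).
// weighted: abundance-weighted (true) or presence-based mean (false).
//
// betaMNTD(j,k) = 0.5 * [ sum_i f_ij * min_{i' in k} D(i,i')
//                       + sum_i f_ik * min_{i' in j} D(i,i') ]
// where the minimum runs over taxa present in the other sample (a taxon
// present in both samples matches itself at distance 0).
// [[Rcpp::export]]
NumericMatrix betamntd_cpp(const NumericMatrix& D, const NumericMatrix& W,
                           bool weighted) {
  const int ntaxa = W.nrow(), nsamp = W.ncol();
  if (D.nrow() != ntaxa || D.ncol() != ntaxa)
    stop("distance matrix does not match taxon count");

  // presence lists per sample
  std::vector<std::vector<int> > present(nsamp);
  for (int s = 0; s < nsamp; ++s)
    for (int i = 0; i < ntaxa; ++i)
      if (W(i, s) > 0) present[s].push_back(i);

  NumericMatrix out(nsamp, nsamp);
  for (int j = 0; j < nsamp; ++j) {
    for (int k = j + 1; k < nsamp; ++k) {
      const std::vector<int>& pj = present[j];
      const std::vector<int>& pk = present[k];
      if (pj.empty() || pk.empty())
        stop("sample with zero total in betaMNTD");
      double half = 0.0;
      // direction j -> k
      double acc = 0.0, wtot = 0.0;
      for (size_t a = 0; a < pj.size(); ++a) {
        const int i = pj[a];
        double mn = R_PosInf;
        for (size_t b = 0; b < pk.size(); ++b) {
          const double d = D(i, pk[b]);
          if (d < mn) mn = d;
        }
        const double w = weighted ? W(i, j) : 1.0;
        acc += w * mn;
        wtot += w;
      }
      half += acc / wtot;
      // direction k -> j
      acc = 0.0; wtot = 0.0;
      for (size_t a = 0; a < pk.size(); ++a) {
        const int i = pk[a];
        double mn = R_PosInf;
        for (size_t b = 0; b < pj.size(); ++b) {
          const double d = D(i, pj[b]);
          if (d < mn) mn = d;
        }
        const double w = weighted ? W(i, k) : 1.0;
        acc += w * mn;
        wtot += w;
      }
      half += acc / wtot;
      out(j, k) = out(k, j) = 0.5 * half;
    }
  }
  return out;
}

// Null betaMNTD distributions under tip-label shuffling.
//
// perms: ntaxa x n_null matrix of 1-based permutations mapping taxon i to
// tip perms(i, t) in randomization t; D is indexed through the permutation
// so the community matrix W stays fixed. Returns running mean and M2 so the
// caller can derive the null mean and sd without storing all draws.
// [[Rcpp::export]]
List betamntd_null_cpp(const NumericMatrix& D, const NumericMatrix& W,
                       bool weighted, const IntegerMatrix& perms) {
  const int ntaxa = W.nrow(), nsamp = W.ncol(), nnull = perms.ncol();
  NumericMatrix mean(nsamp, nsamp), m2(nsamp, nsamp);
  NumericMatrix Dp(ntaxa, ntaxa);
  for (int t = 0; t < nnull; ++t) {
    for (int a = 0; a < ntaxa; ++a)
      for (int b = 0; b < ntaxa; ++b)
        Dp(a, b) = D(perms(a, t) - 1, perms(b, t) - 1);
    NumericMatrix bm = betamntd_cpp(Dp, W, weighted);
    // Welford update per pair
    for (int j = 0; j < nsamp; ++j)
      for (int k = j + 1; k < nsamp; ++k) {
        const double delta = bm(j, k) - mean(j, k);
        mean(j, k) += delta / (t + 1);
        m2(j, k) += delta * (bm(j, k) - mean(j, k));
      }
  }
  NumericMatrix sd(nsamp, nsamp);
  for (int j = 0; j < nsamp; ++j)
    for (int k = j + 1; k < nsamp; ++k) {
      const double s = nnull > 1 ? std::sqrt(m2(j, k) / (nnull - 1)) : 0.0;
      sd(j, k) = sd(k, j) = s;
      mean(k, j) = mean(j, k);
    }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}
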