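#include <Rcpp.h>
using namespace Rcpp;

// Pairwise transition/transversion/overlap counts over a coded alignment.
// `codes` is L x n (one column per specimen): 0 = not comparable (N or gap),
// 1 = A, 2 = G, 3 = C, 4 = T.  Purines are codes <= 2, pyrimidines >= 3, so a
// mismatch within the same half is a transition, across halves a transversion.
// Pairs are emitted in stats::dist order: (1,2),(1,3),...,(1,n),(2,3),...
// [[Rcpp::export]]
List pair_counts_cpp(const IntegerMatrix& codes) {
  const int L = codes.nrow(), n = codes.ncol();
  const R_xlen_t np = (R_xlen_t)n * (n - 1) / 2;
  IntegerVector ov(np), ti(np), tv(np);
  const int* x = INTEGER(codes);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i) {
    const int* a = x + (R_xlen_t)i * L;
    for (int j = i + 1; j < n; ++j, ++k) {
      const int* b = x + (R_xlen_t)j * L;
      int o = 0, t = 0, v = 0;
      for (int p = 0; p < L; ++p) {
        const int ca = a[p], cb = b[p];
        if (ca == 0 || cb == 0) continue;
        ++o;
        if (ca != cb) {
          if ((ca <= 2) == (cb <= 2)) ++t; else ++v;
        }
      }
      ov[k] = o; ti[k] = t; tv[k] = v;
    }
  }
  return List::create(_["overlap"] = ov,
                      _["transitions"] = ti,
                      _["transversions"] = tv);
}
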