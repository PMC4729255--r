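#include <Rcpp.h>
using namespace Rcpp;

// Independent-swap chain engine: performs successful 2x2 checkerboard
// swaps on a binary matrix using R's RNG stream (so set.seed() governs
// reproducibility). Rejected attempts (non-checkerboard 2x2 submatrices)
// do not count towards n_swaps; attempts are capped by max_attempts.
// [[Rcpp::export(name = ".swap_engine")]]
IntegerMatrix swap_engine(IntegerMatrix mat, double n_swaps,
                          double max_attempts) {
  IntegerMatrix m = clone(mat);
  int nr = m.nrow(), nc = m.ncol();
  double done = 0.0, attempts = 0.0;
  if (nr >= 2 && nc >= 2) {
    while (done < n_swaps && attempts < max_attempts) {
      attempts += 1.0;
      int r1 = (int)(unif_rand() * nr); if (r1 >= nr) r1 = nr - 1;
      int r2 = (int)(unif_rand() * nr); if (r2 >= nr) r2 = nr - 1;
      int c1 = (int)(unif_rand() * nc); if (c1 >= nc) c1 = nc - 1;
      int c2 = (int)(unif_rand() * nc); if (c2 >= nc) c2 = nc - 1;
      if (r1 == r2 || c1 == c2) continue;
      int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
      if (a == d && b == c && a != b) {
        m(r1, c1) = b; m(r1, c2) = a;
        m(r2, c1) = d; m(r2, c2) = c;
        done += 1.0;
      }
    }
  }
  m.attr("swaps_done") = done;
  m.attr("attempts") = attempts;
  return m;
}
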