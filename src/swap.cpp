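#include <Rcpp.h>
using namespace Rcpp;

// Trial-swap Markov chain on a binary matrix: repeatedly pick a random
// 2 x 2 submatrix and swap it when it is a checkerboard. Row and column
// totals are invariant. Runs until n_swaps successful swaps or
// max_attempts proposals, whichever comes first. Uses R's RNG so results
// are reproducible under set.seed()/withr::with_seed().
// [[Rcpp::export]]
List swap_chain_cpp(IntegerMatrix b, double n_swaps, double max_attempts) {
  IntegerMatrix m = clone(b);
  int nr = m.nrow(), nc = m.ncol();
  double swaps = 0, attempts = 0;
  if (nr >= 2 && nc >= 2 && n_swaps >= 1) {
    while (swaps < n_swaps && attempts < max_attempts) {
      attempts += 1;
      int i = (int)(unif_rand() * nr);
      int k = (int)(unif_rand() * (nr - 1));
      if (k >= i) k++;
      int j = (int)(unif_rand() * nc);
      int l = (int)(unif_rand() * (nc - 1));
      if (l >= j) l++;
      // checkerboard: equal diagonal cells, complementary off-diagonal
      int a = m(i, j);
      if (m(k, l) == a && m(i, l) == 1 - a && m(k, j) == 1 - a) {
        m(i, j) = 1 - a;
        m(k, l) = 1 - a;
        m(i, l) = a;
        m(k, j) = a;
        swaps += 1;
      }
    }
  }
  return List::create(_["m"] = m, _["swaps"] = swaps);
}
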