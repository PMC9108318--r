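#include <Rcpp.h>
using namespace Rcpp;

// Trial-swap chain for the fixed-fixed null model: each trial picks two rows
// and two columns at random; when the 2x2 submatrix is a checkerboard
// ([[1,0],[0,1]] or [[0,1],[1,0]]) it is flipped, preserving every row and
// column sum exactly.  Uses R's RNG so set.seed() governs the chain.
static void run_trial_swaps(IntegerMatrix m, const int nswaps) {
  const int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2) return;
  for (int s = 0; s < nswaps; ++s) {
    int r1 = static_cast<int>(unif_rand() * nr);
    int r2 = static_cast<int>(unif_rand() * (nr - 1));
    if (r2 >= r1) ++r2;
    int c1 = static_cast<int>(unif_rand() * nc);
    int c2 = static_cast<int>(unif_rand() * (nc - 1));
    if (c2 >= c1) ++c2;
    const int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    if (a == d && b == c && a != b) {
      m(r1, c1) = b; m(r1, c2) = a;
      m(r2, c1) = d; m(r2, c2) = c;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix swap_randomize_cpp(const IntegerMatrix m, const int nswaps) {
  IntegerMatrix out = clone(m);
  run_trial_swaps(out, nswaps);
  return out;
}

// Null distribution of pairwise Jaccard dissimilarities from one sequential
// swap chain: burn-in, then n_null draws separated by `thin` trial swaps.
// `pairs` holds 0-based row indices (n_pairs x 2).  Returns n_pairs x n_null.
// Pairs with an empty union get 0 when empty_union_zero, otherwise NA.
// [[Rcpp::export]]
NumericMatrix null_pair_jaccard_cpp(const IntegerMatrix m,
                                    const IntegerMatrix pairs,
                                    const int n_null, const int burn_in,
                                    const int thin,
                                    const bool empty_union_zero) {
  IntegerMatrix w = clone(m);
  run_trial_swaps(w, burn_in);
  const int np = pairs.nrow(), nc = m.ncol();
  NumericMatrix out(np, n_null);
  for (int k = 0; k < n_null; ++k) {
    run_trial_swaps(w, thin);
    for (int p = 0; p < np; ++p) {
      const int i = pairs(p, 0), j = pairs(p, 1);
      int inter = 0, uni = 0;
      for (int c = 0; c < nc; ++c) {
        const int a = w(i, c), b = w(j, c);
        inter += a & b;
        uni += a | b;
      }
      if (uni == 0) {
        out(p, k) = empty_union_zero ? 0.0 : NA_REAL;
      } else {
        out(p, k) = 1.0 - static_cast<double>(inter) / uni;
      }
    }
  }
  return out;
}
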