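#include <Rcpp.h>
using namespace Rcpp;

// Permutation null for the perfect-identity fragment scan.
//
// B: n_pair x n_poly 0/1 matrix; B(p, j) == 1 iff sequence pair p is
// identical at the j-th polymorphic column. For each of n_perm random
// permutations of the column order (one shared permutation per replicate,
// conditioning on the observed pattern of variable sites), returns each
// pair's maximal run of identical polymorphic sites.
//
// Uses R's RNG (deterministic under set.seed from the caller).
// [[Rcpp::export]]
IntegerMatrix perm_max_runs(IntegerMatrix B, int n_perm) {
  const int np = B.nrow(), n = B.ncol();
  IntegerMatrix out(n_perm, np);
  if (n == 0 || np == 0) return out;
  std::vector<int> idx(n);
  for (int j = 0; j < n; ++j) idx[j] = j;
  // column-major copy: all pairs for one polymorphic column are contiguous,
  // so visiting columns in permuted order stays cache-friendly
  std::vector<unsigned char> M((size_t)np * n);
  for (int j = 0; j < n; ++j)
    for (int p = 0; p < np; ++p)
      M[(size_t)j * np + p] = (unsigned char)(B(p, j) != 0);
  std::vector<int> run(np), best(np);
  for (int r = 0; r < n_perm; ++r) {
    for (int j = n - 1; j > 0; --j) {           // Fisher-Yates shuffle
      int k = (int)(unif_rand() * (j + 1));
      if (k > j) k = j;
      std::swap(idx[j], idx[k]);
    }
    std::fill(run.begin(), run.end(), 0);
    std::fill(best.begin(), best.end(), 0);
    for (int j = 0; j < n; ++j) {
      const unsigned char *col = &M[(size_t)idx[j] * np];
      for (int p = 0; p < np; ++p) {
        int rr = col[p] ? run[p] + 1 : 0;
        run[p] = rr;
        if (rr > best[p]) best[p] = rr;
      }
    }
    for (int p = 0; p < np; ++p) out(r, p) = best[p];
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Maximal run of 1s in each row of B (observed statistic per pair).
// [[Rcpp::export]]
IntegerVector row_max_runs(IntegerMatrix B) {
  const int np = B.nrow(), n = B.ncol();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    int run = 0, best = 0;
    for (int j = 0; j < n; ++j) {
      if (B(p, j) != 0) {
        if (++run > best) best = run;
      } else run = 0;
    }
    out[p] = best;
  }
  return out;
}
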