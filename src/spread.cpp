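#include <Rcpp.h>
using namespace Rcpp;

// Stochastic 3x3 spread kernel.
//
// Occupancy and suitability are passed as R matrices (column-major,
// n_rows x n_cols). A cell is occupied at t+1 iff at least one cell of its
// 3x3 neighbourhood (8 neighbours plus itself) is occupied at t and an
// independent Bernoulli(s) trial for the cell succeeds; grid edges truncate
// the neighbourhood. One uniform deviate is consumed per non-missing cell
// per step, in fixed column-major order, regardless of the occupancy
// pattern: runs that share a seed are therefore coupled through identical
// deviates, which makes occupancy path-wise monotone in the suitability
// values.
//
// The 3x3 "any neighbour occupied" test is evaluated for the whole grid by
// two separable dilation passes (vertical then horizontal smear), which is
// what keeps long runs (hundreds of iterations on 10^4-cell grids) cheap.

static void dilate3x3(const std::vector<char> &occ, std::vector<char> &tmp,
                      std::vector<char> &dil, int nr, int nc) {
  for (int c = 0; c < nc; ++c) {
    const char *col = &occ[(size_t)c * nr];
    char *out = &tmp[(size_t)c * nr];
    for (int r = 0; r < nr; ++r) {
      char v = col[r];
      if (r > 0) v |= col[r - 1];
      if (r < nr - 1) v |= col[r + 1];
      out[r] = v;
    }
  }
  for (int c = 0; c < nc; ++c) {
    const char *mid = &tmp[(size_t)c * nr];
    const char *lft = c > 0 ? &tmp[(size_t)(c - 1) * nr] : NULL;
    const char *rgt = c < nc - 1 ? &tmp[(size_t)(c + 1) * nr] : NULL;
    char *out = &dil[(size_t)c * nr];
    for (int r = 0; r < nr; ++r) {
      char v = mid[r];
      if (lft) v |= lft[r];
      if (rgt) v |= rgt[r];
      out[r] = v;
    }
  }
}

// [[Rcpp::export]]
LogicalMatrix cpp_spread_step(LogicalMatrix occupancy, NumericMatrix s) {
  int nr = occupancy.nrow(), nc = occupancy.ncol();
  size_t n = (size_t)nr * nc;
  if (s.nrow() != nr || s.ncol() != nc)
    stop("occupancy and suitability must share dimensions");
  std::vector<char> occ(n), tmp(n), dil(n);
  for (size_t i = 0; i < n; ++i) {
    if (occupancy[i] == TRUE && NumericMatrix::is_na(s[i]))
      stop("occupied cell with missing suitability");
    occ[i] = occupancy[i] == TRUE ? 1 : 0;
  }
  dilate3x3(occ, tmp, dil, nr, nc);
  LogicalMatrix out(nr, nc);
  for (size_t i = 0; i < n; ++i) {
    if (NumericMatrix::is_na(s[i])) { out[i] = FALSE; continue; }
    double u = unif_rand();
    out[i] = dil[i] && (u < s[i]);
  }
  return out;
}

// First-occurrence iteration per cell for one stochastic replicate.
// origins are 0-based column-major indices, occupied unconditionally from
// t = 0 on (they model an external source pool and are exempt from local
// extinction). Returns NA for cells never occupied within `iterations`
// steps.
// [[Rcpp::export]]
IntegerMatrix cpp_first_occurrence(NumericMatrix s, IntegerVector origins,
                                   int iterations) {
  int nr = s.nrow(), nc = s.ncol();
  size_t n = (size_t)nr * nc;
  if (iterations < 1) stop("iterations must be >= 1");
  std::vector<char> occ(n, 0), nxt(n, 0), tmp(n), dil(n), miss(n);
  std::vector<char> orig(n, 0);
  for (size_t i = 0; i < n; ++i)
    miss[i] = NumericMatrix::is_na(s[i]) ? 1 : 0;
  IntegerMatrix tfirst(nr, nc);
  std::fill(tfirst.begin(), tfirst.end(), NA_INTEGER);
  for (int k = 0; k < origins.size(); ++k) {
    int i = origins[k];
    if (i < 0 || (size_t)i >= n) stop("origin index out of range");
    if (miss[i]) stop("origin on missing suitability");
    occ[i] = 1; orig[i] = 1; tfirst[i] = 0;
  }
  for (int t = 1; t <= iterations; ++t) {
    dilate3x3(occ, tmp, dil, nr, nc);
    for (size_t i = 0; i < n; ++i) {
      if (miss[i]) { nxt[i] = 0; continue; }
      double u = unif_rand();
      if (orig[i]) { nxt[i] = 1; continue; }
      nxt[i] = dil[i] && (u < s[i]);
      if (nxt[i] && tfirst[i] == NA_INTEGER) tfirst[i] = t;
    }
    std::swap(occ, nxt);
  }
  return tfirst;
}
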