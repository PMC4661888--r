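#include <Rcpp.h>
using namespace Rcpp;

// Raw log-odds scores of every length-w window of every sequence.
// codes: L x n integer matrix of base codes (A=1..T=4, NA = non-ACGT,
// also used to pad ragged sequence sets). Windows touching an NA code
// score NA. Returns an (L - w + 1) x n matrix.
// [[Rcpp::export]]
NumericMatrix cpp_window_scores_batch(NumericMatrix lo, IntegerMatrix codes) {
  int w = lo.nrow(), L = codes.nrow(), n = codes.ncol();
  int nw = L - w + 1;
  if (nw < 1) return NumericMatrix(0, n);
  NumericMatrix out(nw, n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < nw; ++i) {
      double s = 0.0;
      bool ok = true;
      for (int p = 0; p < w; ++p) {
        int c = codes(i + p, j);
        if (c == NA_INTEGER) { ok = false; break; }
        s += lo(p, c - 1);
      }
      out(i, j) = ok ? s : NA_REAL;
    }
  }
  return out;
}

// Existence-only variant: does any window of sequence j, on either strand,
// have a raw score strictly above thr_raw? lo_f scores the forward strand,
// lo_r the reverse complement (position-reversed, letter-complemented
// table applied to the forward codes). Early exit on the first hit.
// [[Rcpp::export]]
LogicalVector cpp_any_hit(NumericMatrix lo_f, NumericMatrix lo_r,
                          IntegerMatrix codes, double thr_raw,
                          bool both_strands) {
  int w = lo_f.nrow(), L = codes.nrow(), n = codes.ncol();
  int nw = L - w + 1;
  LogicalVector out(n);
  if (nw < 1) return out;
  for (int j = 0; j < n; ++j) {
    bool hit = false;
    for (int i = 0; i < nw && !hit; ++i) {
      double sf = 0.0, sr = 0.0;
      bool ok = true;
      for (int p = 0; p < w; ++p) {
        int c = codes(i + p, j);
        if (c == NA_INTEGER) { ok = false; break; }
        sf += lo_f(p, c - 1);
        sr += lo_r(p, c - 1);
      }
      if (ok && (sf > thr_raw || (both_strands && sr > thr_raw))) hit = true;
    }
    out[j] = hit;
  }
  return out;
}
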