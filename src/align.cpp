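#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) over integer-encoded sequences with an
// arbitrary substitution matrix. A gap of length k costs gap_open +
// k * gap_extend. Optionally banded around a fixed diagonal (j - i == diag0,
// 0-based), which is how seed extension stays cheap. Returns the single best
// local alignment with 0-based half-open coordinates.

// [[Rcpp::export(name = ".sw_kernel")]]
List sw_kernel(IntegerVector a, IntegerVector b, NumericMatrix smat,
               double gap_open, double gap_extend,
               bool banded = false, int diag0 = 0, int band = 48) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["n_match"] = 0, _["aln_len"] = 0);
  }
  // (n+1) x (m+1) matrices, flattened
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> F((n + 1) * (m + 1), NEG);
  // traceback: 0 stop, 1 diag, 2 from E (gap in a, consumes b), 3 from F
  std::vector<unsigned char> TB((n + 1) * (m + 1), 0);
  std::vector<unsigned char> TE((n + 1) * (m + 1), 0); // 1 = extend
  std::vector<unsigned char> TF((n + 1) * (m + 1), 0);
  const double go = gap_open + gap_extend;

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (banded) {
      jlo = std::max(1, i + diag0 - band);
      jhi = std::min(m, i + diag0 + band);
      if (jlo > jhi) continue;
    }
    const int ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const size_t c = (size_t)i * (m + 1) + j;
      const size_t up = c - (m + 1), left = c - 1, diag = up - 1;
      double e_open = H[left] - go, e_ext = E[left] - gap_extend;
      double ee = e_open >= e_ext ? e_open : e_ext;
      TE[c] = e_open >= e_ext ? 0 : 1;
      E[c] = ee;
      double f_open = H[up] - go, f_ext = F[up] - gap_extend;
      double ff = f_open >= f_ext ? f_open : f_ext;
      TF[c] = f_open >= f_ext ? 0 : 1;
      F[c] = ff;
      double hd = H[diag] + smat(ai, b[j - 1]);
      double h = 0.0; unsigned char t = 0;
      if (hd > h) { h = hd; t = 1; }
      if (ee > h) { h = ee; t = 2; }
      if (ff > h) { h = ff; t = 3; }
      H[c] = h; TB[c] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["n_match"] = 0, _["aln_len"] = 0);
  }
  // traceback
  int i = bi, j = bj;
  int n_match = 0, aln_len = 0;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j > 0) {
    const size_t c = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = TB[c];
      if (t == 0) break;
      if (t == 1) {
        if (a[i - 1] == b[j - 1]) ++n_match;
        ++aln_len; --i; --j;
      } else if (t == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // E: gap in a, consumes b[j]
      ++aln_len;
      if (TE[c] == 0) state = 0;
      --j;
    } else {               // F: gap in b, consumes a[i]
      ++aln_len;
      if (TF[c] == 0) state = 0;
      --i;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj,
                      _["n_match"] = n_match, _["aln_len"] = aln_len);
}
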