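#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Banded global affine-gap (Gotoh) alignment.
// Scoring: match/mismatch per column; a gap of length k costs
// gap_open + k * gap_extend (both negative). Cells with |i - j*n/m|
// outside the band are unreachable. Returns the optimal score within
// the band, the per-column operation string (=/X/I/D; I = base present
// only in the read), and whether the traceback touched the band edge.
//
// [[Rcpp::export]]
List banded_gotoh_cpp(std::string read, std::string ref, int band,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = read.size();   // rows: read
  const int m = ref.size();    // cols: reference
  const double NEG = -std::numeric_limits<double>::infinity();

  // band around the line i = j * n / max(m,1)
  auto lo = [&](int j) {
    int c = (m > 0) ? (int)((double)j * n / m) : 0;
    return std::max(0, c - band);
  };
  auto hi = [&](int j) {
    int c = (m > 0) ? (int)((double)j * n / m) : 0;
    return std::min(n, c + band);
  };

  // M: end in match/mismatch; X: gap in read (deletion, consumes ref);
  // Y: gap in ref (insertion, consumes read)
  std::vector<std::vector<double>> M(m + 1), X(m + 1), Y(m + 1);
  for (int j = 0; j <= m; ++j) {
    M[j].assign(n + 1, NEG);
    X[j].assign(n + 1, NEG);
    Y[j].assign(n + 1, NEG);
  }
  M[0][0] = 0.0;
  for (int i = 1; i <= std::min(n, hi(0)); ++i)
    Y[0][i] = gap_open + i * gap_extend;
  for (int j = 1; j <= m; ++j)
    if (lo(j) == 0) X[j][0] = gap_open + j * gap_extend;

  for (int j = 1; j <= m; ++j) {
    int ilo = std::max(lo(j), 0), ihi = hi(j);
    for (int i = ilo; i <= ihi; ++i) {
      if (i > 0) {
        double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
        double best = std::max({M[j - 1][i - 1], X[j - 1][i - 1],
                                Y[j - 1][i - 1]});
        if (best > NEG) M[j][i] = best + s;
      }
      // X: consume ref (horizontal)
      double xo = std::max(M[j - 1][i], Y[j - 1][i]) + gap_open + gap_extend;
      double xe = X[j - 1][i] + gap_extend;
      X[j][i] = std::max(xo, xe);
      // Y: consume read (vertical)
      if (i > 0) {
        double yo = std::max(M[j][i - 1], X[j][i - 1]) + gap_open + gap_extend;
        double ye = Y[j][i - 1] + gap_extend;
        Y[j][i] = std::max(yo, ye);
      }
    }
  }

  double score = std::max({M[m][n], X[m][n], Y[m][n]});
  bool band_hit = false;
  std::string ops;
  if (score == NEG) {
    band_hit = true;  // end cell unreachable within the band
    return List::create(_["score"] = R_NegInf, _["ops"] = "",
                        _["band_hit"] = true);
  }

  // traceback
  int i = n, j = m;
  char state = (score == M[m][n]) ? 'M' : (score == X[m][n]) ? 'X' : 'Y';
  while (i > 0 || j > 0) {
    if (j > 0 && ((i <= lo(j) && lo(j) > 0) ||
                  (i >= hi(j) && hi(j) < n))) band_hit = true;
    if (state == 'M') {
      double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      ops.push_back(read[i - 1] == ref[j - 1] ? '=' : 'X');
      double prev = M[j][i] - s;
      --i; --j;
      state = (prev == M[j][i]) ? 'M' : (prev == X[j][i]) ? 'X' : 'Y';
    } else if (state == 'X') {       // deletion column
      ops.push_back('D');
      double prev_open = X[j][i] - gap_open - gap_extend;
      double prev_ext = X[j][i] - gap_extend;
      --j;
      if (prev_ext == X[j][i]) state = 'X';
      else state = (prev_open == M[j][i]) ? 'M' : 'Y';
    } else {                          // insertion column
      ops.push_back('I');
      double prev_open = Y[j][i] - gap_open - gap_extend;
      double prev_ext = Y[j][i] - gap_extend;
      --i;
      if (prev_ext == Y[j][i]) state = 'Y';
      else state = (prev_open == M[j][i]) ? 'M' : 'X';
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = ops,
                      _["band_hit"] = band_hit);
}
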