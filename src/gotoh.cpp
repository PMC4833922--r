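#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (Gotoh).
// A gap of length k costs gap_open + k * gap_extend.
// 'N' on either side scores 0 against anything (neutral: masked or
// ambiguous bases neither reward nor penalise).
// Traceback is deterministic: on ties, diagonal (match state) is
// preferred and gap runs are extended leftward, which together with the
// downstream left-normalisation of indels yields a canonical result.

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List gotoh_align_cpp(std::string read, std::string ref,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  const int n = read.size();
  const int m = ref.size();
  if (n == 0 || m == 0) stop("gotoh_align_cpp: sequences must be non-empty");

  const int W = m + 1;
  // State matrices: M = read[i] aligned to ref[j];
  // X = gap in read (ref base consumed, deletion from the read);
  // Y = gap in ref (read base consumed, insertion in the read).
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // Backpointers: previous state 0=M, 1=X, 2=Y, -1 = origin.
  std::vector<signed char> PM((n + 1) * W, -1), PX((n + 1) * W, -1),
      PY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    X[j] = gap_open + j * gap_extend;
    PX[j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    Y[i * W] = gap_open + i * gap_extend;
    PY[i * W] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const char a = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char b = ref[j - 1];
      const double s = (a == 'N' || b == 'N') ? 0.0 : (a == b ? match : mismatch);
      const int idx = i * W + j;
      const int di = (i - 1) * W + (j - 1);
      // M: predecessors at (i-1, j-1); prefer M, then X, then Y on ties.
      {
        double best = M[di]; signed char p = 0;
        if (X[di] > best) { best = X[di]; p = 1; }
        if (Y[di] > best) { best = Y[di]; p = 2; }
        if (best > NEG_INF / 2) { M[idx] = best + s; PM[idx] = p; }
      }
      // X: gap in read, predecessors at (i, j-1); prefer extending X.
      {
        const int li = i * W + (j - 1);
        double best = X[li] + gap_extend; signed char p = 1;
        const double fromM = M[li] + gap_open + gap_extend;
        const double fromY = Y[li] + gap_open + gap_extend;
        if (fromM > best) { best = fromM; p = 0; }
        if (fromY > best) { best = fromY; p = 2; }
        if (best > NEG_INF / 2) { X[idx] = best; PX[idx] = p; }
      }
      // Y: gap in ref, predecessors at (i-1, j); prefer extending Y.
      {
        const int ui = (i - 1) * W + j;
        double best = Y[ui] + gap_extend; signed char p = 2;
        const double fromM = M[ui] + gap_open + gap_extend;
        const double fromX = X[ui] + gap_open + gap_extend;
        if (fromM > best) { best = fromM; p = 0; }
        if (fromX > best) { best = fromX; p = 1; }
        if (best > NEG_INF / 2) { Y[idx] = best; PY[idx] = p; }
      }
    }
  }

  const int end = n * W + m;
  int state = 0;
  double score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ar, br;  // aligned read / aligned ref, built backwards
  ar.reserve(n + m); br.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = PM[i * W + j];
      ar.push_back(read[i - 1]); br.push_back(ref[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = PX[i * W + j];
      ar.push_back('-'); br.push_back(ref[j - 1]);
      --j;
    } else {
      prev = PY[i * W + j];
      ar.push_back(read[i - 1]); br.push_back('-');
      --i;
    }
    if (prev < 0) break;
    state = prev;
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(br.begin(), br.end());

  return List::create(_["read"] = ar, _["ref"] = br, _["score"] = score);
}
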