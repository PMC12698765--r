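#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap global (Needleman-Wunsch) alignment. Gap of length L costs
// gap_open + L * gap_ext. Traceback tie-breaking is deterministic: prefer
// the diagonal (match/mismatch) state over gaps, and a gap in the read
// (deletion) over a gap in the reference (insertion).

static const double NEG_INF = -1e30;

// base -> index; N (or anything unexpected) -> 4
static inline int bidx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return 4;
  }
}

// [[Rcpp::export(name = ".nw_affine_cpp")]]
List nw_affine_cpp(CharacterVector reads, std::string ref,
                   NumericMatrix subst, double gap_open, double gap_ext) {
  const int m = ref.size();
  std::vector<int> refi(m);
  for (int j = 0; j < m; ++j) refi[j] = bidx(ref[j]);

  const double open1 = gap_open + gap_ext;  // cost of opening a 1-base gap
  List out(reads.size());

  for (int r = 0; r < reads.size(); ++r) {
    std::string read = as<std::string>(reads[r]);
    const int n = read.size();
    std::vector<int> readi(n);
    for (int i = 0; i < n; ++i) readi[i] = bidx(read[i]);

    // DP matrices, (n+1) x (m+1), row-major
    const int W = m + 1;
    std::vector<double> M((n + 1) * W, NEG_INF);
    std::vector<double> X((n + 1) * W, NEG_INF);  // gap in read (deletion)
    std::vector<double> Y((n + 1) * W, NEG_INF);  // gap in ref (insertion)

    M[0] = 0.0;
    for (int j = 1; j <= m; ++j) X[j] = -(gap_open + j * gap_ext);
    for (int i = 1; i <= n; ++i) Y[i * W] = -(gap_open + i * gap_ext);

    for (int i = 1; i <= n; ++i) {
      const int row = i * W, prow = (i - 1) * W;
      for (int j = 1; j <= m; ++j) {
        const double s = subst(readi[i - 1], refi[j - 1]);
        double d = M[prow + j - 1];
        if (X[prow + j - 1] > d) d = X[prow + j - 1];
        if (Y[prow + j - 1] > d) d = Y[prow + j - 1];
        M[row + j] = d + s;

        double x = M[row + j - 1] - open1;
        if (X[row + j - 1] - gap_ext > x) x = X[row + j - 1] - gap_ext;
        if (Y[row + j - 1] - open1 > x) x = Y[row + j - 1] - open1;
        X[row + j] = x;

        double y = M[prow + j] - open1;
        if (Y[prow + j] - gap_ext > y) y = Y[prow + j] - gap_ext;
        if (X[prow + j] - open1 > y) y = X[prow + j] - open1;
        Y[row + j] = y;
      }
    }

    // traceback; state 0 = M, 1 = X, 2 = Y, preference M > X > Y on ties
    int i = n, j = m, state;
    {
      const double fm = M[n * W + m], fx = X[n * W + m], fy = Y[n * W + m];
      state = (fm >= fx && fm >= fy) ? 0 : (fx >= fy ? 1 : 2);
    }
    const double score = (state == 0) ? M[n * W + m]
                       : (state == 1) ? X[n * W + m] : Y[n * W + m];

    std::string ra, fa;  // reversed aligned read / reference
    ra.reserve(n + m); fa.reserve(n + m);
    while (i > 0 || j > 0) {
      if (state == 0) {
        if (i == 0 || j == 0) { state = (j > 0) ? 1 : 2; continue; }
        ra.push_back(read[i - 1]);
        fa.push_back(ref[j - 1]);
        const double prev = M[i * W + j] - subst(readi[i - 1], refi[j - 1]);
        const double pm = M[(i - 1) * W + j - 1], px = X[(i - 1) * W + j - 1];
        --i; --j;
        const double eps = 1e-9;
        state = (pm >= prev - eps) ? 0 : (px >= prev - eps ? 1 : 2);
      } else if (state == 1) {  // gap in read, consume ref[j]
        ra.push_back('-');
        fa.push_back(ref[j - 1]);
        const double cur = X[i * W + j];
        const double eps = 1e-9;
        const double pm = M[i * W + j - 1], px = X[i * W + j - 1];
        --j;
        if (pm - open1 >= cur - eps) state = 0;
        else if (px - gap_ext >= cur - eps) state = 1;
        else state = 2;
      } else {                  // gap in ref, consume read[i]
        ra.push_back(read[i - 1]);
        fa.push_back('-');
        const double cur = Y[i * W + j];
        const double eps = 1e-9;
        const double pm = M[(i - 1) * W + j], py = Y[(i - 1) * W + j];
        --i;
        if (pm - open1 >= cur - eps) state = 0;
        else if (py - gap_ext >= cur - eps) state = 2;
        else state = 1;
      }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(fa.begin(), fa.end());

    int matched = 0;
    for (size_t k = 0; k < ra.size(); ++k) {
      if (ra[k] == fa[k] && ra[k] != '-' && ra[k] != 'N') ++matched;
    }
    out[r] = List::create(_["read_aln"] = ra, _["ref_aln"] = fa,
                          _["score"] = score,
                          _["identity"] = (double)matched / ra.size());
  }
  return out;
}
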