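#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Semi-global pairwise alignment: the query is aligned end-to-end, leading
// and trailing gaps on the reference are free. Gap scoring charges
// gap_open on the first gap base and gap_extend on each subsequent base of
// the same gap (so open == extend gives a linear gap penalty). Traceback
// ties prefer diagonal (match/mismatch) over query-gap over reference-gap
// moves, which makes results deterministic.

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

// [[Rcpp::export(name = ".semi_global_align_cpp")]]
List semi_global_align_cpp(std::string query, std::string ref,
                           int match, int mismatch,
                           int gap_open, int gap_extend) {
  const int n = (int) query.size();
  const int m = (int) ref.size();
  const int W = m + 1;
  // M: ends in aligned pair; X: ends with query base against gap;
  // Y: ends with reference base against gap.
  std::vector<int> M((n + 1) * W, NEG_INF);
  std::vector<int> X((n + 1) * W, NEG_INF);
  std::vector<int> Y((n + 1) * W, NEG_INF);
  for (int j = 0; j <= m; ++j) M[j] = 0;  // free reference prefix
  for (int i = 1; i <= n; ++i) {
    // query bases before the reference starts: charged gap
    X[i * W] = gap_open + (i - 1) * gap_extend;
  }
  for (int i = 1; i <= n; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      const int diag = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j;
      const int left = i * W + (j - 1);
      const int s = (qc == ref[j - 1]) ? match : mismatch;
      int best = M[diag];
      if (X[diag] > best) best = X[diag];
      if (Y[diag] > best) best = Y[diag];
      M[idx] = (best <= NEG_INF) ? NEG_INF : best + s;
      int x = M[up] + gap_open;
      if (X[up] + gap_extend > x) x = X[up] + gap_extend;
      if (Y[up] + gap_open > x) x = Y[up] + gap_open;
      X[idx] = (M[up] <= NEG_INF && X[up] <= NEG_INF && Y[up] <= NEG_INF)
                   ? NEG_INF : x;
      int y = M[left] + gap_open;
      if (Y[left] + gap_extend > y) y = Y[left] + gap_extend;
      if (X[left] + gap_open > y) y = X[left] + gap_open;
      Y[idx] = (M[left] <= NEG_INF && Y[left] <= NEG_INF &&
                X[left] <= NEG_INF) ? NEG_INF : y;
    }
  }
  // best end: smallest j among maxima, prefer M over X (Y endings are
  // trailing reference gaps, which are free and thus never optimal ends
  // beyond an equivalent smaller j).
  int best_score = NEG_INF, end_j = 0;
  char end_state = 'M';
  for (int j = 0; j <= m; ++j) {
    const int idx = n * W + j;
    if (M[idx] > best_score) { best_score = M[idx]; end_j = j; end_state = 'M'; }
    if (X[idx] > best_score) { best_score = X[idx]; end_j = j; end_state = 'X'; }
  }
  // traceback
  std::string aq, ar;
  int i = n, j = end_j;
  char state = end_state;
  int n_match = 0;
  while (i > 0) {
    const int idx = i * W + j;
    if (state == 'M') {
      const int s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      if (s == match) ++n_match;
      aq.push_back(query[i - 1]);
      ar.push_back(ref[j - 1]);
      const int prev = M[idx] - s;
      const int diag = (i - 1) * W + (j - 1);
      if (i == 1) {            // row 0 is the free-start row (state M)
        state = 'M';
      } else if (M[diag] == prev) state = 'M';
      else if (X[diag] == prev) state = 'X';
      else state = 'Y';
      --i; --j;
    } else if (state == 'X') {
      aq.push_back(query[i - 1]);
      ar.push_back('-');
      const int up = (i - 1) * W + j;
      if (M[up] + gap_open == X[idx]) state = 'M';
      else if (X[up] + gap_extend == X[idx]) state = 'X';
      else state = 'Y';
      --i;
    } else {  // Y: reference base against gap in query
      aq.push_back('-');
      ar.push_back(ref[j - 1]);
      const int left = i * W + (j - 1);
      if (M[left] + gap_open == Y[idx]) state = 'M';
      else if (Y[left] + gap_extend == Y[idx]) state = 'Y';
      else state = 'X';
      --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());
  const int ref_start = j;  // reference prefix before the aligned span
  const int n_columns = (int) aq.size();
  return List::create(
      _["score"] = best_score, _["n_match"] = n_match,
      _["n_columns"] = n_columns, _["query_aligned"] = aq,
      _["ref_aligned"] = ar, _["ref_start"] = ref_start,
      _["ref_end"] = end_j);
}

// [[Rcpp::export(name = ".semi_global_score_cpp")]]
int semi_global_score_cpp(std::string query, std::string ref,
                          int match, int mismatch,
                          int gap_open, int gap_extend) {
  const int n = (int) query.size();
  const int m = (int) ref.size();
  std::vector<int> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  std::vector<int> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  for (int j = 0; j <= m; ++j) { Mp[j] = 0; Xp[j] = NEG_INF; Yp[j] = NEG_INF; }
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF;
    Xc[0] = gap_open + (i - 1) * gap_extend;
    Yc[0] = NEG_INF;
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int s = (qc == ref[j - 1]) ? match : mismatch;
      int best = Mp[j - 1];
      if (Xp[j - 1] > best) best = Xp[j - 1];
      if (Yp[j - 1] > best) best = Yp[j - 1];
      Mc[j] = (best <= NEG_INF) ? NEG_INF : best + s;
      int x = Mp[j] + gap_open;
      if (Xp[j] + gap_extend > x) x = Xp[j] + gap_extend;
      if (Yp[j] + gap_open > x) x = Yp[j] + gap_open;
      Xc[j] = x;
      int y = Mc[j - 1] + gap_open;
      if (Yc[j - 1] + gap_extend > y) y = Yc[j - 1] + gap_extend;
      if (Xc[j - 1] + gap_open > y) y = Xc[j - 1] + gap_open;
      Yc[j] = y;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  int best = NEG_INF;
  for (int j = 0; j <= m; ++j) {
    if (Mp[j] > best) best = Mp[j];
    if (Xp[j] > best) best = Xp[j];
  }
  return best;
}
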