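#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Affine-gap alignment kernels (Gotoh three-state DP).
// Sequences arrive as 0-based integer codes indexing the substitution
// matrix; a gap of length k costs gap_open + k * gap_extend.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix mat,
                  int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int open_cost = gap_open + gap_extend;

  // DP matrices, (n+1) x (m+1), row-major.  M = match/mismatch state,
  // X = gap in b (consumes a), Y = gap in a (consumes b).
  std::vector<int> M((n + 1) * (m + 1), 0);
  std::vector<int> X((n + 1) * (m + 1), NEG);
  std::vector<int> Y((n + 1) * (m + 1), NEG);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int up = (i - 1) * (m + 1) + j;
      const int left = i * (m + 1) + (j - 1);
      const int diag = (i - 1) * (m + 1) + (j - 1);

      int x = M[up] - open_cost;
      if (X[up] != NEG && X[up] - gap_extend > x) x = X[up] - gap_extend;
      X[idx] = x;

      int y = M[left] - open_cost;
      if (Y[left] != NEG && Y[left] - gap_extend > y) y = Y[left] - gap_extend;
      Y[idx] = y;

      int pre = 0;  // local alignment: restart allowed
      if (M[diag] > pre) pre = M[diag];
      if (X[diag] > pre) pre = X[diag];
      if (Y[diag] > pre) pre = Y[diag];
      const int mm = pre + mat(a[i - 1], b[j - 1]);
      M[idx] = mm;
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
  }

  int aln_len = 0, n_ident = 0;
  if (best > 0) {
    // Traceback from the best match cell.  Deterministic tie rule: stop
    // as soon as the predecessor contribution is 0 (shortest optimal
    // alignment), otherwise prefer M > X > Y.
    int i = bi, j = bj, state = 0;  // 0 = M, 1 = X, 2 = Y
    for (;;) {
      if (state == 0) {
        ++aln_len;
        if (a[i - 1] == b[j - 1]) ++n_ident;
        const int diag = (i - 1) * (m + 1) + (j - 1);
        const int pre = M[i * (m + 1) + j] - mat(a[i - 1], b[j - 1]);
        --i; --j;
        if (pre == 0) break;
        if (M[diag] == pre) state = 0;
        else if (X[diag] == pre) state = 1;
        else state = 2;
      } else if (state == 1) {
        ++aln_len;
        const int here = X[i * (m + 1) + j];
        const int up = (i - 1) * (m + 1) + j;
        --i;
        state = (M[up] - open_cost == here) ? 0 : 1;
      } else {
        ++aln_len;
        const int here = Y[i * (m + 1) + j];
        const int left = i * (m + 1) + (j - 1);
        --j;
        state = (M[left] - open_cost == here) ? 0 : 2;
      }
    }
  }

  return List::create(_["score"] = best,
                      _["aln_len"] = aln_len,
                      _["n_ident"] = n_ident);
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix mat,
                  int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int open_cost = gap_open + gap_extend;

  std::vector<int> M((n + 1) * (m + 1), NEG);
  std::vector<int> X((n + 1) * (m + 1), NEG);
  std::vector<int> Y((n + 1) * (m + 1), NEG);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) X[i * (m + 1)] = -gap_open - i * gap_extend;
  for (int j = 1; j <= m; ++j) Y[j] = -gap_open - j * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int up = (i - 1) * (m + 1) + j;
      const int left = i * (m + 1) + (j - 1);
      const int diag = (i - 1) * (m + 1) + (j - 1);

      int x = NEG;
      if (M[up] != NEG) x = M[up] - open_cost;
      if (X[up] != NEG && X[up] - gap_extend > x) x = X[up] - gap_extend;
      X[idx] = x;

      int y = NEG;
      if (M[left] != NEG) y = M[left] - open_cost;
      if (Y[left] != NEG && Y[left] - gap_extend > y) y = Y[left] - gap_extend;
      Y[idx] = y;

      int pre = M[diag];
      if (X[diag] > pre) pre = X[diag];
      if (Y[diag] > pre) pre = Y[diag];
      M[idx] = (pre == NEG) ? NEG : pre + mat(a[i - 1], b[j - 1]);
    }
  }

  const int end = n * (m + 1) + m;
  int state = 0, score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  // Traceback; columns emitted tail-first then reversed.
  std::vector<int> apos, bpos;  // 1-based positions, 0 = gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      apos.push_back(i); bpos.push_back(j);
      const int diag = (i - 1) * (m + 1) + (j - 1);
      const int pre = M[i * (m + 1) + j] - mat(a[i - 1], b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[diag] == pre) state = 0;
      else if (X[diag] == pre) state = 1;
      else state = 2;
    } else if (state == 1) {
      apos.push_back(i); bpos.push_back(0);
      const int here = X[i * (m + 1) + j];
      const int up = (i - 1) * (m + 1) + j;
      --i;
      if (i == 0 && j == 0) break;
      state = (M[up] != NEG && M[up] - open_cost == here) ? 0 : 1;
    } else {
      apos.push_back(0); bpos.push_back(j);
      const int here = Y[i * (m + 1) + j];
      const int left = i * (m + 1) + (j - 1);
      --j;
      if (i == 0 && j == 0) break;
      state = (M[left] != NEG && M[left] - open_cost == here) ? 0 : 2;
    }
  }
  std::reverse(apos.begin(), apos.end());
  std::reverse(bpos.begin(), bpos.end());

  return List::create(_["score"] = score,
                      _["a_pos"] = IntegerVector(apos.begin(), apos.end()),
                      _["b_pos"] = IntegerVector(bpos.begin(), bpos.end()));
}
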