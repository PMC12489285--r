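#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Bounded (Ukkonen-banded) Levenshtein distance with unit costs.
// Returns the exact distance if <= k, otherwise k + 1.
// [[Rcpp::export]]
int cpp_bounded_edit(const std::string& a, const std::string& b, int k) {
  const int n = (int) a.size(), m = (int) b.size();
  if (k < 0) stop("k must be >= 0");
  if (std::abs(n - m) > k) return k + 1;
  if (n == 0) return m;
  if (m == 0) return n;
  const int INF = k + 1;
  const int w = 2 * k + 1;
  std::vector<int> prev(w, INF), cur(w, INF);
  // column j stored at index j - (i - k)
  for (int j = 0; j <= std::min(m, k); ++j) prev[j + k] = j;  // row 0
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = std::max(1, i - k), jhi = std::min(m, i + k);
    int rowmin = INF;
    if (i - k <= 0) {
      // column 0 in band
      cur[0 - (i - k)] = i <= k ? i : INF;
      rowmin = std::min(rowmin, cur[0 - (i - k)]);
    }
    for (int j = jlo; j <= jhi; ++j) {
      int idx = j - (i - k);
      int best = INF;
      // diagonal (i-1, j-1): index j-1 - (i-1-k) = idx
      int d = prev[idx];
      if (d < INF) {
        int v = d + (a[i - 1] == b[j - 1] ? 0 : 1);
        if (v < best) best = v;
      }
      // up (i-1, j): index j - (i-1-k) = idx + 1
      if (idx + 1 < w && prev[idx + 1] < INF) {
        int v = prev[idx + 1] + 1;
        if (v < best) best = v;
      }
      // left (i, j-1): index idx - 1
      if (idx - 1 >= 0 && cur[idx - 1] < INF) {
        int v = cur[idx - 1] + 1;
        if (v < best) best = v;
      }
      if (best > k) best = INF;
      cur[idx] = best;
      if (best < rowmin) rowmin = best;
    }
    if (rowmin >= INF) return k + 1;  // whole band exceeded k: abandon
    std::swap(prev, cur);
  }
  int res = prev[m - (n - k)];
  return res > k ? k + 1 : res;
}

// Affine-gap pairwise alignment (Gotoh three-state DP) with optional band.
// A gap of length L scores gap_open + L * gap_extend (both <= 0).
// end_free = 0: global; end_free = 1: terminal gaps in either sequence are free
// (overlap/"glocal" alignment, used for read-to-reference mapping).
// Tie-breaking during traceback: diagonal (match/mismatch) preferred over gaps,
// then gap placed in the first sequence (state Y, consuming b).
//
// States: M = a[i] vs b[j]; X = a[i] vs '-' (gap in b); Y = '-' vs b[j] (gap in a).
// [[Rcpp::export]]
List cpp_align_affine(const std::string& a, const std::string& b,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      int end_free, int band) {
  const int n = (int) a.size(), m = (int) b.size();
  std::string aa, bb;
  if (n == 0 || m == 0) {
    aa = a + std::string(m, '-');
    bb = std::string(n, '-') + b;
    double sc = 0.0;
    if (!end_free && (n + m) > 0) sc = gap_open + (n + m) * gap_extend;
    return List::create(_["a"] = aa, _["b"] = bb, _["score"] = sc);
  }
  int B = band;
  if (B <= 0) B = std::max(n, m);                  // effectively full matrix
  B = std::max(B, std::abs(n - m) + 1);            // band must reach the corner
  B = std::min(B, std::max(n, m));
  const int W = 2 * B + 1;
  if ((double) (n + 1) * W > 6e7)
    stop("alignment problem too large; supply a (smaller) band");
  const double NEG = -1e18;
  // banded storage: row i holds columns c(i)-B .. c(i)+B with c(i) = round(i*m/n)
  std::vector<double> M((size_t)(n + 1) * W, NEG), X((size_t)(n + 1) * W, NEG),
      Y((size_t)(n + 1) * W, NEG);
  std::vector<signed char> tM((size_t)(n + 1) * W, -1), tX((size_t)(n + 1) * W, -1),
      tY((size_t)(n + 1) * W, -1);  // predecessor state: 0=M,1=Y,2=X
  std::vector<int> ctr(n + 1);
  for (int i = 0; i <= n; ++i)
    ctr[i] = (int) std::lround((double) i * m / n);
  auto IDX = [&](int i, int j) -> long { return (long) i * W + (j - (ctr[i] - B)); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && j >= ctr[i] - B && j <= ctr[i] + B;
  };
  // row 0
  M[IDX(0, 0)] = 0.0;
  for (int j = 1; j <= std::min(m, ctr[0] + B); ++j) {
    Y[IDX(0, j)] = end_free ? 0.0 : gap_open + j * gap_extend;
    tY[IDX(0, j)] = 1;
  }
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, ctr[i] - B), jhi = std::min(m, ctr[i] + B);
    for (int j = jlo; j <= jhi; ++j) {
      long id = IDX(i, j);
      if (j == 0) {
        X[id] = end_free ? 0.0 : gap_open + i * gap_extend;
        tX[id] = 2;
        continue;
      }
      // M from (i-1, j-1)
      if (inband(i - 1, j - 1)) {
        long p = IDX(i - 1, j - 1);
        double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
        double bm = M[p]; signed char st = 0;
        if (Y[p] > bm) { bm = Y[p]; st = 1; }
        if (X[p] > bm) { bm = X[p]; st = 2; }
        if (bm > NEG / 2) { M[id] = bm + s; tM[id] = st; }
      }
      // X: gap in b, from (i-1, j)
      if (inband(i - 1, j)) {
        long p = IDX(i - 1, j);
        double open = gap_open + gap_extend, ext = gap_extend;
        double bm = NEG; signed char st = -1;
        if (M[p] > NEG / 2 && M[p] + open > bm) { bm = M[p] + open; st = 0; }
        if (Y[p] > NEG / 2 && Y[p] + open > bm) { bm = Y[p] + open; st = 1; }
        if (X[p] > NEG / 2 && X[p] + ext  > bm) { bm = X[p] + ext;  st = 2; }
        if (end_free && j == m && X[p] > NEG / 2 && X[p] >= bm) { bm = X[p]; st = 2; }
        if (end_free && j == m && M[p] > NEG / 2 && M[p] >= bm) { bm = M[p]; st = 0; }
        if (end_free && j == m && Y[p] > NEG / 2 && Y[p] >= bm) { bm = Y[p]; st = 1; }
        if (st >= 0) { X[id] = bm; tX[id] = st; }
      }
      // Y: gap in a, from (i, j-1)
      if (j - 1 >= ctr[i] - B) {
        long p = IDX(i, j - 1);
        double open = gap_open + gap_extend, ext = gap_extend;
        double bm = NEG; signed char st = -1;
        if (M[p] > NEG / 2 && M[p] + open > bm) { bm = M[p] + open; st = 0; }
        if (Y[p] > NEG / 2 && Y[p] + ext  > bm) { bm = Y[p] + ext;  st = 1; }
        if (X[p] > NEG / 2 && X[p] + open > bm) { bm = X[p] + open; st = 2; }
        if (end_free && i == n && Y[p] > NEG / 2 && Y[p] >= bm) { bm = Y[p]; st = 1; }
        if (end_free && i == n && M[p] > NEG / 2 && M[p] >= bm) { bm = M[p]; st = 0; }
        if (end_free && i == n && X[p] > NEG / 2 && X[p] >= bm) { bm = X[p]; st = 2; }
        if (st >= 0) { Y[id] = bm; tY[id] = st; }
      }
    }
  }
  long fin = IDX(n, m);
  double best = M[fin]; int state = 0;
  if (Y[fin] > best) { best = Y[fin]; state = 1; }
  if (X[fin] > best) { best = X[fin]; state = 2; }
  // tie preference at the end: M, then Y, then X
  if (M[fin] >= best - 1e-12 && M[fin] > NEG / 2) { best = M[fin]; state = 0; }
  else if (Y[fin] >= best - 1e-12 && Y[fin] > NEG / 2) { best = Y[fin]; state = 1; }
  if (best <= NEG / 2)
    stop("band too narrow: no path reached the end of the alignment");
  // traceback
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    long id = IDX(i, j);
    signed char prev;
    if (state == 0) {
      prev = tM[id];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = tY[id];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
    } else {
      prev = tX[id];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
    }
    if (prev < 0) stop("internal traceback error");
    state = prev;
    if (i == 0 && j > 0) state = 1;
    if (j == 0 && i > 0) state = 2;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = best);
}

// Swarm-style agglomeration: sequences must already be sorted by
// (abundance desc, sequence asc). Returns 1-based cluster index per sequence.
// BFS from the highest-abundance unassigned seed, linking any unassigned
// sequence within edit distance d of a current member.
// [[Rcpp::export]]
IntegerVector cpp_swarm_components(CharacterVector seqs, int d) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  IntegerVector cl(n, NA_INTEGER);
  int next = 0;
  std::vector<int> queue;
  for (int seed = 0; seed < n; ++seed) {
    if (cl[seed] != NA_INTEGER) continue;
    ++next;
    cl[seed] = next;
    queue.clear();
    queue.push_back(seed);
    for (size_t q = 0; q < queue.size(); ++q) {
      const std::string& mem = s[queue[q]];
      for (int t = 0; t < n; ++t) {
        if (cl[t] != NA_INTEGER) continue;
        if (cpp_bounded_edit(mem, s[t], d) <= d) {
          cl[t] = next;
          queue.push_back(t);
        }
      }
    }
  }
  return cl;
}
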