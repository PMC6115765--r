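#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Alignment kernels. Scores are integers; a gap of length L costs
// gap_open + L * gap_extend (BLAST-style existence/extension).
// 'N' never matches anything, including another 'N'.

static const int NEG = -(1 << 29);

static inline bool base_match(char x, char y) {
  return x == y && x != 'N' && x != 'n';
}

struct TB {
  // traceback matrices, one byte per state cell
  std::vector<uint8_t> m, x, y;
};

// state codes in traceback: 0 = stop, 1 = from M, 2 = from X, 3 = from Y
enum { FROM_STOP = 0, FROM_M = 1, FROM_X = 2, FROM_Y = 3 };

static List traceback(const std::string& a, const std::string& b,
                      const TB& tb, int n, int m,
                      int bi, int bj, int bstate, int best) {
  // walk back from (bi, bj) collecting alignment statistics
  int i = bi, j = bj, st = bstate;
  int a2 = bi, b2 = bj;
  int len = 0, matches = 0, gaps = 0;
  int a1 = bi, b1 = bj;
  while (i > 0 || j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    uint8_t from;
    if (st == 0) { // M state
      from = tb.m[idx];
      len++;
      if (base_match(a[i - 1], b[j - 1])) matches++;
      a1 = i; b1 = j;
      i--; j--;
    } else if (st == 1) { // X state: a[i] vs gap
      from = tb.x[idx];
      len++; gaps++;
      a1 = i;
      i--;
    } else { // Y state: gap vs b[j]
      from = tb.y[idx];
      len++; gaps++;
      b1 = j;
      j--;
    }
    if (from == FROM_STOP) break;
    st = (from == FROM_M) ? 0 : (from == FROM_X) ? 1 : 2;
  }
  return List::create(_["score"] = best,
                      _["a_start"] = a1, _["a_end"] = a2,
                      _["b_start"] = b1, _["b_end"] = b2,
                      _["length"] = len, _["matches"] = matches,
                      _["gaps"] = gaps);
}

// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_extend) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["length"] = 0,
                        _["matches"] = 0, _["gaps"] = 0);
  if ((double)(n + 1) * (m + 1) > 6.5e7)
    stop("sequences too long for exact DP (%d x %d)", n, m);
  size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<int> M(sz, 0), X(sz, NEG), Y(sz, NEG);
  TB tb; tb.m.assign(sz, FROM_STOP); tb.x.assign(sz, FROM_STOP);
  tb.y.assign(sz, FROM_STOP);
  int go = gap_open + gap_extend, ge = gap_extend;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      size_t idx = (size_t)i * (m + 1) + j;
      size_t up = idx - (m + 1), left = idx - 1, diag = up - 1;
      // X: a[i] against gap
      int xs = M[up] - go, xx = X[up] - ge;
      if (xx >= xs) { X[idx] = xx; tb.x[idx] = FROM_X; }
      else { X[idx] = xs; tb.x[idx] = FROM_M; }
      // Y: gap against b[j]
      int ys = M[left] - go, yy = Y[left] - ge;
      if (yy >= ys) { Y[idx] = yy; tb.y[idx] = FROM_Y; }
      else { Y[idx] = ys; tb.y[idx] = FROM_M; }
      // M
      int s = base_match(a[i - 1], b[j - 1]) ? match : mismatch;
      int dm = M[diag], dx = X[diag], dy = Y[diag];
      int pre = dm; uint8_t from = FROM_M;
      if (dx > pre) { pre = dx; from = FROM_X; }
      if (dy > pre) { pre = dy; from = FROM_Y; }
      if (pre <= 0) { pre = 0; from = FROM_STOP; }
      M[idx] = pre + s;
      tb.m[idx] = from;
      if (M[idx] < 0) { M[idx] = 0; tb.m[idx] = FROM_STOP; }
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["length"] = 0,
                        _["matches"] = 0, _["gaps"] = 0);
  return traceback(a, b, tb, n, m, bi, bj, 0, best);
}

// Glocal ("free end gaps" on the candidate): every base of b (the reference)
// is aligned, while unaligned prefix/suffix of a (the candidate) cost zero.
// [[Rcpp::export]]
List cpp_overlap_align(std::string a, std::string b,
                       int match, int mismatch, int gap_open, int gap_extend) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = NA_INTEGER, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["length"] = 0,
                        _["matches"] = 0, _["gaps"] = 0);
  if ((double)(n + 1) * (m + 1) > 6.5e7)
    stop("sequences too long for exact DP (%d x %d)", n, m);
  size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<int> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  TB tb; tb.m.assign(sz, FROM_STOP); tb.x.assign(sz, FROM_STOP);
  tb.y.assign(sz, FROM_STOP);
  int go = gap_open + gap_extend, ge = gap_extend;
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      size_t idx = (size_t)i * (m + 1) + j;
      size_t up = idx - (m + 1), left = idx - 1, diag = up - 1;
      int xs = M[up] - go, xx = X[up] - ge;
      if (xx >= xs) { X[idx] = xx; tb.x[idx] = FROM_X; }
      else { X[idx] = xs; tb.x[idx] = FROM_M; }
      int ys = (j == 1) ? -go : M[left] - go;
      int yy = (j == 1) ? NEG : Y[left] - ge;
      uint8_t yfrom = FROM_M;
      if (j == 1) yfrom = FROM_STOP;
      if (yy >= ys) { Y[idx] = yy; tb.y[idx] = FROM_Y; }
      else { Y[idx] = ys; tb.y[idx] = yfrom; }
      int s = base_match(a[i - 1], b[j - 1]) ? match : mismatch;
      int pre; uint8_t from;
      if (j == 1) { // free prefix of a
        pre = 0; from = FROM_STOP;
      } else {
        pre = M[diag]; from = FROM_M;
        if (X[diag] > pre) { pre = X[diag]; from = FROM_X; }
        if (Y[diag] > pre) { pre = Y[diag]; from = FROM_Y; }
      }
      if (pre <= NEG / 2) { M[idx] = NEG; tb.m[idx] = FROM_STOP; }
      else { M[idx] = pre + s; tb.m[idx] = from; }
    }
  }
  // free suffix of a: best over last column, M or Y state
  int best = NEG, bi = 0, bstate = 0;
  for (int i = 0; i <= n; i++) {
    size_t idx = (size_t)i * (m + 1) + m;
    if (M[idx] > best) { best = M[idx]; bi = i; bstate = 0; }
    if (Y[idx] > best) { best = Y[idx]; bi = i; bstate = 2; }
  }
  if (best <= NEG / 2)
    return List::create(_["score"] = NA_INTEGER, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["length"] = 0,
                        _["matches"] = 0, _["gaps"] = 0);
  return traceback(a, b, tb, n, m, bi, m, bstate, best);
}

// Best ungapped segment score over all diagonals (Kadane per diagonal).
// [[Rcpp::export]]
int cpp_max_segment(std::string a, std::string b, int match, int mismatch) {
  int n = a.size(), m = b.size();
  int best = 0;
  for (int d = -(n - 1); d <= m - 1; d++) {
    int i0 = d < 0 ? -d : 0;   // 0-based start in a
    int j0 = d < 0 ? 0 : d;
    int run = 0;
    for (int i = i0, j = j0; i < n && j < m; i++, j++) {
      int s = base_match(a[i], b[j]) ? match : mismatch;
      run += s;
      if (run < 0) run = 0;
      if (run > best) best = run;
    }
  }
  return best;
}

// For each TRUE-run of v, its maximal extension over up to max_merges
// FALSE-runs of length <= merge_gap. Vectors: start, span, paired.
// [[Rcpp::export]]
List cpp_merge_true_runs(LogicalVector v, int max_merges, int merge_gap,
                         int min_merge_run = 1) {
  int n = v.size();
  std::vector<int> rs, rl; // run starts / lengths, TRUE runs at even parity
  std::vector<bool> rv;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && v[j] == v[i]) j++;
    rs.push_back(i + 1); rl.push_back(j - i); rv.push_back(v[i]);
    i = j;
  }
  int k = rs.size();
  std::vector<int> out_s, out_sp, out_p;
  for (int j = 0; j < k; j++) {
    if (!rv[j]) continue;
    int jj = j, paired = rl[j], merges = 0;
    while (jj + 2 < k && merges < max_merges && rl[jj + 1] <= merge_gap &&
           rv[jj + 2] && rl[jj + 2] >= min_merge_run) {
      paired += rl[jj + 2];
      jj += 2;
      merges++;
    }
    out_s.push_back(rs[j]);
    out_sp.push_back(rs[jj] + rl[jj] - rs[j]);
    out_p.push_back(paired);
  }
  return List::create(_["start"] = wrap(out_s), _["span"] = wrap(out_sp),
                      _["paired"] = wrap(out_p));
}

// Exact word seeds between query and target (1-based positions).
// [[Rcpp::export]]
IntegerMatrix cpp_seed_positions(std::string q, std::string t, int w) {
  int nq = q.size(), nt = t.size();
  if (w < 4) stop("word size must be >= 4");
  if (w > 15) stop("word size must be <= 15");
  if (nq < w || nt < w) return IntegerMatrix(0, 2);
  auto code = [](char c) -> int {
    switch (c) {
      case 'A': return 0; case 'C': return 1;
      case 'G': return 2; case 'T': return 3;
      default: return -1;
    }
  };
  uint32_t mask = (w == 16) ? 0xFFFFFFFFu : ((1u << (2 * w)) - 1);
  std::unordered_map<uint32_t, std::vector<int> > words;
  uint32_t h = 0; int valid = 0;
  for (int i = 0; i < nq; i++) {
    int c = code(q[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    valid++;
    if (valid >= w) words[h].push_back(i - w + 2); // 1-based word start
  }
  std::vector<int> qs, ts;
  h = 0; valid = 0;
  for (int i = 0; i < nt; i++) {
    int c = code(t[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    valid++;
    if (valid >= w) {
      auto it = words.find(h);
      if (it != words.end()) {
        int tp = i - w + 2;
        for (int qp : it->second) {
          qs.push_back(qp); ts.push_back(tp);
          if (qs.size() > 500000) stop("too many word seeds; raise word_size");
        }
      }
    }
  }
  IntegerMatrix out(qs.size(), 2);
  for (size_t k = 0; k < qs.size(); k++) { out(k, 0) = qs[k]; out(k, 1) = ts[k]; }
  colnames(out) = CharacterVector::create("q", "t");
  return out;
}
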