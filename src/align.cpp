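#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int INF = 1 << 29;

// Forward infix (HW) pass: query must be fully aligned, leading and trailing
// target characters are free. Returns the minimal edit distance and the
// 1-based target column where the best alignment ends (0 = empty span).
static void infix_forward(const std::string& t, const std::string& q,
                          int& best, int& best_end) {
  const int n = (int) t.size(), m = (int) q.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int i = 0; i <= m; ++i) prev[i] = i;  // column 0
  best = prev[m];
  best_end = 0;
  for (int j = 1; j <= n; ++j) {
    const char tc = t[j - 1];
    cur[0] = 0;
    for (int i = 1; i <= m; ++i) {
      int v = prev[i - 1] + (q[i - 1] != tc);  // match / mismatch
      int vi = cur[i - 1] + 1;                 // insertion in query
      int vd = prev[i] + 1;                    // deletion from target
      if (vi < v) v = vi;
      if (vd < v) v = vd;
      cur[i] = v;
    }
    if (cur[m] < best) { best = cur[m]; best_end = j; }
    std::swap(prev, cur);
  }
}

// Prefix (SHW) pass on reversed strings: the alignment is anchored at the
// start of the target, the end is free. Returns the number of target
// characters consumed by the best alignment.
static int shw_consumed(const std::string& t, const std::string& q,
                        int expect) {
  const int n = (int) t.size(), m = (int) q.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int i = 0; i <= m; ++i) prev[i] = i;
  int best = prev[m], best_j = 0;
  for (int j = 1; j <= n; ++j) {
    const char tc = t[j - 1];
    cur[0] = j;
    for (int i = 1; i <= m; ++i) {
      int v = prev[i - 1] + (q[i - 1] != tc);
      int vi = cur[i - 1] + 1;
      int vd = prev[i] + 1;
      if (vi < v) v = vi;
      if (vd < v) v = vd;
      cur[i] = v;
    }
    if (cur[m] < best) { best = cur[m]; best_j = j; }
    std::swap(prev, cur);
  }
  if (best != expect) stop("internal error: backward pass distance mismatch");
  return best_j;
}

// Banded global alignment with backpointers; band radius r guarantees
// optimality because the optimal path's diagonal offset is bounded by the
// edit distance. Returns the edit script over {'=','X','I','D'}.
static std::string banded_global_ops(const std::string& t,
                                     const std::string& q, int d) {
  const int n = (int) t.size(), m = (int) q.size();
  int r = std::max(d, std::abs(n - m)) + 1;
  if (r > std::max(n, m)) r = std::max(n, m);
  const long long w = 2LL * r + 1;
  const long long cells = (long long)(m + 1) * w;
  if (cells > 2000000000LL)
    stop("alignment traceback band too large (%lld cells); edit distance %d "
         "at query length %d exceeds the supported range", cells, d, m);
  std::vector<uint8_t> bp((size_t) cells, 255);
  std::vector<int> prev(w, INF), cur(w, INF);

  // row 0: j in [0, r]
  for (int j = 0; j <= std::min(n, r); ++j) {
    prev[j + r] = j;
    bp[(size_t) j + r] = 2;  // left (D)
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    const char qc = q[i - 1];
    const int jlo = std::max(0, i - r), jhi = std::min(n, i + r);
    uint8_t* bprow = &bp[(size_t) i * w];
    for (int j = jlo; j <= jhi; ++j) {
      const int b = j - i + r;
      int v = INF; uint8_t o = 255;
      if (j >= 1 && prev[b] != INF) {            // diag: (i-1, j-1)
        v = prev[b] + (qc != t[j - 1]);
        o = (qc != t[j - 1]) ? 1 : 0;            // 0 '=', 1 'X'
      }
      if (b + 1 < w && prev[b + 1] != INF && prev[b + 1] + 1 < v) {
        v = prev[b + 1] + 1; o = 3;              // up: consume query, 'I'
      }
      if (j >= 1 && b - 1 >= 0 && cur[b - 1] != INF && cur[b - 1] + 1 < v) {
        v = cur[b - 1] + 1; o = 2;               // left: consume target, 'D'
      }
      cur[b] = v;
      bprow[b] = o;
    }
    std::swap(prev, cur);
  }
  const int bend = n - m + r;
  if (bend < 0 || bend >= w || prev[bend] != d)
    stop("internal error: banded pass distance mismatch");

  static const char OPS[4] = {'=', 'X', 'D', 'I'};
  std::string ops;
  ops.reserve((size_t) (std::max(n, m) + d));
  int i = m, j = n;
  while (i > 0 || j > 0) {
    uint8_t o = bp[(size_t) i * w + (j - i + r)];
    if (o == 255) stop("internal error: traceback fell out of band");
    ops.push_back(OPS[o]);
    if (o == 0 || o == 1) { --i; --j; }
    else if (o == 2) { --j; }
    else { --i; }
  }
  std::reverse(ops.begin(), ops.end());
  return ops;
}

// [[Rcpp::export]]
List cpp_infix_align(std::string target, std::string query,
                     double max_distance, bool traceback) {
  if (target.empty() || query.empty())
    stop("target and query must be non-empty");

  int d, end;
  infix_forward(target, query, d, end);

  if (max_distance >= 0 && d > max_distance) {
    return List::create(_["hit"] = false, _["edit_distance"] = d);
  }
  if (!traceback) {
    return List::create(_["hit"] = true, _["edit_distance"] = d,
                        _["target_end"] = end);
  }

  std::string ops;
  int start;
  if (end == 0) {
    start = 1;  // empty target span; the whole query is unaligned insertions
    ops = std::string((size_t) query.size(), 'I');
  } else {
    std::string tr(target.rbegin() + (target.size() - end), target.rend());
    std::string qr(query.rbegin(), query.rend());
    int consumed = shw_consumed(tr, qr, d);
    start = end - consumed + 1;
    std::string seg = target.substr(start - 1, consumed);
    ops = banded_global_ops(seg, query, d);
  }
  return List::create(
    _["hit"] = true,
    _["edit_distance"] = d,
    _["target_start"] = start,
    _["target_end"] = end,
    _["ops"] = ops
  );
}
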