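// Core event loop of the progressive-rearrangement simulation.
//
// The arrangement is a vector of signed segment ids.  End codes follow the
// package-wide scheme: head of segment s -> 2s-2, tail -> 2s-1; a copy +s
// exposes (head, tail) as (left, right) ends, -s the reverse.  All
// randomness is drawn from R's RNG so a set.seed() in R makes runs
// reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_set>
#include <unordered_map>

using namespace Rcpp;

static inline int left_code(int c) {
  return c > 0 ? 2 * c - 2 : -2 * c - 1;
}
static inline int right_code(int c) {
  return c > 0 ? 2 * c - 1 : -2 * c - 2;
}
// a junction is a reference adjacency iff the codes differ by one and the
// smaller is odd ({tail i, head i+1})
static inline bool junction_normal(int rc, int lc) {
  int lo = rc < lc ? rc : lc, hi = rc < lc ? lc : rc;
  return hi - lo == 1 && (lo & 1) == 1;
}

struct Cand { int kind, from, to; };  // kind: 1 inv, 2 del, 3 dup

// enumerate events creating a junction with end codes {a, b}
static void realizations(const std::vector<int>& copies, int a, int b,
                         std::vector<Cand>& out) {
  out.clear();
  int len = (int)copies.size();
  if (len == 0) return;
  std::vector<int> la, lb, ra, rb;
  for (int i = 0; i < len; ++i) {
    int lc = left_code(copies[i]), rc = right_code(copies[i]);
    if (lc == a) la.push_back(i + 1);
    if (lc == b) lb.push_back(i + 1);
    if (rc == a) ra.push_back(i + 1);
    if (rc == b) rb.push_back(i + 1);
  }
  bool same = (a == b);
  // tandem duplication of [i, j]: right end of j joins left end of i
  for (int i : la) for (int j : rb) if (j >= i) out.push_back({3, i, j});
  if (!same) for (int i : lb) for (int j : ra) if (j >= i) out.push_back({3, i, j});
  // deletion of [u+1, v-1]
  for (int u : ra) for (int v : lb) if (v >= u + 2) out.push_back({2, u + 1, v - 1});
  if (!same) for (int u : rb) for (int v : la) if (v >= u + 2) out.push_back({2, u + 1, v - 1});
  // inversion of [u+1, j]: right ends of u and j meet
  if (same) {
    for (size_t x = 0; x < ra.size(); ++x) for (size_t y = x + 1; y < ra.size(); ++y)
      out.push_back({1, ra[x] + 1, ra[y]});
  } else {
    for (int u : ra) for (int j : rb) if (j >= u + 1) out.push_back({1, u + 1, j});
    for (int u : rb) for (int j : ra) if (j >= u + 1) out.push_back({1, u + 1, j});
  }
  // inversion of [i, w-1]: left ends of i and w meet
  if (same) {
    for (size_t x = 0; x < la.size(); ++x) for (size_t y = x + 1; y < la.size(); ++y)
      out.push_back({1, la[x], la[y] - 1});
  } else {
    for (int i : la) for (int w : lb) if (w >= i + 1) out.push_back({1, i, w - 1});
    for (int i : lb) for (int w : la) if (w >= i + 1) out.push_back({1, i, w - 1});
  }
  // dedupe, keep deterministic order (kind, from, to)
  std::sort(out.begin(), out.end(), [](const Cand& p, const Cand& q) {
    if (p.kind != q.kind) return p.kind < q.kind;
    if (p.from != q.from) return p.from < q.from;
    return p.to < q.to;
  });
  out.erase(std::unique(out.begin(), out.end(), [](const Cand& p, const Cand& q) {
    return p.kind == q.kind && p.from == q.from && p.to == q.to;
  }), out.end());
}

static void apply_ev(std::vector<int>& copies, int kind, int from, int to) {
  // 1-based inclusive span
  if (kind == 1) {
    std::reverse(copies.begin() + from - 1, copies.begin() + to);
    for (int i = from - 1; i < to; ++i) copies[i] = -copies[i];
  } else if (kind == 2) {
    copies.erase(copies.begin() + from - 1, copies.begin() + to);
  } else {
    std::vector<int> slice(copies.begin() + from - 1, copies.begin() + to);
    copies.insert(copies.begin() + to, slice.begin(), slice.end());
  }
}

// counting_mode: 1 adjacency, 2 pes, 3 microarray
static int count_bp(const std::vector<int>& copies, int mode, int n,
                    std::vector<int>& counts_buf) {
  if (mode == 3) {
    std::fill(counts_buf.begin(), counts_buf.end(), 0);
    for (int c : copies) counts_buf[std::abs(c) - 1]++;
    int ch = 0;
    for (int i = 1; i < n; ++i) if (counts_buf[i] != counts_buf[i - 1]) ch++;
    return ch;
  }
  int len = (int)copies.size();
  if (len < 2) return 0;
  if (mode == 1) {
    int k = 0;
    for (int i = 0; i + 1 < len; ++i)
      if (!junction_normal(right_code(copies[i]), left_code(copies[i + 1]))) k++;
    return k;
  }
  static std::unordered_set<long long> keys;
  keys.clear();
  keys.reserve(len);
  for (int i = 0; i + 1 < len; ++i) {
    int rc = right_code(copies[i]), lc = left_code(copies[i + 1]);
    if (!junction_normal(rc, lc)) {
      long long lo = rc < lc ? rc : lc, hi = rc < lc ? lc : rc;
      keys.insert(lo * 2LL * n + hi);
    }
  }
  return (int)keys.size();
}

// state_mode: 1 strict, 2 relaxed
static int count_states(const std::vector<int>& copies, int mode, int n,
                        const std::vector<double>& seg_len, double total_len,
                        double fraction, std::vector<int>& counts_buf) {
  std::fill(counts_buf.begin(), counts_buf.end(), 0);
  for (int c : copies) counts_buf[std::abs(c) - 1]++;
  // aggregate coverage per copy-number value
  static std::unordered_map<int, double> covmap;
  covmap.clear();
  for (int i = 0; i < n; ++i) covmap[counts_buf[i]] += seg_len[i];
  if (mode == 1) return (int)covmap.size();
  static std::vector<double> cov;
  cov.clear();
  for (const auto& kv : covmap) cov.push_back(kv.second);
  std::sort(cov.begin(), cov.end(), std::greater<double>());
  double need = fraction * total_len, acc = 0;
  int k = 0;
  for (size_t i = 0; i < cov.size(); ++i) {
    acc += cov[i]; ++k;
    if (acc >= need) break;
  }
  return k;
}

// [[Rcpp::export]]
List cpp_simulate_progressive(IntegerMatrix codes, IntegerVector class_id,
                              NumericVector weights, int n_segments,
                              NumericVector seg_len, int counting_mode,
                              int state_mode, double relaxed_fraction,
                              int strategy, double max_events,
                              double stop_at) {
  int n_obs = codes.nrow();
  std::vector<int> copies(n_segments);
  for (int i = 0; i < n_segments; ++i) copies[i] = i + 1;
  std::vector<bool> in_pool(n_obs, true);
  std::vector<double> w(n_obs);
  for (int i = 0; i < n_obs; ++i) w[i] = weights[class_id[i] - 1];
  int n_pool = n_obs;
  double total_len = 0;
  std::vector<double> slen(seg_len.begin(), seg_len.end());
  for (double v : slen) total_len += v;
  std::vector<int> counts_buf(n_segments);

  std::vector<int> s_bp, s_kind, s_nbp, s_nst, s_len, applied, discarded;
  std::vector<Cand> cand;
  RNGScope scope;
  int ev = 0, nbp = 0;
  while (n_pool > 0 && ev < max_events && nbp < stop_at) {
    // weighted draw without replacement
    double tot = 0;
    for (int i = 0; i < n_obs; ++i) if (in_pool[i]) tot += w[i];
    double u = unif_rand() * tot, acc = 0;
    int k = -1;
    for (int i = 0; i < n_obs; ++i) {
      if (!in_pool[i]) continue;
      acc += w[i];
      if (u <= acc) { k = i; break; }
    }
    if (k < 0) { for (int i = n_obs - 1; i >= 0; --i) if (in_pool[i]) { k = i; break; } }
    in_pool[k] = false; n_pool--;

    realizations(copies, codes(k, 0), codes(k, 1), cand);
    // the observed orientation dictates the operation type: only events of
    // the breakpoint's own class may realize it
    cand.erase(std::remove_if(cand.begin(), cand.end(), [&](const Cand& c) {
      return c.kind != class_id[k];
    }), cand.end());
    if (cand.empty()) { discarded.push_back(k + 1); continue; }
    int row;
    if (strategy == 1) {
      row = (int)(unif_rand() * cand.size());
      if (row >= (int)cand.size()) row = (int)cand.size() - 1;
    } else if (strategy == 2) {  // nearest: smallest span
      row = 0;
      for (size_t i = 1; i < cand.size(); ++i)
        if (cand[i].to - cand[i].from < cand[row].to - cand[row].from) row = (int)i;
    } else {                     // furthest: largest span
      row = 0;
      for (size_t i = 1; i < cand.size(); ++i)
        if (cand[i].to - cand[i].from > cand[row].to - cand[row].from) row = (int)i;
    }
    apply_ev(copies, cand[row].kind, cand[row].from, cand[row].to);
    applied.push_back(k + 1);
    ++ev;
    nbp = count_bp(copies, counting_mode, n_segments, counts_buf);
    int nst = count_states(copies, state_mode, n_segments, slen, total_len,
                           relaxed_fraction, counts_buf);
    s_bp.push_back(k + 1);
    s_kind.push_back(cand[row].kind);
    s_nbp.push_back(nbp);
    s_nst.push_back(nst);
    s_len.push_back((int)copies.size());
  }
  return List::create(
    _["bp_index"] = wrap(s_bp), _["kind"] = wrap(s_kind),
    _["n_breakpoints"] = wrap(s_nbp), _["n_states"] = wrap(s_nst),
    _["arrangement_length"] = wrap(s_len), _["applied"] = wrap(applied),
    _["discarded"] = wrap(discarded), _["final"] = wrap(copies));
}
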