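// De Bruijn graph core: canonical kmers packed 2 bits/base into 128-bit
// integers (k <= 63). Edges are k-mers with coverage counts; nodes are the
// implied (k-1)-mers. All outputs are sorted so results are deterministic.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <functional>
#include <cstdint>

using namespace Rcpp;

typedef unsigned __int128 u128;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}
static const char BASES[5] = "ACGT";

struct U128Hash {
  size_t operator()(const u128 &x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL ^ (hi + 0xC2B2AE3D27D4EB4FULL);
    h ^= h >> 32;
    h *= 0xD6E8FEB86659FD93ULL;
    h ^= h >> 32;
    return (size_t)h;
  }
};

// reverse the 32 2-bit groups of a 64-bit word and complement each
static inline uint64_t rc_word(uint64_t v) {
  v = ~v;
  v = ((v >> 2) & 0x3333333333333333ULL) | ((v & 0x3333333333333333ULL) << 2);
  v = ((v >> 4) & 0x0F0F0F0F0F0F0F0FULL) | ((v & 0x0F0F0F0F0F0F0F0FULL) << 4);
  v = __builtin_bswap64(v);
  return v;
}

// reverse complement of an L-base kmer held in the low 2L bits
static inline u128 revcomp_bits(u128 x, int L) {
  uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
  u128 r = ((u128)rc_word(lo) << 64) | (u128)rc_word(hi);
  return r >> (128 - 2 * L);
}

static inline u128 canon_bits(u128 x, int L) {
  u128 r = revcomp_bits(x, L);
  return x < r ? x : r;
}

static inline u128 mask_bits(int L) {
  return (L >= 64) ? ((((u128)1) << (2 * L)) - 1) : ((((u128)1) << (2 * L)) - 1);
}

static std::string decode_bits(u128 x, int L) {
  std::string s(L, 'A');
  for (int i = L - 1; i >= 0; --i) {
    s[i] = BASES[(int)(x & 3)];
    x >>= 2;
  }
  return s;
}

static bool encode_bits(const std::string &s, size_t pos, int L, u128 &out) {
  u128 v = 0;
  for (int i = 0; i < L; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (u128)c;
  }
  out = v;
  return true;
}

typedef std::unordered_map<u128, uint32_t, U128Hash> CovMap;

struct DBG {
  int k;           // edge (kmer) length; nodes are (k-1)-mers
  CovMap cov;      // canonical kmer -> coverage
  u128 mk, mn;     // masks for k and k-1 bases

  explicit DBG(int k_) : k(k_) {
    mk = mask_bits(k);
    mn = mask_bits(k - 1);
  }

  bool has_edge(u128 oriented) const {
    return cov.find(canon_bits(oriented, k)) != cov.end();
  }
  uint32_t edge_cov(u128 oriented) const {
    CovMap::const_iterator it = cov.find(canon_bits(oriented, k));
    return it == cov.end() ? 0 : it->second;
  }
  void erase_edge(u128 oriented) { cov.erase(canon_bits(oriented, k)); }

  // oriented node helpers (node = (k-1)-mer in a fixed orientation)
  u128 suffix_node(u128 edge) const { return edge & mn; }
  u128 prefix_node(u128 edge) const { return edge >> 2; }

  int out_edges(u128 node, u128 *es) const {
    int n = 0;
    for (int b = 0; b < 4; ++b) {
      u128 e = ((node << 2) | (u128)b) & mk;
      if (has_edge(e)) es[n++] = e;
    }
    return n;
  }
  int in_edges(u128 node, u128 *es) const {
    int n = 0;
    for (int b = 0; b < 4; ++b) {
      u128 e = ((u128)b << (2 * (k - 1))) | node;
      if (has_edge(e)) es[n++] = e;
    }
    return n;
  }
  int outdeg(u128 node) const { u128 t[4]; return out_edges(node, t); }
  int indeg(u128 node) const { u128 t[4]; return in_edges(node, t); }

  std::vector<u128> sorted_keys() const {
    std::vector<u128> ks;
    ks.reserve(cov.size());
    for (CovMap::const_iterator it = cov.begin(); it != cov.end(); ++it)
      ks.push_back(it->first);
    std::sort(ks.begin(), ks.end());
    return ks;
  }

  void add_sequence(const std::string &s) {
    int run = 0;
    u128 cur = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | (u128)c) & mk;
      if (++run >= k) cov[canon_bits(cur, k)]++;
    }
  }
};

static DBG graph_from_r(const CharacterVector &kmers, const IntegerVector &cnt,
                        int k) {
  DBG g(k);
  g.cov.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    u128 v;
    if (!encode_bits(s, 0, k, v)) stop("non-ACGT character in kmer");
    g.cov[canon_bits(v, k)] += (uint32_t)cnt[i];
  }
  return g;
}

static List graph_to_r(const DBG &g) {
  std::vector<u128> ks = g.sorted_keys();
  CharacterVector km(ks.size());
  IntegerVector cn(ks.size());
  for (size_t i = 0; i < ks.size(); ++i) {
    km[i] = decode_bits(ks[i], g.k);
    cn[i] = (int)g.cov.at(ks[i]);
  }
  return List::create(_["kmer"] = km, _["count"] = cn);
}

// ---------------------------------------------------------------- build

static void build_from_seqs(DBG &g, const CharacterVector &seqs) {
  size_t total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    int len = LENGTH(STRING_ELT(seqs, i));
    if (len >= g.k) total += (size_t)(len - g.k + 1);
  }
  g.cov.reserve(total);
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    g.add_sequence(as<std::string>(seqs[i]));
}

// [[Rcpp::export]]
List cpp_build_edges(CharacterVector seqs, int k) {
  DBG g(k);
  build_from_seqs(g, seqs);
  return graph_to_r(g);
}

// ---------------------------------------------------------------- simplify

// Walk a non-branching path forward from oriented edge e. Stops when the
// next node branches, when max_len is hit, or when the path would revisit a
// canonical edge. Returns the terminal node; fills path with oriented edges.
static u128 walk_unbranched(const DBG &g, u128 e, size_t max_len,
                            std::vector<u128> &path, bool &closed) {
  std::unordered_set<u128, U128Hash> seen;
  path.clear();
  path.push_back(e);
  seen.insert(canon_bits(e, g.k));
  u128 v = g.suffix_node(e);
  closed = false;
  while (path.size() < max_len) {
    if (g.indeg(v) != 1 || g.outdeg(v) != 1) break;
    u128 es[4];
    g.out_edges(v, es);
    u128 nxt = es[0];
    u128 cn = canon_bits(nxt, g.k);
    if (cn == canon_bits(path[0], g.k)) { closed = true; break; }
    if (seen.count(cn)) break;
    seen.insert(cn);
    path.push_back(nxt);
    v = g.suffix_node(nxt);
  }
  return v;
}

// Clip dead-end branches of at most max_tip edges hanging off a branch
// node. Clipping is competitive: the tip must lose to a sibling branch at
// its attachment node on mean coverage (then on unbranched length), so the
// genuine end of a linear path is never mistaken for a tip.
static bool clip_tips(DBG &g, int max_tip) {
  std::vector<u128> keys = g.sorted_keys();
  std::vector<u128> doomed;
  for (size_t i = 0; i < keys.size(); ++i) {
    u128 reprs[2] = {keys[i], revcomp_bits(keys[i], g.k)};
    for (int o = 0; o < 2; ++o) {
      u128 e = reprs[o];
      if (!g.has_edge(e)) continue;          // may already be marked
      if (g.outdeg(g.suffix_node(e)) != 0) continue;  // not a dead end
      // walk backwards collecting the tip (oriented toward the dead end)
      std::vector<u128> path;
      path.push_back(e);
      u128 u = g.prefix_node(e);
      bool loop = false;
      while ((int)path.size() <= max_tip && g.indeg(u) == 1 &&
             g.outdeg(u) == 1) {
        u128 es[4];
        g.in_edges(u, es);
        u128 prev = es[0];
        if (canon_bits(prev, g.k) == canon_bits(e, g.k)) { loop = true; break; }
        path.push_back(prev);
        u = g.prefix_node(prev);
      }
      if (loop || (int)path.size() > max_tip) continue;
      u128 first = path.back();  // edge leaving the attachment node u
      if (g.outdeg(u) < 2) continue;  // no sibling branch to carry on
      double tip_cov = 0;
      for (size_t j = 0; j < path.size(); ++j) tip_cov += g.edge_cov(path[j]);
      tip_cov /= path.size();
      // best sibling: highest immediate coverage, then longest extension
      u128 es[4];
      int n_out = g.out_edges(u, es);
      double sib_cov = -1;
      size_t sib_len = 0;
      for (int s = 0; s < n_out; ++s) {
        if (es[s] == first) continue;
        double c = g.edge_cov(es[s]);
        if (c > sib_cov) {
          std::vector<u128> sp;
          bool cl;
          walk_unbranched(g, es[s], (size_t)max_tip + 1, sp, cl);
          sib_cov = c;
          sib_len = sp.size();
        }
      }
      bool lose = tip_cov < sib_cov ||
                  (tip_cov == sib_cov && path.size() < sib_len);
      if (lose) {
        for (size_t j = 0; j < path.size(); ++j)
          doomed.push_back(canon_bits(path[j], g.k));
      }
    }
  }
  for (size_t i = 0; i < doomed.size(); ++i) g.cov.erase(doomed[i]);
  return !doomed.empty();
}

static bool drop_low_coverage(DBG &g, int min_cov) {
  if (min_cov <= 1) return false;
  std::vector<u128> doomed;
  for (CovMap::const_iterator it = g.cov.begin(); it != g.cov.end(); ++it)
    if ((int)it->second < min_cov) doomed.push_back(it->first);
  for (size_t i = 0; i < doomed.size(); ++i) g.cov.erase(doomed[i]);
  return !doomed.empty();
}

struct Bubble {
  u128 s, t;
  std::vector<u128> p1, p2;  // oriented edges of each branch
};

// find simple bubbles: node s with outdeg 2 whose two unbranched paths
// converge on the same node t with disjoint interiors
static std::vector<Bubble> find_bubbles(const DBG &g, size_t max_len) {
  std::vector<Bubble> out;
  std::unordered_set<u128, U128Hash> seen_pair;  // canonical (s,t) dedup
  std::vector<u128> keys = g.sorted_keys();
  std::unordered_set<u128, U128Hash> nodes_done;
  for (size_t i = 0; i < keys.size(); ++i) {
    u128 reprs[2] = {keys[i], revcomp_bits(keys[i], g.k)};
    for (int o = 0; o < 2; ++o) {
      u128 s = g.prefix_node(reprs[o]);
      if (nodes_done.count(s)) continue;
      nodes_done.insert(s);
      u128 es[4];
      if (g.out_edges(s, es) != 2) continue;
      Bubble b;
      bool c1, c2;
      u128 t1 = walk_unbranched(g, es[0], max_len, b.p1, c1);
      u128 t2 = walk_unbranched(g, es[1], max_len, b.p2, c2);
      if (c1 || c2 || t1 != t2 || t1 == s) continue;
      // interiors must be disjoint
      std::unordered_set<u128, U128Hash> inter;
      bool ok = true;
      for (size_t j = 1; j < b.p1.size(); ++j)
        inter.insert(g.prefix_node(b.p1[j]));
      for (size_t j = 1; j < b.p2.size(); ++j)
        if (inter.count(g.prefix_node(b.p2[j]))) { ok = false; break; }
      if (!ok) continue;
      b.s = s;
      b.t = t1;
      // dedup against the mirror-strand copy (rc(t) -> rc(s))
      u128 key1 = (canon_bits(s, g.k - 1) << 1) ^ canon_bits(t1, g.k - 1);
      u128 key2 = (canon_bits(revcomp_bits(t1, g.k - 1), g.k - 1) << 1) ^
                  canon_bits(revcomp_bits(s, g.k - 1), g.k - 1);
      u128 key = std::min(key1, key2);
      if (seen_pair.count(key)) continue;
      seen_pair.insert(key);
      out.push_back(b);
    }
  }
  return out;
}

static std::string path_seq(const DBG &g, const std::vector<u128> &path) {
  std::string s = decode_bits(g.prefix_node(path[0]), g.k - 1);
  for (size_t i = 0; i < path.size(); ++i)
    s.push_back(BASES[(int)(path[i] & 3)]);
  return s;
}

// collapse each bubble onto its higher-coverage branch, adding the loser's
// mean edge coverage to every winner edge; ties break to the lexicographically
// smaller branch sequence
static bool pop_bubbles(DBG &g, size_t max_len) {
  std::vector<Bubble> bs = find_bubbles(g, max_len);
  bool any = false;
  for (size_t i = 0; i < bs.size(); ++i) {
    Bubble &b = bs[i];
    // edges may have been removed by a previously popped bubble
    bool alive = true;
    for (size_t j = 0; j < b.p1.size() && alive; ++j)
      if (!g.has_edge(b.p1[j])) alive = false;
    for (size_t j = 0; j < b.p2.size() && alive; ++j)
      if (!g.has_edge(b.p2[j])) alive = false;
    if (!alive) continue;
    double c1 = 0, c2 = 0;
    for (size_t j = 0; j < b.p1.size(); ++j) c1 += g.edge_cov(b.p1[j]);
    for (size_t j = 0; j < b.p2.size(); ++j) c2 += g.edge_cov(b.p2[j]);
    c1 /= b.p1.size();
    c2 /= b.p2.size();
    std::vector<u128> *win = &b.p1, *lose = &b.p2;
    double lose_mean = c2;
    if (c2 > c1 ||
        (c2 == c1 && path_seq(g, b.p2) < path_seq(g, b.p1))) {
      win = &b.p2; lose = &b.p1; lose_mean = c1;
    }
    uint32_t add = (uint32_t)(lose_mean + 0.5);
    for (size_t j = 0; j < lose->size(); ++j) g.erase_edge((*lose)[j]);
    for (size_t j = 0; j < win->size(); ++j)
      g.cov[canon_bits((*win)[j], g.k)] += add;
    any = true;
  }
  return any;
}

static void simplify_graph_cpp(DBG &g, int min_cov, int max_tip,
                               int bubble_max) {
  for (int round = 0; round < 100; ++round) {
    bool changed = false;
    if (drop_low_coverage(g, min_cov)) changed = true;
    if (clip_tips(g, max_tip)) changed = true;
    if (pop_bubbles(g, (size_t)bubble_max)) changed = true;
    if (!changed) break;
  }
}

// [[Rcpp::export]]
List cpp_simplify(CharacterVector kmers, IntegerVector counts, int k,
                  int min_cov, int max_tip, int bubble_max) {
  DBG g = graph_from_r(kmers, counts, k);
  simplify_graph_cpp(g, min_cov, max_tip, bubble_max);
  return graph_to_r(g);
}

// [[Rcpp::export]]
int cpp_count_bubbles(CharacterVector kmers, IntegerVector counts, int k) {
  DBG g = graph_from_r(kmers, counts, k);
  std::vector<Bubble> bs = find_bubbles(g, (size_t)1 << 30);
  return (int)bs.size();
}

// ---------------------------------------------------------------- components

// [[Rcpp::export]]
int cpp_components(CharacterVector kmers, IntegerVector counts, int k) {
  DBG g = graph_from_r(kmers, counts, k);
  std::unordered_map<u128, u128, U128Hash> parent;
  std::function<u128(u128)> find = [&](u128 x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  int n_nodes = 0;
  for (CovMap::const_iterator it = g.cov.begin(); it != g.cov.end(); ++it) {
    u128 a = canon_bits(g.prefix_node(it->first), k - 1);
    u128 b = canon_bits(g.suffix_node(it->first), k - 1);
    if (!parent.count(a)) { parent[a] = a; ++n_nodes; }
    if (!parent.count(b)) { parent[b] = b; ++n_nodes; }
    u128 ra = find(a), rb = find(b);
    if (ra != rb) parent[ra] = rb;
  }
  std::unordered_set<u128, U128Hash> roots;
  for (std::unordered_map<u128, u128, U128Hash>::iterator it = parent.begin();
       it != parent.end(); ++it)
    roots.insert(find(it->first));
  return (int)roots.size();
}

// ---------------------------------------------------------------- contigs

// Booth's least-rotation
static std::string least_rotation(const std::string &s) {
  std::string ss = s + s;
  size_t n = ss.size();
  std::vector<long> f(n, -1);
  size_t kk = 0;
  for (size_t j = 1; j < n; ++j) {
    char sj = ss[j];
    long i = f[j - kk - 1];
    while (i != -1 && sj != ss[kk + i + 1]) {
      if (sj < ss[kk + i + 1]) kk = j - i - 1;
      i = f[i];
    }
    if (sj != ss[kk + i + 1]) {
      if (sj < ss[kk]) kk = j;
      f[j - kk] = -1;
    } else {
      f[j - kk] = i + 1;
    }
  }
  return ss.substr(kk, s.size());
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
std::string cpp_least_rotation(std::string s) { return least_rotation(s); }

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }

static List extract_contigs_cpp(const DBG &g) {
  std::vector<std::string> seqs;
  std::vector<bool> circ;
  std::vector<double> mean_cov;
  std::unordered_set<u128, U128Hash> visited;
  std::vector<u128> keys = g.sorted_keys();
  size_t cap = g.cov.size() + 1;
  for (size_t i = 0; i < keys.size(); ++i) {
    if (visited.count(keys[i])) continue;
    u128 e0 = keys[i];  // canonical orientation as start
    std::vector<u128> path;
    bool closed;
    walk_unbranched(g, e0, cap, path, closed);
    if (!closed) {
      // extend left from prefix of first edge
      std::vector<u128> left;
      u128 u = g.prefix_node(path[0]);
      std::unordered_set<u128, U128Hash> seen;
      for (size_t j = 0; j < path.size(); ++j)
        seen.insert(canon_bits(path[j], g.k));
      while (left.size() + path.size() < cap && g.indeg(u) == 1 &&
             g.outdeg(u) == 1) {
        u128 es[4];
        g.in_edges(u, es);
        u128 prev = es[0];
        u128 cn = canon_bits(prev, g.k);
        if (seen.count(cn)) break;
        seen.insert(cn);
        left.push_back(prev);
        u = g.prefix_node(prev);
      }
      std::reverse(left.begin(), left.end());
      left.insert(left.end(), path.begin(), path.end());
      path.swap(left);
    }
    double cv = 0;
    for (size_t j = 0; j < path.size(); ++j) {
      visited.insert(canon_bits(path[j], g.k));
      cv += g.edge_cov(path[j]);
    }
    cv /= path.size();
    std::string s = path_seq(g, path);
    if (closed) {
      // drop the duplicated closing (k-1)-mer, normalize rotation and strand
      s = s.substr(0, path.size());
      std::string a = least_rotation(s);
      std::string b = least_rotation(revcomp_str(s));
      s = (a < b) ? a : b;
    } else {
      std::string r = revcomp_str(s);
      if (r < s) s = r;
    }
    seqs.push_back(s);
    circ.push_back(closed);
    mean_cov.push_back(cv);
  }
  // deterministic report order: longest first, then sequence
  std::vector<size_t> ord(seqs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (seqs[a].size() != seqs[b].size()) return seqs[a].size() > seqs[b].size();
    return seqs[a] < seqs[b];
  });
  CharacterVector rs(seqs.size());
  LogicalVector rc(seqs.size());
  NumericVector rv(seqs.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    rs[i] = seqs[ord[i]];
    rc[i] = (bool)circ[ord[i]];
    rv[i] = mean_cov[ord[i]];
  }
  return List::create(_["sequence"] = rs, _["is_circular"] = rc,
                      _["mean_coverage"] = rv);
}

// [[Rcpp::export]]
List cpp_extract_contigs(CharacterVector kmers, IntegerVector counts, int k) {
  DBG g = graph_from_r(kmers, counts, k);
  return extract_contigs_cpp(g);
}

// fused build + simplify + extract, avoiding the R-level edge table
// [[Rcpp::export]]
List cpp_assemble(CharacterVector seqs, int k, int min_cov, int max_tip,
                  int bubble_max) {
  DBG g(k);
  build_from_seqs(g, seqs);
  simplify_graph_cpp(g, min_cov, max_tip, bubble_max);
  return extract_contigs_cpp(g);
}

// ---------------------------------------------------------------- mapping

// banded global edit distance between two similar strings (diag band +-band)
static int banded_edit(const std::string &a, const std::string &b, int band) {
  int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > band) return n + m;
  const int INF = 1 << 28;
  // cell (i, j) stored at index d + band with d = j - i
  std::vector<int> prev(2 * band + 1, INF), cur(2 * band + 1, INF);
  for (int d = 0; d <= band && d <= m; ++d) prev[d + band] = d;  // row 0
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int d = -band; d <= band; ++d) {
      int j = i + d;
      if (j < 0 || j > m) continue;
      int best = INF;
      if (j >= 1 && prev[d + band] < INF)  // substitution/match from (i-1,j-1)
        best = std::min(best, prev[d + band] + (a[i - 1] == b[j - 1] ? 0 : 1));
      if (d + 1 <= band && prev[d + 1 + band] < INF)  // gap in b from (i-1,j)
        best = std::min(best, prev[d + 1 + band] + 1);
      cur[d + band] = best;
    }
    for (int d = -band + 1; d <= band; ++d) {  // gap in a from (i,j-1)
      int j = i + d;
      if (j < 1 || j > m) continue;
      if (cur[d - 1 + band] < INF && cur[d - 1 + band] + 1 < cur[d + band])
        cur[d + band] = cur[d - 1 + band] + 1;
    }
    prev.swap(cur);
  }
  return prev[(m - n) + band];
}

// Map reads to contigs by exact seed match + verification.
// Returns 1-based best contig index (0 = unmapped) and identity per read.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector contigs,
                   LogicalVector circular, int seed_len, double min_identity,
                   bool allow_rc, int band) {
  int nC = contigs.size();
  // virtually extend circular contigs so junction-spanning reads map
  int max_rlen = 0;
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    max_rlen = std::max(max_rlen, (int)LENGTH(STRING_ELT(reads, i)));
  std::vector<std::string> cseq(nC);
  std::vector<int> true_len(nC);
  for (int c = 0; c < nC; ++c) {
    std::string s = as<std::string>(contigs[c]);
    true_len[c] = (int)s.size();
    if (circular[c] && (int)s.size() > 1) {
      int ext = std::min((int)s.size(), std::max(seed_len, max_rlen) - 1);
      s += s.substr(0, ext);
    }
    cseq[c] = s;
  }
  // seed index over contig forward strands
  std::unordered_map<u128, std::vector<std::pair<int, int> >, U128Hash> idx;
  for (int c = 0; c < nC; ++c) {
    const std::string &s = cseq[c];
    if ((int)s.size() < seed_len) continue;
    for (size_t p = 0; p + seed_len <= s.size(); ++p) {
      u128 v;
      if (!encode_bits(s, p, seed_len, v)) continue;
      idx[v].push_back(std::make_pair(c, (int)p));
    }
  }
  R_xlen_t nR = reads.size();
  IntegerVector best_ci(nR, 0);
  NumericVector best_id(nR, NA_REAL);
  std::vector<std::pair<int, int> > cands;  // (contig, offset)
  for (R_xlen_t r = 0; r < nR; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int m = (int)fwd.size();
    double bid = -1.0;
    int bci = -1;
    for (int ori = 0; ori < (allow_rc ? 2 : 1); ++ori) {
      std::string rd = (ori == 0) ? fwd : revcomp_str(fwd);
      if (m < seed_len) continue;
      cands.clear();
      for (int p = 0; p + seed_len <= m; ++p) {
        u128 v;
        if (!encode_bits(rd, p, seed_len, v)) continue;
        std::unordered_map<u128, std::vector<std::pair<int, int> >,
                           U128Hash>::const_iterator it = idx.find(v);
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int c = it->second[h].first;
          int off = it->second[h].second - p;
          cands.push_back(std::make_pair(c, off));
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (size_t q = 0; q < cands.size(); ++q) {
        int c = cands[q].first, off = cands[q].second;
        if (off < 0 || off + m > (int)cseq[c].size()) continue;
        // fast ungapped identity
        int mism = 0;
        const std::string &cs = cseq[c];
        int allowed = (int)(m * (1.0 - min_identity));
        for (int p = 0; p < m; ++p) {
          if (rd[p] != cs[off + p]) ++mism;
          if (mism > allowed + 2 * band) break;
        }
        double id;
        if (mism <= allowed) {
          id = (double)(m - mism) / m;
        } else {
          int d = banded_edit(rd, cs.substr(off, m), band);
          id = (double)(m - d) / m;
        }
        if (id >= min_identity && id > bid + 1e-12) {
          bid = id;
          bci = c;
        } else if (id >= min_identity && std::abs(id - bid) <= 1e-12 &&
                   bci >= 0 && c < bci) {
          bci = c;
        }
      }
      if (bid >= 1.0 - 1e-12) break;  // cannot improve with the other strand
    }
    if (bci >= 0) {
      best_ci[r] = bci + 1;
      best_id[r] = bid;
    }
  }
  return List::create(_["contig"] = best_ci, _["identity"] = best_id);
}
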