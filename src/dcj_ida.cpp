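// Iterative-deepening A* refinement for the DCJ-indel distance.
//
// Using the deletions-before-insertions normal form, the distance is the
// shortest joint sequence of moves bringing the two configurations to a
// common middle genome, where each side may apply DCJs or delete
// contiguous segments of its own private markers. The search state is
// the genome pair; the admissible heuristic is the adjacency-graph bound
// max(N' - C - I/2 over shared markers, pending private sides), which no
// single move can reduce by more than one. This resolves the run-merge
// credit of the closed-form distance exactly and shares no search code
// with the breadth-first oracle.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <set>
#include <string>
#include <unordered_map>
#include <vector>

namespace ida {

struct Chr {
  std::vector<int> seq;
  bool circ;
};
typedef std::vector<Chr> Side;

static std::vector<int> revneg(const std::vector<int>& v) {
  std::vector<int> r(v.rbegin(), v.rend());
  for (auto& x : r) x = -x;
  return r;
}

static std::string side_key(const Side& st) {
  std::vector<std::string> parts;
  for (const auto& c : st) {
    if (c.seq.empty()) continue;
    std::vector<int> best;
    if (!c.circ) {
      best = std::min(c.seq, revneg(c.seq));
    } else {
      best = c.seq;
      size_t n = c.seq.size();
      for (int f = 0; f < 2; ++f) {
        std::vector<int> base = f ? revneg(c.seq) : c.seq;
        for (size_t s = 0; s < n; ++s) {
          std::vector<int> rot(n);
          for (size_t i = 0; i < n; ++i) rot[i] = base[(s + i) % n];
          if (rot < best) best = rot;
        }
      }
    }
    std::string p = c.circ ? "o" : "l";
    for (int x : best) p += std::to_string(x) + ";";
    parts.push_back(p);
  }
  std::sort(parts.begin(), parts.end());
  std::string k;
  for (auto& p : parts) k += p + "#";
  return k;
}

static int eleft(int x) { return x > 0 ? 2 * x - 1 : -2 * x; }
static int eright(int x) { return x > 0 ? 2 * x : -2 * x - 1; }

static void adjacencies(const Side& st, const std::set<int>& keep,
                        std::vector<std::pair<int, int> >& out) {
  for (const auto& c : st) {
    std::vector<int> m;
    for (int x : c.seq)
      if (keep.count(std::abs(x))) m.push_back(x);
    if (m.empty()) continue;
    size_t n = m.size();
    for (size_t i = 0; i + 1 < n; ++i)
      out.push_back(std::minmax(eright(m[i]), eleft(m[i + 1])));
    if (c.circ) {
      out.push_back(std::minmax(eright(m[n - 1]), eleft(m[0])));
    } else {
      out.push_back(std::make_pair(eleft(m[0]), 0));
      out.push_back(std::make_pair(eright(m[n - 1]), 0));
    }
  }
}

// adjacency-graph lower bound between the two sides
static int hbound(const Side& X, const Side& Y) {
  std::set<int> mx, my;
  for (const auto& c : X)
    for (int x : c.seq) mx.insert(std::abs(x));
  for (const auto& c : Y)
    for (int x : c.seq) my.insert(std::abs(x));
  std::set<int> shared;
  for (int m : mx)
    if (my.count(m)) shared.insert(m);
  int needx = 0, needy = 0;
  for (int m : mx)
    if (!shared.count(m)) {
      needx = 1;
      break;
    }
  for (int m : my)
    if (!shared.count(m)) {
      needy = 1;
      break;
    }
  int N = (int)shared.size();
  if (N == 0) return needx + needy;

  std::vector<std::pair<int, int> > sa, ta;
  adjacencies(X, shared, sa);
  adjacencies(Y, shared, ta);
  std::map<int, int> snext, tnext;
  for (size_t i = 0; i < sa.size(); ++i) {
    snext[sa[i].first] = (int)i;
    if (sa[i].second) snext[sa[i].second] = (int)i;
  }
  for (size_t i = 0; i < ta.size(); ++i) {
    tnext[ta[i].first] = (int)i;
    if (ta[i].second) tnext[ta[i].second] = (int)i;
  }
  std::vector<bool> sv(sa.size(), false), tv(ta.size(), false);
  int C = 0, odd = 0;
  for (int side = 0; side < 2; ++side) {
    const auto& start_els = side == 0 ? sa : ta;
    for (size_t i = 0; i < start_els.size(); ++i) {
      if (start_els[i].second != 0) continue;
      if ((side == 0 ? sv : tv)[i]) continue;
      int edges = 0;
      bool on_s = side == 0;
      int cur = (int)i, ent = 0;
      while (true) {
        (on_s ? sv : tv)[cur] = true;
        const auto& el = on_s ? sa[cur] : ta[cur];
        int out_ext;
        if (el.second == 0) {
          out_ext = (ent == 0) ? el.first : 0;
        } else {
          out_ext = (ent == 0) ? el.first
                               : (el.first == ent ? el.second : el.first);
        }
        if (out_ext == 0) break;
        const auto& omap = on_s ? tnext : snext;
        auto it = omap.find(out_ext);
        if (it == omap.end()) break;
        int nxt = it->second;
        if ((on_s ? tv : sv)[nxt]) break;
        edges++;
        on_s = !on_s;
        cur = nxt;
        ent = out_ext;
      }
      if (edges % 2 == 1) odd++;
    }
  }
  for (size_t i = 0; i < sa.size(); ++i) {
    if (sv[i]) continue;
    bool on_s = true;
    int cur = (int)i, ent = 0, guard = 0;
    while (!(on_s ? sv : tv)[cur] && guard++ < 10000) {
      (on_s ? sv : tv)[cur] = true;
      const auto& el = on_s ? sa[cur] : ta[cur];
      int out_ext = (ent == 0) ? el.first
                               : (el.first == ent ? el.second : el.first);
      const auto& omap = on_s ? tnext : snext;
      auto it = omap.find(out_ext);
      if (it == omap.end()) break;
      cur = it->second;
      on_s = !on_s;
      ent = out_ext;
    }
    C++;
  }
  int hd = N - C - odd / 2;
  int hi = needx + needy;
  return hd > hi ? hd : hi;
}

// rebuild a side from an element multiset
static Side rebuild(const std::vector<std::pair<int, int> >& e) {
  std::map<int, int> partner;
  std::set<int> exts;
  for (const auto& p : e) {
    partner[p.first] = p.second;
    if (p.second) partner[p.second] = p.first;
    exts.insert(p.first);
    if (p.second) exts.insert(p.second);
  }
  std::set<int> used;
  Side g;
  for (const auto& p : e) {
    if (p.second != 0 || used.count(p.first)) continue;
    std::vector<int> seq;
    int ex = p.first;
    while (true) {
      used.insert(ex);
      int m = (ex + 1) / 2;
      seq.push_back(ex % 2 == 1 ? m : -m);
      int e2 = (ex % 2 == 1) ? ex + 1 : ex - 1;
      used.insert(e2);
      auto it = partner.find(e2);
      int nx = (it == partner.end()) ? 0 : it->second;
      if (nx == 0) break;
      ex = nx;
    }
    Chr c;
    c.seq = seq;
    c.circ = false;
    g.push_back(c);
  }
  for (int e0 : exts) {
    if (used.count(e0)) continue;
    std::vector<int> seq;
    int ex = e0;
    while (!used.count(ex)) {
      used.insert(ex);
      int m = (ex + 1) / 2;
      seq.push_back(ex % 2 == 1 ? m : -m);
      int e2 = (ex % 2 == 1) ? ex + 1 : ex - 1;
      used.insert(e2);
      ex = partner[e2];
    }
    Chr c;
    c.seq = seq;
    c.circ = true;
    g.push_back(c);
  }
  return g;
}

// DCJ + private-deletion successors of one side
static void side_successors(const Side& st, const std::set<int>& deletable,
                            std::vector<Side>& out) {
  std::vector<std::pair<int, int> > els;
  {
    std::set<int> all;
    for (const auto& c : st)
      for (int x : c.seq) all.insert(std::abs(x));
    adjacencies(st, all, els);
  }
  size_t n = els.size();
  for (size_t i = 0; i < n; ++i) {
    if (els[i].second != 0) {
      auto e = els;
      e[i] = std::make_pair(els[i].first, 0);
      e.push_back(std::make_pair(els[i].second, 0));
      out.push_back(rebuild(e));
    }
    for (size_t j = i + 1; j < n; ++j) {
      int p = els[i].first, q = els[i].second;
      int r = els[j].first, s = els[j].second;
      if (q && s) {
        auto e = els;
        e[i] = std::minmax(p, r);
        e[j] = std::minmax(q, s);
        out.push_back(rebuild(e));
        e = els;
        e[i] = std::minmax(p, s);
        e[j] = std::minmax(q, r);
        out.push_back(rebuild(e));
      } else if (q && !s) {
        auto e = els;
        e[i] = std::minmax(p, r);
        e[j] = std::make_pair(q, 0);
        out.push_back(rebuild(e));
        e = els;
        e[i] = std::minmax(q, r);
        e[j] = std::make_pair(p, 0);
        out.push_back(rebuild(e));
      } else if (!q && s) {
        auto e = els;
        e[j] = std::minmax(r, p);
        e[i] = std::make_pair(s, 0);
        out.push_back(rebuild(e));
        e = els;
        e[j] = std::minmax(s, p);
        e[i] = std::make_pair(r, 0);
        out.push_back(rebuild(e));
      } else {
        std::vector<std::pair<int, int> > e;
        for (size_t k = 0; k < n; ++k)
          if (k != i && k != j) e.push_back(els[k]);
        e.push_back(std::minmax(p, r));
        out.push_back(rebuild(e));
      }
    }
  }
  // deletions
  for (size_t ci = 0; ci < st.size(); ++ci) {
    const auto& s = st[ci].seq;
    size_t m = s.size();
    bool circ = st[ci].circ;
    bool alldel = true;
    for (int x : s)
      if (!deletable.count(std::abs(x))) alldel = false;
    if (alldel) {
      Side h;
      for (size_t k = 0; k < st.size(); ++k)
        if (k != ci) h.push_back(st[k]);
      out.push_back(h);
    }
    for (size_t i = 0; i < m; ++i) {
      size_t maxlen = circ ? m - 1 : m - i;
      for (size_t len = 1; len <= maxlen; ++len) {
        bool ok = true;
        for (size_t k = 0; k < len; ++k)
          if (!deletable.count(std::abs(s[(i + k) % m]))) {
            ok = false;
            break;
          }
        if (!ok) break;
        if (!circ && i == 0 && len == m) continue;
        std::vector<int> rest;
        if (!circ) {
          for (size_t k = 0; k < i; ++k) rest.push_back(s[k]);
          for (size_t k = i + len; k < m; ++k) rest.push_back(s[k]);
        } else {
          for (size_t k = 0; k < m - len; ++k)
            rest.push_back(s[(i + len + k) % m]);
        }
        Side h;
        for (size_t k = 0; k < st.size(); ++k)
          if (k != ci) h.push_back(st[k]);
        if (!rest.empty()) {
          Chr c;
          c.seq = rest;
          c.circ = circ;
          h.push_back(c);
        }
        out.push_back(h);
      }
    }
  }
}

struct Search {
  std::set<int> del_x, del_y;
  std::unordered_map<std::string, int> seen;
  long nodes = 0;

  bool dfs(const Side& X, const Side& Y, int g, int bound) {
    int h = hbound(X, Y);
    if (g + h > bound) return false;
    std::string kx = side_key(X), ky = side_key(Y);
    if (kx == ky) return true;
    std::string key = kx + "~" + ky;
    auto it = seen.find(key);
    if (it != seen.end() && it->second <= g) return false;
    seen[key] = g;
    if (++nodes > 4000000L) Rcpp::stop("IDA* node budget exceeded");
    std::vector<Side> sx;
    side_successors(X, del_x, sx);
    for (const auto& nx : sx) {
      if (dfs(nx, Y, g + 1, bound)) return true;
    }
    std::vector<Side> sy;
    side_successors(Y, del_y, sy);
    for (const auto& ny : sy) {
      if (dfs(X, ny, g + 1, bound)) return true;
    }
    return false;
  }
};

}  // namespace ida

// [[Rcpp::export]]
int dcj_ida_distance_cpp(Rcpp::IntegerVector a, Rcpp::IntegerVector b,
                         int max_bound = 16) {
  ida::Side X, Y;
  if (a.size()) {
    ida::Chr c;
    c.seq = std::vector<int>(a.begin(), a.end());
    c.circ = false;
    X.push_back(c);
  }
  if (b.size()) {
    ida::Chr c;
    c.seq = std::vector<int>(b.begin(), b.end());
    c.circ = false;
    Y.push_back(c);
  }
  if (ida::side_key(X) == ida::side_key(Y)) return 0;
  std::set<int> ma, mb;
  for (const auto& c : X)
    for (int x : c.seq) ma.insert(std::abs(x));
  for (const auto& c : Y)
    for (int x : c.seq) mb.insert(std::abs(x));
  ida::Search S;
  for (int m : ma)
    if (!mb.count(m)) S.del_x.insert(m);
  for (int m : mb)
    if (!ma.count(m)) S.del_y.insert(m);
  int h0 = ida::hbound(X, Y);
  for (int bound = std::max(1, h0); bound <= max_bound; ++bound) {
    S.seen.clear();
    S.nodes = 0;
    if (S.dfs(X, Y, 0, bound)) return bound;
  }
  Rcpp::stop("IDA* exceeded max_bound");
}
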