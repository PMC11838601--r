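// Exact DCJ-indel distance by exhaustive breadth-first search.
//
// Model: double-cut-and-join operations (including cuts, joins and
// circular intermediates) plus insertions/deletions of one contiguous
// marker segment per operation. Every sorting scenario can be reordered
// so that all deletions precede all insertions; reading the insertion
// phase backwards turns it into a deletion phase from the target, so
//
//   d(A, B) = min over middle genomes M of
//             d_delDCJ(A -> M) + d_delDCJ(B -> M),
//
// where d_delDCJ uses DCJs and deletions of markers absent from the
// other genome. The search below runs the two deletion-only BFS waves
// and meets in the middle; no insertion enumeration is needed, and the
// distance is symmetric by construction.
//
// Markers are nonzero signed integers, unique within each genome.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <set>
#include <string>
#include <unordered_map>
#include <vector>

typedef std::vector<int> Chrom;                 // signed marker sequence
struct Chromosome {
  Chrom seq;
  bool circular;
};
typedef std::vector<Chromosome> Genome;

static Chrom reverse_neg(const Chrom& c) {
  Chrom r(c.rbegin(), c.rend());
  for (auto& x : r) x = -x;
  return r;
}

static Chrom canon_linear(const Chrom& c) {
  Chrom r = reverse_neg(c);
  return std::min(c, r);
}

static Chrom canon_circular(const Chrom& c) {
  Chrom best = c;
  size_t n = c.size();
  for (int flip = 0; flip < 2; ++flip) {
    Chrom base = flip ? reverse_neg(c) : c;
    for (size_t s = 0; s < n; ++s) {
      Chrom rot(n);
      for (size_t i = 0; i < n; ++i) rot[i] = base[(s + i) % n];
      if (rot < best) best = rot;
    }
  }
  return best;
}

static std::string genome_key(const Genome& g) {
  std::vector<std::string> parts;
  for (const auto& ch : g) {
    if (ch.seq.empty()) continue;
    Chrom c = ch.circular ? canon_circular(ch.seq) : canon_linear(ch.seq);
    std::string s = ch.circular ? "c:" : "l:";
    for (int x : c) {
      s += std::to_string(x);
      s += ',';
    }
    parts.push_back(s);
  }
  std::sort(parts.begin(), parts.end());
  std::string key;
  for (auto& p : parts) {
    key += p;
    key += '|';
  }
  return key;
}

// ---- extremity/adjacency representation for DCJ moves ----
static int ext_left(int x) { return x > 0 ? 2 * x - 1 : -2 * x; }
static int ext_right(int x) { return x > 0 ? 2 * x : -2 * x - 1; }

static std::vector<std::pair<int, int> > genome_elements(const Genome& g) {
  std::vector<std::pair<int, int> > adj;  // second = 0 for telomere
  for (const auto& ch : g) {
    const Chrom& s = ch.seq;
    if (s.empty()) continue;
    size_t n = s.size();
    for (size_t i = 0; i + 1 < n; ++i) {
      adj.push_back(std::minmax(ext_right(s[i]), ext_left(s[i + 1])));
    }
    if (ch.circular) {
      adj.push_back(std::minmax(ext_right(s[n - 1]), ext_left(s[0])));
    } else {
      adj.push_back(std::make_pair(ext_left(s[0]), 0));
      adj.push_back(std::make_pair(ext_right(s[n - 1]), 0));
    }
  }
  return adj;
}

// rebuild a genome from an element multiset
static Genome elements_genome(const std::vector<std::pair<int, int> >& els) {
  std::map<int, int> partner;
  std::set<int> exts;
  for (const auto& p : els) {
    partner[p.first] = p.second;
    if (p.second) partner[p.second] = p.first;
    exts.insert(p.first);
    if (p.second) exts.insert(p.second);
  }
  auto other_end = [](int e) { return (e % 2 == 1) ? e + 1 : e - 1; };
  auto marker_of = [](int e) { return (e + 1) / 2; };
  std::set<int> visited;
  Genome g;
  for (const auto& p : els) {
    if (p.second != 0) continue;
    if (visited.count(p.first)) continue;
    Chrom seq;
    int e = p.first;
    while (true) {
      visited.insert(e);
      int m = marker_of(e);
      seq.push_back(e % 2 == 1 ? m : -m);
      int e2 = other_end(e);
      visited.insert(e2);
      int nxt = partner.count(e2) ? partner[e2] : 0;
      if (nxt == 0) break;
      e = nxt;
    }
    Chromosome ch;
    ch.seq = seq;
    ch.circular = false;
    g.push_back(ch);
  }
  for (int e0 : exts) {
    if (visited.count(e0)) continue;
    Chrom seq;
    int e = e0;
    while (!visited.count(e)) {
      visited.insert(e);
      int m = marker_of(e);
      seq.push_back(e % 2 == 1 ? m : -m);
      int e2 = other_end(e);
      visited.insert(e2);
      e = partner[e2];
    }
    Chromosome ch;
    ch.seq = seq;
    ch.circular = true;
    g.push_back(ch);
  }
  return g;
}

// all DCJ successors
static void dcj_successors(const Genome& g, std::vector<Genome>& out) {
  std::vector<std::pair<int, int> > e = genome_elements(g);
  size_t n = e.size();
  for (size_t i = 0; i < n; ++i) {
    if (e[i].second != 0) {  // cut an adjacency into two telomeres
      auto els = e;
      els[i] = std::make_pair(e[i].first, 0);
      els.push_back(std::make_pair(e[i].second, 0));
      out.push_back(elements_genome(els));
    }
    for (size_t j = i + 1; j < n; ++j) {
      int p = e[i].first, q = e[i].second;
      int r = e[j].first, s = e[j].second;
      if (q != 0 && s != 0) {
        auto els = e;
        els[i] = std::minmax(p, r);
        els[j] = std::minmax(q, s);
        out.push_back(elements_genome(els));
        els = e;
        els[i] = std::minmax(p, s);
        els[j] = std::minmax(q, r);
        out.push_back(elements_genome(els));
      } else if (q != 0 && s == 0) {
        auto els = e;
        els[i] = std::minmax(p, r);
        els[j] = std::make_pair(q, 0);
        out.push_back(elements_genome(els));
        els = e;
        els[i] = std::minmax(q, r);
        els[j] = std::make_pair(p, 0);
        out.push_back(elements_genome(els));
      } else if (q == 0 && s != 0) {
        auto els = e;
        els[j] = std::minmax(r, p);
        els[i] = std::make_pair(s, 0);
        out.push_back(elements_genome(els));
        els = e;
        els[j] = std::minmax(s, p);
        els[i] = std::make_pair(r, 0);
        out.push_back(elements_genome(els));
      } else {  // join two telomeres
        std::vector<std::pair<int, int> > els;
        for (size_t k = 0; k < n; ++k)
          if (k != i && k != j) els.push_back(e[k]);
        els.push_back(std::minmax(p, r));
        out.push_back(elements_genome(els));
      }
    }
  }
}

// deletions of contiguous segments of deletable markers
static void del_successors(const Genome& g, const std::set<int>& deletable,
                           std::vector<Genome>& out) {
  for (size_t ci = 0; ci < g.size(); ++ci) {
    const Chrom& s = g[ci].seq;
    size_t n = s.size();
    bool circ = g[ci].circular;
    bool all_del = true;
    for (int x : s)
      if (!deletable.count(std::abs(x))) all_del = false;
    if (all_del) {
      Genome h;
      for (size_t k = 0; k < g.size(); ++k)
        if (k != ci) h.push_back(g[k]);
      out.push_back(h);
    }
    for (size_t i = 0; i < n; ++i) {
      size_t maxlen = circ ? n - 1 : n - i;
      for (size_t len = 1; len <= maxlen; ++len) {
        bool ok = true;
        for (size_t k = 0; k < len; ++k) {
          if (!deletable.count(std::abs(s[(i + k) % n]))) {
            ok = false;
            break;
          }
        }
        if (!ok) break;
        if (!circ && i == 0 && len == n) continue;  // handled above
        Chrom rest;
        if (!circ) {
          for (size_t k = 0; k < i; ++k) rest.push_back(s[k]);
          for (size_t k = i + len; k < n; ++k) rest.push_back(s[k]);
        } else {
          for (size_t k = 0; k < n - len; ++k)
            rest.push_back(s[(i + len + k) % n]);
        }
        Genome h;
        for (size_t k = 0; k < g.size(); ++k)
          if (k != ci) h.push_back(g[k]);
        if (!rest.empty()) {
          Chromosome ch;
          ch.seq = rest;
          ch.circular = circ;
          h.push_back(ch);
        }
        out.push_back(h);
      }
    }
  }
}

struct Wave {
  std::unordered_map<std::string, int> dist;
  std::vector<Genome> frontier;
  std::set<int> deletable;
  int depth = 0;
};

static void expand_wave(Wave& w, const Wave& other, int& best) {
  std::vector<Genome> next;
  for (const auto& g : w.frontier) {
    std::vector<Genome> succ;
    dcj_successors(g, succ);
    del_successors(g, w.deletable, succ);
    for (auto& h : succ) {
      std::string key = genome_key(h);
      auto ins = w.dist.insert(std::make_pair(key, w.depth + 1));
      if (!ins.second) continue;
      auto it = other.dist.find(key);
      if (it != other.dist.end()) {
        int cand = w.depth + 1 + it->second;
        if (cand < best) best = cand;
      }
      next.push_back(h);
    }
  }
  w.frontier.swap(next);
  w.depth++;
}

// [[Rcpp::export]]
int dcj_bfs_distance_cpp(Rcpp::IntegerVector a, Rcpp::IntegerVector b,
                         int max_depth = 12) {
  Chrom ca(a.begin(), a.end()), cb(b.begin(), b.end());
  Genome ga, gb;
  if (!ca.empty()) {
    Chromosome ch;
    ch.seq = ca;
    ch.circular = false;
    ga.push_back(ch);
  }
  if (!cb.empty()) {
    Chromosome ch;
    ch.seq = cb;
    ch.circular = false;
    gb.push_back(ch);
  }
  std::string ka = genome_key(ga), kb = genome_key(gb);
  if (ka == kb) return 0;

  std::set<int> ma, mb;
  for (int x : ca) ma.insert(std::abs(x));
  for (int x : cb) mb.insert(std::abs(x));

  Wave F, B;
  for (int m : ma)
    if (!mb.count(m)) F.deletable.insert(m);
  for (int m : mb)
    if (!ma.count(m)) B.deletable.insert(m);
  F.dist[ka] = 0;
  F.frontier.push_back(ga);
  B.dist[kb] = 0;
  B.frontier.push_back(gb);
  if (B.dist.count(ka)) return 0;  // unreachable; keys differ

  int best = INT32_MAX;
  while (F.depth + B.depth < max_depth) {
    // all meets of total length <= F.depth + B.depth have been seen
    if (best <= F.depth + B.depth) break;
    Wave& w = (F.frontier.size() <= B.frontier.size()) ? F : B;
    const Wave& o = (&w == &F) ? B : F;
    if (w.frontier.empty()) {
      Wave& w2 = (&w == &F) ? B : F;
      const Wave& o2 = (&w == &F) ? F : B;
      if (w2.frontier.empty()) break;
      expand_wave(w2, o2, best);
    } else {
      expand_wave(w, o, best);
    }
    Rcpp::checkUserInterrupt();
  }
  if (best == INT32_MAX) Rcpp::stop("BFS exceeded max_depth");
  return best;
}
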