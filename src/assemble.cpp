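// Greedy overlap-layout-consensus core.
//
// Overlap discovery anchors on each read's leading k-mer: an overlap a->b (b
// extending a's right end at offset p) is found when b's first k bases occur
// exactly at position p of a. Qualifying overlaps (length >= min_ovl, identity
// >= min_id, Hamming on the implied diagonal) feed a mutual-best unitig walk;
// an end with two qualifying extensions whose extension sequences disagree is
// a branch point and stops extension. Consensus is per-column majority vote.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

std::string es_revcomp(const std::string& s);
int es_nt2i(char c);

namespace {

struct Edge {
  int partner;   // oriented id, -1 = none
  int p;         // partner start offset within this oriented read
  int ov;        // overlap length
  int mm;        // mismatches in overlap
};

struct Containment {
  int host;      // oriented host id, -1 = none
  int p;
  int mm;
};

inline uint64_t kmer_at(const std::string& s, int pos, int k, bool& ok) {
  uint64_t key = 0;
  for (int j = 0; j < k; ++j) {
    int c = es_nt2i(s[pos + j]);
    if (c < 0) { ok = false; return 0; }
    key = (key << 2) | (uint64_t)c;
  }
  ok = true;
  return key;
}

// disagreement scan between two candidate extensions: a branch shows a dense
// run of mismatches once the sequences diverge; sparse sequencing errors do not.
bool ext_conflict(const char* e1, int l1, const char* e2, int l2) {
  int m = std::min(l1, l2);
  if (m < 3) return false;
  if (m < 6) {
    int mm = 0;
    for (int j = 0; j < m; ++j) if (e1[j] != e2[j]) ++mm;
    return mm >= m - 1;
  }
  int win = 6, mm = 0;
  for (int j = 0; j < m; ++j) {
    if (e1[j] != e2[j]) ++mm;
    if (j >= win && e1[j - win] != e2[j - win]) --mm;
    if (mm >= 3) return true;
  }
  return false;
}

} // namespace

// [[Rcpp::export]]
List cpp_assemble_core(CharacterVector seqs, double min_id, int min_ovl, int kmer) {
  const int n = seqs.size();
  std::vector<std::string> os(2 * n); // oriented sequences: 2i fwd, 2i+1 rc
  for (int i = 0; i < n; ++i) {
    os[2 * i] = as<std::string>(seqs[i]);
    os[2 * i + 1] = es_revcomp(os[2 * i]);
  }
  auto rd = [](int o) { return o >> 1; };

  // index anchors of every oriented read: the leading k-mer plus a second
  // k-mer a fixed offset in, so a sequencing error in one anchor window
  // cannot hide a partner (entries pack oriented id and anchor offset)
  const int aoff2 = kmer + 3;
  std::unordered_map<uint64_t, std::vector<int> > pref;
  pref.reserve(2 * n * 4);
  for (int o = 0; o < 2 * n; ++o) {
    if ((int)os[o].size() < kmer) continue;
    bool ok; uint64_t key = kmer_at(os[o], 0, kmer, ok);
    if (ok) pref[key].emplace_back(o << 1);
    if ((int)os[o].size() >= aoff2 + kmer) {
      key = kmer_at(os[o], aoff2, kmer, ok);
      if (ok) pref[key].emplace_back((o << 1) | 1);
    }
  }

  std::vector<Edge> best(2 * n, Edge{-1, 0, 0, 0});
  std::vector<char> amb(2 * n, 0);
  std::vector<Containment> cont(n, Containment{-1, 0, 0});
  std::vector<char> contained(n, 0);

  std::vector<std::pair<int, int> > cand; // (partner oriented, p)
  struct QEdge { int partner, p, ov, mm; };
  std::vector<QEdge> qual;

  for (int o = 0; o < 2 * n; ++o) {
    const std::string& S = os[o];
    const int L = S.size();
    if (L < kmer) continue;
    cand.clear();
    uint64_t key = 0, mask = (1ULL << (2 * kmer)) - 1;
    int run = 0;
    for (int i = 0; i < L; ++i) {
      int c = es_nt2i(S[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      ++run;
      if (run < kmer) continue;
      auto it = pref.find(key);
      if (it == pref.end()) continue;
      int ipos = i - kmer + 1;
      for (int ent : it->second) {
        int c2 = ent >> 1;
        int p = ipos - ((ent & 1) ? aoff2 : 0);
        if (p >= 0 && rd(c2) != rd(o)) cand.emplace_back(p, c2);
      }
    }
    // smallest offset first: the longest (best) overlaps are verified first,
    // and verification stops once enough evidence is gathered
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    qual.clear();
    int n_cont = 0;
    for (auto& cp : cand) {
      const int c2 = cp.second, p = cp.first;
      if ((int)qual.size() >= 16 && n_cont >= 8) break;
      const std::string& Sc = os[c2];
      const int Lc = Sc.size();
      if (Lc <= L - p) {
        // candidate lies fully inside this oriented read: containment
        if (n_cont >= 8) continue;
        if (p == 0 && Lc == L && rd(c2) < rd(o)) continue; // mirror handles dups
        if (Lc < kmer) continue;
        int allowed = (int)std::floor((1.0 - min_id) * Lc);
        int mm = 0;
        for (int j = 0; j < Lc && mm <= allowed; ++j)
          if (S[p + j] != Sc[j]) ++mm;
        if (mm <= allowed) {
          ++n_cont;
          int b = rd(c2);
          Containment& cb = cont[b];
          if (cb.host < 0 || mm < cb.mm) { // first (index-ordered) best host
            // orientation bookkeeping: record host as seen from c2's frame
            cb.host = (c2 & 1) ? (o ^ 1) : o;
            cb.p = (c2 & 1) ? (L - p - Lc) : p;
            cb.mm = mm;
            contained[b] = 1;
          }
        }
      } else {
        if ((int)qual.size() >= 16) continue;
        int ov = L - p;
        if (ov < min_ovl) continue;
        int allowed = (int)std::floor((1.0 - min_id) * ov);
        int mm = 0;
        for (int j = 0; j < ov && mm <= allowed; ++j)
          if (S[p + j] != Sc[j]) ++mm;
        if (mm <= allowed) qual.push_back(QEdge{c2, p, ov, mm});
      }
    }
    if (qual.empty()) continue;
    std::sort(qual.begin(), qual.end(), [](const QEdge& a, const QEdge& b) {
      if (a.ov != b.ov) return a.ov > b.ov;
      if (a.mm != b.mm) return a.mm < b.mm;
      return a.partner < b.partner;
    });
    const QEdge& e0 = qual[0];
    const char* ext0 = os[e0.partner].data() + e0.ov;
    int l0 = (int)os[e0.partner].size() - e0.ov;
    int lim = std::min((int)qual.size(), 8);
    for (int i = 1; i < lim && !amb[o]; ++i) {
      const QEdge& ei = qual[i];
      const char* exti = os[ei.partner].data() + ei.ov;
      int li = (int)os[ei.partner].size() - ei.ov;
      if (ext_conflict(ext0, l0, exti, li)) amb[o] = 1;
    }
    best[o] = Edge{e0.partner, e0.p, e0.ov, e0.mm};
  }

  // successor by predecessor election: each unambiguous end claims its best
  // extension; every claimed node accepts only its best claimant (longest
  // overlap, then fewest mismatches, then smallest id), so in-degree <= 1
  // and the layout decomposes into disjoint paths
  std::vector<int> succ(2 * n, -1), succ_p(2 * n, 0);
  std::vector<int> pred_of(2 * n, -1);
  for (int o = 0; o < 2 * n; ++o) {
    int b = best[o].partner;
    if (b < 0 || amb[o]) continue;
    if (contained[rd(o)] || contained[rd(b)]) continue;
    if (amb[b ^ 1]) continue;
    int cur = pred_of[b];
    if (cur < 0) { pred_of[b] = o; continue; }
    const Edge& eo = best[o];
    const Edge& ec = best[cur];
    bool better = (eo.ov > ec.ov) ||
      (eo.ov == ec.ov && (eo.mm < ec.mm ||
                          (eo.mm == ec.mm && o < cur)));
    if (better) pred_of[b] = o;
  }
  for (int b = 0; b < 2 * n; ++b) {
    int o = pred_of[b];
    if (o < 0) continue;
    succ[o] = b;
    succ_p[o] = best[o].p;
  }

  // walk chains
  std::vector<char> visited(n, 0);
  std::vector<int> m_read, m_contig, m_off, m_strand;
  std::vector<std::string> contigs;
  std::vector<char> circ;
  // placement of chain reads for containment resolution: oriented -> (contig, off)
  std::unordered_map<int, std::pair<int, int> > placed;

  auto walk = [&](int start) {
    int cidx = (int)contigs.size();
    std::vector<std::pair<int, int> > chain; // (oriented, offset)
    bool circular = false;
    int cur = start, off = 0;
    while (true) {
      chain.emplace_back(cur, off);
      visited[rd(cur)] = 1;
      int nxt = succ[cur];
      if (nxt < 0) break;
      if (visited[rd(nxt)]) { circular = (nxt == start); break; }
      off += succ_p[cur];
      cur = nxt;
    }
    int len = 0;
    for (auto& co : chain) len = std::max(len, co.second + (int)os[co.first].size());
    std::vector<int> cnt(4 * (size_t)len, 0);
    for (auto& co : chain) {
      const std::string& S = os[co.first];
      for (int j = 0; j < (int)S.size(); ++j) {
        int b = es_nt2i(S[j]);
        if (b >= 0) ++cnt[4 * (size_t)(co.second + j) + b];
      }
      placed[co.first] = std::make_pair(cidx, co.second);
      m_read.push_back(rd(co.first) + 1);
      m_contig.push_back(cidx + 1);
      m_off.push_back(co.second);
      m_strand.push_back((co.first & 1) ? -1 : 1);
    }
    std::string cons(len, 'A');
    for (int j = 0; j < len; ++j) {
      int bi = 0, bc = cnt[4 * (size_t)j];
      for (int b = 1; b < 4; ++b)
        if (cnt[4 * (size_t)j + b] > bc) { bc = cnt[4 * (size_t)j + b]; bi = b; }
      cons[j] = "ACGT"[bi];
    }
    contigs.emplace_back(cons);
    circ.push_back(circular ? 1 : 0);
  };

  for (int o = 0; o < 2 * n; ++o) {
    if (contained[rd(o)] || visited[rd(o)]) continue;
    if (pred_of[o] >= 0) continue; // has an in-edge: not a chain start
    walk(o);
  }
  for (int i = 0; i < n; ++i) // leftover cycles
    if (!contained[i] && !visited[i]) walk(2 * i);

  // resolve contained reads onto their hosts' contigs
  bool changed = true;
  int guard = 0;
  while (changed && guard++ <= n) {
    changed = false;
    for (int i = 0; i < n; ++i) {
      if (!contained[i] || placed.count(2 * i) || placed.count(2 * i + 1)) continue;
      const Containment& cb = cont[i];
      if (cb.host < 0) continue;
      int Lh = os[cb.host].size(), Li = os[2 * i].size();
      int o_i = -1, off = 0;
      auto it = placed.find(cb.host);
      if (it != placed.end()) {
        o_i = 2 * i; off = it->second.second + cb.p;
      } else {
        it = placed.find(cb.host ^ 1);
        if (it != placed.end()) {
          o_i = 2 * i + 1;
          off = it->second.second + (Lh - cb.p - Li);
        }
      }
      if (o_i >= 0) {
        placed[o_i] = std::make_pair(it->second.first, off);
        m_read.push_back(i + 1);
        m_contig.push_back(it->second.first + 1);
        m_off.push_back(off);
        m_strand.push_back((o_i & 1) ? -1 : 1);
        changed = true;
      }
    }
  }

  return List::create(
      _["seqs"] = wrap(contigs),
      _["circular"] = wrap(circ),
      _["members"] = DataFrame::create(_["read"] = wrap(m_read),
                                       _["contig"] = wrap(m_contig),
                                       _["offset"] = wrap(m_off),
                                       _["strand"] = wrap(m_strand)));
}

// Exhaustive qualifying suffix-prefix overlap edges (for small inputs and the
// assembler's discoverable-overlap contract): every (a, b, orientation, offset)
// with overlap >= min_ovl at identity >= min_id where b's leading k-mer is
// intact. Intended for fixtures; quadratic in read count.
// [[Rcpp::export]]
DataFrame cpp_enumerate_overlaps(CharacterVector seqs, double min_id, int min_ovl,
                                 int kmer) {
  const int n = seqs.size();
  std::vector<std::string> os(2 * n);
  for (int i = 0; i < n; ++i) {
    os[2 * i] = as<std::string>(seqs[i]);
    os[2 * i + 1] = es_revcomp(os[2 * i]);
  }
  std::vector<int> a_, as_, b_, bs_, p_, ov_, mm_;
  for (int o = 0; o < 2 * n; ++o) {
    const std::string& S = os[o];
    int L = S.size();
    for (int c2 = 0; c2 < 2 * n; ++c2) {
      if ((c2 >> 1) == (o >> 1)) continue;
      const std::string& Sc = os[c2];
      int Lc = Sc.size();
      for (int p = 1; p <= L - min_ovl; ++p) {
        int ov = L - p;
        if (Lc <= ov) continue; // containment, not an extension edge
        int allowed = (int)std::floor((1.0 - min_id) * ov);
        int mm = 0;
        for (int j = 0; j < ov && mm <= allowed; ++j)
          if (S[p + j] != Sc[j]) ++mm;
        if (mm > allowed) continue;
        // discoverability: partner's leading k-mer must match exactly
        if (ov < kmer) continue;
        bool seed_ok = true;
        for (int j = 0; j < kmer; ++j) if (S[p + j] != Sc[j]) { seed_ok = false; break; }
        if (!seed_ok) continue;
        a_.push_back((o >> 1) + 1); as_.push_back((o & 1) ? -1 : 1);
        b_.push_back((c2 >> 1) + 1); bs_.push_back((c2 & 1) ? -1 : 1);
        p_.push_back(p); ov_.push_back(ov); mm_.push_back(mm);
      }
    }
  }
  return DataFrame::create(_["a"] = a_, _["a_strand"] = as_, _["b"] = b_,
                           _["b_strand"] = bs_, _["offset"] = p_,
                           _["overlap"] = ov_, _["mismatches"] = mm_);
}
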