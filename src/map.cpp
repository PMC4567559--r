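// Seeded diagonal read mapping onto contigs with Full/Partial classification.
//
// Contig k-mers (default k=15) are indexed; read k-mers vote for
// (contig, diagonal, strand) candidates; each candidate diagonal is verified
// by direct comparison over the read/contig intersection. Built for the
// substitution-dominant regime: alignments live on single diagonals.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

std::string es_revcomp(const std::string& s);
int es_nt2i(char c);

namespace {
struct Cand { int contig; int diag; int strand; };
}

// `self`: optional 1-based contig index to ignore for each read (used when
// mapping contigs against each other for containment removal); 0 = none.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector contigs,
                        int kmer, double min_id, int min_len, int seed_step,
                        IntegerVector self = IntegerVector::create()) {
  const int nc = contigs.size(), nr = reads.size();
  std::vector<std::string> cs(nc);
  for (int i = 0; i < nc; ++i) cs[i] = as<std::string>(contigs[i]);

  // contig k-mer index: key -> packed (contig, pos)
  std::unordered_map<uint64_t, std::vector<uint64_t> > idx;
  const uint64_t mask = (1ULL << (2 * kmer)) - 1;
  for (int ci = 0; ci < nc; ++ci) {
    const std::string& S = cs[ci];
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < (int)S.size(); ++i) {
      int c = es_nt2i(S[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= kmer)
        idx[key].emplace_back(((uint64_t)ci << 32) | (uint32_t)(i - kmer + 1));
    }
  }

  IntegerVector o_read(nr), o_contig(nr), o_start(nr), o_end(nr), o_strand(nr),
      o_qs(nr), o_qe(nr);
  CharacterVector o_class(nr);
  NumericVector o_ident(nr);

  std::vector<std::pair<uint64_t, int> > votes; // (contig<<32|diag+off, strand)
  for (int ri = 0; ri < nr; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    std::string rev = es_revcomp(fwd);
    const int L = fwd.size();
    double best_score = -1;
    int b_contig = -1, b_start = 0, b_end = 0, b_strand = 0, b_alen = 0,
        b_rs = 0;
    double b_ident = 0;
    std::string b_class = "Unmapped";
    if (L >= kmer && nc > 0) {
      votes.clear();
      std::vector<int> poss;
      for (int p = 0; p + kmer <= L; p += seed_step) poss.push_back(p);
      if (!poss.empty() && poss.back() != L - kmer) poss.push_back(L - kmer);
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& S = strand ? rev : fwd;
        for (int p : poss) {
          bool ok = true; uint64_t key = 0;
          for (int j = 0; j < kmer; ++j) {
            int c = es_nt2i(S[p + j]);
            if (c < 0) { ok = false; break; }
            key = (key << 2) | (uint64_t)c;
          }
          if (!ok) continue;
          auto it = idx.find(key);
          if (it == idx.end() || it->second.size() > 256) continue;
          for (uint64_t pk : it->second) {
            int ci = (int)(pk >> 32);
            int cpos = (int)(pk & 0xffffffffu);
            int diag = cpos - p; // contig position of read base 0 (may be <0)
            votes.emplace_back(((uint64_t)ci << 34) | (uint64_t)(uint32_t)(diag + (1 << 20)), strand);
          }
        }
      }
      std::sort(votes.begin(), votes.end());
      votes.erase(std::unique(votes.begin(), votes.end()), votes.end());
      for (auto& v : votes) {
        int ci = (int)(v.first >> 34);
        if (self.size() == nr && self[ri] == ci + 1) continue;
        int diag = (int)(uint32_t)(v.first & 0x3ffffffffULL) - (1 << 20);
        int strand = v.second;
        const std::string& S = strand ? rev : fwd;
        const std::string& C = cs[ci];
        int rs = std::max(0, -diag);              // first read base aligned
        int re = std::min(L, (int)C.size() - diag); // one past last read base
        int alen = re - rs;
        if (alen < std::min(min_len, L)) continue;
        int mm = 0;
        const char* a = S.data() + rs;
        const char* b = C.data() + diag + rs;
        for (int j = 0; j < alen; ++j) if (a[j] != b[j]) ++mm;
        double ident = 1.0 - (double)mm / alen;
        if (ident < min_id) {
          // locally diverged read: best qualifying sub-segment on the diagonal
          // (Kadane with a mismatch penalty matched to the identity threshold)
          double pen = min_id / std::max(1e-9, 1.0 - min_id);
          double run = 0; int run_s = 0, seg_s = -1, seg_e = -1; double best_run = 0;
          for (int j = 0; j < alen; ++j) {
            double v = (a[j] == b[j]) ? 1.0 : -pen;
            if (run <= 0) { run = v; run_s = j; } else run += v;
            if (run > best_run) { best_run = run; seg_s = run_s; seg_e = j + 1; }
          }
          if (seg_s < 0) continue;
          int slen = seg_e - seg_s, smm = 0;
          for (int j = seg_s; j < seg_e; ++j) if (a[j] != b[j]) ++smm;
          double sident = 1.0 - (double)smm / slen;
          if (slen < min_len || slen == L || sident < min_id) continue;
          rs += seg_s; alen = slen; ident = sident; // re-scope to the segment
        }
        double score = alen * ident;
        int start = diag + rs;
        bool better = score > best_score + 1e-9;
        if (!better && std::abs(score - best_score) <= 1e-9) {
          if (ci < b_contig || (ci == b_contig && start < b_start)) better = true;
        }
        if (better) {
          best_score = score;
          b_contig = ci; b_start = start; b_end = start + alen;
          b_strand = strand ? -1 : 1; b_alen = alen; b_ident = ident;
          b_rs = rs;
          b_class = (alen == L) ? "Full" : "Partial";
        }
      }
      if (b_alen > 0 && b_alen < std::min(min_len, L)) b_class = "Unmapped";
    }
    o_read[ri] = ri + 1;
    o_contig[ri] = b_contig + 1; // 0 = unmapped
    o_start[ri] = b_start; o_end[ri] = b_end;
    o_strand[ri] = b_strand;
    o_ident[ri] = b_ident;
    o_class[ri] = b_class;
    o_qs[ri] = b_rs; o_qe[ri] = b_rs + b_alen; // span on the oriented read
  }
  return DataFrame::create(_["read"] = o_read, _["contig"] = o_contig,
                           _["start"] = o_start, _["end"] = o_end,
                           _["strand"] = o_strand, _["identity"] = o_ident,
                           _["class"] = o_class,
                           _["qstart"] = o_qs, _["qend"] = o_qe,
                           _["stringsAsFactors"] = false);
}
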