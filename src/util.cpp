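// Shared low-level helpers: sequence codecs, quality trimming, anchor blocks.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

char es_comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'N': return 'N';
    default: return 'N';
  }
}

std::string es_revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = es_comp(c);
  return r;
}

int es_nt2i(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = es_revcomp(as<std::string>(seqs[i]));
  return out;
}

// 3' quality trimming: repeatedly drop the final base while its Phred score is
// below trim_q. Qualities are Phred+33 ASCII strings aligned with seqs.
// [[Rcpp::export]]
List cpp_trim3(CharacterVector seqs, CharacterVector quals, int trim_q) {
  int n = seqs.size();
  CharacterVector oseq(n), oqual(n);
  IntegerVector len(n);
  NumericVector meanq(n);
  LogicalVector trimmed(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    size_t L = q.size();
    while (L > 0 && (int)(q[L - 1] - 33) < trim_q) --L;
    trimmed[i] = (L != q.size());
    s.resize(std::min(L, s.size()));
    q.resize(L);
    double tot = 0;
    for (size_t j = 0; j < L; ++j) tot += (int)(q[j] - 33);
    oseq[i] = s; oqual[i] = q;
    len[i] = (int)L;
    meanq[i] = L > 0 ? tot / L : 0.0;
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual, _["len"] = len,
                      _["mean_q"] = meanq, _["trimmed"] = trimmed);
}

// Apply substitution errors at (read index, position, base) triples; indices 1-based.
// [[Rcpp::export]]
CharacterVector cpp_substitute(CharacterVector seqs, IntegerVector idx,
                               IntegerVector pos, CharacterVector base) {
  CharacterVector out = clone(seqs);
  for (int k = 0; k < idx.size(); ++k) {
    std::string s = as<std::string>(out[idx[k] - 1]);
    int p = pos[k] - 1;
    if (p >= 0 && p < (int)s.size()) {
      char b = as<std::string>(base[k])[0];
      // shift to the next base cyclically if the draw equals the original
      if (s[p] == b) {
        const char* nts = "ACGT";
        int j = es_nt2i(b);
        b = nts[(j + 1) % 4];
      }
      s[p] = b;
      out[idx[k] - 1] = s;
    }
  }
  return out;
}

// Best suffix(s1)/prefix(s2) overlap with length in [min_len, max_len] and
// identity >= min_id. Returns c(len, mismatches) or c(0, 0).
// [[Rcpp::export]]
IntegerVector cpp_best_end_overlap(std::string s1, std::string s2,
                                   int min_len, int max_len, double min_id) {
  int L1 = s1.size(), L2 = s2.size();
  int hi = std::min({max_len, L1, L2});
  int best_len = 0, best_mm = 0;
  double best_score = -1;
  for (int o = min_len; o <= hi; ++o) {
    int mm = 0, allowed = (int)std::floor((1.0 - min_id) * o);
    const char* a = s1.data() + (L1 - o);
    const char* b = s2.data();
    for (int j = 0; j < o && mm <= allowed; ++j) if (a[j] != b[j]) ++mm;
    if (mm <= allowed) {
      double sc = o * (1.0 - (double)mm / o);
      if (sc > best_score) { best_score = sc; best_len = o; best_mm = mm; }
    }
  }
  return IntegerVector::create(best_len, best_mm);
}

// Maximal near-identity diagonal blocks between each query and a subject,
// anchored on shared k-mers and extended with an X-drop (match +1 /
// mismatch -2). Built for the substitution-only regime: alignments live on
// single diagonals. The subject is indexed once for all queries.
// Returns a data.frame of 0-based half-open spans plus match counts.
// [[Rcpp::export]]
DataFrame cpp_anchor_blocks(CharacterVector qs, std::string s, int k,
                            int min_len, int xdrop) {
  std::vector<int> qi_, qs_, qe_, ss_, se_, mt_;
  int Ls = s.size();
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  // index subject k-mers
  std::unordered_map<uint64_t, std::vector<int> > idx;
  {
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < Ls; ++i) {
      int c = es_nt2i(s[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) idx[key].emplace_back(i - k + 1);
    }
  }
  for (int qn = 0; qn < qs.size(); ++qn) {
    std::string q = as<std::string>(qs[qn]);
    int Lq = q.size();
    if (Lq < k || Ls < k) continue;
    // collect seeds per diagonal (diag = qpos - spos)
    std::unordered_map<int64_t, std::vector<int> > diag_seeds;
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < Lq; ++i) {
      int c = es_nt2i(q[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (run + 1 >= k) {
        auto it = idx.find(key);
        if (it != idx.end() && it->second.size() <= 64) {
          int qpos = i - k + 1;
          for (int sp : it->second) diag_seeds[(int64_t)qpos - sp].emplace_back(qpos);
        }
      }
      ++run;
    }
    std::vector<int64_t> diags;
    diags.reserve(diag_seeds.size());
    for (auto& kv : diag_seeds) diags.emplace_back(kv.first);
    std::sort(diags.begin(), diags.end());
    for (int64_t d : diags) {
      std::vector<int>& seeds = diag_seeds[d];
      std::sort(seeds.begin(), seeds.end());
      int covered_to = -1;
      for (int qpos : seeds) {
        if (qpos < covered_to) continue;
        int qi = qpos + k, si = qpos - (int)d + k;
        int score = 0, best = 0, bq = qi;
        while (qi < Lq && si < Ls) {
          score += (q[qi] == s[si]) ? 1 : -2;
          if (score > best) { best = score; bq = qi + 1; }
          if (score < best - xdrop) break;
          ++qi; ++si;
        }
        int right_end = bq;
        qi = qpos - 1; si = qpos - (int)d - 1;
        score = 0; best = 0; int lq = qpos;
        while (qi >= 0 && si >= 0) {
          score += (q[qi] == s[si]) ? 1 : -2;
          if (score > best) { best = score; lq = qi; }
          if (score < best - xdrop) break;
          --qi; --si;
        }
        int left_start = lq;
        int len = right_end - left_start;
        covered_to = right_end;
        if (len >= min_len) {
          int m = 0;
          for (int j = left_start; j < right_end; ++j)
            if (q[j] == s[j - (int)d]) ++m;
          qi_.emplace_back(qn + 1);
          qs_.emplace_back(left_start); qe_.emplace_back(right_end);
          ss_.emplace_back(left_start - (int)d); se_.emplace_back(right_end - (int)d);
          mt_.emplace_back(m);
        }
      }
    }
  }
  return DataFrame::create(_["query"] = qi_, _["qstart"] = qs_, _["qend"] = qe_,
                           _["sstart"] = ss_, _["send"] = se_,
                           _["matches"] = mt_);
}
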