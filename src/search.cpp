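// Seed-and-extend local homology search core.
//
// Subject variants (translation frames or strands) are concatenated with
// sentinel separators and word-indexed once. Exact word seeds are extended
// ungapped with an X-drop; promising HSPs are re-scored by a banded
// Smith-Waterman(-Gotoh) with traceback over a window around the HSP, so the
// reported score is the optimal local alignment score of the reported span
// (the band spans the whole window whenever the window is small).
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

namespace {

struct Hit {
  int qvar, svar;
  int qs, qe, ss, se;
  int score, matches, cols, gaps;
};

const int NEG = -1000000;

struct Aligner {
  int open, ext;
  const std::vector<int>* enc_q;
  const std::vector<int>* enc_s;
  const int* mat;
  int A;

  int sc(int a, int b) const {
    if (a < 0 || b < 0) return (a == -2 || b == -2) ? NEG : -3;
    return mat[a * A + b];
  }

  // banded local alignment over q[q0,q1) x s[s0,s1), band around diagonal d0.
  // returns best score and fills span/matches/cols/gaps via out params.
  int align(int q0, int q1, int s0, int s1, int d0, int hw,
            int& bqs, int& bqe, int& bss, int& bse,
            int& matches, int& cols, int& gaps) const {
    const std::vector<int>& Q = *enc_q;
    const std::vector<int>& S = *enc_s;
    int nq = q1 - q0;
    int W = 2 * hw + 1;
    // rows i=0..nq ; band column c corresponds to j = (i + d0 - hw + c)
    std::vector<int> H(W, 0), E(W, NEG), F(W, NEG);
    std::vector<int> Hp(W, 0), Ep(W, NEG), Fp(W, NEG);
    std::vector<uint8_t> tb((size_t)(nq + 1) * W, 0);
    int best = 0, bi = 0, bc = 0;
    for (int i = 1; i <= nq; ++i) {
      std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
      std::fill(H.begin(), H.end(), 0);
      std::fill(E.begin(), E.end(), NEG);
      std::fill(F.begin(), F.end(), NEG);
      int qi = Q[q0 + i - 1];
      int jbase = i + d0 - hw; // j at c=0 (j is 1-based col index into s window)
      for (int c = 0; c < W; ++c) {
        int j = jbase + c;
        if (j < 1 || j > s1 - s0) continue;
        int sj = S[s0 + j - 1];
        uint8_t t = 0;
        // E: gap consuming subject (left move): cell (i, j-1) is band c-1 same row
        int e = NEG;
        if (c >= 1) {
          int fromH = H[c - 1] - (open + ext);
          int fromE = E[c - 1] - ext;
          if (fromE > fromH) { e = fromE; t |= 4; } else e = fromH;
        }
        E[c] = e;
        // F: gap consuming query (up move): cell (i-1, j) is band c+1 prev row
        int f = NEG;
        if (c + 1 < W) {
          int fromH = Hp[c + 1] - (open + ext);
          int fromF = Fp[c + 1] - ext;
          if (fromF > fromH) { f = fromF; t |= 8; } else f = fromH;
        }
        F[c] = f;
        // H: diag is (i-1, j-1): band c prev row
        int d = (qi == -2 || sj == -2) ? NEG : Hp[c] + sc(qi, sj);
        int h = 0; uint8_t src = 0;
        if (d > h) { h = d; src = 1; }
        if (f > h) { h = f; src = 2; }
        if (e > h) { h = e; src = 3; }
        H[c] = h;
        tb[(size_t)i * W + c] = t | src;
        if (h > best) { best = h; bi = i; bc = c; }
      }
    }
    // traceback
    matches = 0; cols = 0; gaps = 0;
    int i = bi, c = bc;
    int jend = bi + d0 - hw + bc;
    bqe = q0 + bi; bse = s0 + jend;
    enum { MH, ME, MF } state = MH;
    while (i > 0) {
      uint8_t t = tb[(size_t)i * W + c];
      if (state == MH) {
        uint8_t src = t & 3;
        if (src == 0) break;
        if (src == 1) {
          int j = i + d0 - hw + c;
          ++cols;
          if (Q[q0 + i - 1] >= 0 && Q[q0 + i - 1] == S[s0 + j - 1]) ++matches;
          --i; // c stays (diag)
        } else if (src == 2) { state = MF; } else { state = ME; }
      } else if (state == ME) {
        ++cols; ++gaps;
        if (!(t & 4)) state = MH;
        --c; // left move within row
      } else {
        ++cols; ++gaps;
        if (!(t & 8)) state = MH;
        --i; ++c; // up move
      }
      if (c < 0 || c >= W) break;
    }
    int jstart = i + d0 - hw + c;
    bqs = q0 + i; bss = s0 + jstart;
    return best;
  }
};

} // namespace

// [[Rcpp::export]]
DataFrame cpp_search_core(CharacterVector qvars, CharacterVector svars,
                          std::string alphabet, IntegerMatrix submat,
                          int w, int gap_open, int gap_ext,
                          int xdrop_ungapped, int trigger_raw, int min_raw,
                          int window_margin, int band_halfwidth,
                          double cell_cap) {
  const int A = alphabet.size();
  int cmap[256];
  std::fill(cmap, cmap + 256, -1);
  for (int i = 0; i < A; ++i) cmap[(unsigned char)alphabet[i]] = i;

  // concatenate subject variants with sentinels
  std::string scat;
  std::vector<int> seg_of;     // position -> segment
  std::vector<int> seg_start(svars.size()), seg_end(svars.size());
  for (int si = 0; si < svars.size(); ++si) {
    std::string s = as<std::string>(svars[si]);
    seg_start[si] = scat.size();
    scat += s;
    seg_end[si] = scat.size();
    seg_of.resize(scat.size(), si);
    scat.push_back('\x01');
    seg_of.push_back(-1);
  }
  std::vector<int> enc_s(scat.size());
  for (size_t i = 0; i < scat.size(); ++i)
    enc_s[i] = (scat[i] == '\x01') ? -2 : cmap[(unsigned char)scat[i]];

  std::vector<int> matv(submat.begin(), submat.end());
  // IntegerMatrix is column-major; build row-major copy
  std::vector<int> mat((size_t)A * A);
  for (int i = 0; i < A; ++i)
    for (int j = 0; j < A; ++j) mat[(size_t)i * A + j] = submat(i, j);

  // subject word index
  std::unordered_map<uint64_t, std::vector<int> > idx;
  {
    for (int i = 0; i + w <= (int)enc_s.size(); ++i) {
      uint64_t key = 0; bool ok = true;
      for (int j = 0; j < w; ++j) {
        if (enc_s[i + j] < 0) { ok = false; break; }
        key = key * (uint64_t)A + (uint64_t)enc_s[i + j];
      }
      if (ok) idx[key].emplace_back(i);
    }
  }

  std::vector<Hit> hits;
  Aligner al;
  al.open = gap_open; al.ext = gap_ext; al.mat = mat.data(); al.A = A;
  al.enc_s = &enc_s;

  for (int qi = 0; qi < qvars.size(); ++qi) {
    std::string q = as<std::string>(qvars[qi]);
    const int Lq = q.size();
    std::vector<int> enc_q(Lq);
    for (int i = 0; i < Lq; ++i) enc_q[i] = cmap[(unsigned char)q[i]];
    al.enc_q = &enc_q;
    std::unordered_map<int64_t, int> extent; // diag -> q pos already covered
    for (int qp = 0; qp + w <= Lq; ++qp) {
      uint64_t key = 0; bool ok = true;
      for (int j = 0; j < w; ++j) {
        if (enc_q[qp + j] < 0) { ok = false; break; }
        key = key * (uint64_t)A + (uint64_t)enc_q[qp + j];
      }
      if (!ok) continue;
      auto it = idx.find(key);
      if (it == idx.end()) continue;
      for (int sp : it->second) {
        int64_t diag = (int64_t)qp - sp;
        auto ex = extent.find(diag);
        if (ex != extent.end() && qp < ex->second) continue;
        // ungapped x-drop extension
        int i1 = qp + w, j1 = sp + w;
        int score = 0;
        for (int j = 0; j < w; ++j) score += al.sc(enc_q[qp + j], enc_s[sp + j]);
        int bests = score, bq1 = i1, bq0 = qp;
        while (i1 < Lq && j1 < (int)enc_s.size()) {
          int s2 = al.sc(enc_q[i1], enc_s[j1]);
          if (s2 <= NEG / 2) break;
          score += s2;
          ++i1; ++j1;
          if (score > bests) { bests = score; bq1 = i1; }
          if (score < bests - xdrop_ungapped) break;
        }
        int i0 = qp - 1, j0 = sp - 1;
        score = bests;
        while (i0 >= 0 && j0 >= 0) {
          int s2 = al.sc(enc_q[i0], enc_s[j0]);
          if (s2 <= NEG / 2) break;
          score += s2;
          if (score > bests) { bests = score; bq0 = i0; }
          if (score < bests - xdrop_ungapped) break;
          --i0; --j0;
        }
        extent[diag] = bq1;
        if (bests < trigger_raw) continue;
        // gapped re-score over a window around the HSP, clipped to the segment
        int sp0 = bq0 - qp + sp; // subject pos of bq0 on this diagonal
        int seg = seg_of[sp];
        int q0 = std::max(0, bq0 - window_margin);
        int q1w = std::min(Lq, bq1 + window_margin);
        int s0 = std::max(seg_start[seg], sp0 - window_margin);
        int s1 = std::min(seg_end[seg], sp0 + (bq1 - bq0) + window_margin);
        int nqw = q1w - q0, nsw = s1 - s0;
        if (nqw <= 0 || nsw <= 0) continue;
        int d0 = (bq0 - q0) - (sp0 - s0); // band centre diagonal in window coords
        int hw = band_halfwidth;
        // widen the band to the full window when affordable
        double full_hw = (cell_cap / std::max(1, nqw) - 1.0) / 2.0;
        int hw_full = (int)std::min((double)(nqw + nsw), full_hw);
        if (hw_full > hw) hw = hw_full;
        Hit h; h.qvar = qi + 1; h.svar = seg + 1;
        int sc = al.align(q0, q1w, s0, s1, d0, hw, h.qs, h.qe, h.ss, h.se,
                          h.matches, h.cols, h.gaps);
        if (sc < min_raw) continue;
        h.score = sc;
        h.ss -= seg_start[seg]; h.se -= seg_start[seg];
        extent[diag] = std::max(extent[diag], h.qe);
        hits.push_back(h);
      }
    }
  }

  int nh = hits.size();
  IntegerVector qv(nh), sv(nh), qs(nh), qe(nh), ss(nh), se(nh),
      sco(nh), mt(nh), co(nh), gp(nh);
  for (int i = 0; i < nh; ++i) {
    qv[i] = hits[i].qvar; sv[i] = hits[i].svar;
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ss[i] = hits[i].ss; se[i] = hits[i].se;
    sco[i] = hits[i].score; mt[i] = hits[i].matches;
    co[i] = hits[i].cols; gp[i] = hits[i].gaps;
  }
  return DataFrame::create(_["qvar"] = qv, _["svar"] = sv, _["qstart"] = qs,
                           _["qend"] = qe, _["sstart"] = ss, _["send"] = se,
                           _["score"] = sco, _["matches"] = mt,
                           _["cols"] = co, _["gaps"] = gp);
}
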