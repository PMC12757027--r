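#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Seed-and-extend local alignment, BLASTn-flavoured: exact word seeds on a
// shared diagonal band, banded affine-gap Smith-Waterman extension per band.
// Coordinates returned 1-based, closed.

static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // never matches, never seeds
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

struct AlnHit {
  int score, qs, qe, ss, se; // 0-based inclusive during DP
};

static const int NEG = -1000000000;

// Banded affine SW over diagonals d = j - i in [dlo, dhi].
// q rows (i), s cols (j). Start coordinates of the best path are tracked so
// hits report full spans without a traceback matrix.
static AlnHit banded_sw(const std::vector<int>& q, const std::vector<int>& s,
                        int dlo, int dhi,
                        int match, int mismatch, int gap_open, int gap_ext) {
  const int m = (int)q.size(), n = (int)s.size();
  dlo = std::max(dlo, -(m - 1));
  dhi = std::min(dhi, n - 1);
  AlnHit best{0, -1, -1, -1, -1};
  if (dlo > dhi || m == 0 || n == 0) return best;
  const int W = dhi - dlo + 1;

  std::vector<int> H(W, 0), E(W, NEG), F(W, NEG);
  std::vector<int> Hqs(W, 0), Hss(W, 0), Eqs(W, 0), Ess(W, 0), Fqs(W, 0), Fss(W, 0);
  std::vector<int> Hp(W), Hpqs(W), Hpss(W), Fp(W), Fpqs(W), Fpss(W);

  for (int k = 0; k < W; ++k) { H[k] = NEG; } // row -1 conceptually unused
  // row-by-row; for row i, cell k holds diagonal d = dlo + k, i.e. j = i + d.
  for (int i = 0; i < m; ++i) {
    Hp.swap(H); Hpqs.swap(Hqs); Hpss.swap(Hss);
    Fp.swap(F); Fpqs.swap(Fqs); Fpss.swap(Fss);
    std::fill(H.begin(), H.end(), NEG);
    std::fill(F.begin(), F.end(), NEG);
    std::fill(E.begin(), E.end(), NEG);
    for (int k = 0; k < W; ++k) {
      const int j = i + dlo + k;
      if (j < 0 || j >= n) { H[k] = NEG; continue; }
      // E: gap in query (consume subject), from (i, j-1) = same row, k-1
      int e = NEG, eqs = 0, ess = 0;
      if (k > 0) {
        if (H[k - 1] > NEG) { e = H[k - 1] + gap_open + gap_ext; eqs = Hqs[k - 1]; ess = Hss[k - 1]; }
        if (E[k - 1] > NEG && E[k - 1] + gap_ext > e) { e = E[k - 1] + gap_ext; eqs = Eqs[k - 1]; ess = Ess[k - 1]; }
      }
      E[k] = e; Eqs[k] = eqs; Ess[k] = ess;
      // F: gap in subject (consume query), from (i-1, j) = prev row, k+1
      int f = NEG, fqs = 0, fss = 0;
      if (i > 0 && k + 1 < W) {
        if (Hp[k + 1] > NEG) { f = Hp[k + 1] + gap_open + gap_ext; fqs = Hpqs[k + 1]; fss = Hpss[k + 1]; }
        if (Fp[k + 1] > NEG && Fp[k + 1] + gap_ext > f) { f = Fp[k + 1] + gap_ext; fqs = Fpqs[k + 1]; fss = Fpss[k + 1]; }
      }
      F[k] = f; Fqs[k] = fqs; Fss[k] = fss;
      // H
      const int sub = (q[i] == s[j] && q[i] < 4) ? match : mismatch;
      int h = sub, hqs = i, hss = j;             // start a fresh alignment here
      if (i > 0 && j > 0 && Hp[k] > NEG && Hp[k] + sub > h) { h = Hp[k] + sub; hqs = Hpqs[k]; hss = Hpss[k]; }
      if (e > h) { h = e; hqs = eqs; hss = ess; }
      if (f > h) { h = f; hqs = fqs; hss = fss; }
      if (h < 0) { H[k] = NEG; continue; }       // local: floor at zero-start
      H[k] = h; Hqs[k] = hqs; Hss[k] = hss;
      if (h > best.score ||
          (h == best.score && (hss < best.ss || (hss == best.ss && j < best.se)))) {
        best.score = h; best.qs = hqs; best.qe = i; best.ss = hss; best.se = j;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string query, std::string subject,
                  int match = 2, int mismatch = -3,
                  int gap_open = -5, int gap_ext = -2) {
  std::vector<int> q = encode(query), s = encode(subject);
  AlnHit h = banded_sw(q, s, -(int)q.size(), (int)s.size(),
                       match, mismatch, gap_open, gap_ext);
  return List::create(_["score"] = h.score,
                      _["qstart"] = h.qs + 1, _["qend"] = h.qe + 1,
                      _["sstart"] = h.ss + 1, _["send"] = h.se + 1);
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string subject,
                          int word_size = 11, int band = 64,
                          int match = 2, int mismatch = -3,
                          int gap_open = -5, int gap_ext = -2,
                          int score_floor = 20, int max_hits = 25) {
  std::vector<int> q = encode(query), s = encode(subject);
  const int m = (int)q.size(), n = (int)s.size();
  std::vector<int> score_v, qs_v, qe_v, ss_v, se_v;
  if (m >= word_size && n >= word_size) {
    // word lists (sort-merge join on 2-bit hashes; words with N skipped)
    auto words = [&](const std::vector<int>& x) {
      std::vector<std::pair<uint64_t, int> > w;
      uint64_t h = 0; int run = 0;
      const uint64_t mask = (word_size >= 32) ? ~0ULL : ((1ULL << (2 * word_size)) - 1);
      for (int i = 0; i < (int)x.size(); ++i) {
        if (x[i] > 3) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)x[i]) & mask;
        if (++run >= word_size) w.push_back(std::make_pair(h, i - word_size + 1));
      }
      std::sort(w.begin(), w.end());
      return w;
    };
    std::vector<std::pair<uint64_t, int> > qw = words(q), sw = words(s);
    // merge-join -> seed diagonals
    std::vector<std::pair<int, int> > seeds; // (diag, qpos)
    size_t a = 0, b = 0;
    while (a < qw.size() && b < sw.size()) {
      if (qw[a].first < sw[b].first) ++a;
      else if (sw[b].first < qw[a].first) ++b;
      else {
        size_t a2 = a, b2 = b;
        while (a2 < qw.size() && qw[a2].first == qw[a].first) ++a2;
        while (b2 < sw.size() && sw[b2].first == sw[b].first) ++b2;
        if ((a2 - a) * (b2 - b) <= 100000) {
          for (size_t ai = a; ai < a2; ++ai)
            for (size_t bi = b; bi < b2; ++bi)
              seeds.push_back(std::make_pair(sw[bi].second - qw[ai].second, qw[ai].second));
        }
        a = a2; b = b2;
      }
    }
    if (!seeds.empty()) {
      std::sort(seeds.begin(), seeds.end());
      // cluster diagonals closer than `band`, extend each cluster
      std::vector<AlnHit> hits;
      size_t i0 = 0;
      for (size_t i1 = 1; i1 <= seeds.size(); ++i1) {
        if (i1 == seeds.size() || seeds[i1].first - seeds[i1 - 1].first > band) {
          int dlo = seeds[i0].first - band, dhi = seeds[i1 - 1].first + band;
          AlnHit h = banded_sw(q, s, dlo, dhi, match, mismatch, gap_open, gap_ext);
          if (h.score >= score_floor) hits.push_back(h);
          i0 = i1;
        }
      }
      // best-first, drop hits overlapping a kept hit on the subject by > 50%
      std::sort(hits.begin(), hits.end(), [](const AlnHit& x, const AlnHit& y) {
        if (x.score != y.score) return x.score > y.score;
        return x.ss < y.ss;
      });
      std::vector<AlnHit> kept;
      for (const AlnHit& h : hits) {
        bool dup = false;
        for (const AlnHit& k : kept) {
          int ov = std::min(h.se, k.se) - std::max(h.ss, k.ss) + 1;
          int len = h.se - h.ss + 1;
          if (ov > 0 && 2 * ov > len) { dup = true; break; }
        }
        if (!dup) kept.push_back(h);
        if ((int)kept.size() >= max_hits) break;
      }
      for (const AlnHit& h : kept) {
        score_v.push_back(h.score);
        qs_v.push_back(h.qs + 1); qe_v.push_back(h.qe + 1);
        ss_v.push_back(h.ss + 1); se_v.push_back(h.se + 1);
      }
    }
  }
  return DataFrame::create(_["score"] = score_v,
                           _["qstart"] = qs_v, _["qend"] = qe_v,
                           _["sstart"] = ss_v, _["send"] = se_v);
}
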