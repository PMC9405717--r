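#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Seeded, banded, gapped local alignment of queries against a reference set.
// The DP carries (score, matches, alignment length) jointly through the three
// Gotoh states so per-hit identity is available without a traceback. A k-mer
// presence index restricts full scoring to references sharing at least one
// exact seed with the query (BLAST-like seeding); seed_k <= 0 disables the
// screen and scores every reference.

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0; case 'C': case 'c': return 1;
    case 'G': case 'g': return 2; case 'T': case 't': return 3;
    default: return 4;
  }
}

struct Cell { double s; int m; int l; };

// [[Rcpp::export]]
List align_batch_cpp(CharacterVector queries, CharacterVector refs,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     int band, int seed_k) {
  const int nq = queries.size(), nr = refs.size();
  std::vector<std::vector<int>> R(nr);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(refs[r]);
    R[r].resize(s.size());
    for (size_t j = 0; j < s.size(); ++j) R[r][j] = enc(s[j]);
  }

  // k-mer -> reference ids (2-bit encoding, k-mers containing N skipped)
  std::unordered_map<uint64_t, std::vector<int>> index;
  if (seed_k > 0) {
    const uint64_t mask = (seed_k >= 32) ? ~0ULL : ((1ULL << (2 * seed_k)) - 1);
    for (int r = 0; r < nr; ++r) {
      uint64_t key = 0; int run = 0;
      for (size_t j = 0; j < R[r].size(); ++j) {
        int b = R[r][j];
        if (b > 3) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run >= seed_k) {
          auto &v = index[key];
          if (v.empty() || v.back() != r) v.push_back(r);
        }
      }
    }
  }

  const double NEG = -1e30;
  const double go = gap_open + gap_extend, ge = gap_extend;
  List out(nq);
  std::vector<int> stamp(nr, -1);
  std::vector<int> cand;

  for (int qi = 0; qi < nq; ++qi) {
    std::string qs = as<std::string>(queries[qi]);
    const int lq = (int)qs.size();
    if (lq == 0) stop("empty query sequence");
    std::vector<int> Q(lq);
    for (int i = 0; i < lq; ++i) Q[i] = enc(qs[i]);

    cand.clear();
    if (seed_k > 0) {
      const uint64_t mask = (seed_k >= 32) ? ~0ULL : ((1ULL << (2 * seed_k)) - 1);
      uint64_t key = 0; int run = 0;
      for (int i = 0; i < lq; ++i) {
        int b = Q[i];
        if (b > 3) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run >= seed_k) {
          auto it = index.find(key);
          if (it != index.end())
            for (int r : it->second)
              if (stamp[r] != qi) { stamp[r] = qi; cand.push_back(r); }
        }
      }
    } else {
      for (int r = 0; r < nr; ++r) cand.push_back(r);
    }

    NumericMatrix res(cand.size(), 4);
    colnames(res) = CharacterVector::create("ref", "score", "matches", "aln_len");
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      const std::vector<int> &Rr = R[cand[ci]];
      const int lr = (int)Rr.size();
      const int diff = lr - lq;
      const int dlo = std::min(0, diff) - band, dhi = std::max(0, diff) + band;
      const int W = dhi - dlo + 1;
      // rows indexed by diagonal offset d = j - i; index = d - dlo
      std::vector<Cell> Hp(W, {0, 0, 0}), Hc(W, {0, 0, 0});
      std::vector<Cell> Ep(W, {NEG, 0, 0}), Ec(W, {NEG, 0, 0});
      Cell best = {0, 0, 0};
      // row i = 0: H = 0 everywhere (local start), E invalid
      for (int i = 1; i <= lq; ++i) {
        Cell F = {NEG, 0, 0};
        for (int idx = 0; idx < W; ++idx) {
          const int j = i + dlo + idx;
          if (j < 1 || j > lr) { Hc[idx] = {0, 0, 0}; Ec[idx] = {NEG, 0, 0};
                                 if (j == 0) F = {NEG, 0, 0}; continue; }
          // E: gap in reference (consume query base), from (i-1, j) = prev idx+1
          Cell e = {NEG, 0, 0};
          if (idx + 1 < W) {
            double fromH = Hp[idx + 1].s - go, fromE = Ep[idx + 1].s - ge;
            if (fromH >= fromE) e = {fromH, Hp[idx + 1].m, Hp[idx + 1].l + 1};
            else e = {fromE, Ep[idx + 1].m, Ep[idx + 1].l + 1};
          }
          // F: gap in query (consume reference base), from (i, j-1) = idx-1
          Cell f = {NEG, 0, 0};
          if (idx - 1 >= 0) {
            double fromH = Hc[idx - 1].s - go, fromF = F.s - ge;
            if (fromH >= fromF) f = {fromH, Hc[idx - 1].m, Hc[idx - 1].l + 1};
            else f = {fromF, F.m, F.l + 1};
          }
          // H: diagonal from (i-1, j-1) = prev same idx
          const bool is_match = (Q[i - 1] == Rr[j - 1]) && Q[i - 1] < 4;
          const double sub = is_match ? match : mismatch;
          Cell d = {Hp[idx].s + sub, Hp[idx].m + (is_match ? 1 : 0),
                    Hp[idx].l + 1};
          Cell h = d;
          if (e.s > h.s) h = e;
          if (f.s > h.s) h = f;
          if (h.s <= 0) h = {0, 0, 0};
          Hc[idx] = h; Ec[idx] = e; F = f;
          if (h.s > best.s) best = h;
        }
        std::swap(Hp, Hc); std::swap(Ep, Ec);
      }
      res(ci, 0) = cand[ci] + 1;
      res(ci, 1) = best.s;
      res(ci, 2) = best.m;
      res(ci, 3) = best.l;
    }
    out[qi] = res;
    if (qi % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
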