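#include <Rcpp.h>
using namespace Rcpp;

// Phred+33 throughout; sequences are plain std::strings over ACGTN.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(std::string(seqs[i]));
  return out;
}

// Sliding-window quality trim of one read: scan full windows left to right,
// truncate at the start of the first window whose mean quality is below the
// threshold (removing the 3' tail). Reads shorter than the window are kept.
static int trim_point(const std::string &qual, int window, double meanq) {
  const int n = (int)qual.size();
  if (n < window) return n;
  double sum = 0.0;
  for (int i = 0; i < window; ++i) sum += qual[i] - 33;
  if (sum < meanq * window) return 0;
  for (int s = 1; s + window <= n; ++s) {
    sum += (qual[s + window - 1] - 33) - (qual[s - 1] - 33);
    if (sum < meanq * window) return s;
  }
  return n;
}

// [[Rcpp::export]]
List trim_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                    CharacterVector seq2, CharacterVector qual2,
                    int window_len, double mean_q, int min_len) {
  const R_xlen_t n = seq1.size();
  CharacterVector s1(n), q1(n), s2(n), q2(n);
  LogicalVector keep(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(seq1[i]), qa = as<std::string>(qual1[i]);
    std::string b = as<std::string>(seq2[i]), qb = as<std::string>(qual2[i]);
    int ta = trim_point(qa, window_len, mean_q);
    int tb = trim_point(qb, window_len, mean_q);
    keep[i] = (ta >= min_len) && (tb >= min_len);
    s1[i] = a.substr(0, ta); q1[i] = qa.substr(0, ta);
    s2[i] = b.substr(0, tb); q2[i] = qb.substr(0, tb);
  }
  return List::create(_["seq1"] = s1, _["qual1"] = q1,
                      _["seq2"] = s2, _["qual2"] = q2, _["keep"] = keep);
}

// Best ungapped overlap merge of read1 with revcomp(read2): the overlap
// maximizing matches minus mismatches wins (largest overlap on ties; the
// penalty term stops long spurious overlaps with ~25% chance matches from
// shadowing the true overlap); accepted iff overlap >= min_overlap and
// mismatch fraction <= max_mm_frac. In the overlap the higher-quality base
// is taken (read1 on quality ties).
// status: 0 merged, 1 no acceptable overlap, 2 merged length below minimum.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mm_frac, int min_merged_len) {
  const R_xlen_t n = seq1.size();
  CharacterVector merged(n);
  IntegerVector status(n), overlap(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(seq1[i]), qa = as<std::string>(qual1[i]);
    std::string b0 = as<std::string>(seq2[i]), qb0 = as<std::string>(qual2[i]);
    std::string b = revcomp(b0);
    std::string qb(qb0.rbegin(), qb0.rend());
    const int la = (int)a.size(), lb = (int)b.size();
    const int omax = std::min(la, lb);
    int best_o = -1, best_m = -1, best_s = 0;
    for (int o = omax; o >= min_overlap; --o) {
      if (o <= best_s) break;  // score <= overlap length: cannot beat best
      // suffix of a (length o) vs prefix of b (length o)
      int m = 0;
      bool abandoned = false;
      const int offa = la - o;
      for (int k = 0; k < o; ++k) {
        if (a[offa + k] == b[k]) ++m;
        // best attainable score from here on
        else if (2 * (m + o - k - 1) - o <= best_s) { abandoned = true; break; }
      }
      if (!abandoned && 2 * m - o > best_s) {
        best_s = 2 * m - o; best_m = m; best_o = o;
      }
    }
    if (best_o < 0 ||
        (double)(best_o - best_m) > max_mm_frac * (double)best_o) {
      merged[i] = NA_STRING; status[i] = 1; overlap[i] = NA_INTEGER;
      continue;
    }
    const int mlen = la + lb - best_o;
    if (mlen < min_merged_len) {
      merged[i] = NA_STRING; status[i] = 2; overlap[i] = best_o;
      continue;
    }
    std::string out = a.substr(0, la - best_o);
    const int offa = la - best_o;
    for (int k = 0; k < best_o; ++k) {
      char ca = a[offa + k], cb = b[k];
      out.push_back((qb[k] > qa[offa + k]) ? cb : ca);
    }
    out += b.substr(best_o);
    merged[i] = out; status[i] = 0; overlap[i] = best_o;
  }
  return List::create(_["merged"] = merged, _["status"] = status,
                      _["overlap"] = overlap);
}

// Per-base substitution errors at a fixed rate (uses R's RNG).
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < rate) {
        char repl = s[j];
        while (repl == s[j]) repl = bases[(int)(unif_rand() * 4) & 3];
        s[j] = repl;
      }
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector random_seqs_cpp(int n, int len) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(n);
  std::string s(len, 'A');
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < len; ++j) s[j] = bases[(int)(unif_rand() * 4) & 3];
    out[i] = s;
  }
  return out;
}
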