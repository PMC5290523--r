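#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Approximate occurrence of a primer in a read.
struct Hit {
  int start;  // 1-based inclusive
  int end;    // 1-based inclusive
  int edits;
};

// Levenshtein distance between pattern and text[s..e] for every suffix start s
// of a window ending at `end0` (0-based inclusive). Returns the chosen start
// (0-based) for the occurrence ending at end0 with distance `dist`:
// minimal distance, ties broken towards the leftmost (longest) match.
static int recover_start(const char* text, int tlen, const char* pat, int m,
                         int end0, int maxk, int dist) {
  int lo = end0 - m - maxk + 1;
  if (lo < 0) lo = 0;
  int wlen = end0 - lo + 1;
  // DP over reversed pattern vs reversed window; row i = chars of reversed
  // window consumed, free start in window (i.e. suffix match in original).
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  int best_len = -1, best_d = dist + 1;
  for (int i = 1; i <= wlen; ++i) {
    cur[0] = i;
    char tc = text[end0 - (i - 1)];
    for (int j = 1; j <= m; ++j) {
      char pc = pat[m - j];
      int d = prev[j - 1] + (tc == pc ? 0 : 1);
      int d2 = prev[j] + 1; if (d2 < d) d = d2;
      int d3 = cur[j - 1] + 1; if (d3 < d) d = d3;
      cur[j] = d;
    }
    // full pattern consumed after i window chars => candidate length i
    if (cur[m] < best_d || (cur[m] == best_d && i > best_len)) {
      best_d = cur[m]; best_len = i;
    }
    std::swap(prev, cur);
  }
  if (best_len < 0) best_len = m;  // should not happen
  return end0 - best_len + 1;
}

// All approximate matches (edit distance <= maxk) of pattern in text,
// Myers bit-parallel scan (pattern length <= 64).
static void myers_hits(const char* text, int tlen, const char* pat, int m,
                       int maxk, std::vector<Hit>& out) {
  uint64_t Peq[256];
  for (int i = 0; i < 256; ++i) Peq[i] = 0;
  for (int i = 0; i < m; ++i) Peq[(unsigned char)pat[i]] |= (1ULL << i);
  uint64_t Pv = ~0ULL, Mv = 0;
  const uint64_t top = 1ULL << (m - 1);
  int score = m;
  for (int j = 0; j < tlen; ++j) {
    uint64_t Eq = Peq[(unsigned char)text[j]];
    uint64_t Xv = Eq | Mv;
    uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
    uint64_t Ph = Mv | ~(Xh | Pv);
    uint64_t Mh = Pv & Xh;
    if (Ph & top) ++score; else if (Mh & top) --score;
    // free start: the row-0 horizontal delta is 0 (search, not global edit)
    Ph <<= 1;
    Mh <<= 1;
    Pv = Mh | ~(Xv | Ph);
    Mv = Ph & Xv;
    if (score <= maxk) {
      int s0 = recover_start(text, tlen, pat, m, j, maxk, score);
      out.push_back(Hit{s0 + 1, j + 1, score});
    }
  }
}

// Substitution-only matches: fixed-length sliding window Hamming scan.
static void hamming_hits(const char* text, int tlen, const char* pat, int m,
                         int maxk, std::vector<Hit>& out) {
  for (int s = 0; s + m <= tlen; ++s) {
    int d = 0;
    for (int i = 0; i < m && d <= maxk; ++i)
      if (text[s + i] != pat[i]) ++d;
    if (d <= maxk) out.push_back(Hit{s + 1, s + m, d});
  }
}

// Reduce a start-sorted candidate list: transitively overlapping spans
// collapse to the best one (lowest edits, then leftmost start, then
// leftmost end).
static std::vector<Hit> reduce_overlaps(std::vector<Hit>& hits) {
  std::vector<Hit> kept;
  if (hits.empty()) return kept;
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.start != b.start) return a.start < b.start;
    if (a.end != b.end) return a.end < b.end;
    return a.edits < b.edits;
  });
  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i;
    int max_end = hits[i].end;
    Hit best = hits[i];
    while (j + 1 < hits.size() && hits[j + 1].start <= max_end) {
      ++j;
      if (hits[j].end > max_end) max_end = hits[j].end;
      if (hits[j].edits < best.edits ||
          (hits[j].edits == best.edits && hits[j].start < best.start) ||
          (hits[j].edits == best.edits && hits[j].start == best.start &&
           hits[j].end < best.end))
        best = hits[j];
    }
    kept.push_back(best);
    i = j + 1;
  }
  return kept;
}

static std::vector<Hit> scan_one(const char* text, int tlen, const char* pat,
                                 int m, int maxk, bool subs_only) {
  std::vector<Hit> raw;
  if (m >= 1 && m <= 64 && tlen >= 1) {
    if (subs_only) hamming_hits(text, tlen, pat, m, maxk, raw);
    else myers_hits(text, tlen, pat, m, maxk, raw);
  }
  return reduce_overlaps(raw);
}

// [[Rcpp::export]]
DataFrame cpp_primer_hits(std::string text, std::string pattern, int max_errors,
                          bool subs_only) {
  if (pattern.size() > 64) stop("primer longer than 64 nt is not supported");
  std::vector<Hit> hits = scan_one(text.c_str(), (int)text.size(),
                                   pattern.c_str(), (int)pattern.size(),
                                   max_errors, subs_only);
  int n = (int)hits.size();
  IntegerVector st(n), en(n), ed(n);
  for (int i = 0; i < n; ++i) {
    st[i] = hits[i].start; en[i] = hits[i].end; ed[i] = hits[i].edits;
  }
  return DataFrame::create(_["start"] = st, _["end"] = en, _["edits"] = ed);
}

// Candidate amplicon excision across a vector of reads.
// For each locus a plus-strand amplicon reads fwd ... rc(rev) and a
// minus-strand amplicon reads rev ... rc(fwd); each start-primer hit is
// paired with the nearest downstream end-primer hit whose resulting span
// length lies in [min_len, max_len]. Competing overlapping candidates are
// admitted by (total primer edits, start) priority so exact amplicon matches
// always beat chance fuzzy hits; a read base is assigned to at most one
// excision.
// [[Rcpp::export]]
DataFrame cpp_extract_candidates(CharacterVector reads,
                                 CharacterVector start_plus,
                                 CharacterVector end_plus,
                                 CharacterVector start_minus,
                                 CharacterVector end_minus,
                                 int max_errors, bool subs_only,
                                 int min_len, int max_len) {
  int n_loci = start_plus.size();
  std::vector<int> o_read, o_locus, o_start, o_end, o_edits;
  std::vector<int> o_strand;  // 1 = plus, -1 = minus

  struct Cand { int locus; int strand; int start; int end; int edits; };

  for (int r = 0; r < reads.size(); ++r) {
    const char* txt = CHAR(STRING_ELT(reads, r));
    int tlen = LENGTH(STRING_ELT(reads, r));
    std::vector<Cand> cands;
    for (int s = 0; s < 2; ++s) {
      CharacterVector& sp = (s == 0) ? start_plus : start_minus;
      CharacterVector& ep = (s == 0) ? end_plus : end_minus;
      for (int l = 0; l < n_loci; ++l) {
        const char* p1 = CHAR(STRING_ELT(sp, l));
        int m1 = LENGTH(STRING_ELT(sp, l));
        std::vector<Hit> sh = scan_one(txt, tlen, p1, m1, max_errors, subs_only);
        if (sh.empty()) continue;
        const char* p2 = CHAR(STRING_ELT(ep, l));
        int m2 = LENGTH(STRING_ELT(ep, l));
        std::vector<Hit> eh = scan_one(txt, tlen, p2, m2, max_errors, subs_only);
        if (eh.empty()) continue;
        for (const Hit& a : sh) {
          // nearest downstream compatible end hit
          const Hit* pick = nullptr;
          for (const Hit& b : eh) {
            if (b.start <= a.end) continue;
            int span = b.end - a.start + 1;
            if (span > max_len) break;  // eh sorted by start; only grows
            if (span < min_len) continue;
            pick = &b;
            break;
          }
          if (pick)
            cands.push_back(Cand{l, s == 0 ? 1 : -1, a.start, pick->end,
                                 a.edits + pick->edits});
        }
      }
    }
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.edits != b.edits) return a.edits < b.edits;
      if (a.start != b.start) return a.start < b.start;
      if (a.end != b.end) return a.end < b.end;
      return a.locus < b.locus;
    });
    std::vector<std::pair<int, int>> taken;
    for (const Cand& c : cands) {
      bool clash = false;
      for (auto& t : taken)
        if (c.start <= t.second && t.first <= c.end) { clash = true; break; }
      if (clash) continue;
      taken.push_back({c.start, c.end});
      o_read.push_back(r + 1);
      o_locus.push_back(c.locus + 1);
      o_strand.push_back(c.strand);
      o_start.push_back(c.start);
      o_end.push_back(c.end);
      o_edits.push_back(c.edits);
    }
  }
  return DataFrame::create(
      _["read_index"] = wrap(o_read), _["locus_index"] = wrap(o_locus),
      _["strand"] = wrap(o_strand), _["start"] = wrap(o_start),
      _["end"] = wrap(o_end), _["edits"] = wrap(o_edits));
}
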