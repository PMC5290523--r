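#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local (Smith-Waterman) alignment of query (rows) against ref
// (cols). A gap of length L scores gap_open + L * gap_extend (both negative).
// Deterministic tie-breaking: the best-scoring end cell with the smallest ref
// column (then smallest query row) wins, and traceback prefers ungapped
// (diagonal) moves over gaps, then deletions over insertions.
struct AlnResult {
  int score;
  std::string cigar;       // M/I/D, I consumes query only, D consumes ref only
  int ref_start, ref_end;  // 1-based inclusive; 0 when empty alignment
  int query_start, query_end;
  int mismatches;
  int indels;              // total gapped bases (I + D)
  char snp_obs;            // 'A'.. base, '-' deleted, '?' uncovered
};

static AlnResult sw_affine(const char* q, int n, const char* r, int m,
                           int match, int mismatch, int gap_open,
                           int gap_extend, int snp_pos /*1-based, 0=skip*/) {
  const int NEG = -1000000000;
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  // traceback: 0 stop, 1 diag, 2 from E (gap consuming ref, 'D'),
  // 3 from F (gap consuming query, 'I'); plus whether gap continues
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 0),
      tbE((n + 1) * (m + 1), 0), tbF((n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int diag = H[(i - 1) * (m + 1) + (j - 1)] +
                 (q[i - 1] == r[j - 1] ? match : mismatch);
      // E: gap consuming ref (deletion relative to query row)
      int openE = H[i * (m + 1) + (j - 1)] + gap_open + gap_extend;
      int extE = E[i * (m + 1) + (j - 1)] + gap_extend;
      if (openE >= extE) { E[idx] = openE; tbE[idx] = 0; }
      else { E[idx] = extE; tbE[idx] = 1; }
      // F: gap consuming query (insertion)
      int openF = H[(i - 1) * (m + 1) + j] + gap_open + gap_extend;
      int extF = F[(i - 1) * (m + 1) + j] + gap_extend;
      if (openF >= extF) { F[idx] = openF; tbF[idx] = 0; }
      else { F[idx] = extF; tbF[idx] = 1; }
      // prefer diagonal, then D (E), then I (F), then stop
      int h = 0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[idx] > h) { h = E[idx]; tb = 2; }
      if (F[idx] > h) { h = F[idx]; tb = 3; }
      if (diag == h && diag > 0) tb = 1;  // ungapped move wins ties
      H[idx] = h; tbH[idx] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
      else if (h == best && h > 0 && (j < bj || (j == bj && i < bi))) {
        bi = i; bj = j;
      }
    }
  }
  AlnResult res;
  res.score = best;
  res.mismatches = 0; res.indels = 0;
  res.snp_obs = '?';
  if (best <= 0) {
    res.cigar = ""; res.ref_start = res.ref_end = 0;
    res.query_start = res.query_end = 0;
    return res;
  }
  // traceback
  std::string ops;
  int i = bi, j = bj, state = 0;  // state 0 = in H
  while (i > 0 && j > 0) {
    int idx = i * (m + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) {
        ops.push_back('M');
        if (q[i - 1] != r[j - 1]) ++res.mismatches;
        --i; --j;
      } else if (tb == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) {
      ops.push_back('D');
      ++res.indels;
      unsigned char cont = tbE[idx];
      --j;
      if (!cont) state = 0;
    } else {
      ops.push_back('I');
      ++res.indels;
      unsigned char cont = tbF[idx];
      --i;
      if (!cont) state = 0;
    }
  }
  res.query_start = i + 1; res.query_end = bi;
  res.ref_start = j + 1; res.ref_end = bj;
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  for (size_t k = 0; k < ops.size();) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    cig += std::to_string(k2 - k);
    cig.push_back(ops[k]);
    k = k2;
  }
  res.cigar = cig;
  // SNP observation: walk columns, find ref position snp_pos
  if (snp_pos > 0) {
    if (snp_pos < res.ref_start || snp_pos > res.ref_end) {
      res.snp_obs = '?';
    } else {
      int rj = res.ref_start - 1;  // 0-based ref cursor
      int qi = res.query_start - 1;
      for (char op : ops) {
        if (op == 'M') {
          if (rj == snp_pos - 1) { res.snp_obs = q[qi]; break; }
          ++rj; ++qi;
        } else if (op == 'D') {
          if (rj == snp_pos - 1) { res.snp_obs = '-'; break; }
          ++rj;
        } else {
          ++qi;
        }
      }
    }
  }
  return res;
}

static List aln_to_list(const AlnResult& a) {
  std::string obs;
  if (a.snp_obs == '-') obs = "DELETED";
  else if (a.snp_obs == '?') obs = "UNCOVERED";
  else obs = std::string(1, a.snp_obs);
  return List::create(
      _["score"] = a.score, _["cigar"] = a.cigar,
      _["ref_start"] = a.ref_start, _["ref_end"] = a.ref_end,
      _["query_start"] = a.query_start, _["query_end"] = a.query_end,
      _["mismatches"] = a.mismatches, _["indels"] = a.indels,
      _["snp_observation"] = obs);
}

// [[Rcpp::export]]
List cpp_align_local(std::string query, std::string ref, int match,
                     int mismatch, int gap_open, int gap_extend, int snp_pos) {
  AlnResult a = sw_affine(query.c_str(), (int)query.size(), ref.c_str(),
                          (int)ref.size(), match, mismatch, gap_open,
                          gap_extend, snp_pos);
  return aln_to_list(a);
}

// Map a batch of subread sequences against the ref-allele and alt-allele
// versions of one locus context; keep the better-scoring alignment
// (ref context wins ties).
// [[Rcpp::export]]
DataFrame cpp_map_batch(CharacterVector queries, std::string ctx_ref,
                        std::string ctx_alt, int snp_pos, int match,
                        int mismatch, int gap_open, int gap_extend) {
  int n = queries.size();
  IntegerVector score(n), ref_start(n), ref_end(n), mism(n), indels(n),
      aligned_ref_len(n);
  CharacterVector cigar(n), obs(n), allele_ctx(n);
  for (int k = 0; k < n; ++k) {
    const char* q = CHAR(STRING_ELT(queries, k));
    int qn = LENGTH(STRING_ELT(queries, k));
    AlnResult ar = sw_affine(q, qn, ctx_ref.c_str(), (int)ctx_ref.size(),
                             match, mismatch, gap_open, gap_extend, snp_pos);
    AlnResult aa = sw_affine(q, qn, ctx_alt.c_str(), (int)ctx_alt.size(),
                             match, mismatch, gap_open, gap_extend, snp_pos);
    const AlnResult& a = (aa.score > ar.score) ? aa : ar;
    allele_ctx[k] = (aa.score > ar.score) ? "alt" : "ref";
    score[k] = a.score;
    cigar[k] = a.cigar;
    ref_start[k] = a.ref_start; ref_end[k] = a.ref_end;
    mism[k] = a.mismatches; indels[k] = a.indels;
    aligned_ref_len[k] = a.ref_end >= a.ref_start && a.ref_start > 0
                             ? a.ref_end - a.ref_start + 1 : 0;
    if (a.snp_obs == '-') obs[k] = "DELETED";
    else if (a.snp_obs == '?') obs[k] = "UNCOVERED";
    else obs[k] = std::string(1, a.snp_obs);
  }
  return DataFrame::create(
      _["score"] = score, _["cigar"] = cigar, _["ref_start"] = ref_start,
      _["ref_end"] = ref_end, _["mismatches"] = mism, _["indels"] = indels,
      _["aligned_ref_len"] = aligned_ref_len, _["snp_observation"] = obs,
      _["chosen_context"] = allele_ctx, _["stringsAsFactors"] = false);
}

// Best local alignment score only (used for the optional cross-locus
// uniqueness screen).
// [[Rcpp::export]]
IntegerVector cpp_score_batch(std::string query, CharacterVector refs,
                              int match, int mismatch, int gap_open,
                              int gap_extend) {
  int n = refs.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    const char* r = CHAR(STRING_ELT(refs, k));
    int rn = LENGTH(STRING_ELT(refs, k));
    AlnResult a = sw_affine(query.c_str(), (int)query.size(), r, rn, match,
                            mismatch, gap_open, gap_extend, 0);
    out[k] = a.score;
  }
  return out;
}
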