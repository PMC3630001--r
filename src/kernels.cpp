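#include <Rcpp.h>
#include <unordered_map>
#include <climits>
using namespace Rcpp;

// N matches nothing, even another N (conservative trimming).
static inline bool base_eq(char a, char b) { return a == b && a != 'N'; }

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char base_comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

// Semi-global edit distance of `pattern` against a prefix of `read`:
// the pattern is consumed entirely, the read suffix is free, alignment is
// anchored at read position 0. Unit costs (mismatch 1, indel 1).
// Returns the minimum distance, the smallest prefix end attaining it, and
// whether the minimum is within max_errors.
//
// The optimal prefix end never exceeds 2*len(pattern): D[m][j] >= j - m and
// D[m][0] = m, so columns beyond 2m cannot hold the minimum.
// [[Rcpp::export]]
List cpp_semiglobal_prefix(std::string pattern, std::string read, int max_errors) {
  const int m = (int)pattern.size();
  const int n = (int)read.size();
  if (m == 0) stop("pattern must be non-empty");
  if (n == 0)
    return List::create(_["errors"] = m, _["read_end"] = 0, _["aligned"] = false);
  const int ncap = std::min(n, 2 * m);
  std::vector<int> prev(ncap + 1), cur(ncap + 1);
  for (int j = 0; j <= ncap; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= ncap; ++j) {
      int d = prev[j - 1] + (base_eq(pattern[i - 1], read[j - 1]) ? 0 : 1);
      if (prev[j] + 1 < d) d = prev[j] + 1;
      if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  int best = prev[0], arg = 0;
  for (int j = 1; j <= ncap; ++j)
    if (prev[j] < best) { best = prev[j]; arg = j; }  // strict < keeps shortest prefix
  return List::create(_["errors"] = best, _["read_end"] = arg,
                      _["aligned"] = best <= max_errors);
}

// Exact shared words of length word_size between the subject (and its reverse
// complement) and the read. Positions are 0-based; for reverse-orientation
// seeds subj_pos refers to the reverse-complemented subject, so read
// coordinates stay stable. Words containing non-ACGT characters are skipped.
// [[Rcpp::export]]
DataFrame cpp_seed_hits(std::string subject, std::string read, int word_size) {
  if (word_size < 4 || word_size > 31) stop("word_size must be in [4, 31]");
  std::vector<int> spos, rpos, orient;
  const int m = (int)subject.size();
  const int n = (int)read.size();
  if (m >= word_size && n >= word_size) {
    std::unordered_map<uint64_t, std::vector<int> > idx;
    const uint64_t mask = (1ULL << (2 * word_size)) - 1;
    uint64_t w = 0; int run = 0;
    for (int j = 0; j < n; ++j) {
      int c = base_code(read[j]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      if (++run >= word_size) idx[w].push_back(j - word_size + 1);
    }
    std::string rc(m, 'N');
    for (int i = 0; i < m; ++i) rc[m - 1 - i] = base_comp(subject[i]);
    for (int o = 0; o < 2; ++o) {
      const std::string &s = o ? rc : subject;
      w = 0; run = 0;
      for (int i = 0; i < m; ++i) {
        int c = base_code(s[i]);
        if (c < 0) { run = 0; w = 0; continue; }
        w = ((w << 2) | (uint64_t)c) & mask;
        if (++run >= word_size) {
          std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(w);
          if (it != idx.end())
            for (size_t k = 0; k < it->second.size(); ++k) {
              spos.push_back(i - word_size + 1);
              rpos.push_back(it->second[k]);
              orient.push_back(o);
            }
        }
      }
    }
  }
  CharacterVector ov(orient.size());
  for (size_t k = 0; k < orient.size(); ++k)
    ov[k] = orient[k] ? "reverse" : "forward";
  return DataFrame::create(_["subj_pos"] = spos, _["read_pos"] = rpos,
                           _["orientation"] = ov, _["stringsAsFactors"] = false);
}

// Banded global Needleman-Wunsch of a vs b with linear gap penalties, followed
// by trimming of terminal gap runs from the traceback. The band of half-width
// `band` is centred between the matrix corners and is widened to the minimum
// needed to connect them, so bases unreachable at the requested band end up in
// terminal gaps (reported as overhangs by the caller).
// Traceback tie-break: diagonal > gap-in-b > gap-in-a (leftmost, shortest).
// [[Rcpp::export]]
List cpp_banded_nw(std::string a, std::string b, int band,
                   int match, int mismatch, int gap) {
  const int m = (int)a.size();
  const int n = (int)b.size();
  const int NEG = INT_MIN / 4;
  if (m == 0 || n == 0)
    return List::create(_["score"] = gap * (m + n), _["aln_len"] = 0,
                        _["matches"] = 0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  const int diff = n - m;
  const int c = diff / 2;
  int B = band;
  int need = std::max(std::abs(c), std::abs(diff - c));
  if (B < need) B = need;
  // Two DP matrices over the same band:
  //  S -- global (terminal gaps penalised on both sequences); its corner
  //       value is the reported alignment score, identical to unbanded
  //       Needleman-Wunsch whenever the band covers the full matrix.
  //  F -- fitting (terminal gaps on the *read* b are free); the hit geometry
  //       is traced on F, because b is an arbitrary read window whose flanks
  //       must not be forced into the alignment: a global path has to spend
  //       terminal gap penalties on them, which can make absorbing
  //       repeat-similar flank bases into the core score-optimal and
  //       depress the core's percent identity.
  const int W = n + 1;
  std::vector<int> S((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  S[0] = 0; F[0] = 0;
  for (int j = 1; j <= n; ++j) {
    if (std::abs(j - c) > B) break;
    S[j] = S[j - 1] + gap;
    F[j] = 0;
  }
  for (int i = 1; i <= m; ++i) {
    if (std::abs(-i - c) <= B) {
      S[(size_t)i * W] = S[(size_t)(i - 1) * W] + gap;
      F[(size_t)i * W] = F[(size_t)(i - 1) * W] + gap;
    }
    int lo = std::max(1, i + c - B), hi = std::min(n, i + c + B);
    for (int j = lo; j <= hi; ++j) {
      const int sub = base_eq(a[i - 1], b[j - 1]) ? match : mismatch;
      int bestS = NEG, bestF = NEG;
      int v = S[(size_t)(i - 1) * W + j - 1];
      if (v > NEG && v + sub > bestS) bestS = v + sub;
      v = S[(size_t)(i - 1) * W + j];
      if (v > NEG && v + gap > bestS) bestS = v + gap;
      v = S[(size_t)i * W + j - 1];
      if (v > NEG && v + gap > bestS) bestS = v + gap;
      if (bestS > NEG) S[(size_t)i * W + j] = bestS;
      v = F[(size_t)(i - 1) * W + j - 1];
      if (v > NEG && v + sub > bestF) bestF = v + sub;
      v = F[(size_t)(i - 1) * W + j];
      if (v > NEG && v + gap > bestF) bestF = v + gap;
      v = F[(size_t)i * W + j - 1];
      if (v > NEG && v + gap > bestF) bestF = v + gap;
      if (bestF > NEG) F[(size_t)i * W + j] = bestF;
    }
  }
  const int score = S[(size_t)m * W + n];
  if (score <= NEG)
    stop("internal error: banded DP failed to reach the corner");
  // Alignment end: best fitting score on the last row (free trailing read
  // gap), leftmost on ties (shortest alignment).
  int jend = -1, bestF = NEG;
  for (int j = 0; j <= n; ++j) {
    int v = F[(size_t)m * W + j];
    if (v > bestF) { bestF = v; jend = j; }
  }
  if (jend < 0) stop("internal error: empty fitting row");
  // Traceback on F among equal-scoring paths with a two-phase tie
  // preference: gap moves first until the first diagonal is taken, diagonal
  // first afterwards, so score-neutral gap placements become terminal runs
  // (trimmed into overhangs) rather than core columns. Stops at row 0:
  // leading read bases are free.
  int i = m, j = jend;
  bool in_core = false;
  std::vector<signed char> path;  // 1 diag, 2 up (gap in b), 3 left (gap in a)
  while (i > 0) {
    const int cur = F[(size_t)i * W + j];
    bool diag_ok = false, up_ok = false, left_ok = false;
    if (j > 0) {
      int d = F[(size_t)(i - 1) * W + j - 1];
      diag_ok = d > NEG &&
        d + (base_eq(a[i - 1], b[j - 1]) ? match : mismatch) == cur;
      int l = F[(size_t)i * W + j - 1];
      left_ok = l > NEG && l + gap == cur;
    }
    {
      int u = F[(size_t)(i - 1) * W + j];
      up_ok = u > NEG && u + gap == cur;
    }
    signed char t;
    if (in_core) t = diag_ok ? 1 : (up_ok ? 2 : (left_ok ? 3 : 0));
    else t = left_ok ? 3 : (up_ok ? 2 : (diag_ok ? 1 : 0));
    if (t == 0) stop("internal error: broken traceback");
    if (t == 1) { in_core = true; --i; --j; }
    else if (t == 2) { --i; }
    else { --j; }
    path.push_back(t);
  }
  const int jstart = j;
  std::reverse(path.begin(), path.end());
  int first = -1, last = -1;
  for (size_t k = 0; k < path.size(); ++k)
    if (path[k] == 1) { if (first < 0) first = (int)k; last = (int)k; }
  if (first < 0)
    return List::create(_["score"] = score, _["aln_len"] = 0, _["matches"] = 0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  int ai = 0, bj = jstart, a0 = 0, b0 = 0, a1 = 0, b1 = 0, matches = 0, aln = 0;
  for (size_t k = 0; k < path.size(); ++k) {
    if ((int)k == first) { a0 = ai; b0 = bj; }
    if (path[k] == 1) { if (base_eq(a[ai], b[bj])) ++matches; ++ai; ++bj; }
    else if (path[k] == 2) ++ai;
    else ++bj;
    if ((int)k >= first && (int)k <= last) ++aln;
    if ((int)k == last) { a1 = ai; b1 = bj; }
  }
  return List::create(_["score"] = score, _["aln_len"] = aln, _["matches"] = matches,
                      _["a_start"] = a0, _["a_end"] = a1,
                      _["b_start"] = b0, _["b_end"] = b1);
}
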