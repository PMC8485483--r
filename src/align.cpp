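#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // ambiguity / gap: never seeds, never matches
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// Ungapped seed-and-extend local hits of query against subject, one strand.
// Exact word seeds of size w; X-drop extension with +match/-mismatch scores.
// Coordinates are 0-based half-open on both sequences.
// [[Rcpp::export(name = ".cpp_seed_hits")]]
DataFrame cpp_seed_hits(std::string query, std::string subject, int word_size,
                        int match, int mismatch, int xdrop) {
  const std::vector<int> q = encode(query), s = encode(subject);
  const int lq = (int)q.size(), ls = (int)s.size(), w = word_size;
  std::vector<int> qs_out, qe_out, ss_out, match_out;
  if (lq < w || ls < w) {
    return DataFrame::create(_["query_start"] = qs_out, _["query_end"] = qe_out,
                             _["ref_start"] = ss_out, _["matches"] = match_out);
  }
  // index subject words (2 bits/base); w <= 15 enforced in R
  const uint32_t mask = (w == 16) ? 0xFFFFFFFFu : ((1u << (2 * w)) - 1u);
  std::unordered_map<uint32_t, std::vector<int> > idx;
  idx.reserve(ls);
  {
    uint32_t key = 0; int run = 0;
    for (int j = 0; j < ls; ++j) {
      if (s[j] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)s[j]) & mask;
      if (++run >= w) idx[key].push_back(j - w + 1);
    }
  }
  // per-diagonal high-water mark of query positions already inside a hit
  std::unordered_map<int64_t, int> covered;
  uint32_t key = 0; int run = 0;
  for (int i = 0; i < lq; ++i) {
    if (q[i] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)q[i]) & mask;
    if (++run < w) continue;
    const int qpos = i - w + 1;
    std::unordered_map<uint32_t, std::vector<int> >::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    for (size_t t = 0; t < it->second.size(); ++t) {
      const int spos = it->second[t];
      const int64_t diag = (int64_t)qpos - (int64_t)spos;
      std::unordered_map<int64_t, int>::iterator cv = covered.find(diag);
      if (cv != covered.end() && qpos < cv->second) continue;
      // extend right from the seed
      int score = w * match, best = score;
      int qe = qpos + w, best_qe = qe;
      int mm_right = 0, mm_best_right = 0;
      while (qe < lq && qe - diag < ls) {
        const int a = q[qe], b = s[qe - diag];
        if (a < 0 || b < 0) break;
        if (a == b) score += match; else { score -= mismatch; ++mm_right; }
        ++qe;
        if (score > best) { best = score; best_qe = qe; mm_best_right = mm_right; }
        if (best - score > xdrop) break;
      }
      // extend left
      score = best;
      int qb = qpos, best_qb = qb;
      int mm_left = 0, mm_best_left = 0;
      while (qb > 0 && qb - diag > 0) {
        const int a = q[qb - 1], b = s[qb - 1 - diag];
        if (a < 0 || b < 0) break;
        if (a == b) score += match; else { score -= mismatch; ++mm_left; }
        --qb;
        if (score > best) { best = score; best_qb = qb; mm_best_left = mm_left; }
        if (best - score > xdrop) break;
      }
      const int len = best_qe - best_qb;
      const int nmatch = len - mm_best_right - mm_best_left;
      qs_out.push_back(best_qb);
      qe_out.push_back(best_qe);
      ss_out.push_back((int)(best_qb - diag));
      match_out.push_back(nmatch);
      int& hw = covered[diag];
      if (best_qe > hw) hw = best_qe;
    }
  }
  return DataFrame::create(_["query_start"] = qs_out, _["query_end"] = qe_out,
                           _["ref_start"] = ss_out, _["matches"] = match_out);
}

static void revcomp_inplace(std::string& s) {
  std::reverse(s.begin(), s.end());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
    case 'A': s[i] = 'T'; break; case 'T': s[i] = 'A'; break;
    case 'C': s[i] = 'G'; break; case 'G': s[i] = 'C'; break;
    default: s[i] = 'N';
    }
  }
}

// Best ungapped local hit (matches, length) of one encoded query against an
// indexed subject; shares the seeding/extension logic of cpp_seed_hits but
// only tracks the best-scoring hit.
static void best_hit_one(const std::vector<int>& q, const std::vector<int>& s,
                         const std::vector<std::vector<int> >& idx,
                         const uint32_t mask, int w, int match, int mismatch,
                         int xdrop, int& best_matches, int& best_len) {
  const int lq = (int)q.size(), ls = (int)s.size();
  std::unordered_map<int64_t, int> covered;
  uint32_t key = 0; int run = 0;
  int top_score = -1;
  for (int i = 0; i < lq; ++i) {
    if (q[i] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)q[i]) & mask;
    if (++run < w) continue;
    const int qpos = i - w + 1;
    const std::vector<int>& plist = idx[key];
    for (size_t t = 0; t < plist.size(); ++t) {
      const int spos = plist[t];
      const int64_t diag = (int64_t)qpos - (int64_t)spos;
      std::unordered_map<int64_t, int>::iterator cv = covered.find(diag);
      if (cv != covered.end() && qpos < cv->second) continue;
      int score = w * match, best = score;
      int qe = qpos + w, best_qe = qe, mm_right = 0, mm_best_right = 0;
      while (qe < lq && qe - diag < ls) {
        const int a = q[qe], b = s[qe - diag];
        if (a < 0 || b < 0) break;
        if (a == b) score += match; else { score -= mismatch; ++mm_right; }
        ++qe;
        if (score > best) { best = score; best_qe = qe; mm_best_right = mm_right; }
        if (best - score > xdrop) break;
      }
      score = best;
      int qb = qpos, best_qb = qb, mm_left = 0, mm_best_left = 0;
      while (qb > 0 && qb - diag > 0) {
        const int a = q[qb - 1], b = s[qb - 1 - diag];
        if (a < 0 || b < 0) break;
        if (a == b) score += match; else { score -= mismatch; ++mm_left; }
        --qb;
        if (score > best) { best = score; best_qb = qb; mm_best_left = mm_left; }
        if (best - score > xdrop) break;
      }
      const int len = best_qe - best_qb;
      const int nmatch = len - mm_best_right - mm_best_left;
      if (best > top_score ||
          (best == top_score && nmatch > best_matches)) {
        top_score = best; best_matches = nmatch; best_len = len;
      }
      int& hw = covered[diag];
      if (best_qe > hw) hw = best_qe;
    }
  }
}

// Per-fragment best local hit of consecutive query fragments against one
// subject, indexing the subject only once. Returns matches and length of the
// best hit per fragment (0,0 when the fragment has no seed).
// [[Rcpp::export(name = ".cpp_ani_fragments")]]
DataFrame cpp_ani_fragments(std::string query, std::string subject,
                            int fragment_length, int word_size,
                            int match, int mismatch, int xdrop) {
  const std::vector<int> s = encode(subject);
  const int ls = (int)s.size(), w = word_size;
  const uint32_t mask = (1u << (2 * w)) - 1u;
  std::vector<std::vector<int> > idx((size_t)1 << (2 * w));
  {
    uint32_t key = 0; int run = 0;
    for (int j = 0; j < ls; ++j) {
      if (s[j] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)s[j]) & mask;
      if (++run >= w) idx[key].push_back(j - w + 1);
    }
  }
  const int nfrag = (int)query.size() / fragment_length;
  IntegerVector matches(nfrag), length(nfrag);
  for (int f = 0; f < nfrag; ++f) {
    std::string frag = query.substr((size_t)f * fragment_length,
                                    (size_t)fragment_length);
    int bm = 0, bl = 0;
    best_hit_one(encode(frag), s, idx, mask, w, match, mismatch, xdrop, bm, bl);
    std::string rc = frag;
    revcomp_inplace(rc);
    int bm2 = 0, bl2 = 0;
    best_hit_one(encode(rc), s, idx, mask, w, match, mismatch, xdrop, bm2, bl2);
    if (bm2 > bm || (bm2 == bm && bl2 > bl)) { bm = bm2; bl = bl2; }
    matches[f] = bm; length[f] = bl;
  }
  return DataFrame::create(_["matches"] = matches, _["length"] = length);
}

// Banded global (Needleman-Wunsch) alignment of a vs b maximising
// match=+1 / mismatch=-1 / gap=-1; end gaps are penalised like any gap.
// Returns matches and total alignment columns so identity = matches/columns,
// plus (optionally) a projection of `a` onto `b` coordinates: for every
// position of b, the aligned base of a or '-'; insertions in a are dropped.
static List band_align(const std::string& sa, const std::string& sb,
                       int band, bool want_projection) {
  const std::vector<int> a = encode(sa), b = encode(sb);
  const int la = (int)a.size(), lb = (int)b.size();
  int bd = band;
  const int mind = (la > lb) ? la - lb : lb - la;
  if (bd < mind + 8) bd = mind + 8;
  if (bd > std::max(la, lb)) bd = std::max(la, lb);
  const int width = 2 * bd + 1;
  const int NEG = -1000000000;
  // dp[i][k] where k = j - i + bd, j in [i-bd, i+bd]
  std::vector<int> prev((size_t)width, NEG), cur((size_t)width, NEG);
  std::vector<int8_t> tb((size_t)(la + 1) * width, 0); // 1 diag, 2 up(gap in b), 3 left(gap in a)
  // row 0
  for (int j = 0; j <= std::min(lb, bd); ++j) { prev[(size_t)(j + bd)] = -j; tb[(size_t)(j + bd)] = 3; }
  for (int i = 1; i <= la; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int jlo = std::max(0, i - bd), jhi = std::min(lb, i + bd);
    for (int j = jlo; j <= jhi; ++j) {
      const int k = j - i + bd;
      int bestv = NEG; int8_t dir = 0;
      if (j > 0) { // diagonal
        const int v = prev[(size_t)k] ;
        if (v > NEG) {
          const int sc = v + ((a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ? 1 : -1);
          if (sc > bestv) { bestv = sc; dir = 1; }
        }
      } else if (i <= bd) { // j == 0 column: all gaps in b
        const int sc = -(i);
        if (sc > bestv) { bestv = sc; dir = 2; }
      }
      if (k + 1 < width) { // up: consume a[i-1], gap in b
        const int v = prev[(size_t)(k + 1)];
        if (v > NEG && v - 1 > bestv) { bestv = v - 1; dir = 2; }
      }
      if (k - 1 >= 0 && j > 0) { // left: consume b[j-1], gap in a
        const int v = cur[(size_t)(k - 1)];
        if (v > NEG && v - 1 > bestv) { bestv = v - 1; dir = 3; }
      }
      cur[(size_t)k] = bestv;
      tb[(size_t)i * width + k] = dir;
    }
    std::swap(prev, cur);
  }
  // traceback from (la, lb)
  int i = la, j = lb;
  long matches = 0, columns = 0;
  std::string proj;
  if (want_projection) proj.assign((size_t)lb, '-');
  while (i > 0 || j > 0) {
    const int k = j - i + bd;
    int8_t dir = (k >= 0 && k < width) ? tb[(size_t)i * width + k] : 0;
    if (dir == 0) dir = (i > 0) ? 2 : 3; // degenerate border fallback
    if (dir == 1) {
      if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ++matches;
      if (want_projection) proj[(size_t)(j - 1)] = sa[(size_t)(i - 1)];
      --i; --j;
    } else if (dir == 2) {
      --i; // a base against gap: dropped from projection
    } else {
      --j; // gap in a against b[j-1]: projection stays '-'
    }
    ++columns;
  }
  List out = List::create(_["matches"] = (double)matches,
                          _["columns"] = (double)columns,
                          _["identity"] = columns > 0 ? (double)matches / (double)columns : NA_REAL);
  if (want_projection) out["projection"] = proj;
  return out;
}

// [[Rcpp::export(name = ".cpp_global_identity")]]
List cpp_global_identity(std::string a, std::string b, int band) {
  return band_align(a, b, band, false);
}

// [[Rcpp::export(name = ".cpp_global_projection")]]
List cpp_global_projection(std::string a, std::string b, int band) {
  return band_align(a, b, band, true);
}
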