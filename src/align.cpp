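#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps and a deterministic
// traceback. A gap of length k costs open + k * extend (both negative).
// 'N' scores as a mismatch against everything, including itself.
//
// Traceback conventions (documented package-wide):
//  - best cell: maximal score, ties broken by smallest query index, then
//    smallest subject index (row-major first maximum);
//  - per column: prefer diagonal, then up (gap in subject), then left;
//  - traceback stops at the first cell with score 0;
//  - gap runs are closed as early as possible (prefer re-entering the
//    match state on ties).

struct AlnResult {
  int score = 0;
  int aligned_length = 0;
  int identical = 0;
  int gaps = 0;
  int qstart = 0, qend = 0, sstart = 0, send = 0; // 1-based, 0 = empty
  bool centers_paired = false;   // q center and s center in one diagonal column
  bool center_match = false;     // that column is an identical match
  int q_center_paired_pos = 0;   // subject pos (1-based) paired with q center
  char q_center_paired_char = 0; // subject char paired with q center
};

static inline int subscore(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

static AlnResult sw_core(const std::string &q, const std::string &s,
                         int match, int mismatch, int gap_open, int gap_ext,
                         int q_center, int s_center,
                         std::vector<int> &H, std::vector<int> &E,
                         std::vector<int> &F) {
  const int n = (int)q.size(), m = (int)s.size();
  const size_t sz = (size_t)(n + 1) * (m + 1);
  if (H.size() < sz) { H.resize(sz); E.resize(sz); F.resize(sz); }
  const int NEG = INT_MIN / 4;
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) { H[idx(0, j)] = 0; E[idx(0, j)] = NEG; F[idx(0, j)] = NEG; }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    H[idx(i, 0)] = 0; E[idx(i, 0)] = NEG; F[idx(i, 0)] = NEG;
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[idx(i - 1, j)] + gap_open + gap_ext,
                       E[idx(i - 1, j)] + gap_ext);
      int f = std::max(H[idx(i, j - 1)] + gap_open + gap_ext,
                       F[idx(i, j - 1)] + gap_ext);
      int d = H[idx(i - 1, j - 1)] + subscore(q[i - 1], s[j - 1], match, mismatch);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[idx(i, j)] = e; F[idx(i, j)] = f; H[idx(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  AlnResult r;
  r.score = best;
  if (best == 0) return r;

  // traceback
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E (up), 2 = F (left)
  r.qend = bi; r.send = bj;
  while (true) {
    if (state == 0) {
      int h = H[idx(i, j)];
      if (h == 0) break;
      int d = H[idx(i - 1, j - 1)] + subscore(q[i - 1], s[j - 1], match, mismatch);
      if (i > 0 && j > 0 && h == d) {
        ++r.aligned_length;
        bool id = (q[i - 1] != 'N' && q[i - 1] == s[j - 1]);
        if (id) ++r.identical;
        if (i == q_center) {
          r.q_center_paired_pos = j;
          r.q_center_paired_char = s[j - 1];
          if (j == s_center) { r.centers_paired = true; r.center_match = id; }
        }
        --i; --j;
      } else if (h == E[idx(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++r.aligned_length; ++r.gaps;
      bool from_h = (E[idx(i, j)] == H[idx(i - 1, j)] + gap_open + gap_ext);
      --i;
      if (from_h) state = 0;
    } else {
      ++r.aligned_length; ++r.gaps;
      bool from_h = (F[idx(i, j)] == H[idx(i, j - 1)] + gap_open + gap_ext);
      --j;
      if (from_h) state = 0;
    }
  }
  r.qstart = i + 1; r.sstart = j + 1;
  return r;
}

static List aln_to_list(const AlnResult &r) {
  return List::create(
      _["score"] = r.score, _["alignedLength"] = r.aligned_length,
      _["identical"] = r.identical, _["gaps"] = r.gaps,
      _["qstart"] = r.qstart, _["qend"] = r.qend,
      _["sstart"] = r.sstart, _["send"] = r.send,
      _["centersPaired"] = r.centers_paired, _["centerMatch"] = r.center_match,
      _["qCenterPairedPos"] = r.q_center_paired_pos,
      _["qCenterPairedChar"] = r.q_center_paired_char
                                   ? std::string(1, r.q_center_paired_char)
                                   : std::string(""));
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string q, std::string s, int match, int mismatch,
              int gap_open, int gap_ext, int q_center, int s_center) {
  std::vector<int> H, E, F;
  AlnResult r = sw_core(q, s, match, mismatch, gap_open, gap_ext,
                        q_center, s_center, H, E, F);
  return aln_to_list(r);
}

// Align pairs element-wise (q[i] vs s[i]); returns one row per pair.
// [[Rcpp::export(name = ".sw_align_pairs")]]
DataFrame sw_align_pairs(CharacterVector qs, CharacterVector ss,
                         int match, int mismatch, int gap_open, int gap_ext,
                         IntegerVector q_centers, IntegerVector s_centers) {
  int n = qs.size();
  if (ss.size() != n) stop("query and subject vectors differ in length");
  IntegerVector score(n), alen(n), ident(n), gaps(n), ppos(n);
  LogicalVector paired(n), cmatch(n);
  CharacterVector pchar(n);
  std::vector<int> H, E, F;
  for (int k = 0; k < n; ++k) {
    AlnResult r = sw_core(as<std::string>(qs[k]), as<std::string>(ss[k]),
                          match, mismatch, gap_open, gap_ext,
                          q_centers[k], s_centers[k], H, E, F);
    score[k] = r.score; alen[k] = r.aligned_length; ident[k] = r.identical;
    gaps[k] = r.gaps; paired[k] = r.centers_paired; cmatch[k] = r.center_match;
    ppos[k] = r.q_center_paired_pos;
    pchar[k] = r.q_center_paired_char ? std::string(1, r.q_center_paired_char)
                                      : std::string("");
  }
  return DataFrame::create(
      _["score"] = score, _["alignedLength"] = alen, _["identical"] = ident,
      _["gaps"] = gaps, _["centersPaired"] = paired, _["centerMatch"] = cmatch,
      _["qCenterPairedPos"] = ppos, _["qCenterPairedChar"] = pchar,
      _["stringsAsFactors"] = false);
}

// All-vs-all screen: returns the pairs passing the conservation criterion:
// identical >= min_identical and the two centers paired in one column.
// require_center_match additionally demands that column be an identical
// match, and a non-empty require_base pins the query center base (editing
// screens: both on, base "A"; SNP controls: both off).
// [[Rcpp::export(name = ".sw_screen_all")]]
DataFrame sw_screen_all(CharacterVector qs, CharacterVector ss,
                        int match, int mismatch, int gap_open, int gap_ext,
                        IntegerVector q_centers, IntegerVector s_centers,
                        int min_identical, bool require_center_match,
                        std::string require_base) {
  std::vector<int> qi_v, si_v, score_v, alen_v, ident_v, gaps_v;
  std::vector<int> H, E, F;
  char req = require_base.empty() ? 0 : require_base[0];
  int nq = qs.size(), ns = ss.size();
  std::vector<std::string> qstr(nq), sstr(ns);
  for (int a = 0; a < nq; ++a) qstr[a] = as<std::string>(qs[a]);
  for (int b = 0; b < ns; ++b) sstr[b] = as<std::string>(ss[b]);
  for (int a = 0; a < nq; ++a) {
    for (int b = 0; b < ns; ++b) {
      AlnResult r = sw_core(qstr[a], sstr[b], match, mismatch, gap_open,
                            gap_ext, q_centers[a], s_centers[b], H, E, F);
      if (r.identical < min_identical || !r.centers_paired)
        continue;
      if (require_center_match && !r.center_match) continue;
      if (req && qstr[a][q_centers[a] - 1] != req) continue;
      qi_v.push_back(a + 1); si_v.push_back(b + 1);
      score_v.push_back(r.score); alen_v.push_back(r.aligned_length);
      ident_v.push_back(r.identical); gaps_v.push_back(r.gaps);
    }
    if (a % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
      _["qIndex"] = wrap(qi_v), _["sIndex"] = wrap(si_v),
      _["score"] = wrap(score_v), _["alignedLength"] = wrap(alen_v),
      _["identical"] = wrap(ident_v), _["gaps"] = wrap(gaps_v),
      _["stringsAsFactors"] = false);
}
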