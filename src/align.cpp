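#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <string>
#include <vector>
#include <climits>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh recurrences.
// A gap of length L costs gap_open + L * gap_extend: the first gap column
// pays both the opening and one extension charge, matching the
// gapOpening/gapExtension convention of classic pairwise aligners so an
// external implementation with identical parameters is directly
// comparable.
//
// The substitution matrix is passed with single-character dimnames; any
// residue not present scores the matrix minimum.  A column counts as a
// match only when the residues are equal and neither is an ambiguity
// placeholder (N for nucleotides, X for amino acids).
//
// Scores are filled with rolling rows; the full traceback is kept as one
// packed byte per cell: bits 0-1 = origin of H (none/diag/up/left),
// bit 2 = E arrived by extension, bit 3 = F arrived by extension.

enum TB : unsigned char { TB_NONE = 0, TB_DIAG = 1, TB_UP = 2, TB_LEFT = 3 };
static const unsigned char EXT_E = 4, EXT_F = 8;

// d_lo/d_hi restrict the DP to diagonals j - i in [d_lo, d_hi]
// (0-based); pass d_lo <= -n and d_hi >= m for the unrestricted
// alignment.  When the reported path touches the band boundary the
// result carries band_edge = true so the caller can recompute without
// the band.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string s, IntegerMatrix submat,
                  int gap_open, int gap_extend,
                  int d_lo = NA_INTEGER, int d_hi = NA_INTEGER,
                  std::string ambig = "NX") {
  const int n = (int) q.size(), m = (int) s.size();
  if (d_lo == NA_INTEGER) d_lo = -n;
  if (d_hi == NA_INTEGER) d_hi = m;
  const bool banded = (d_lo > -n) || (d_hi < m);
  if (n == 0 || m == 0) return List::create(_["score"] = 0);

  int lut[256];
  std::fill(lut, lut + 256, -1);
  CharacterVector rn = rownames(submat);
  const int nl = rn.size();
  for (int i = 0; i < nl; i++) {
    std::string ch = as<std::string>(rn[i]);
    if (ch.size() == 1) lut[(unsigned char) ch[0]] = i;
  }
  int smin = submat[0];
  for (int i = 0; i < submat.size(); i++) smin = std::min(smin, submat[i]);
  // flat row-major copy of the matrix with an extra "unknown" row/col
  std::vector<int> flat((nl + 1) * (nl + 1), smin);
  for (int i = 0; i < nl; i++)
    for (int j = 0; j < nl; j++) flat[i * (nl + 1) + j] = submat(i, j);
  std::vector<int> qi(n), si(m);
  for (int i = 0; i < n; i++) {
    int v = lut[(unsigned char) q[i]]; qi[i] = (v < 0 ? nl : v);
  }
  for (int j = 0; j < m; j++) {
    int v = lut[(unsigned char) s[j]]; si[j] = (v < 0 ? nl : v);
  }

  const int gi = gap_open + gap_extend;
  const int ge = gap_extend;
  const int NEG = INT_MIN / 4;

  static thread_local std::vector<int> H0, H1, E1, F1;
  static thread_local std::vector<unsigned char> tb;
  H0.assign(m + 1, 0); H1.assign(m + 1, 0);
  E1.assign(m + 1, NEG); F1.assign(m + 1, NEG);
  if ((size_t) (n + 1) * (m + 1) > tb.size())
    tb.resize((size_t) (n + 1) * (m + 1));
  std::fill(tb.begin(), tb.begin() + (size_t) (n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; i++) {
    const int *srow = &flat[qi[i - 1] * (nl + 1)];
    unsigned char *trow = &tb[(size_t) i * (m + 1)];
    int j_lo = 1, j_hi = m;
    if (banded) {
      j_lo = std::max(1, i + d_lo);
      j_hi = std::min(m, i + d_hi);
      if (j_lo > j_hi) continue;
      // cells just outside the previous row's band read as empty
      if (i + d_hi <= m) { H0[i + d_hi] = 0; F1[i + d_hi] = NEG; }
      if (j_lo - 1 >= 0) H1[j_lo - 1] = 0;
    }
    int hdiag = H0[j_lo - 1];    // H[i-1][j-1]
    if (!banded) { H1[0] = 0; E1[0] = NEG; }
    int e = NEG;                 // E[i][j] running value
    for (int j = j_lo; j <= j_hi; j++) {
      unsigned char t = 0;
      // E: gap consuming subject, from the left
      int e_open = H1[j - 1] - gi, e_ext = e - ge;
      e = (e_ext > e_open) ? e_ext : e_open;
      if (e_ext > e_open) t |= EXT_E;
      // F: gap consuming query, from above (F1 holds row i-1 values)
      int f_open = H0[j] - gi, f_ext = F1[j] - ge;
      int f = (f_ext > f_open) ? f_ext : f_open;
      if (f_ext > f_open) t |= EXT_F;
      F1[j] = f;
      int diag = hdiag + srow[si[j - 1]];
      hdiag = H0[j];
      int h = diag;
      unsigned char o = TB_DIAG;
      if (f > h) { h = f; o = TB_UP; }
      if (e > h) { h = e; o = TB_LEFT; }
      if (h <= 0) { h = 0; o = TB_NONE; }
      H1[j] = h;
      trow[j] = t | o;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(H0, H1);
  }

  if (best <= 0) return List::create(_["score"] = 0);

  // traceback from (bi, bj); a local path never passes through a zero
  // cell, so TB_NONE terminates it
  int i = bi, j = bj;
  int matches = 0, mismatches = 0, gap_cols = 0, gap_opens = 0, cols = 0;
  bool band_edge = false;
  for (;;) {
    if (banded && (j - i <= d_lo || j - i >= d_hi)) band_edge = true;
    unsigned char cell = tb[(size_t) i * (m + 1) + j];
    unsigned char o = cell & 3;
    if (o == TB_NONE || i == 0 || j == 0) break;
    if (o == TB_DIAG) {
      char a = q[i - 1], b = s[j - 1];
      bool amb = ambig.find(a) != std::string::npos ||
                 ambig.find(b) != std::string::npos;
      if (a == b && !amb) matches++; else mismatches++;
      cols++; i--; j--;
    } else if (o == TB_LEFT) {
      for (;;) {
        unsigned char c2 = tb[(size_t) i * (m + 1) + j];
        cols++; gap_cols++; j--;
        if (!(c2 & EXT_E)) { gap_opens++; break; }
      }
    } else {  // TB_UP
      for (;;) {
        unsigned char c2 = tb[(size_t) i * (m + 1) + j];
        cols++; gap_cols++; i--;
        if (!(c2 & EXT_F)) { gap_opens++; break; }
      }
    }
  }

  return List::create(
    _["score"] = best,
    _["q_start"] = i, _["q_end"] = bi,    // 0-based half-open on query
    _["s_start"] = j, _["s_end"] = bj,    // 0-based half-open on subject
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["gap_columns"] = gap_cols, _["gap_opens"] = gap_opens,
    _["aligned_length"] = cols, _["band_edge"] = band_edge);
}

// Diagonal range (j - i, 0-based) of exact shared k-mers per subject;
// rows are (has_seed, dmin, dmax).
// [[Rcpp::export(name = ".seed_diags_cpp")]]
IntegerMatrix seed_diags_cpp(std::string query, CharacterVector subjects,
                             int k) {
  IntegerMatrix out(subjects.size(), 3);
  if ((int) query.size() < k) return out;
  std::unordered_map<std::string, std::vector<int>> words;
  for (size_t i = 0; i + k <= query.size(); i++)
    words[query.substr(i, k)].push_back((int) i);
  for (int s = 0; s < subjects.size(); s++) {
    std::string sub = as<std::string>(subjects[s]);
    if ((int) sub.size() < k) continue;
    int dmin = INT_MAX, dmax = INT_MIN;
    for (size_t j = 0; j + k <= sub.size(); j++) {
      auto it = words.find(sub.substr(j, k));
      if (it == words.end()) continue;
      for (int qi : it->second) {
        int d = (int) j - qi;
        if (d < dmin) dmin = d;
        if (d > dmax) dmax = d;
      }
    }
    if (dmax >= dmin) { out(s, 0) = 1; out(s, 1) = dmin; out(s, 2) = dmax; }
  }
  return out;
}

// [[Rcpp::export(name = ".seed_mask_cpp")]]
LogicalVector seed_mask_cpp(std::string query, CharacterVector subjects, int k) {
  LogicalVector out(subjects.size(), false);
  if ((int) query.size() < k) return out;
  std::unordered_set<std::string> words;
  for (size_t i = 0; i + k <= query.size(); i++)
    words.insert(query.substr(i, k));
  for (int s = 0; s < subjects.size(); s++) {
    std::string sub = as<std::string>(subjects[s]);
    if ((int) sub.size() < k) continue;
    for (size_t i = 0; i + k <= sub.size(); i++) {
      if (words.count(sub.substr(i, k))) { out[s] = true; break; }
    }
  }
  return out;
}

// Longest exact common substring between two strings, used by the
// self-hybridization screen tests.  Dynamic programme over suffix
// match lengths.
// [[Rcpp::export(name = ".longest_common_substring_cpp")]]
int longest_common_substring_cpp(std::string a, std::string b) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (cur[j] > best) best = cur[j];
    }
    std::swap(prev, cur);
  }
  return best;
}
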