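#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Affine-gap local alignment (Gotoh) restricted to a diagonal band.
// Diagonal d = j - i (0-based ref column minus query row); only cells with
// d in [diag_lo, diag_hi] are computed.  A gap of length L scores
// gap_open + L * gap_extend (gap_open charged once per gap).
//
// Tie-breaking is deterministic: rows then columns are scanned in
// ascending order and only a strictly greater score replaces the current
// optimum, so the end cell with the smallest (query, ref) coordinates
// wins; traceback sources are resolved in the fixed order
// diagonal > gap-in-query > gap-in-read.

static const int NEG_INF = -1073741824; // avoid overflow when adding penalties

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_extend,
                  int diag_lo, int diag_hi) {
  const int m = (int)a.size();
  const int n = (int)b.size();

  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["r_start"] = 0, _["r_end"] = 0,
                        _["n_match"] = 0, _["n_cols"] = 0,
                        _["cigar"] = "");
  }
  if (diag_lo < -m) diag_lo = -m;
  if (diag_hi > n) diag_hi = n;
  if (diag_lo > diag_hi)
    stop("empty diagonal band");

  // dense layout when the band covers the whole matrix (avoids the
  // O(m*(m+n)) storage the diagonal-banded layout would need there)
  const bool dense = (diag_lo <= -m && diag_hi >= n);
  const int W = dense ? (n + 1) : (diag_hi - diag_lo + 1);
  const size_t sz = (size_t)(m + 1) * (size_t)W;

  std::vector<int> H(sz, 0), E(sz, NEG_INF), F(sz, NEG_INF);
  std::vector<uint8_t> TB(sz, 0);

  auto off = [&](int i, int j) -> long {
    return dense ? ((long)i * W + j) : ((long)i * W + (j - i - diag_lo));
  };
  auto in_band = [&](int i, int j) -> bool {
    int d = j - i;
    return d >= diag_lo && d <= diag_hi;
  };

  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    int jlo = i + diag_lo; if (jlo < 1) jlo = 1;
    int jhi = i + diag_hi; if (jhi > n) jhi = n;
    for (int j = jlo; j <= jhi; ++j) {
      long c = off(i, j);
      // E: gap consuming ref base j (gap in query)
      int e_open = NEG_INF, e_ext = NEG_INF;
      if (in_band(i, j - 1)) {
        long cl = off(i, j - 1);
        e_open = H[cl] + gap_open + gap_extend;
        if (E[cl] > NEG_INF / 2) e_ext = E[cl] + gap_extend;
      }
      uint8_t ebit = 0;
      int e = e_open;
      if (e_ext > e) { e = e_ext; ebit = 1; }
      E[c] = e;

      // F: gap consuming query base i (gap in ref)
      int f_open = NEG_INF, f_ext = NEG_INF;
      if (in_band(i - 1, j)) {
        long cu = off(i - 1, j);
        f_open = H[cu] + gap_open + gap_extend;
        if (F[cu] > NEG_INF / 2) f_ext = F[cu] + gap_extend;
      }
      uint8_t fbit = 0;
      int f = f_open;
      if (f_ext > f) { f = f_ext; fbit = 1; }
      F[c] = f;

      // H
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int diag = H[off(i - 1, j - 1)] + s; // same band offset, always stored
      int h = 0; uint8_t hsrc = 0;
      if (diag > h) { h = diag; hsrc = 1; }
      if (e > h) { h = e; hsrc = 2; }
      if (f > h) { h = f; hsrc = 3; }
      H[c] = h;
      TB[c] = hsrc | (ebit << 2) | (fbit << 3);

      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback
  std::string ops; // per-column ops, reversed
  int i = bi, j = bj, n_match = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    if (i == 0 || j == 0) break;
    long c = off(i, j);
    if (state == 0) {
      uint8_t src = TB[c] & 3;
      if (src == 0) break;
      if (src == 1) {
        bool eq = (a[i - 1] == b[j - 1]);
        ops.push_back(eq ? '=' : 'X');
        if (eq) ++n_match;
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      uint8_t ebit = (TB[c] >> 2) & 1;
      ops.push_back('D');
      --j;
      state = ebit ? 1 : 0;
    } else {
      uint8_t fbit = (TB[c] >> 3) & 1;
      ops.push_back('I');
      --i;
      state = fbit ? 2 : 0;
    }
  }

  // run-length encode (ops is reversed)
  std::string cigar;
  int n_cols = (int)ops.size();
  if (n_cols > 0) {
    char cur = ops[n_cols - 1];
    int run = 0;
    for (int k = n_cols - 1; k >= 0; --k) {
      if (ops[k] == cur) ++run;
      else {
        cigar += std::to_string(run); cigar.push_back(cur);
        cur = ops[k]; run = 1;
      }
    }
    cigar += std::to_string(run); cigar.push_back(cur);
  }

  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["r_start"] = j, _["r_end"] = bj,
                      _["n_match"] = n_match, _["n_cols"] = n_cols,
                      _["cigar"] = cigar);
}

// Exact k-mer hits between query and reference, plus-strand only; k-mers
// containing non-ACGT characters are skipped.  Returns a 2-column matrix
// of 0-based (query_pos, ref_pos).

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".kmer_hits_cpp")]]
IntegerMatrix kmer_hits_cpp(std::string query, std::string ref, int k) {
  const int m = (int)query.size(), n = (int)ref.size();
  std::unordered_map<uint64_t, std::vector<int> > index;
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  uint64_t h = 0; int run = 0;
  for (int j = 0; j < n; ++j) {
    int c = base_code(ref[j]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) index[h].push_back(j - k + 1);
  }

  std::vector<int> qpos, rpos;
  h = 0; run = 0;
  for (int i = 0; i < m; ++i) {
    int c = base_code(query[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      auto it = index.find(h);
      if (it != index.end()) {
        for (int p : it->second) {
          qpos.push_back(i - k + 1);
          rpos.push_back(p);
        }
      }
    }
  }

  IntegerMatrix out((int)qpos.size(), 2);
  for (size_t t = 0; t < qpos.size(); ++t) {
    out(t, 0) = qpos[t];
    out(t, 1) = rpos[t];
  }
  return out;
}

// Reverse complement (IUPAC core alphabet, case-preserving for ACGT).

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) {
      switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      case 'a': c = 't'; break; case 'c': c = 'g'; break;
      case 'g': c = 'c'; break; case 't': c = 'a'; break;
      case 'N': case 'n': break;
      default: stop("revcomp: unexpected character '%c'", c);
      }
    }
    out[i] = r;
  }
  return out;
}

// Approximate presence of a short pattern in a text allowing up to
// max_edits edits (substitutions or indels), via the classic
// semi-global DP (any substring of the text may match).

// [[Rcpp::export(name = ".edit_presence_cpp")]]
bool edit_presence_cpp(std::string pattern, std::string text,
                       int max_edits) {
  const int p = (int)pattern.size(), n = (int)text.size();
  if (p == 0) return true;
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= p; ++i) {
    cur[0] = i;
    int rowmin = cur[0];
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
      int del = prev[j] + 1;   // skip pattern base
      int ins = cur[j - 1] + 1; // skip text base
      int v = sub < del ? sub : del;
      if (ins < v) v = ins;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin > max_edits) return false; // cannot recover
    std::swap(prev, cur);
  }
  for (int j = 0; j <= n; ++j)
    if (prev[j] <= max_edits) return true;
  return false;
}

// Substitution-only sliding match of pattern against text (plus strand of
// text as given).  Returns 0-based positions and mismatch counts.

// [[Rcpp::export(name = ".hamming_scan_cpp")]]
IntegerMatrix hamming_scan_cpp(std::string pattern, std::string text,
                               int max_mismatches) {
  const int p = (int)pattern.size(), n = (int)text.size();
  std::vector<int> pos, mm;
  for (int s = 0; s + p <= n; ++s) {
    int d = 0;
    for (int i = 0; i < p; ++i) {
      if (pattern[i] != text[s + i] && ++d > max_mismatches) break;
    }
    if (d <= max_mismatches) { pos.push_back(s); mm.push_back(d); }
  }
  IntegerMatrix out((int)pos.size(), 2);
  for (size_t t = 0; t < pos.size(); ++t) {
    out(t, 0) = pos[t];
    out(t, 1) = mm[t];
  }
  return out;
}
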