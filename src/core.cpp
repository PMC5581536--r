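#include <Rcpp.h>
#include <cctype>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// ---- IUPAC bit masks -------------------------------------------------------
// Bits 1/2/4/8 = A/C/G/T. Bit 16 is a wildcard bit carried only by N on the
// pattern side and by N on the read side, so that a pattern N matches a read
// N, while a read N never satisfies any concrete pattern character.

static int iupac4(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;
    case 'W': return 9;  case 'K': return 12; case 'M': return 3;
    case 'B': return 14; case 'D': return 13; case 'H': return 11;
    case 'V': return 7;  case 'N': return 15;
    default: return -1;
  }
}

// pattern (adapter) side: full IUPAC, N additionally matches read N
static int pat_mask(char c, int pos) {
  int m = iupac4(c);
  if (m < 0)
    stop("invalid IUPAC character '%s' at position %d",
         std::string(1, c).c_str(), pos + 1);
  if (std::toupper(static_cast<unsigned char>(c)) == 'N') m |= 16;
  return m;
}

// read side: A/C/G/T get one bit, N gets only the wildcard bit (so it
// mismatches every concrete pattern character); other IUPAC codes in the
// subject are tolerated with their 4-bit mask.
static int sub_mask(char c, int pos) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'N': return 16;
    default: {
      int m = iupac4(c);
      if (m < 0)
        stop("invalid nucleotide character '%s' at position %d",
             std::string(1, c).c_str(), pos + 1);
      return m;
    }
  }
}

// strict mask for read-vs-read comparison: N matches nothing
static int strict_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': case 'U': return 8;
    default: return 0;
  }
}

static std::vector<int> mask_string_pat(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = pat_mask(s[i], (int)i);
  return v;
}
static std::vector<int> mask_string_sub(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = sub_mask(s[i], (int)i);
  return v;
}

// ---- semi-global alignment (3' adapter orientation) ------------------------
//
// Edit-distance DP over adapter prefixes (rows i) and read prefixes
// (columns j), one column in memory.  Base cases: D(0,j) = 0 (a read prefix
// may be skipped for free), D(i,0) = i.  Candidate end cells are the bottom
// row (full adapter ending at read position j) plus, unless the adapter is
// anchored, the final column (partial adapter occurrence running off the 3'
// read end).  Within a cell, ties are resolved lexicographically:
// minimal edits, then maximal matches, then leftmost alignment start.
// The Ukkonen cutoff skips rows whose cost provably exceeds
// floor(max_error_rate * m); it never changes the result.

struct Cand {
  int alen;     // aligned adapter characters (error-rate denominator)
  int rstart;   // 0-based alignment start in the read
  int rstop;    // 0-based exclusive end in the read
  int errors;
  int matches;
};

static bool cand_better(const Cand& a, const Cand& b) {
  // selection rule: max matches, then min errors, then longest aligned
  // adapter span, then leftmost read start
  if (a.matches != b.matches) return a.matches > b.matches;
  if (a.errors != b.errors) return a.errors < b.errors;
  if (a.alen != b.alen) return a.alen > b.alen;
  return a.rstart < b.rstart;
}

static void collect_back_candidates(const std::string& adapter,
                                    const std::string& read,
                                    bool allow_indels, bool anchored,
                                    bool use_cutoff, double max_error_rate,
                                    std::vector<Cand>& out) {
  const int m = (int)adapter.size(), n = (int)read.size();
  std::vector<int> am = mask_string_pat(adapter);
  std::vector<int> rm = mask_string_sub(read);

  if (!allow_indels) {
    // enumerate every shift; Hamming distance over the overlap
    if (anchored) {
      int alen = std::min(m, n);
      if (alen > 0 && alen == m) {  // full adapter must fit as a suffix
        int s = n - m, err = 0, mat = 0;
        for (int i = 0; i < m; ++i) {
          if (am[i] & rm[s + i]) ++mat; else ++err;
        }
        out.push_back({m, s, n, err, mat});
      }
      return;
    }
    for (int s = 0; s < n; ++s) {
      int alen = std::min(m, n - s);
      int err = 0, mat = 0;
      for (int i = 0; i < alen; ++i) {
        if (am[i] & rm[s + i]) ++mat; else ++err;
      }
      out.push_back({alen, s, s + alen, err, mat});
    }
    return;
  }

  const int INF = m + n + 10;
  const int klim = (int)(max_error_rate * m + 1e-9);
  std::vector<int> D(m + 1), M(m + 1), S(m + 1);
  std::vector<int> nD(m + 1), nM(m + 1), nS(m + 1);
  for (int i = 0; i <= m; ++i) { D[i] = i; M[i] = 0; S[i] = 0; }
  int filled = m;                        // rows valid in previous column
  int last = use_cutoff ? std::min(m, klim) : m;

  if (!anchored && filled == m)          // column 0 bottom-row cell
    out.push_back({m, S[m], 0, D[m], M[m]});

  for (int j = 1; j <= n; ++j) {
    int lim = std::min(last + 1, m);
    nD[0] = 0; nM[0] = 0; nS[0] = j;
    for (int i = 1; i <= lim; ++i) {
      bool match = (am[i - 1] & rm[j - 1]) != 0;
      // diagonal
      int bd = D[i - 1] + (match ? 0 : 1);
      int bm = M[i - 1] + (match ? 1 : 0);
      int bs = S[i - 1];
      // deletion in adapter (consume read char): left neighbour
      if (i <= filled) {
        int d = D[i] + 1;
        if (d < bd || (d == bd && (M[i] > bm || (M[i] == bm && S[i] < bs)))) {
          bd = d; bm = M[i]; bs = S[i];
        }
      }
      // insertion in adapter (consume adapter char): upper neighbour
      {
        int d = nD[i - 1] + 1;
        if (d < bd || (d == bd && (nM[i - 1] > bm ||
                                   (nM[i - 1] == bm && nS[i - 1] < bs)))) {
          bd = d; bm = nM[i - 1]; bs = nS[i - 1];
        }
      }
      nD[i] = bd; nM[i] = bm; nS[i] = bs;
    }
    for (int i = lim + 1; i <= m; ++i) nD[i] = INF;
    std::swap(D, nD); std::swap(M, nM); std::swap(S, nS);
    filled = lim;
    if (use_cutoff) {
      last = lim;
      while (last > 0 && D[last] > klim) --last;
    } else {
      last = m;
    }
    if (filled == m && (!anchored || j == n))
      out.push_back({m, S[m], j, D[m], M[m]});
  }
  if (!anchored) {
    // final column: partial adapter occurrences at the 3' read end
    for (int i = 1; i < m && i <= filled; ++i)
      out.push_back({i, S[i], n, D[i], M[i]});
  }
}

static SEXP cand_to_list(const Cand& c, bool found) {
  if (!found) return R_NilValue;
  return List::create(_["read_start"] = c.rstart, _["read_stop"] = c.rstop,
                      _["adapter_start"] = 0, _["adapter_stop"] = c.alen,
                      _["matches"] = c.matches, _["errors"] = c.errors,
                      _["origin"] = c.rstart);
}

// [[Rcpp::export]]
SEXP cpp_semiglobal_back(std::string adapter, std::string read,
                         double max_error_rate, int min_overlap,
                         bool allow_indels, bool anchored, bool use_cutoff,
                         bool all_candidates = false) {
  std::vector<Cand> cands;
  collect_back_candidates(adapter, read, allow_indels, anchored, use_cutoff,
                          max_error_rate, cands);
  if (all_candidates) {
    // accepted candidate table, for oracle comparisons
    std::vector<Cand> acc;
    for (const Cand& c : cands)
      if (c.alen >= min_overlap &&
          c.errors <= max_error_rate * c.alen + 1e-9)
        acc.push_back(c);
    IntegerMatrix mat((int)acc.size(), 5);
    for (int i = 0; i < (int)acc.size(); ++i) {
      mat(i, 0) = acc[i].rstart; mat(i, 1) = acc[i].rstop;
      mat(i, 2) = acc[i].alen;  mat(i, 3) = acc[i].errors;
      mat(i, 4) = acc[i].matches;
    }
    colnames(mat) = CharacterVector::create("read_start", "read_stop",
                                            "alen", "errors", "matches");
    return List::create(_["candidates"] = mat);
  }
  bool found = false;
  Cand best{0, 0, 0, 0, -1};
  for (const Cand& c : cands) {
    if (c.alen < min_overlap) continue;
    if (c.errors > max_error_rate * c.alen + 1e-9) continue;
    if (!found || cand_better(c, best)) { best = c; found = true; }
  }
  return cand_to_list(best, found);
}

// ---- insert-overlap scan ---------------------------------------------------
//
// Enumerates candidate insert lengths L for a pair (read1, rc(read2)) and
// counts matches/mismatches over the implied overlap without indels.
// L <= min(n1, n2): full overlap of length L (adapters in the overhangs);
// L >= max(n1, n2): partial 3' overlap of length n1 + n2 - L (no overhangs).
// A candidate passes when mismatches <= floor(max_mm_frac * overlap) and the
// binomial random-match probability P(X >= matches), X ~ Bin(overlap, p),
// is <= max_prob.  Results are sorted by decreasing overlap length, then
// more matches, then lower probability.

// [[Rcpp::export]]
NumericMatrix cpp_insert_candidates(std::string r1, std::string r2rc,
                                    int min_overlap, double max_mm_frac,
                                    double max_prob, double p) {
  const int n1 = (int)r1.size(), n2 = (int)r2rc.size();
  std::vector<int> m1(n1), m2(n2);
  for (int i = 0; i < n1; ++i) m1[i] = strict_mask(r1[i]);
  for (int i = 0; i < n2; ++i) m2[i] = strict_mask(r2rc[i]);

  struct ICand { int L, ov, mat, mm; double prob; };
  std::vector<ICand> keep;
  const int Lmax = n1 + n2 - min_overlap;
  for (int L = min_overlap; L <= Lmax; ++L) {
    int ov = std::min(std::min(n1, n2), std::min(L, n1 + n2 - L));
    if (ov < min_overlap) continue;
    int o1 = std::max(0, L - n2);        // start of overlap in read1
    int o2 = std::max(0, n2 - L);        // start of overlap in rc(read2)
    int allowed = (int)(max_mm_frac * ov + 1e-9);
    int mm = 0;
    for (int i = 0; i < ov; ++i) {
      if (!(m1[o1 + i] & m2[o2 + i])) {
        if (++mm > allowed) break;
      }
    }
    if (mm > allowed) continue;
    int mat = ov - mm;
    double prob = R::pbinom((double)(mat - 1), (double)ov, p, 0, 0);
    if (prob > max_prob) continue;
    keep.push_back({L, ov, mat, mm, prob});
  }
  std::sort(keep.begin(), keep.end(), [](const ICand& a, const ICand& b) {
    if (a.ov != b.ov) return a.ov > b.ov;
    if (a.mat != b.mat) return a.mat > b.mat;
    if (a.prob != b.prob) return a.prob < b.prob;
    return a.L < b.L;
  });
  NumericMatrix out((int)keep.size(), 5);
  for (int i = 0; i < (int)keep.size(); ++i) {
    out(i, 0) = keep[i].L;   out(i, 1) = keep[i].ov;
    out(i, 2) = keep[i].mat; out(i, 3) = keep[i].mm;
    out(i, 4) = keep[i].prob;
  }
  colnames(out) = CharacterVector::create("insert_length", "overlap_len",
                                          "matches", "mismatches", "prob");
  return out;
}

// pattern-vs-subject position-wise comparison over min(|a|, |b|) characters
// [[Rcpp::export]]
IntegerVector cpp_hamming_prefix(std::string a, std::string b) {
  int len = std::min(a.size(), b.size());
  int mat = 0;
  for (int i = 0; i < len; ++i)
    if (pat_mask(a[i], i) & sub_mask(b[i], i)) ++mat;
  return IntegerVector::create(_["len"] = len, _["matches"] = mat,
                               _["mismatches"] = len - mat);
}

// ---- reverse complement ----------------------------------------------------

static char comp_char(char c) {
  bool lower = std::islower(static_cast<unsigned char>(c));
  char u = std::toupper(static_cast<unsigned char>(c));
  char r;
  switch (u) {
    case 'A': r = 'T'; break; case 'C': r = 'G'; break;
    case 'G': r = 'C'; break; case 'T': r = 'A'; break; case 'U': r = 'A'; break;
    case 'R': r = 'Y'; break; case 'Y': r = 'R'; break;
    case 'S': r = 'S'; break; case 'W': r = 'W'; break;
    case 'K': r = 'M'; break; case 'M': r = 'K'; break;
    case 'B': r = 'V'; break; case 'V': r = 'B'; break;
    case 'D': r = 'H'; break; case 'H': r = 'D'; break;
    case 'N': r = 'N'; break;
    default: r = 0;
  }
  if (r == 0) return 0;
  return lower ? (char)std::tolower(r) : r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    if (CharacterVector::is_na(x[k])) { out[k] = NA_STRING; continue; }
    std::string s = as<std::string>(x[k]);
    std::string r(s.size(), ' ');
    for (size_t i = 0; i < s.size(); ++i) {
      char c = comp_char(s[s.size() - 1 - i]);
      if (c == 0)
        stop("invalid IUPAC character '%s' at position %d",
             std::string(1, s[s.size() - 1 - i]).c_str(),
             (int)(s.size() - i));
      r[i] = c;
    }
    out[k] = r;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_reverse_str(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    if (CharacterVector::is_na(x[k])) { out[k] = NA_STRING; continue; }
    std::string s = as<std::string>(x[k]);
    std::reverse(s.begin(), s.end());
    out[k] = s;
  }
  return out;
}

// ---- quality trimming ------------------------------------------------------
//
// Partial-sum scan from the 3' end: accumulate (cutoff - q) and cut at the
// position maximising the running sum; ties keep the longer read.  In
// NextSeq mode the quality of G bases is treated as 0 during the scan.

// [[Rcpp::export]]
IntegerVector cpp_quality_trim_index(CharacterVector seqs,
                                     CharacterVector quals, int cutoff,
                                     bool nextseq) {
  R_xlen_t n = seqs.size();
  IntegerVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    std::string s = as<std::string>(seqs[k]);
    std::string q = as<std::string>(quals[k]);
    int len = (int)q.size();
    if ((int)s.size() != len)
      stop("sequence/quality length mismatch in record %d", (int)k + 1);
    long best = 0, run = 0;
    int cut = len;
    for (int i = len - 1; i >= 0; --i) {
      int qv = (int)q[i] - 33;
      if (nextseq &&
          std::toupper(static_cast<unsigned char>(s[i])) == 'G')
        qv = 0;
      run += cutoff - qv;
      if (run > best) { best = run; cut = i; }
    }
    out[k] = cut;  // kept length
  }
  return out;
}
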