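#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Status codes shared with R/extraction.R (keep in sync with .status_levels)
// 0 PASS, 1 NO_FLANK5, 2 NO_FLANK3, 3 LENGTH_FAIL, 4 AMBIGUOUS_BASE

namespace {

struct Candidate {
  bool found = false;
  int mm5 = 0, mm3 = 0;
  int off5 = 0, off3 = 0;  // 0-based start offsets of the flanks
  int len = 0;             // insert length
};

inline int hamming_at(const std::string &read, const std::string &pat,
                      int off, int cutoff) {
  int mm = 0;
  for (size_t k = 0; k < pat.size(); ++k) {
    if (read[off + k] != pat[k] && ++mm > cutoff) return mm;
  }
  return mm;
}

inline bool better(const Candidate &a, const Candidate &b, int n_length) {
  // smaller total mismatches, then insert length closest to design length,
  // then leftmost 5' flank, then leftmost 3' flank
  int ta = a.mm5 + a.mm3, tb = b.mm5 + b.mm3;
  if (ta != tb) return ta < tb;
  int da = std::abs(a.len - n_length), db = std::abs(b.len - n_length);
  if (da != db) return da < db;
  if (a.off5 != b.off5) return a.off5 < b.off5;
  return a.off3 < b.off3;
}

// Scan one strand. level: 0 = flank5 absent, 1 = flank5 only,
// 2 = flank5 then flank3 but no length in window, 3 = PASS.
void scan_strand(const std::string &read, const std::string &f5,
                 const std::string &f3, int n_length, int tol,
                 int max_mm, int &level, Candidate &best) {
  const int L = (int)read.size(), l5 = (int)f5.size(), l3 = (int)f3.size();
  level = 0;
  best = Candidate();
  const int lo = n_length - tol, hi = n_length + tol;
  for (int i = 0; i + l5 <= L; ++i) {
    int mm5 = hamming_at(read, f5, i, max_mm);
    if (mm5 > max_mm) continue;
    if (level < 1) level = 1;
    for (int j = i + l5; j + l3 <= L; ++j) {
      int mm3 = hamming_at(read, f3, j, max_mm);
      if (mm3 > max_mm) continue;
      if (level < 2) level = 2;
      int len = j - (i + l5);
      if (len < lo || len > hi) continue;
      level = 3;
      Candidate c;
      c.found = true; c.mm5 = mm5; c.mm3 = mm3;
      c.off5 = i; c.off3 = j; c.len = len;
      if (!best.found || better(c, best, n_length)) best = c;
    }
  }
}

std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i], r;
    switch (c) {
      case 'A': r = 'T'; break;
      case 'C': r = 'G'; break;
      case 'G': r = 'C'; break;
      case 'T': r = 'A'; break;
      default:  r = 'N'; break;
    }
    out[i] = r;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector bases) {
  CharacterVector out(bases.size());
  for (int i = 0; i < bases.size(); ++i) {
    if (bases[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    out[i] = revcomp(as<std::string>(bases[i]));
  }
  return out;
}

// [[Rcpp::export]]
List scan_reads_cpp(CharacterVector reads, std::string flank5,
                    std::string flank3, int n_length, int tol, int max_mm) {
  const int n = reads.size();
  IntegerVector status(n), mm5(n, NA_INTEGER), mm3(n, NA_INTEGER),
      insert_length(n, NA_INTEGER);
  CharacterVector insert(n, NA_STRING), orientation(n, NA_STRING);
  LogicalVector both_strand(n, false);

  for (int r = 0; r < n; ++r) {
    if (reads[r] == NA_STRING) { status[r] = 1; continue; }
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);

    int lev_f, lev_r;
    Candidate cf, cr;
    scan_strand(fwd, flank5, flank3, n_length, tol, max_mm, lev_f, cf);
    scan_strand(rev, flank5, flank3, n_length, tol, max_mm, lev_r, cr);

    int lev = std::max(lev_f, lev_r);
    if (lev < 3) {
      status[r] = (lev == 0) ? 1 : (lev == 1) ? 2 : 3;
      continue;
    }
    both_strand[r] = (lev_f == 3 && lev_r == 3);
    // forward strand wins whenever it passes
    const Candidate &c = (lev_f == 3) ? cf : cr;
    const std::string &src = (lev_f == 3) ? fwd : rev;
    std::string ins = src.substr(c.off5 + flank5.size(), c.len);
    bool ambiguous = false;
    for (char b : ins) {
      if (b != 'A' && b != 'C' && b != 'G' && b != 'T') { ambiguous = true; break; }
    }
    if (ambiguous) { status[r] = 4; continue; }
    status[r] = 0;
    insert[r] = ins;
    orientation[r] = (lev_f == 3) ? "forward" : "reverse";
    mm5[r] = c.mm5;
    mm3[r] = c.mm3;
    insert_length[r] = c.len;
  }

  return List::create(_["status"] = status, _["insert"] = insert,
                      _["orientation"] = orientation, _["mismatches5"] = mm5,
                      _["mismatches3"] = mm3,
                      _["insert_length"] = insert_length,
                      _["both_strand"] = both_strand);
}
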