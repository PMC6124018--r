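#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

// Canonical k-mer counting over a set of reads. A k-mer and its reverse
// complement are collapsed onto the lexicographically smaller 2-bit encoding.
// Windows containing a non-ACGT base are skipped (the window restarts after
// the offending base). Multiplicities above max_mult are pooled into an
// overflow bin at max_mult, but total_instances keeps the exact sum.
// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector reads, int k, int max_mult) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> tab;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  double total_bases = 0.0;
  double n_short = 0.0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP el = STRING_ELT(reads, r);
    const char* s = CHAR(el);
    const int n = LENGTH(el);
    total_bases += n;
    if (n < k) { n_short += 1.0; continue; }
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      const int b = base2bits(s[i]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | (((uint64_t)(3 - b)) << shift);
      if (++run >= k) tab[fwd < rev ? fwd : rev]++;
    }
  }
  std::unordered_map<uint32_t, double> hist;
  double total_instances = 0.0;
  for (std::unordered_map<uint64_t, uint32_t>::const_iterator it = tab.begin();
       it != tab.end(); ++it) {
    total_instances += (double)it->second;
    uint32_t m = it->second;
    if ((int)m > max_mult) m = (uint32_t)max_mult;
    hist[m] += 1.0;
  }
  std::vector<uint32_t> mult;
  mult.reserve(hist.size());
  for (std::unordered_map<uint32_t, double>::const_iterator it = hist.begin();
       it != hist.end(); ++it)
    mult.push_back(it->first);
  std::sort(mult.begin(), mult.end());
  IntegerVector m_out(mult.size());
  NumericVector c_out(mult.size());
  for (size_t i = 0; i < mult.size(); ++i) {
    m_out[i] = (int)mult[i];
    c_out[i] = hist[mult[i]];
  }
  return List::create(_["multiplicity"] = m_out,
                      _["count"] = c_out,
                      _["total_instances"] = total_instances,
                      _["total_bases"] = total_bases,
                      _["n_too_short"] = n_short);
}

// Apply point substitutions to reads in place (on a copy): read_idx (1-based),
// pos (1-based within the read), newbase single characters.
// [[Rcpp::export]]
CharacterVector mutate_bases_cpp(CharacterVector reads, IntegerVector read_idx,
                                 IntegerVector pos, CharacterVector newbase) {
  std::vector<std::string> out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    out[i] = std::string(CHAR(STRING_ELT(reads, i)));
  for (R_xlen_t i = 0; i < read_idx.size(); ++i) {
    const int r = read_idx[i] - 1;
    const int p = pos[i] - 1;
    if (r < 0 || r >= (int)out.size()) stop("read index out of range");
    if (p < 0 || p >= (int)out[r].size()) stop("position out of range");
    out[r][p] = CHAR(STRING_ELT(newbase, i))[0];
  }
  CharacterVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i];
  return res;
}

// Pileup of read bases over target sites. Reads live on one coordinate system
// (1-based start positions, variable lengths); sites are 1-based positions on
// the same system. Reads must be sorted by start. Returns a sites x 5 count
// matrix with columns A, C, G, T, other.
// [[Rcpp::export]]
IntegerMatrix pileup_alleles_cpp(CharacterVector reads, IntegerVector starts,
                                 IntegerVector sites) {
  const R_xlen_t nr = reads.size();
  if (starts.size() != nr) stop("starts must match reads");
  int max_len = 0;
  for (R_xlen_t i = 0; i < nr; ++i) {
    const int L = LENGTH(STRING_ELT(reads, i));
    if (L > max_len) max_len = L;
  }
  IntegerMatrix counts(sites.size(), 5);
  R_xlen_t lo = 0;
  for (R_xlen_t s = 0; s < sites.size(); ++s) {
    const int q = sites[s];
    while (lo < nr && starts[lo] < q - max_len + 1) ++lo;
    for (R_xlen_t r = lo; r < nr && starts[r] <= q; ++r) {
      SEXP el = STRING_ELT(reads, r);
      const int off = q - starts[r];
      if (off < 0 || off >= LENGTH(el)) continue;
      int col;
      switch (CHAR(el)[off]) {
      case 'A': case 'a': col = 0; break;
      case 'C': case 'c': col = 1; break;
      case 'G': case 'g': col = 2; break;
      case 'T': case 't': col = 3; break;
      default: col = 4;
      }
      counts(s, col)++;
    }
  }
  colnames(counts) = CharacterVector::create("A", "C", "G", "T", "other");
  return counts;
}
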