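#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return '\0';
  }
}

std::string revcomp_one(const std::string& s) {
  const size_t n = s.size();
  std::string out(n, 'N');
  for (size_t i = 0; i < n; ++i) {
    char c = comp_base(s[n - 1 - i]);
    if (c == '\0') Rcpp::stop("invalid DNA alphabet: sequence contains a non-ACGT character");
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_one(as<std::string>(seqs[i]));
  }
  return out;
}

// Sliding-window k-mer counting over a set of reads. Windows containing any
// non-ACGT base are skipped. With canonical = true, a window and its reverse
// complement pool under the lexicographically smaller key.
// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector reads, int k, bool canonical) {
  if (k < 2) stop("k must be >= 2");
  std::unordered_map<std::string, double> tab;
  tab.reserve(1 << 20);
  std::string win, rc;
  win.resize(k); rc.resize(k);
  bool any_window = false;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (CharacterVector::is_na(reads[r])) continue;
    const char* s = CHAR(STRING_ELT(reads, r));
    const int len = (int) LENGTH(STRING_ELT(reads, r));
    if (len < k) continue;
    // run[i] = length of the ACGT-only run ending at i
    int run = 0;
    for (int i = 0; i < len; ++i) {
      run = (comp_base(s[i]) != '\0') ? run + 1 : 0;
      if (run < k) continue;
      any_window = true;
      const char* w = s + i - k + 1;
      if (!canonical) {
        tab[std::string(w, (size_t) k)] += 1.0;
      } else {
        for (int j = 0; j < k; ++j) rc[j] = comp_base(w[k - 1 - j]);
        int cmp = memcmp(w, rc.data(), (size_t) k);
        if (cmp <= 0) tab[std::string(w, (size_t) k)] += 1.0;
        else tab[rc] += 1.0;
      }
    }
  }
  if (!any_window)
    stop("no k-mer windows: k is larger than every read");
  std::vector<const std::pair<const std::string, double>*> ptrs;
  ptrs.reserve(tab.size());
  for (auto& kv : tab) ptrs.push_back(&kv);
  std::sort(ptrs.begin(), ptrs.end(),
            [](const std::pair<const std::string, double>* a,
               const std::pair<const std::string, double>* b) {
              return a->first < b->first;
            });
  const R_xlen_t m = (R_xlen_t) ptrs.size();
  CharacterVector kmers(m);
  NumericVector counts(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    kmers[i] = ptrs[i]->first;
    counts[i] = ptrs[i]->second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// Canonicalize a vector of equal-length words: each word is replaced by the
// lexicographic min of itself and its reverse complement. Returns the words;
// pooling of counts is done on the R side.
// [[Rcpp::export(name = ".canonicalize_cpp")]]
CharacterVector canonicalize_cpp(CharacterVector words) {
  const R_xlen_t n = words.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string w = as<std::string>(words[i]);
    std::string rc = revcomp_one(w);
    out[i] = (w <= rc) ? w : rc;
  }
  return out;
}
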