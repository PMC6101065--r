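#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

std::string revcomp_one(const std::string& s);

// Longest common subsequence length: the optimal gapped-alignment score when
// a match rewards 1 and mismatches/gaps cost nothing.
static int lcs_len(const char* a, int na, const char* b, int nb) {
  if (na == 0 || nb == 0) return 0;
  std::vector<int> prev(nb + 1, 0), cur(nb + 1, 0);
  for (int i = 1; i <= na; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= nb; ++j) {
      if (ai == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export(name = ".lcs_cpp")]]
IntegerVector lcs_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("lengths of a and b must match or be 1");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sa = STRING_ELT(a, a.size() == 1 ? 0 : i);
    SEXP sb = STRING_ELT(b, b.size() == 1 ? 0 : i);
    out[i] = lcs_len(CHAR(sa), LENGTH(sa), CHAR(sb), LENGTH(sb));
  }
  return out;
}

typedef std::unordered_map<std::string, std::vector<int> > SeedMap;

static void index_windows(SeedMap& idx, const std::string& s, int seed_len, int id) {
  if ((int) s.size() < seed_len) return;
  for (int i = 0; i + seed_len <= (int) s.size(); ++i)
    idx[s.substr(i, seed_len)].push_back(id);
}

// Do any length-seed_len windows of the queries (checked in both orientations
// when both_strands) occur in some target word?
// [[Rcpp::export(name = ".shares_seed_cpp")]]
LogicalVector shares_seed_cpp(CharacterVector queries, CharacterVector targets,
                              int seed_len, bool both_strands) {
  std::unordered_set<std::string> idx;
  for (R_xlen_t i = 0; i < targets.size(); ++i) {
    std::string t = as<std::string>(targets[i]);
    if ((int) t.size() < seed_len) continue;
    for (int j = 0; j + seed_len <= (int) t.size(); ++j)
      idx.insert(t.substr(j, seed_len));
    if (both_strands) {
      std::string rc = revcomp_one(t);
      for (int j = 0; j + seed_len <= (int) rc.size(); ++j)
        idx.insert(rc.substr(j, seed_len));
    }
  }
  LogicalVector out(queries.size());
  for (R_xlen_t i = 0; i < queries.size(); ++i) {
    std::string q = as<std::string>(queries[i]);
    bool hit = false;
    for (int j = 0; !hit && j + seed_len <= (int) q.size(); ++j)
      hit = idx.count(q.substr(j, seed_len)) > 0;
    out[i] = hit;
  }
  return out;
}

// Recruitment filter: an intermediate k-mer is recruited when some high k-mer
// sharing a length-seed_len seed with it (either orientation of the query when
// both_strands) attains LCS >= min_score. Alignment is per target k-mer, never
// across a concatenation.
// [[Rcpp::export(name = ".recruit_cpp")]]
LogicalVector recruit_cpp(CharacterVector queries, CharacterVector targets,
                          int seed_len, int min_score, bool both_strands) {
  SeedMap idx;
  for (R_xlen_t i = 0; i < targets.size(); ++i)
    index_windows(idx, as<std::string>(targets[i]), seed_len, (int) i);

  const R_xlen_t nq = queries.size();
  LogicalVector out(nq);
  std::vector<int> stamp(targets.size(), -1);
  for (R_xlen_t i = 0; i < nq; ++i) {
    std::string fwd = as<std::string>(queries[i]);
    std::vector<std::string> orients;
    orients.push_back(fwd);
    if (both_strands) {
      std::string rc = revcomp_one(fwd);
      if (rc != fwd) orients.push_back(rc);
    }
    bool recruited = false;
    for (size_t o = 0; o < orients.size() && !recruited; ++o) {
      const std::string& q = orients[o];
      for (int j = 0; j + seed_len <= (int) q.size() && !recruited; ++j) {
        SeedMap::const_iterator it = idx.find(q.substr(j, seed_len));
        if (it == idx.end()) continue;
        for (size_t c = 0; c < it->second.size() && !recruited; ++c) {
          int tid = it->second[c];
          // stamp combines query index and orientation so each (query
          // orientation, target) pair is scored at most once
          int key = (int) (2 * i + (int) o);
          if (stamp[tid] == key) continue;
          stamp[tid] = key;
          SEXP st = STRING_ELT(targets, tid);
          int sc = lcs_len(q.data(), (int) q.size(), CHAR(st), LENGTH(st));
          if (sc >= min_score) recruited = true;
        }
      }
    }
    out[i] = recruited;
  }
  return out;
}

// Longest suffix(a)/prefix(b) overlap with at most max_mismatch mismatching
// positions. Returns 0-length when none qualifies.
// [[Rcpp::export(name = ".suffix_prefix_cpp")]]
IntegerVector suffix_prefix_cpp(std::string a, std::string b,
                                int min_overlap, int max_mismatch) {
  const int na = (int) a.size(), nb = (int) b.size();
  const int lmax = std::min(na, nb);
  for (int L = lmax; L >= min_overlap; --L) {
    const char* pa = a.data() + (na - L);
    const char* pb = b.data();
    int mism = 0;
    for (int j = 0; j < L; ++j) {
      if (pa[j] != pb[j] && ++mism > max_mismatch) break;
    }
    if (mism <= max_mismatch)
      return IntegerVector::create(L, mism);
  }
  return IntegerVector::create(0, NA_INTEGER);
}
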