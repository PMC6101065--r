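#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
};

// Bucket all k-mers by the h-mer extracted at each trial's positions; k-mers
// sharing a bucket in any trial are linked; groups are connected components.
// position_sets: list of integer vectors (1-based positions into the k-mer).
// Buckets may be processed in any number of partitions without changing the
// result because all links feed one global union-find.
// [[Rcpp::export(name = ".group_kmers_cpp")]]
IntegerVector group_kmers_cpp(CharacterVector kmers, List position_sets,
                              int n_partitions) {
  const int n = (int) kmers.size();
  UnionFind uf(n);
  if (n_partitions < 1) stop("n_partitions must be >= 1");
  std::string key;
  for (R_xlen_t t = 0; t < position_sets.size(); ++t) {
    IntegerVector pos = position_sets[t];
    const int h = (int) pos.size();
    key.resize(h);
    for (int part = 0; part < n_partitions; ++part) {
      std::unordered_map<std::string, int> first_seen;
      first_seen.reserve((size_t) n / n_partitions + 16);
      for (int i = 0; i < n; ++i) {
        const char* s = CHAR(STRING_ELT(kmers, i));
        for (int j = 0; j < h; ++j) key[j] = s[pos[j] - 1];
        // deterministic bucket-key hash assigns each bucket to one partition
        unsigned long hsh = 1469598103934665603UL;
        for (int j = 0; j < h; ++j) { hsh ^= (unsigned char) key[j]; hsh *= 1099511628211UL; }
        if ((int) (hsh % (unsigned long) n_partitions) != part) continue;
        std::unordered_map<std::string, int>::iterator it = first_seen.find(key);
        if (it == first_seen.end()) first_seen[key] = i;
        else uf.unite(it->second, i);
      }
    }
  }
  // component ids renumbered in order of first appearance
  IntegerVector out(n);
  std::unordered_map<int, int> relabel;
  int next_id = 1;
  for (int i = 0; i < n; ++i) {
    int root = uf.find(i);
    std::unordered_map<int, int>::iterator it = relabel.find(root);
    if (it == relabel.end()) { relabel[root] = next_id; out[i] = next_id; ++next_id; }
    else out[i] = it->second;
  }
  return out;
}

// Frequency-weighted positional voting. Each member votes its base at every
// position with weight equal to its count; ties break to the alphabetically
// smallest base; the consensus count is the maximum winning vote over
// positions.
// [[Rcpp::export(name = ".consensus_vote_cpp")]]
List consensus_vote_cpp(CharacterVector words, NumericVector counts,
                        IntegerVector group_ids) {
  const int n = (int) words.size();
  if (n == 0) stop("empty group");
  int n_groups = 0;
  for (int i = 0; i < n; ++i) n_groups = std::max(n_groups, group_ids[i]);
  std::vector<std::vector<int> > members(n_groups);
  for (int i = 0; i < n; ++i) members[group_ids[i] - 1].push_back(i);

  CharacterVector out_words(n_groups);
  NumericVector out_counts(n_groups);
  const char* bases = "ACGT";
  for (int g = 0; g < n_groups; ++g) {
    const std::vector<int>& mem = members[g];
    if (mem.empty()) stop("empty group");
    const int k = (int) LENGTH(STRING_ELT(words, mem[0]));
    std::string cons(k, 'A');
    double final_count = 0.0;
    std::vector<double> votes(4);
    for (int p = 0; p < k; ++p) {
      votes.assign(4, 0.0);
      for (size_t m = 0; m < mem.size(); ++m) {
        const char* s = CHAR(STRING_ELT(words, mem[m]));
        switch (s[p]) {
        case 'A': votes[0] += counts[mem[m]]; break;
        case 'C': votes[1] += counts[mem[m]]; break;
        case 'G': votes[2] += counts[mem[m]]; break;
        case 'T': votes[3] += counts[mem[m]]; break;
        default: stop("invalid DNA alphabet in consensus voting");
        }
      }
      int best = 0;
      for (int b = 1; b < 4; ++b) if (votes[b] > votes[best]) best = b;
      cons[p] = bases[best];
      if (votes[best] > final_count) final_count = votes[best];
    }
    out_words[g] = cons;
    out_counts[g] = final_count;
  }
  return List::create(_["kmer"] = out_words, _["count"] = out_counts);
}
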