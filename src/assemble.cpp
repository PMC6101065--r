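#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

std::string revcomp_one(const std::string& s);

// Native de Bruijn unitig assembler. Nodes are (ak-1)-mers, edges the ak-mers
// extracted from the input k-mers (both orientations when both_strands). A
// unitig is a maximal path whose interior nodes all have in-degree 1 and
// out-degree 1. Optionally, dead-end branches shorter than tip_max_len edges
// whose edges all have instance support <= tip_max_support are pruned before
// unitig extraction.
// [[Rcpp::export(name = ".assemble_unitigs_cpp")]]
List assemble_unitigs_cpp(CharacterVector kmers, NumericVector counts, int ak,
                          bool both_strands, int min_edge_support,
                          bool prune_tips, int tip_max_len,
                          int tip_max_support) {
  struct EdgeInfo { double weight; int instances; };
  std::unordered_map<std::string, EdgeInfo> emap;
  emap.reserve((size_t) kmers.size() * 4);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string w = as<std::string>(kmers[i]);
    if ((int) w.size() < ak) stop("assembly word length exceeds a k-mer length");
    std::vector<std::string> orients;
    orients.push_back(w);
    if (both_strands) {
      std::string rc = revcomp_one(w);
      if (rc != w) orients.push_back(rc);
    }
    for (size_t o = 0; o < orients.size(); ++o) {
      const std::string& s = orients[o];
      for (int j = 0; j + ak <= (int) s.size(); ++j) {
        EdgeInfo& e = emap[s.substr(j, ak)];
        e.weight += counts[i];
        e.instances += 1;
      }
    }
  }

  // deterministic edge order
  std::vector<std::string> estr;
  estr.reserve(emap.size());
  for (std::unordered_map<std::string, EdgeInfo>::iterator it = emap.begin();
       it != emap.end(); ++it)
    if (it->second.instances >= min_edge_support) estr.push_back(it->first);
  std::sort(estr.begin(), estr.end());
  const int ne = (int) estr.size();

  std::unordered_map<std::string, int> nodes;
  std::vector<std::string> node_str;
  std::vector<int> esrc(ne), etgt(ne);
  std::vector<double> eweight(ne);
  std::vector<int> einst(ne);
  std::vector<std::vector<int> > out_e, in_e;
  for (int i = 0; i < ne; ++i) {
    const std::string& w = estr[i];
    std::string u = w.substr(0, ak - 1), v = w.substr(1, ak - 1);
    int ui, vi;
    std::unordered_map<std::string, int>::iterator it = nodes.find(u);
    if (it == nodes.end()) {
      ui = (int) node_str.size(); nodes[u] = ui; node_str.push_back(u);
      out_e.push_back(std::vector<int>()); in_e.push_back(std::vector<int>());
    } else ui = it->second;
    it = nodes.find(v);
    if (it == nodes.end()) {
      vi = (int) node_str.size(); nodes[v] = vi; node_str.push_back(v);
      out_e.push_back(std::vector<int>()); in_e.push_back(std::vector<int>());
    } else vi = it->second;
    esrc[i] = ui; etgt[i] = vi;
    eweight[i] = emap[w].weight; einst[i] = emap[w].instances;
    out_e[ui].push_back(i); in_e[vi].push_back(i);
  }

  std::vector<bool> alive(ne, true);
  const int nn = (int) node_str.size();
  std::vector<int> outdeg(nn), indeg(nn);
  for (int i = 0; i < ne; ++i) { ++outdeg[esrc[i]]; ++indeg[etgt[i]]; }

  if (prune_tips) {
    // forward tips: path ending at an out-degree-0 node, hanging off a
    // branching (out-degree >= 2) node; mirrored for in-degree-0 starts
    for (int pass = 0; pass < 2; ++pass) {
      bool changed = false;
      for (int v = 0; v < nn; ++v) {
        if (outdeg[v] == 0 && indeg[v] == 1) {
          std::vector<int> path;
          int cur = v;
          bool ok = true;
          while ((int) path.size() < tip_max_len) {
            int ein = -1;
            for (size_t j = 0; j < in_e[cur].size(); ++j)
              if (alive[in_e[cur][j]]) { ein = in_e[cur][j]; break; }
            if (ein < 0) { ok = false; break; }
            path.push_back(ein);
            int u = esrc[ein];
            if (outdeg[u] >= 2) break;            // attach point
            if (indeg[u] != 1 || outdeg[u] != 1) { ok = false; break; }
            cur = u;
          }
          if (!ok || path.empty()) continue;
          int attach = esrc[path.back()];
          if (outdeg[attach] < 2 || (int) path.size() >= tip_max_len) continue;
          bool low = true;
          for (size_t j = 0; j < path.size(); ++j)
            if (einst[path[j]] > tip_max_support) { low = false; break; }
          if (!low) continue;
          for (size_t j = 0; j < path.size(); ++j) {
            alive[path[j]] = false;
            --outdeg[esrc[path[j]]]; --indeg[etgt[path[j]]];
          }
          changed = true;
        } else if (indeg[v] == 0 && outdeg[v] == 1) {
          std::vector<int> path;
          int cur = v;
          bool ok = true;
          while ((int) path.size() < tip_max_len) {
            int eout = -1;
            for (size_t j = 0; j < out_e[cur].size(); ++j)
              if (alive[out_e[cur][j]]) { eout = out_e[cur][j]; break; }
            if (eout < 0) { ok = false; break; }
            path.push_back(eout);
            int u = etgt[eout];
            if (indeg[u] >= 2) break;
            if (indeg[u] != 1 || outdeg[u] != 1) { ok = false; break; }
            cur = u;
          }
          if (!ok || path.empty()) continue;
          int attach = etgt[path.back()];
          if (indeg[attach] < 2 || (int) path.size() >= tip_max_len) continue;
          bool low = true;
          for (size_t j = 0; j < path.size(); ++j)
            if (einst[path[j]] > tip_max_support) { low = false; break; }
          if (!low) continue;
          for (size_t j = 0; j < path.size(); ++j) {
            alive[path[j]] = false;
            --outdeg[esrc[path[j]]]; --indeg[etgt[path[j]]];
          }
          changed = true;
        }
      }
      if (!changed) break;
    }
  }

  // unitig extraction
  std::vector<bool> used(ne, false);
  std::vector<std::string> contigs;
  std::vector<double> supports;
  auto internal = [&](int v) { return indeg[v] == 1 && outdeg[v] == 1; };
  auto emit_from = [&](int e0) {
    std::string seq = node_str[esrc[e0]];
    double supp = 0.0;
    int nedges = 0;
    int e = e0;
    while (true) {
      used[e] = true;
      seq.push_back(estr[e][ak - 1]);
      supp += eweight[e] / einst[e];
      ++nedges;
      int v = etgt[e];
      if (!internal(v)) break;
      int nxt = -1;
      for (size_t j = 0; j < out_e[v].size(); ++j)
        if (alive[out_e[v][j]]) { nxt = out_e[v][j]; break; }
      if (nxt < 0 || used[nxt]) break;
      e = nxt;
    }
    contigs.push_back(seq);
    supports.push_back(supp / nedges);
  };
  for (int e = 0; e < ne; ++e)
    if (alive[e] && !used[e] && !internal(esrc[e])) emit_from(e);
  for (int e = 0; e < ne; ++e)  // isolated cycles
    if (alive[e] && !used[e]) emit_from(e);

  return List::create(_["sequence"] = wrap(contigs),
                      _["mean_support"] = wrap(supports));
}
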