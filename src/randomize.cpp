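// Degree-preserving randomization of the bipartite phenotype-gene
// association graph, and the shared-gene pair recount under the null.
//
// A permutation is produced by double-edge swaps on the bipartite edge
// list: pick two edges (p1, g1), (p2, g2) and exchange gene endpoints to
// (p1, g2), (p2, g1) unless either new edge already exists. Swaps leave
// every phenotype's gene count and every gene's phenotype count unchanged.
// All randomness comes from R's RNG, so results are reproducible from
// set.seed().

#include <Rcpp.h>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline long long edge_key(int p, int g) {
  return static_cast<long long>(p) * 1000003LL + g;
}

// one randomized copy of the gene endpoint vector; n_swaps attempted swaps
static void swap_edges(const std::vector<int>& phen, std::vector<int>& gene,
                       std::unordered_set<long long>& edges, int n_swaps) {
  const int m = static_cast<int>(phen.size());
  for (int s = 0; s < n_swaps; ++s) {
    int e1 = static_cast<int>(R::unif_rand() * m);
    int e2 = static_cast<int>(R::unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int p1 = phen[e1], g1 = gene[e1];
    int p2 = phen[e2], g2 = gene[e2];
    if (g1 == g2 || p1 == p2) continue;
    long long k1 = edge_key(p1, g2), k2 = edge_key(p2, g1);
    if (edges.count(k1) || edges.count(k2)) continue;
    edges.erase(edge_key(p1, g1));
    edges.erase(edge_key(p2, g2));
    edges.insert(k1);
    edges.insert(k2);
    gene[e1] = g2;
    gene[e2] = g1;
  }
}

// [[Rcpp::export(name = ".cpp_swap_bipartite")]]
IntegerVector cpp_swap_bipartite(IntegerVector phen, IntegerVector gene,
                                 int n_swaps) {
  const int m = phen.size();
  if (m != gene.size()) stop("phen and gene lengths differ");
  if (m < 2) stop("degree-preserving shuffle infeasible: fewer than 2 edges");
  std::vector<int> pv(phen.begin(), phen.end());
  std::vector<int> gv(gene.begin(), gene.end());
  std::unordered_set<long long> edges;
  edges.reserve(m * 2);
  for (int i = 0; i < m; ++i) {
    if (!edges.insert(edge_key(pv[i], gv[i])).second)
      stop("duplicate bipartite edge in input");
  }
  swap_edges(pv, gv, edges, n_swaps);
  return IntegerVector(gv.begin(), gv.end());
}

// count SCN pairs (pa[i], pb[i]) whose phenotype gene sets intersect
static int count_sharing(const std::vector<std::unordered_set<int>>& sets,
                         const IntegerVector& pa, const IntegerVector& pb) {
  int count = 0;
  for (int i = 0; i < pa.size(); ++i) {
    const std::unordered_set<int>& sa = sets[pa[i] - 1];
    const std::unordered_set<int>& sb = sets[pb[i] - 1];
    const std::unordered_set<int>& small = sa.size() <= sb.size() ? sa : sb;
    const std::unordered_set<int>& big = sa.size() <= sb.size() ? sb : sa;
    for (int g : small) {
      if (big.count(g)) { ++count; break; }
    }
  }
  return count;
}

// [[Rcpp::export(name = ".cpp_null_shared_counts")]]
IntegerVector cpp_null_shared_counts(IntegerVector phen, IntegerVector gene,
                                     int n_phen, IntegerVector pair_a,
                                     IntegerVector pair_b, int n_perm,
                                     double swap_factor) {
  const int m = phen.size();
  if (m < 2) stop("degree-preserving shuffle infeasible: fewer than 2 edges");
  if (pair_a.size() != pair_b.size()) stop("pair vectors differ in length");
  std::vector<int> pv(phen.begin(), phen.end());
  std::vector<int> gv0(gene.begin(), gene.end());
  std::unordered_set<long long> edges0;
  edges0.reserve(m * 2);
  for (int i = 0; i < m; ++i) {
    if (!edges0.insert(edge_key(pv[i], gv0[i])).second)
      stop("duplicate bipartite edge in input");
  }
  const int n_swaps = static_cast<int>(swap_factor * m);
  IntegerVector out(n_perm);
  std::vector<std::unordered_set<int>> sets(n_phen);
  for (int r = 0; r < n_perm; ++r) {
    // each permutation restarts from the observed edges
    std::vector<int> gv(gv0);
    std::unordered_set<long long> edges(edges0);
    swap_edges(pv, gv, edges, n_swaps);
    for (int p = 0; p < n_phen; ++p) sets[p].clear();
    for (int i = 0; i < m; ++i) sets[pv[i] - 1].insert(gv[i]);
    out[r] = count_sharing(sets, pair_a, pair_b);
  }
  return out;
}
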