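#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving rewiring null for bipartite miRNA->gene networks.
//
// Each null replicate starts from the observed edge list and applies
// swap_factor * n_edges attempted pair swaps: two edges (m1,g1),(m2,g2)
// are replaced by (m1,g2),(m2,g1) when m1!=m2, g1!=g2 and neither new
// edge already exists. Both degree sequences are preserved exactly. For
// every miRNA the function counts, over replicates, how often the null
// NOD (number of its targets with in-degree 1) and null TF-target count
// reach the observed values, yielding add-one permutation p-values
// upstream. Uses R's RNG so results are reproducible under set.seed().
//
// mi, ge: 0-based edge endpoints; n_mirna, n_gene: node counts;
// tf: logical flag per gene; obs_nod, obs_tfcnt: observed per-miRNA values.
// [[Rcpp::export(name = ".rewire_null_counts")]]
List rewire_null_counts(IntegerVector mi, IntegerVector ge,
                        int n_mirna, int n_gene, LogicalVector tf,
                        IntegerVector obs_nod, IntegerVector obs_tfcnt,
                        int n_null, double swap_factor) {
  const int n_edges = mi.size();
  if (n_edges < 2) stop("network too small to rewire");
  std::vector<int> mi0(mi.begin(), mi.end());
  std::vector<int> ge0(ge.begin(), ge.end());

  IntegerVector ge_nod(n_mirna, 0), ge_tf(n_mirna, 0);
  std::vector<int> indeg(n_gene), nod(n_mirna), tfc(n_mirna);
  std::vector<int> m(n_edges), g(n_edges);
  std::unordered_set<long long> present;
  present.reserve(n_edges * 2);
  const long long NG = n_gene;
  const long long n_swaps = (long long)(swap_factor * n_edges);

  RNGScope scope;
  bool any_swap_possible = false;
  for (int rep = 0; rep < n_null; ++rep) {
    m = mi0; g = ge0;
    present.clear();
    for (int e = 0; e < n_edges; ++e) present.insert(m[e] * NG + g[e]);
    for (long long s = 0; s < n_swaps; ++s) {
      int e1 = (int)(unif_rand() * n_edges);
      int e2 = (int)(unif_rand() * n_edges);
      if (e1 >= n_edges) e1 = n_edges - 1;
      if (e2 >= n_edges) e2 = n_edges - 1;
      if (m[e1] == m[e2] || g[e1] == g[e2]) continue;
      long long k1 = m[e1] * NG + g[e2];
      long long k2 = m[e2] * NG + g[e1];
      if (present.count(k1) || present.count(k2)) continue;
      present.erase(m[e1] * NG + g[e1]);
      present.erase(m[e2] * NG + g[e2]);
      present.insert(k1);
      present.insert(k2);
      std::swap(g[e1], g[e2]);
      any_swap_possible = true;
    }
    std::fill(indeg.begin(), indeg.end(), 0);
    std::fill(nod.begin(), nod.end(), 0);
    std::fill(tfc.begin(), tfc.end(), 0);
    for (int e = 0; e < n_edges; ++e) ++indeg[g[e]];
    for (int e = 0; e < n_edges; ++e) {
      if (indeg[g[e]] == 1) ++nod[m[e]];
      if (tf[g[e]]) ++tfc[m[e]];
    }
    for (int i = 0; i < n_mirna; ++i) {
      if (nod[i] >= obs_nod[i]) ++ge_nod[i];
      if (tfc[i] >= obs_tfcnt[i]) ++ge_tf[i];
    }
    if (rep == 0 && !any_swap_possible && n_null > 1) {
      // degenerate topology: no admissible swap exists, the null is the
      // observed graph itself
      stop("network too small to rewire: no admissible edge swap");
    }
  }
  return List::create(_["ge_nod"] = ge_nod, _["ge_tfp"] = ge_tf);
}
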