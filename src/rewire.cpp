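#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving rewiring by repeated double-edge swaps: pick edges
// (a,b), (c,d) with disjoint endpoints and replace them with (a,d),
// (c,b) unless a self-loop or multi-edge would result.  Uses R's RNG,
// so set.seed() makes the shuffle reproducible.
//
// [[Rcpp::export]]
List rewire_edges_cpp(IntegerVector from, IntegerVector to, int n_nodes,
                      double swaps_per_edge = 10) {
  const int m = from.size();
  std::vector<int> a(from.begin(), from.end()), b(to.begin(), to.end());
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  auto key = [n_nodes](int i, int j) {
    if (i > j) std::swap(i, j);
    return (long long)i * (n_nodes + 1) + j;
  };
  for (int e = 0; e < m; ++e) present.insert(key(a[e], b[e]));
  GetRNGstate();
  long long attempts = (long long)(swaps_per_edge * m);
  for (long long t = 0; t < attempts; ++t) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int va = a[e1], vb = b[e1], vc = a[e2], vd = b[e2];
    if (va == vc || va == vd || vb == vc || vb == vd) continue;
    if (present.count(key(va, vd)) || present.count(key(vc, vb))) continue;
    present.erase(key(va, vb));
    present.erase(key(vc, vd));
    present.insert(key(va, vd));
    present.insert(key(vc, vb));
    b[e1] = vd;
    a[e2] = vc; b[e2] = vb;
  }
  PutRNGstate();
  return List::create(_["from"] = IntegerVector(a.begin(), a.end()),
                      _["to"] = IntegerVector(b.begin(), b.end()));
}
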