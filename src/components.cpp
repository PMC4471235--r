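#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labels (1-based) from an undirected edge list.
// [[Rcpp::export]]
IntegerVector components_cpp(IntegerVector from, IntegerVector to, int n) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int e = 0; e < from.size(); ++e) {
    int a = find(from[e] - 1), b = find(to[e] - 1);
    if (a != b) parent[a] = b;
  }
  IntegerVector out(n);
  std::map<int, int> relabel;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = relabel.size() + 1; }
    out[i] = relabel[r];
  }
  return out;
}
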