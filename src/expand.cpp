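#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-vertex, per-network entropy term of the module objective.
// L  = weight from gene i to the rest of the module C,
// T  = total strength of gene i in network k (constant during a search).
// A gene with no in-module connectivity in network k (L == 0, which
// includes the no-edges-at-all case T == 0) is maximally uncertain
// about the module boundary there and contributes log 2; the raw
// binary entropy would score it 0, as "coherent" as all-weight-inside,
// and modules absent from one of the searched networks would rank as
// perfect.  For p in (0, 1) the term is the binary entropy as printed.
static inline double entropy_term(double L, double T) {
  if (T <= 0.0 || L <= 0.0) return M_LN2;
  double p = L / T;
  if (p >= 1.0) return 0.0;
  return -p * std::log(p) - (1.0 - p) * std::log(1.0 - p);
}

static double entropy_sum(const std::vector<NumericMatrix>& A,
                          const NumericMatrix& totals,
                          const std::vector<int>& members) {
  const int m = A.size();
  double S = 0.0;
  for (size_t a = 0; a < members.size(); ++a) {
    int i = members[a];
    for (int k = 0; k < m; ++k) {
      double L = 0.0;
      for (size_t b = 0; b < members.size(); ++b) {
        if (b == a) continue;
        L += A[k](i, members[b]);
      }
      S += entropy_term(L, totals(i, k));
    }
  }
  return S;
}

// [[Rcpp::export]]
double module_entropy_cpp(List Amats, NumericMatrix totals, IntegerVector members1) {
  std::vector<NumericMatrix> A;
  for (int k = 0; k < Amats.size(); ++k) A.push_back(as<NumericMatrix>(Amats[k]));
  std::vector<int> members;
  for (int a = 0; a < members1.size(); ++a) members.push_back(members1[a] - 1);
  if (members.size() < 2) stop("module must have at least 2 genes");
  return entropy_sum(A, totals, members) / members.size();
}

// Greedy entropy minimisation around one seed gene.
//
// Starts from the seed's closed neighbourhood (union over the searched
// networks), then repeatedly applies the single best strict-improvement
// move: add a gene adjacent to the module in >= 1 network, or drop a
// non-seed member.  Stops when no move decreases H(C).  Ties are broken
// by `ord` (lexicographic gene-id rank), making the search deterministic.
//
// [[Rcpp::export]]
List expand_seed_cpp(List Amats, NumericMatrix totals, int seed1,
                     IntegerVector ord, double tol = 1e-12,
                     int max_steps = 10000) {
  const int m = Amats.size();
  std::vector<NumericMatrix> A;
  for (int k = 0; k < m; ++k) A.push_back(as<NumericMatrix>(Amats[k]));
  const int n = totals.nrow();
  const int seed = seed1 - 1;

  // gene indices visited in tie-break order
  std::vector<int> by_ord(n);
  {
    std::vector<std::pair<int, int> > tmp(n);
    for (int i = 0; i < n; ++i) tmp[i] = std::make_pair(ord[i], i);
    std::sort(tmp.begin(), tmp.end());
    for (int i = 0; i < n; ++i) by_ord[i] = tmp[i].second;
  }

  std::vector<bool> inC(n, false);
  std::vector<double> Lfull(static_cast<size_t>(n) * m, 0.0); // in-weight of every gene to C
  std::vector<int> members;

  // L bookkeeping for adding/removing gene u to/from C
  auto apply_gene = [&](int u, double sign) {
    for (int k = 0; k < m; ++k) {
      const double* col = &A[k](0, u);
      for (int v = 0; v < n; ++v) Lfull[static_cast<size_t>(k) * n + v] += sign * col[v];
    }
  };

  inC[seed] = true;
  members.push_back(seed);
  apply_gene(seed, +1.0);
  for (int v = 0; v < n; ++v) {
    if (v == seed) continue;
    bool nb = false;
    for (int k = 0; k < m; ++k)
      if (A[k](v, seed) > 0.0) { nb = true; break; }
    if (nb) {
      inC[v] = true;
      members.push_back(v);
      apply_gene(v, +1.0);
    }
  }
  if (members.size() < 2) {
    return List::create(_["members"] = IntegerVector(0),
                        _["H"] = NA_REAL,
                        _["trace"] = NumericVector(0));
  }

  double S = 0.0; // sum of entropy terms over members x networks
  for (size_t a = 0; a < members.size(); ++a) {
    int i = members[a];
    for (int k = 0; k < m; ++k)
      S += entropy_term(Lfull[static_cast<size_t>(k) * n + i] - 0.0, totals(i, k));
  }
  // Lfull currently includes each member's own column contribution to itself?
  // No: A has zero diagonal, and Lfull[v] sums edges from v to all of C
  // including v itself only via A(v,v) = 0, so member in-weights are correct.

  double H = S / members.size();
  std::vector<double> trace;
  trace.push_back(H);

  for (int step = 0; step < max_steps; ++step) {
    double bestH = H;
    int best_gene = -1;
    bool best_is_add = false;

    int csize = members.size();
    for (int oi = 0; oi < n; ++oi) {
      int v = by_ord[oi];
      if (inC[v]) {
        if (v == seed || csize <= 2) continue;
        // removal of v
        double newS = S;
        for (int k = 0; k < m; ++k)
          newS -= entropy_term(Lfull[static_cast<size_t>(k) * n + v], totals(v, k));
        for (int a = 0; a < csize; ++a) {
          int i = members[a];
          if (i == v) continue;
          for (int k = 0; k < m; ++k) {
            double w = A[k](i, v);
            if (w > 0.0) {
              double Li = Lfull[static_cast<size_t>(k) * n + i];
              newS += entropy_term(Li - w, totals(i, k)) - entropy_term(Li, totals(i, k));
            }
          }
        }
        double newH = newS / (csize - 1);
        if (newH < bestH - tol) { bestH = newH; best_gene = v; best_is_add = false; }
      } else {
        // addition of v: must touch C in some network
        double Lv = 0.0;
        for (int k = 0; k < m; ++k) Lv += Lfull[static_cast<size_t>(k) * n + v];
        if (Lv <= 0.0) continue;
        double newS = S;
        for (int k = 0; k < m; ++k)
          newS += entropy_term(Lfull[static_cast<size_t>(k) * n + v], totals(v, k));
        for (int a = 0; a < csize; ++a) {
          int i = members[a];
          for (int k = 0; k < m; ++k) {
            double w = A[k](i, v);
            if (w > 0.0) {
              double Li = Lfull[static_cast<size_t>(k) * n + i];
              newS += entropy_term(Li + w, totals(i, k)) - entropy_term(Li, totals(i, k));
            }
          }
        }
        double newH = newS / (csize + 1);
        if (newH < bestH - tol) { bestH = newH; best_gene = v; best_is_add = true; }
      }
    }

    if (best_gene < 0) break;

    if (best_is_add) {
      inC[best_gene] = true;
      members.push_back(best_gene);
      apply_gene(best_gene, +1.0);
    } else {
      inC[best_gene] = false;
      members.erase(std::find(members.begin(), members.end(), best_gene));
      apply_gene(best_gene, -1.0);
    }
    S = 0.0;
    for (size_t a = 0; a < members.size(); ++a) {
      int i = members[a];
      for (int k = 0; k < m; ++k)
        S += entropy_term(Lfull[static_cast<size_t>(k) * n + i], totals(i, k));
    }
    H = S / members.size();
    trace.push_back(H);
  }

  std::sort(members.begin(), members.end());
  IntegerVector out(members.size());
  for (size_t a = 0; a < members.size(); ++a) out[a] = members[a] + 1;
  return List::create(_["members"] = out, _["H"] = H,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
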