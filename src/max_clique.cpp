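#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact maximum-clique search: branch and bound with a greedy-colouring
// upper bound. Among cliques of maximal size the one with the smallest
// summed pairwise mismatch (edge weight) is returned, so the result is
// deterministic given the input order. Graphs here are the spot/hkl
// consistency graphs of single still frames (typically < 400 nodes).

namespace {

struct Search {
  const std::vector<std::vector<char> >& adj;
  const NumericMatrix& w;
  std::vector<int> best;
  double bestw;

  Search(const std::vector<std::vector<char> >& a, const NumericMatrix& wm)
    : adj(a), w(wm), bestw(0.0) {}

  void expand(std::vector<int>& R, double wR, std::vector<int>& P) {
    const int n = (int)P.size();
    if (n == 0) {
      if (R.size() > best.size() ||
          (R.size() == best.size() && !R.empty() && wR < bestw)) {
        best = R;
        bestw = wR;
      }
      return;
    }
    if (R.size() + n < best.size()) return;

    // greedy colouring of P (in order); colour number bounds the clique
    std::vector<std::vector<int> > classes;
    std::vector<int> colour(n);
    for (int i = 0; i < n; ++i) {
      int v = P[i];
      size_t c = 0;
      for (; c < classes.size(); ++c) {
        bool clash = false;
        for (size_t j = 0; j < classes[c].size(); ++j)
          if (adj[v][classes[c][j]]) { clash = true; break; }
        if (!clash) break;
      }
      if (c == classes.size()) classes.push_back(std::vector<int>());
      classes[c].push_back(v);
      colour[i] = (int)c + 1;
    }
    // order vertices by colour (ascending); process from the back
    std::vector<std::pair<int, int> > ord(n);
    for (int i = 0; i < n; ++i) ord[i] = std::make_pair(colour[i], P[i]);
    std::stable_sort(ord.begin(), ord.end());

    for (int i = n - 1; i >= 0; --i) {
      // equal-size cliques are still explored (tie-break on weight)
      if (R.size() + ord[i].first < best.size()) return;
      int v = ord[i].second;
      double dw = 0.0;
      for (size_t j = 0; j < R.size(); ++j) dw += w(v, R[j]);
      R.push_back(v);
      std::vector<int> P2;
      P2.reserve(i);
      for (int j = 0; j < i; ++j)
        if (adj[v][ord[j].second]) P2.push_back(ord[j].second);
      expand(R, wR + dw, P2);
      R.pop_back();
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".max_clique_bb")]]
IntegerVector max_clique_bb(LogicalMatrix adjacency, NumericMatrix weight) {
  const int n = adjacency.nrow();
  if (adjacency.ncol() != n || weight.nrow() != n || weight.ncol() != n)
    stop("adjacency and weight must be square matrices of the same size");
  std::vector<std::vector<char> > adj(n, std::vector<char>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      adj[i][j] = (i != j && adjacency(i, j)) ? 1 : 0;

  Search s(adj, weight);
  std::vector<int> R;
  std::vector<int> P(n);
  // start from vertices sorted by degree, descending (stable): better bounds
  std::vector<std::pair<int, int> > deg(n);
  for (int i = 0; i < n; ++i) {
    int d = 0;
    for (int j = 0; j < n; ++j) d += adj[i][j];
    deg[i] = std::make_pair(-d, i);
  }
  std::stable_sort(deg.begin(), deg.end());
  for (int i = 0; i < n; ++i) P[i] = deg[i].second;
  s.expand(R, 0.0, P);

  IntegerVector out(s.best.size());
  for (size_t i = 0; i < s.best.size(); ++i) out[i] = s.best[i] + 1;
  std::sort(out.begin(), out.end());
  return out;
}
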