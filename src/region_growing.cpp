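#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Region growing over the kNN graph. Seeds are taken in ascending order of
// (curvature, index); a neighbour joins the current region when the angle
// between its normal and the recruiting point's normal is at most the
// threshold, and it propagates the front only while its curvature stays under
// the curvature gate. Every point ends up in exactly one region (region size
// filtering happens on the R side). Deterministic for fixed input.
// [[Rcpp::export(rng = false)]]
List cpp_region_growing(NumericMatrix normals, NumericVector curvature,
                        IntegerMatrix nn, double cos_angle,
                        double curvature_gate) {
  int n = normals.nrow(), k = nn.ncol();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (curvature[a] != curvature[b]) return curvature[a] < curvature[b];
    return a < b;
  });

  IntegerVector label(n, NA_INTEGER);
  std::vector<int> seeds;
  int region = 0;
  std::deque<int> front;
  for (int s : order) {
    if (label[s] != NA_INTEGER) continue;
    label[s] = region + 1;
    seeds.push_back(s + 1);
    front.clear();
    front.push_back(s);
    while (!front.empty()) {
      int p = front.front();
      front.pop_front();
      double px = normals(p, 0), py = normals(p, 1), pz = normals(p, 2);
      for (int j = 0; j < k; ++j) {
        int q = nn(p, j) - 1;
        if (label[q] != NA_INTEGER) continue;
        double dot = px * normals(q, 0) + py * normals(q, 1) + pz * normals(q, 2);
        if (std::fabs(dot) >= cos_angle) {
          label[q] = region + 1;
          if (curvature[q] <= curvature_gate) front.push_back(q);
        }
      }
    }
    ++region;
  }
  return List::create(_["label"] = label, _["seeds"] = wrap(seeds),
                      _["n_regions"] = region);
}
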