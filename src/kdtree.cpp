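#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Static 3D kd-tree over the rows of a point matrix. Built once per cloud and
// queried for all points; median splits give a balanced tree so queries are
// O(log n) expected on scanner-like data.
namespace {

struct KDTree {
  const double *x, *y, *z;
  int n;
  std::vector<int> idx;   // permutation of 0..n-1; tree stored implicitly

  double coord(int i, int ax) const {
    return ax == 0 ? x[i] : (ax == 1 ? y[i] : z[i]);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  // max-heap of (distance^2, index) keeping the k current best
  typedef std::pair<double, int> HeapEl;

  void query(int lo, int hi, int depth, double qx, double qy, double qz,
             int self, int k,
             std::priority_queue<HeapEl> &heap) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    int p = idx[mid];
    if (p != self) {
      double dx = x[p] - qx, dy = y[p] - qy, dz = z[p] - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if ((int)heap.size() < k) heap.push(HeapEl(d2, p));
      else if (d2 < heap.top().first) { heap.pop(); heap.push(HeapEl(d2, p)); }
    }
    double q = ax == 0 ? qx : (ax == 1 ? qy : qz);
    double split = coord(p, ax);
    double diff = q - split;
    int first_lo = diff < 0 ? lo : mid + 1;
    int first_hi = diff < 0 ? mid : hi;
    int sec_lo   = diff < 0 ? mid + 1 : lo;
    int sec_hi   = diff < 0 ? hi : mid;
    query(first_lo, first_hi, depth + 1, qx, qy, qz, self, k, heap);
    if ((int)heap.size() < k || diff * diff < heap.top().first)
      query(sec_lo, sec_hi, depth + 1, qx, qy, qz, self, k, heap);
  }
};

} // namespace

// k nearest neighbours of every point (self excluded). Returns an n x k
// matrix of 1-based row indices, columns ordered nearest first.
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_knn(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k < 1) stop("k must be >= 1");
  if (n < k + 1) stop("need at least k+1 points");
  KDTree tree;
  tree.x = &pts(0, 0); tree.y = &pts(0, 1); tree.z = &pts(0, 2);
  tree.n = n;
  tree.idx.resize(n);
  for (int i = 0; i < n; ++i) tree.idx[i] = i;
  tree.build(0, n, 0);

  IntegerMatrix out(n, k);
  for (int i = 0; i < n; ++i) {
    std::priority_queue<KDTree::HeapEl> heap;
    tree.query(0, n, 0, pts(i, 0), pts(i, 1), pts(i, 2), i, k, heap);
    int j = (int)heap.size() - 1;
    while (!heap.empty()) {
      out(i, j--) = heap.top().second + 1;
      heap.pop();
    }
  }
  return out;
}

namespace {

// Jacobi eigen decomposition of a symmetric 3x3 matrix; eigenvalues ascending.
void eigen_sym3(double a[3][3], double eval[3], double evec[3][3]) {
  double v[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double m[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) m[i][j] = a[i][j];
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(m[0][1]) + std::fabs(m[0][2]) + std::fabs(m[1][2]);
    if (off < 1e-15) break;
    for (int p = 0; p < 2; ++p) for (int q = p + 1; q < 3; ++q) {
      if (std::fabs(m[p][q]) < 1e-30) continue;
      double theta = (m[q][q] - m[p][p]) / (2.0 * m[p][q]);
      double t = (theta >= 0 ? 1.0 : -1.0) /
                 (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
      double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
      for (int r = 0; r < 3; ++r) {
        double mrp = m[r][p], mrq = m[r][q];
        m[r][p] = c * mrp - s * mrq;
        m[r][q] = s * mrp + c * mrq;
      }
      for (int r = 0; r < 3; ++r) {
        double mpr = m[p][r], mqr = m[q][r];
        m[p][r] = c * mpr - s * mqr;
        m[q][r] = s * mpr + c * mqr;
      }
      for (int r = 0; r < 3; ++r) {
        double vrp = v[r][p], vrq = v[r][q];
        v[r][p] = c * vrp - s * vrq;
        v[r][q] = s * vrp + c * vrq;
      }
    }
  }
  int ord[3] = {0, 1, 2};
  double d[3] = {m[0][0], m[1][1], m[2][2]};
  std::sort(ord, ord + 3, [&](int i, int j) { return d[i] < d[j]; });
  for (int i = 0; i < 3; ++i) {
    eval[i] = d[ord[i]];
    for (int r = 0; r < 3; ++r) evec[r][i] = v[r][ord[i]];
  }
}

} // namespace

// Per-point PCA surface normals and curvature from a precomputed kNN index
// matrix (1-based). The normal is the eigenvector of the smallest eigenvalue
// of the neighbourhood covariance (point itself included); curvature is
// lambda_min / (lambda_1 + lambda_2 + lambda_3). Normals are flipped to point
// away from the local neighbourhood centroid, i.e. outward on convex surfaces.
// [[Rcpp::export(rng = false)]]
List cpp_pca_normals(NumericMatrix pts, IntegerMatrix nn) {
  int n = pts.nrow(), k = nn.ncol();
  NumericMatrix normals(n, 3);
  NumericVector curvature(n);
  for (int i = 0; i < n; ++i) {
    double mean[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    for (int j = 0; j < k; ++j) {
      int q = nn(i, j) - 1;
      mean[0] += pts(q, 0); mean[1] += pts(q, 1); mean[2] += pts(q, 2);
    }
    double m = k + 1.0;
    mean[0] /= m; mean[1] /= m; mean[2] /= m;
    double cov[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j = -1; j < k; ++j) {
      int q = j < 0 ? i : nn(i, j) - 1;
      double d[3] = {pts(q, 0) - mean[0], pts(q, 1) - mean[1], pts(q, 2) - mean[2]};
      for (int a = 0; a < 3; ++a)
        for (int b = a; b < 3; ++b) cov[a][b] += d[a] * d[b];
    }
    cov[1][0] = cov[0][1]; cov[2][0] = cov[0][2]; cov[2][1] = cov[1][2];
    double eval[3], evec[3][3];
    eigen_sym3(cov, eval, evec);
    double nx = evec[0][0], ny = evec[1][0], nz = evec[2][0];
    double len = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (len < 1e-300) { nx = 0; ny = 0; nz = 1; len = 1; }
    nx /= len; ny /= len; nz /= len;
    // orient away from neighbourhood centroid (outward for convex patches)
    double ox = pts(i, 0) - mean[0], oy = pts(i, 1) - mean[1], oz = pts(i, 2) - mean[2];
    if (nx * ox + ny * oy + nz * oz < 0) { nx = -nx; ny = -ny; nz = -nz; }
    normals(i, 0) = nx; normals(i, 1) = ny; normals(i, 2) = nz;
    double tot = eval[0] + eval[1] + eval[2];
    curvature[i] = tot > 0 ? std::max(0.0, eval[0]) / tot : 0.0;
  }
  return List::create(_["normals"] = normals, _["curvature"] = curvature);
}
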