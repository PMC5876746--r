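#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
using namespace Rcpp;

// The algebraic sphere equation  x^2+y^2+z^2 = 2x*cx + 2y*cy + 2z*cz + e,
// with e = r^2 - |c|^2, is linear in (cx, cy, cz, e). Both the minimal
// 4-point solver and the least-squares refinement reduce to a 4x4 solve.

namespace {

// Gaussian elimination with partial pivoting; returns false when the system
// is (near) singular, i.e. the sample points are coplanar/cocircular.
bool solve4(double A[4][5]) {
  for (int col = 0; col < 4; ++col) {
    int piv = col;
    for (int r = col + 1; r < 4; ++r)
      if (std::fabs(A[r][col]) > std::fabs(A[piv][col])) piv = r;
    if (std::fabs(A[piv][col]) < 1e-10) return false;
    if (piv != col)
      for (int c = col; c < 5; ++c) std::swap(A[piv][c], A[col][c]);
    for (int r = 0; r < 4; ++r) {
      if (r == col) continue;
      double f = A[r][col] / A[col][col];
      for (int c = col; c < 5; ++c) A[r][c] -= f * A[col][c];
    }
  }
  for (int r = 0; r < 4; ++r) A[r][4] /= A[r][r];
  return true;
}

bool sphere_from_rows(const double *px, const double *py, const double *pz,
                      const int *rows, double out[4]) {
  double A[4][5];
  for (int i = 0; i < 4; ++i) {
    double x = px[rows[i]], y = py[rows[i]], z = pz[rows[i]];
    A[i][0] = 2 * x; A[i][1] = 2 * y; A[i][2] = 2 * z; A[i][3] = 1;
    A[i][4] = x * x + y * y + z * z;
  }
  if (!solve4(A)) return false;
  double cx = A[0][4], cy = A[1][4], cz = A[2][4], e = A[3][4];
  double r2 = e + cx * cx + cy * cy + cz * cz;
  if (r2 <= 0) return false;
  out[0] = cx; out[1] = cy; out[2] = cz; out[3] = std::sqrt(r2);
  return true;
}

// algebraic least squares over an index subset (or all points when idx empty)
bool sphere_lsq(const double *px, const double *py, const double *pz, int n,
                const std::vector<int> &idx, double out[4]) {
  double AtA[4][4] = {{0}}, Atb[4] = {0};
  int m = idx.empty() ? n : (int)idx.size();
  if (m < 4) return false;
  for (int t = 0; t < m; ++t) {
    int i = idx.empty() ? t : idx[t];
    double row[4] = {2 * px[i], 2 * py[i], 2 * pz[i], 1.0};
    double b = px[i] * px[i] + py[i] * py[i] + pz[i] * pz[i];
    for (int a = 0; a < 4; ++a) {
      Atb[a] += row[a] * b;
      for (int c = 0; c < 4; ++c) AtA[a][c] += row[a] * row[c];
    }
  }
  double A[4][5];
  for (int r = 0; r < 4; ++r) {
    for (int c = 0; c < 4; ++c) A[r][c] = AtA[r][c] / m;
    A[r][4] = Atb[r] / m;
  }
  if (!solve4(A)) return false;
  double cx = A[0][4], cy = A[1][4], cz = A[2][4], e = A[3][4];
  double r2 = e + cx * cx + cy * cy + cz * cz;
  if (r2 <= 0) return false;
  out[0] = cx; out[1] = cy; out[2] = cz; out[3] = std::sqrt(r2);
  return true;
}

int count_inliers(const double *px, const double *py, const double *pz, int n,
                  const double s[4], double tol, std::vector<int> *keep) {
  int cnt = 0;
  for (int i = 0; i < n; ++i) {
    double dx = px[i] - s[0], dy = py[i] - s[1], dz = pz[i] - s[2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz) - s[3];
    if (std::fabs(d) <= tol) {
      ++cnt;
      if (keep) keep->push_back(i);
    }
  }
  return cnt;
}

} // namespace

// Exposed for the minimal-sample solver: sphere through 4 points, or NULL
// when degenerate (coplanar/cocircular sample).
// [[Rcpp::export(rng = false)]]
SEXP cpp_sphere_from4(NumericMatrix pts) {
  if (pts.nrow() != 4) stop("exactly four points required");
  int rows[4] = {0, 1, 2, 3};
  double s[4];
  if (!sphere_from_rows(&pts(0, 0), &pts(0, 1), &pts(0, 2), rows, s))
    return R_NilValue;
  return List::create(_["center"] = NumericVector::create(s[0], s[1], s[2]),
                      _["radius"] = s[3]);
}

// Algebraic least-squares sphere over all rows; NULL when rank deficient.
// [[Rcpp::export(rng = false)]]
SEXP cpp_sphere_lsq(NumericMatrix pts) {
  if (pts.nrow() < 4) stop("at least four points required");
  double s[4];
  std::vector<int> all;
  if (!sphere_lsq(&pts(0, 0), &pts(0, 1), &pts(0, 2), pts.nrow(), all, s))
    return R_NilValue;
  return List::create(_["center"] = NumericVector::create(s[0], s[1], s[2]),
                      _["radius"] = s[3]);
}

// RANSAC sphere search: `iters` minimal 4-point samples, hypotheses with
// radius outside [min_r, max_r] skipped, best hypothesis by inlier count
// (first winner kept on ties), then one least-squares refinement on its
// inliers and one inlier recount. Deterministic for a fixed seed.
// [[Rcpp::export(rng = false)]]
SEXP cpp_ransac_sphere(NumericMatrix pts, double min_r, double max_r,
                       double tol, int min_sup, int iters, int seed) {
  int n = pts.nrow();
  const double *px = &pts(0, 0), *py = &pts(0, 1), *pz = &pts(0, 2);
  if (n < 4) return R_NilValue;
  std::mt19937 rng((uint32_t)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  double best[4];
  int best_cnt = -1;
  int rows[4];
  for (int it = 0; it < iters; ++it) {
    rows[0] = pick(rng);
    do { rows[1] = pick(rng); } while (rows[1] == rows[0]);
    do { rows[2] = pick(rng); } while (rows[2] == rows[0] || rows[2] == rows[1]);
    do { rows[3] = pick(rng); } while (rows[3] == rows[0] || rows[3] == rows[1] ||
                                       rows[3] == rows[2]);
    double s[4];
    if (!sphere_from_rows(px, py, pz, rows, s)) continue;
    if (s[3] < min_r || s[3] > max_r) continue;
    int cnt = count_inliers(px, py, pz, n, s, tol, nullptr);
    if (cnt > best_cnt) {
      best_cnt = cnt;
      for (int j = 0; j < 4; ++j) best[j] = s[j];
    }
  }
  if (best_cnt < 4) return R_NilValue;

  std::vector<int> inl;
  count_inliers(px, py, pz, n, best, tol, &inl);
  double refined[4];
  if (sphere_lsq(px, py, pz, n, inl, refined)) {
    std::vector<int> inl2;
    count_inliers(px, py, pz, n, refined, tol, &inl2);
    if (inl2.size() >= 4) {
      for (int j = 0; j < 4; ++j) best[j] = refined[j];
      inl.swap(inl2);
    }
  }
  if (best[3] < min_r || best[3] > max_r) return R_NilValue;
  if ((int)inl.size() < min_sup) return R_NilValue;

  IntegerVector inliers(inl.size());
  for (size_t i = 0; i < inl.size(); ++i) inliers[i] = inl[i] + 1;
  return List::create(_["center"] = NumericVector::create(best[0], best[1], best[2]),
                      _["radius"] = best[3], _["inliers"] = inliers);
}
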