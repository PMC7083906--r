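#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact k-nearest-neighbour search by brute force with partial selection.
// Distance ties are broken by point index so neighbour identity is
// reproducible across platforms.  Works for 2D and 3D coordinates.
// [[Rcpp::export(name = ".knn_brute_cpp")]]
List knn_brute_cpp(NumericMatrix coords, int k) {
  const int n = coords.nrow();
  const int d = coords.ncol();
  if (k < 1) stop("k must be >= 1");
  if (n <= k) stop("need more points than neighbours requested");

  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector<std::pair<double, int> > buf(n - 1);

  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = coords(i, c) - coords(j, c);
        s += diff * diff;
      }
      buf[m].first = s;
      buf[m].second = j;
      ++m;
    }
    std::partial_sort(buf.begin(), buf.begin() + k, buf.end());
    for (int q = 0; q < k; ++q) {
      idx(i, q) = buf[q].second + 1;  // 1-based for R
      dst(i, q) = std::sqrt(buf[q].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Even-odd (ray casting) point-in-polygon test for a single closed loop.
// Points exactly on an edge may land on either side; callers that care
// nudge their query points.
// [[Rcpp::export(name = ".points_in_poly_cpp")]]
LogicalVector points_in_poly_cpp(NumericVector px, NumericVector py,
                                 NumericVector vx, NumericVector vy) {
  const int n = px.size();
  const int m = vx.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool inside = false;
    double x = px[i], y = py[i];
    for (int j = 0, k = m - 1; j < m; k = j++) {
      double xj = vx[j], yj = vy[j], xk = vx[k], yk = vy[k];
      if (((yj > y) != (yk > y)) &&
          (x < (xk - xj) * (y - yj) / (yk - yj) + xj))
        inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}

// Grid field used for disc-union-then-erode cluster shapes.  For every
// grid node the distance D1 to the nearest member point is computed, then
// greyscale-dilated by a disc of radius `erosion`:
//   Dt(p) = max over |u| <= erosion of D1(p + u).
// The eroded union of discs of radius r is exactly the sublevel set
// {Dt <= r}, so contouring (r - Dt) at level 0 recovers its outline with
// sub-grid accuracy.
// [[Rcpp::export(name = ".dilated_distance_field_cpp")]]
NumericMatrix dilated_distance_field_cpp(NumericMatrix pts,
                                         NumericVector gx, NumericVector gy,
                                         double erosion) {
  const int nx = gx.size(), ny = gy.size(), m = pts.nrow();
  NumericMatrix d1(nx, ny);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      double best = R_PosInf;
      for (int p = 0; p < m; ++p) {
        double dx = gx[ix] - pts(p, 0);
        double dy = gy[iy] - pts(p, 1);
        double s = dx * dx + dy * dy;
        if (s < best) best = s;
      }
      d1(ix, iy) = std::sqrt(best);
    }
  }
  if (erosion <= 0.0) return d1;

  // the distance field has no interior local maxima, so its max over a
  // disc of radius `erosion` is attained on the boundary circle; sample
  // that circle with bilinear interpolation for sub-grid accuracy
  const double hx = nx > 1 ? gx[1] - gx[0] : 1.0;
  const double hy = ny > 1 ? gy[1] - gy[0] : 1.0;
  const double h = std::min(hx, hy);
  int na = (int)std::ceil(2.0 * M_PI * erosion / h);
  if (na < 24) na = 24;
  if (na > 256) na = 256;
  std::vector<double> ex(na), ey(na);
  for (int a = 0; a < na; ++a) {
    ex[a] = erosion * std::cos(2.0 * M_PI * a / na);
    ey[a] = erosion * std::sin(2.0 * M_PI * a / na);
  }
  const double x0 = gx[0], y0 = gy[0];
  NumericMatrix out(nx, ny);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      double mx = d1(ix, iy);
      for (int a = 0; a < na; ++a) {
        double qx = (gx[ix] + ex[a] - x0) / hx;
        double qy = (gy[iy] + ey[a] - y0) / hy;
        if (qx < 0) qx = 0; if (qx > nx - 1) qx = nx - 1;
        if (qy < 0) qy = 0; if (qy > ny - 1) qy = ny - 1;
        int jx = (int)qx, jy = (int)qy;
        if (jx >= nx - 1) jx = nx - 2;
        if (jy >= ny - 1) jy = ny - 2;
        double fx = qx - jx, fy = qy - jy;
        double v =
          d1(jx, jy) * (1 - fx) * (1 - fy) +
          d1(jx + 1, jy) * fx * (1 - fy) +
          d1(jx, jy + 1) * (1 - fx) * fy +
          d1(jx + 1, jy + 1) * fx * fy;
        if (v > mx) mx = v;
      }
      out(ix, iy) = mx;
    }
  }
  return out;
}
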