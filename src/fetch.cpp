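#include <Rcpp.h>
using namespace Rcpp;

// Sum-of-fetch by ray casting. For every marine cell (depth > 0) the ray
// along each bearing is marched in steps of `step` metres until it first
// enters a land cell (depth <= 0 or NA) or reaches `cap` metres; leaving
// the grid counts as open water (distance = cap). Land cells return NA.
// Rays are clipped to the bounding box of the land cells before marching,
// which changes nothing (there is no land outside it) but skips the long
// open-water marches.
// [[Rcpp::export]]
NumericMatrix fetch_raycast(NumericMatrix depth, double cell,
                            int bearings, double cap, double step) {
  const int nr = depth.nrow(), nc = depth.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> dx(bearings), dy(bearings);
  for (int b = 0; b < bearings; ++b) {
    double th = 2.0 * M_PI * b / bearings;
    dx[b] = std::sin(th);
    dy[b] = std::cos(th);
  }
  const double width = nc * cell, height = nr * cell;
  std::vector<char> land(static_cast<size_t>(nr) * nc);
  double bx0 = width, bx1 = 0.0, by0 = height, by1 = 0.0;
  bool any_land = false;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double d = depth(r, c);
      bool is_land = NumericMatrix::is_na(d) || d <= 0.0;
      land[static_cast<size_t>(r) * nc + c] = is_land ? 1 : 0;
      if (is_land) {
        any_land = true;
        double x0 = c * cell, y0 = (nr - r - 1) * cell;
        bx0 = std::min(bx0, x0); bx1 = std::max(bx1, x0 + cell);
        by0 = std::min(by0, y0); by1 = std::max(by1, y0 + cell);
      }
    }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (land[static_cast<size_t>(r) * nc + c]) {
        out(r, c) = NA_REAL;
        continue;
      }
      if (!any_land) {
        out(r, c) = static_cast<double>(bearings) * cap;
        continue;
      }
      double cx = (c + 0.5) * cell;
      double cy = (nr - r - 0.5) * cell;
      double total = 0.0;
      for (int b = 0; b < bearings; ++b) {
        // parametric clip of the ray to the land bbox (slab method)
        double t0 = 0.0, t1 = cap, dist = cap;
        bool hit_box = true;
        if (std::abs(dx[b]) < 1e-12) {
          if (cx < bx0 || cx > bx1) hit_box = false;
        } else {
          double ta = (bx0 - cx) / dx[b], tb = (bx1 - cx) / dx[b];
          t0 = std::max(t0, std::min(ta, tb));
          t1 = std::min(t1, std::max(ta, tb));
        }
        if (hit_box && std::abs(dy[b]) < 1e-12) {
          if (cy < by0 || cy > by1) hit_box = false;
        } else if (hit_box) {
          double ta = (by0 - cy) / dy[b], tb = (by1 - cy) / dy[b];
          t0 = std::max(t0, std::min(ta, tb));
          t1 = std::min(t1, std::max(ta, tb));
        }
        if (hit_box && t0 <= t1) {
          double start = std::max(step, std::floor(t0 / step) * step);
          for (double t = start; t <= t1; t += step) {
            double px = cx + dx[b] * t;
            double py = cy + dy[b] * t;
            if (px < 0.0 || px >= width || py < 0.0 || py >= height)
              break;  // left the grid: open water out to the cap
            int pc = static_cast<int>(px / cell);
            int pr = nr - 1 - static_cast<int>(py / cell);
            if (land[static_cast<size_t>(pr) * nc + pc]) {
              dist = t;
              break;
            }
          }
        }
        total += dist;
      }
      out(r, c) = total;
    }
  }
  return out;
}
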