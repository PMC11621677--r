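// Even-odd polygon rasterisation core: tests every pixel centre in the
// bounding box for containment (and optionally exact boundary incidence).
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".raster_polygon_cpp")]]
IntegerMatrix raster_polygon_cpp(NumericVector px, NumericVector py,
                                 int cmin, int cmax, int rmin, int rmax,
                                 bool boundary) {
  const int n = px.size();
  const double eps = 1e-9;
  std::vector<int> rows, cols;
  if (!boundary) {
    // scanline even-odd fill (equivalent to the per-pixel rule below for
    // polygons in general position)
    std::vector<double> xs;
    for (int r = rmin; r <= rmax; ++r) {
      const double y = r;
      xs.clear();
      int j = n - 1;
      for (int i = 0; i < n; ++i) {
        const double xi = px[i], yi = py[i], xj = px[j], yj = py[j];
        if ((yi > y) != (yj > y))
          xs.push_back((xj - xi) * (y - yi) / (yj - yi) + xi);
        j = i;
      }
      std::sort(xs.begin(), xs.end());
      for (size_t k = 0; k + 1 < xs.size(); k += 2) {
        int c0 = std::max(cmin, (int)std::ceil(xs[k] - eps));
        int c1 = std::min(cmax, (int)std::floor(xs[k + 1] - eps));
        if (std::fabs(xs[k + 1] - eps - c1) < 1e-12) --c1;  // strict <
        for (int c = c0; c <= c1; ++c) {
          rows.push_back(r);
          cols.push_back(c);
        }
      }
    }
    IntegerMatrix out(rows.size(), 2);
    for (size_t i = 0; i < rows.size(); ++i) {
      out(i, 0) = rows[i];
      out(i, 1) = cols[i];
    }
    colnames(out) = CharacterVector::create("row", "col");
    return out;
  }
  for (int r = rmin; r <= rmax; ++r) {
    for (int c = cmin; c <= cmax; ++c) {
      const double x = c, y = r;
      bool inside = false, onedge = false;
      int j = n - 1;
      for (int i = 0; i < n; ++i) {
        const double xi = px[i], yi = py[i], xj = px[j], yj = py[j];
        if ((yi > y) != (yj > y)) {
          const double xint = (xj - xi) * (y - yi) / (yj - yi) + xi;
          if (x < xint - eps) inside = !inside;
          if (std::fabs(x - xint) <= eps) onedge = true;
        }
        if (boundary && !onedge) {
          const double dx = xj - xi, dy = yj - yi;
          const double len2 = dx * dx + dy * dy;
          if (len2 > 0) {
            double t = ((x - xi) * dx + (y - yi) * dy) / len2;
            t = std::min(1.0, std::max(0.0, t));
            const double ex = xi + t * dx - x, ey = yi + t * dy - y;
            if (ex * ex + ey * ey <= eps) onedge = true;
          } else if ((x - xi) * (x - xi) + (y - yi) * (y - yi) <= eps) {
            onedge = true;
          }
        }
        j = i;
      }
      if (inside || onedge) {
        rows.push_back(r);
        cols.push_back(c);
      }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  colnames(out) = CharacterVector::create("row", "col");
  return out;
}
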