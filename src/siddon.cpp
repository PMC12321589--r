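#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact ray-pixel intersection lengths for a 2-D parallel-beam geometry.
//
// The image is an ny x nx grid of pixels of size (sx, sy) mm, centered on the
// origin; pixel (iy, ix) (0-based) spans
//   x in [x0 + ix*sx, x0 + (ix+1)*sx],  x0 = -nx*sx/2
//   y in [y0 + iy*sy, y0 + (iy+1)*sy],  y0 = -ny*sy/2
// A line of response with projection angle theta and signed radial offset t
// is the line { t*(cos t, sin t) + s*(-sin t, cos t) : s in R }.
//
// Returns triplets (row = LOR index, col = pixel linear index, weight =
// intersection length in mm) for assembly into a sparse system matrix.
// LOR index is angle-major: row = a*n_offsets + b + 1. Pixel linear index is
// R column-major for an ny x nx matrix: iy + ix*ny + 1.

// [[Rcpp::export(name = ".siddon_weights")]]
List siddon_weights(int nx, int ny, double sx, double sy,
                    NumericVector angles, NumericVector offsets) {
  std::vector<int> ri, ci;
  std::vector<double> w;
  const double x0 = -0.5 * nx * sx, y0 = -0.5 * ny * sy;
  const double xmax = -x0, ymax = -y0;
  const int nb = offsets.size();
  const double eps = 1e-12;
  std::vector<double> ts;
  ts.reserve(nx + ny + 4);

  for (int a = 0; a < angles.size(); ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    const double dx = -st, dy = ct;  // ray direction (unit)
    for (int b = 0; b < nb; ++b) {
      const double px = offsets[b] * ct, py = offsets[b] * st;
      // clip the ray parameter to the image bounding box (slab method)
      double tmin = -1e300, tmax = 1e300;
      bool miss = false;
      if (std::fabs(dx) < eps) {
        if (px <= x0 || px >= xmax) miss = true;
      } else {
        double t1 = (x0 - px) / dx, t2 = (xmax - px) / dx;
        if (t1 > t2) std::swap(t1, t2);
        tmin = std::max(tmin, t1);
        tmax = std::min(tmax, t2);
      }
      if (std::fabs(dy) < eps) {
        if (py <= y0 || py >= ymax) miss = true;
      } else {
        double t1 = (y0 - py) / dy, t2 = (ymax - py) / dy;
        if (t1 > t2) std::swap(t1, t2);
        tmin = std::max(tmin, t1);
        tmax = std::min(tmax, t2);
      }
      if (miss || tmax - tmin <= eps) continue;

      // all grid-line crossings inside (tmin, tmax)
      ts.clear();
      ts.push_back(tmin);
      ts.push_back(tmax);
      if (std::fabs(dx) >= eps) {
        for (int i = 1; i < nx; ++i) {
          const double t = (x0 + i * sx - px) / dx;
          if (t > tmin + eps && t < tmax - eps) ts.push_back(t);
        }
      }
      if (std::fabs(dy) >= eps) {
        for (int i = 1; i < ny; ++i) {
          const double t = (y0 + i * sy - py) / dy;
          if (t > tmin + eps && t < tmax - eps) ts.push_back(t);
        }
      }
      std::sort(ts.begin(), ts.end());

      const int row = a * nb + b + 1;
      for (size_t k = 0; k + 1 < ts.size(); ++k) {
        const double len = ts[k + 1] - ts[k];
        if (len <= eps) continue;
        const double tm = 0.5 * (ts[k] + ts[k + 1]);
        const double mx = px + tm * dx, my = py + tm * dy;
        int ix = (int)std::floor((mx - x0) / sx);
        int iy = (int)std::floor((my - y0) / sy);
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) continue;
        ri.push_back(row);
        ci.push_back(iy + ix * ny + 1);
        w.push_back(len);
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci), _["x"] = wrap(w));
}
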