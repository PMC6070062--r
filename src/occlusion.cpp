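#include <Rcpp.h>
using namespace Rcpp;

// Moller-Trumbore ray-triangle intersection for a batch of ray origins
// against a triangle soup, with optional periodic image offsets of the ray.
//
// tri: nf x 9 matrix, rows (ax,ay,az, bx,by,bz, cx,cy,cz) in mm
// origins: np x 3 ray origins (patch centroids)
// dir: length-3 unit direction toward the sun (dz > 0 assumed meaningful)
// self: np 1-based index of each origin's own face in tri (0 = none)
// offsets: m x 2 horizontal (dx, dy) translations applied to the ray origin,
//          first row must be (0,0); implements wrapping at periodic walls
// eps: intersection tolerance (mm)
//
// Returns: logical np vector, true if any triangle blocks the ray.
// [[Rcpp::export]]
LogicalVector cpp_occluded(const NumericMatrix& tri,
                           const NumericMatrix& origins,
                           const NumericVector& dir,
                           const IntegerVector& self,
                           const NumericMatrix& offsets,
                           double eps) {
  const int nf = tri.nrow();
  const int np = origins.nrow();
  const int no = offsets.nrow();
  const double dx = dir[0], dy = dir[1], dz = dir[2];

  // precompute per-triangle edges and max z for early rejection
  std::vector<double> ax(nf), ay(nf), az(nf), e1x(nf), e1y(nf), e1z(nf),
      e2x(nf), e2y(nf), e2z(nf), zmax(nf);
  for (int f = 0; f < nf; ++f) {
    ax[f] = tri(f, 0); ay[f] = tri(f, 1); az[f] = tri(f, 2);
    e1x[f] = tri(f, 3) - ax[f]; e1y[f] = tri(f, 4) - ay[f];
    e1z[f] = tri(f, 5) - az[f];
    e2x[f] = tri(f, 6) - ax[f]; e2y[f] = tri(f, 7) - ay[f];
    e2z[f] = tri(f, 8) - az[f];
    zmax[f] = std::max(tri(f, 2), std::max(tri(f, 5), tri(f, 8)));
  }
  // h = dir x e2 (depends only on triangle)
  std::vector<double> hx(nf), hy(nf), hz(nf), det(nf);
  for (int f = 0; f < nf; ++f) {
    hx[f] = dy * e2z[f] - dz * e2y[f];
    hy[f] = dz * e2x[f] - dx * e2z[f];
    hz[f] = dx * e2y[f] - dy * e2x[f];
    det[f] = e1x[f] * hx[f] + e1y[f] * hy[f] + e1z[f] * hz[f];
  }

  LogicalVector out(np);
  for (int p = 0; p < np; ++p) {
    bool hit = false;
    for (int o = 0; o < no && !hit; ++o) {
      const double ox = origins(p, 0) + offsets(o, 0);
      const double oy = origins(p, 1) + offsets(o, 1);
      const double oz = origins(p, 2);
      const bool zero_off = (offsets(o, 0) == 0.0 && offsets(o, 1) == 0.0);
      for (int f = 0; f < nf; ++f) {
        if (dz > 0 && zmax[f] <= oz + eps) continue;
        if (zero_off && f + 1 == self[p]) continue;
        const double d = det[f];
        if (std::abs(d) < 1e-12) continue;  // ray parallel to triangle
        const double inv = 1.0 / d;
        const double sx = ox - ax[f], sy = oy - ay[f], sz = oz - az[f];
        const double u = (sx * hx[f] + sy * hy[f] + sz * hz[f]) * inv;
        if (u < -1e-9 || u > 1 + 1e-9) continue;
        const double qx = sy * e1z[f] - sz * e1y[f];
        const double qy = sz * e1x[f] - sx * e1z[f];
        const double qz = sx * e1y[f] - sy * e1x[f];
        const double v = (dx * qx + dy * qy + dz * qz) * inv;
        if (v < -1e-9 || u + v > 1 + 1e-9) continue;
        const double t = (e2x[f] * qx + e2y[f] * qy + e2z[f] * qz) * inv;
        if (t > eps) { hit = true; break; }
      }
    }
    out[p] = hit;
  }
  return out;
}
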