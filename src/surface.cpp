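// Low-level geometry kernels: separable Gaussian smoothing of a voxel field,
// marching-tetrahedra isosurfacing with outward (gradient-based) face normals,
// and nearest-foreground-voxel label lookup for face attribution.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long) ny * k);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector arr, IntegerVector dim,
                                  NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  std::vector<double> b(a.size());
  const int n[3] = {nx, ny, nz};
  // zero padding outside the grid: outside counts as background
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int) std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + r];
    }
    for (double &kv : ker) kv /= sum;
    int stride = (ax == 0) ? 1 : (ax == 1 ? nx : nx * ny);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int c[3] = {i, j, k};
          long base = idx3(i, j, k, nx, ny);
          double acc = 0.0;
          int lo = std::max(-r, -c[ax]);
          int hi = std::min(r, n[ax] - 1 - c[ax]);
          for (int t = lo; t <= hi; ++t)
            acc += ker[t + r] * a[base + (long) t * stride];
          b[base] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// trilinear sample of field at continuous voxel index (ix, iy, iz); outside -> 0
static double trilerp(const double *f, int nx, int ny, int nz,
                      double x, double y, double z) {
  int i0 = (int) std::floor(x), j0 = (int) std::floor(y), k0 = (int) std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        double v = (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
                     ? 0.0 : f[idx3(i, j, k, nx, ny)];
        acc += w * v;
      }
  return acc;
}

struct P3 { double x, y, z; };

static P3 edge_interp(const P3 &a, const P3 &b, double fa, double fb, double iso) {
  double t = (fb == fa) ? 0.5 : (iso - fa) / (fb - fa);
  if (t < 0) t = 0; if (t > 1) t = 1;
  P3 p; p.x = a.x + t * (b.x - a.x); p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z);
  return p;
}

// Marching tetrahedra over the cube lattice; cubes split into 6 tetrahedra
// sharing the main diagonal. Triangles are emitted in voxel-index coordinates
// and converted to world mm at the end. Face normals are oriented outward
// (toward decreasing field value) using the trilinearly sampled field.
// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dim,
                    NumericVector spacing, NumericVector origin, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *f = REAL(field);
  // cube corner offsets (standard ordering)
  static const int CO[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6 tetrahedra sharing diagonal 0-6
  static const int TET[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  std::vector<double> verts;   // 9 doubles per triangle
  verts.reserve(1 << 20);

  P3 cp[8]; double cf[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cf[c] = f[idx3(i + CO[c][0], j + CO[c][1], k + CO[c][2], nx, ny)];
          (cf[c] >= iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int c = 0; c < 8; ++c) {
          cp[c].x = i + CO[c][0]; cp[c].y = j + CO[c][1]; cp[c].z = k + CO[c][2];
        }
        for (int t = 0; t < 6; ++t) {
          const int *v = TET[t];
          int mask = 0;
          for (int c = 0; c < 4; ++c)
            if (cf[v[c]] >= iso) mask |= (1 << c);
          if (mask == 0 || mask == 15) continue;
          // collect the separating polygon
          P3 tri[4]; int ntri = 0;
          auto EI = [&](int a, int b) {
            return edge_interp(cp[v[a]], cp[v[b]], cf[v[a]], cf[v[b]], iso);
          };
          switch (mask) {
          case 1: case 14:
            tri[0] = EI(0,1); tri[1] = EI(0,2); tri[2] = EI(0,3); ntri = 3; break;
          case 2: case 13:
            tri[0] = EI(1,0); tri[1] = EI(1,2); tri[2] = EI(1,3); ntri = 3; break;
          case 4: case 11:
            tri[0] = EI(2,0); tri[1] = EI(2,1); tri[2] = EI(2,3); ntri = 3; break;
          case 8: case 7:
            tri[0] = EI(3,0); tri[1] = EI(3,1); tri[2] = EI(3,2); ntri = 3; break;
          case 3: case 12: // {0,1} vs {2,3}
            tri[0] = EI(0,2); tri[1] = EI(0,3); tri[2] = EI(1,3); tri[3] = EI(1,2);
            ntri = 4; break;
          case 5: case 10: // {0,2} vs {1,3}
            tri[0] = EI(0,1); tri[1] = EI(0,3); tri[2] = EI(2,3); tri[3] = EI(2,1);
            ntri = 4; break;
          case 6: case 9:  // {1,2} vs {0,3}
            tri[0] = EI(1,0); tri[1] = EI(1,3); tri[2] = EI(2,3); tri[3] = EI(2,0);
            ntri = 4; break;
          }
          auto push = [&](const P3 &a, const P3 &b, const P3 &c) {
            verts.push_back(a.x); verts.push_back(a.y); verts.push_back(a.z);
            verts.push_back(b.x); verts.push_back(b.y); verts.push_back(b.z);
            verts.push_back(c.x); verts.push_back(c.y); verts.push_back(c.z);
          };
          push(tri[0], tri[1], tri[2]);
          if (ntri == 4) push(tri[0], tri[2], tri[3]);
        }
      }

  const long nf = (long) verts.size() / 9;
  NumericMatrix V(3 * nf, 3), N(nf, 3), CEN(nf, 3);
  NumericVector AR(nf);
  for (long fi = 0; fi < nf; ++fi) {
    double vx[3][3];
    for (int c = 0; c < 3; ++c) {      // corner
      double gx = verts[9 * fi + 3 * c];
      double gy = verts[9 * fi + 3 * c + 1];
      double gz = verts[9 * fi + 3 * c + 2];
      vx[c][0] = gx; vx[c][1] = gy; vx[c][2] = gz;
      V(3 * fi + c, 0) = origin[0] + gx * spacing[0];
      V(3 * fi + c, 1) = origin[1] + gy * spacing[1];
      V(3 * fi + c, 2) = origin[2] + gz * spacing[2];
    }
    // area and centroid in world coordinates
    {
      double e1[3], e2[3];
      for (int d = 0; d < 3; ++d) {
        e1[d] = (vx[1][d] - vx[0][d]) * spacing[d];
        e2[d] = (vx[2][d] - vx[0][d]) * spacing[d];
        CEN(fi, d) = origin[d] +
          (vx[0][d] + vx[1][d] + vx[2][d]) / 3.0 * spacing[d];
      }
      double ax = e1[1] * e2[2] - e1[2] * e2[1];
      double ay = e1[2] * e2[0] - e1[0] * e2[2];
      double az = e1[0] * e2[1] - e1[1] * e2[0];
      AR[fi] = 0.5 * std::sqrt(ax * ax + ay * ay + az * az);
    }
    // outward normal from the smoothed field gradient at the centroid: far
    // smoother than the facet normal on near-binary data, which matters for
    // plane-normal clustering and for inward label probing
    double cxi = (vx[0][0] + vx[1][0] + vx[2][0]) / 3.0;
    double cyi = (vx[0][1] + vx[1][1] + vx[2][1]) / 3.0;
    double czi = (vx[0][2] + vx[1][2] + vx[2][2]) / 3.0;
    double gx = (trilerp(f, nx, ny, nz, cxi + 0.5, cyi, czi) -
                 trilerp(f, nx, ny, nz, cxi - 0.5, cyi, czi)) / spacing[0];
    double gy = (trilerp(f, nx, ny, nz, cxi, cyi + 0.5, czi) -
                 trilerp(f, nx, ny, nz, cxi, cyi - 0.5, czi)) / spacing[1];
    double gz = (trilerp(f, nx, ny, nz, cxi, cyi, czi + 0.5) -
                 trilerp(f, nx, ny, nz, cxi, cyi, czi - 0.5)) / spacing[2];
    double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
    double nxv, nyv, nzv;
    if (gn > 1e-12) {
      nxv = -gx / gn; nyv = -gy / gn; nzv = -gz / gn;  // field decreases outward
    } else {
      // degenerate gradient: fall back to the facet normal, oriented by the
      // field difference across the face
      double e1[3], e2[3];
      for (int d = 0; d < 3; ++d) {
        e1[d] = (vx[1][d] - vx[0][d]) * spacing[d];
        e2[d] = (vx[2][d] - vx[0][d]) * spacing[d];
      }
      nxv = e1[1] * e2[2] - e1[2] * e2[1];
      nyv = e1[2] * e2[0] - e1[0] * e2[2];
      nzv = e1[0] * e2[1] - e1[1] * e2[0];
      double nn = std::sqrt(nxv * nxv + nyv * nyv + nzv * nzv);
      if (nn < 1e-300) { N(fi, 0) = N(fi, 1) = N(fi, 2) = 0.0; continue; }
      nxv /= nn; nyv /= nn; nzv /= nn;
      double ox = nxv / spacing[0], oy = nyv / spacing[1], oz = nzv / spacing[2];
      double on = std::sqrt(ox * ox + oy * oy + oz * oz);
      double fplus  = trilerp(f, nx, ny, nz, cxi + 0.5 * ox / on,
                              cyi + 0.5 * oy / on, czi + 0.5 * oz / on);
      double fminus = trilerp(f, nx, ny, nz, cxi - 0.5 * ox / on,
                              cyi - 0.5 * oy / on, czi - 0.5 * oz / on);
      if (fplus > fminus) { nxv = -nxv; nyv = -nyv; nzv = -nzv; }
    }
    N(fi, 0) = nxv; N(fi, 1) = nyv; N(fi, 2) = nzv;
  }
  return List::create(_["vertices"] = V, _["normals"] = N,
                      _["areas"] = AR, _["centroids"] = CEN);
}

// Consensus scoring: for each candidate plane (row of cand_p/cand_n), count
// the faces whose normals agree within cos_min and whose centroids lie
// within dist_tol of the plane.
// [[Rcpp::export]]
IntegerVector cpp_plane_score(NumericMatrix C, NumericMatrix N,
                              NumericMatrix cand_p, NumericMatrix cand_n,
                              double cos_min, double dist_tol) {
  const int nf = C.nrow(), nc = cand_p.nrow();
  IntegerVector out(nc);
  for (int c = 0; c < nc; ++c) {
    double px = cand_p(c, 0), py = cand_p(c, 1), pz = cand_p(c, 2);
    double nx = cand_n(c, 0), ny = cand_n(c, 1), nz = cand_n(c, 2);
    double d0 = px * nx + py * ny + pz * nz;
    int cnt = 0;
    for (int i = 0; i < nf; ++i) {
      if (N(i, 0) * nx + N(i, 1) * ny + N(i, 2) * nz < cos_min) continue;
      double dd = C(i, 0) * nx + C(i, 1) * ny + C(i, 2) * nz - d0;
      if (dd <= dist_tol && dd >= -dist_tol) ++cnt;
    }
    out[c] = cnt;
  }
  return out;
}

// Trilinear interpolation of a voxel field at world-coordinate points.
// [[Rcpp::export]]
NumericVector cpp_sample_field(NumericVector field, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *f = REAL(field);
  const int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p)
    out[p] = trilerp(f, nx, ny, nz,
                     (pts(p, 0) - origin[0]) / spacing[0],
                     (pts(p, 1) - origin[1]) / spacing[1],
                     (pts(p, 2) - origin[2]) / spacing[2]);
  return out;
}

// For each query point (world mm), the label of the nearest foreground voxel,
// searched over growing Chebyshev shells around the containing voxel.
// [[Rcpp::export]]
IntegerVector cpp_nearest_label(NumericMatrix pts, IntegerVector labels,
                                IntegerVector dim, NumericVector spacing,
                                NumericVector origin, int maxr) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = pts.nrow();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    double xi = (pts(p, 0) - origin[0]) / spacing[0];
    double yi = (pts(p, 1) - origin[1]) / spacing[1];
    double zi = (pts(p, 2) - origin[2]) / spacing[2];
    int ci = (int) std::lround(xi), cj = (int) std::lround(yi),
        ck = (int) std::lround(zi);
    int best = 0; double bestd = R_PosInf;
    int hit_shell = -1;
    for (int r = 0; r <= maxr; ++r) {
      if (hit_shell >= 0 && r > hit_shell) break;
      for (int dk = -r; dk <= r; ++dk)
        for (int dj = -r; dj <= r; ++dj)
          for (int di = -r; di <= r; ++di) {
            if (std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk))) != r)
              continue;  // shell only
            int i = ci + di, j = cj + dj, k = ck + dk;
            if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
              continue;
            int lab = labels[idx3(i, j, k, nx, ny)];
            if (lab <= 0) continue;
            double dx = (i - xi) * spacing[0], dy = (j - yi) * spacing[1],
                   dz = (k - zi) * spacing[2];
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < bestd) { bestd = d2; best = lab; }
          }
      if (best && hit_shell < 0) hit_shell = r;
    }
    out[p] = best;
  }
  return out;
}
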