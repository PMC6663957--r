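// Siddon raytracing kernels: exact voxel/ray intersection lengths and the
// matched forward/back projector pair built on them.  The voxel grid is
// axis-aligned, centered at `origin`, with half-open voxel intervals
// [low, high) along each axis so boundary-touching rays are never counted
// twice.  Images are stored x-fastest (R array dim c(nx, ny, nz)).
#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

struct Grid {
  int n[3];
  double v[3];   // voxel size
  double lo[3];  // lower corner
};

static Grid make_grid(const IntegerVector& dims, const NumericVector& voxsize,
                      const NumericVector& origin) {
  Grid g;
  for (int a = 0; a < 3; ++a) {
    g.n[a] = dims[a];
    g.v[a] = voxsize[a];
    g.lo[a] = origin[a] - 0.5 * dims[a] * voxsize[a];
  }
  return g;
}

// clip the parametric ray p1 + a*(p2-p1), a in [0,1], to the grid box
static bool clip_ray(const double* p1, const double* d, const Grid& g,
                     double& a0, double& a1) {
  a0 = 0.0;
  a1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    double hi = g.lo[a] + g.n[a] * g.v[a];
    if (std::fabs(d[a]) < 1e-12) {
      if (p1[a] < g.lo[a] || p1[a] >= hi) return false;
    } else {
      double t0 = (g.lo[a] - p1[a]) / d[a];
      double t1 = (hi - p1[a]) / d[a];
      if (t0 > t1) std::swap(t0, t1);
      if (t0 > a0) a0 = t0;
      if (t1 < a1) a1 = t1;
    }
  }
  return a1 > a0 + 1e-15;
}

// walk the ray, calling emit(linear_voxel, length_mm) per traversed voxel.
// Voxel identity is decided by the segment midpoint, which is robust at
// boundaries and implements the half-open convention.
template <class F>
static void traverse(const double* p1, const double* p2, const Grid& g,
                     F emit) {
  double d[3] = { p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2] };
  double a0, a1;
  if (!clip_ray(p1, d, g, a0, a1)) return;
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0.0) return;

  double anext[3], dalpha[3];
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      anext[a] = DBL_MAX;
      dalpha[a] = DBL_MAX;
    } else {
      dalpha[a] = g.v[a] / std::fabs(d[a]);
      double pos = p1[a] + a0 * d[a];
      double f = (pos - g.lo[a]) / g.v[a];
      double bnd;
      if (d[a] > 0) {
        bnd = std::floor(f) + 1.0;
        // entry exactly on a boundary: first crossing is one voxel ahead
        if (bnd - f < 1e-12) bnd += 1.0;
      } else {
        bnd = std::ceil(f) - 1.0; // integral f (on-boundary entry) included
      }
      anext[a] = (g.lo[a] + bnd * g.v[a] - p1[a]) / d[a];
      if (anext[a] <= a0 + 1e-15) anext[a] += dalpha[a];
    }
  }

  double alpha = a0;
  while (alpha < a1 - 1e-15) {
    double an = a1;
    if (anext[0] < an) an = anext[0];
    if (anext[1] < an) an = anext[1];
    if (anext[2] < an) an = anext[2];
    double amid = 0.5 * (alpha + an);
    int ix = (int)std::floor((p1[0] + amid * d[0] - g.lo[0]) / g.v[0]);
    int iy = (int)std::floor((p1[1] + amid * d[1] - g.lo[1]) / g.v[1]);
    int iz = (int)std::floor((p1[2] + amid * d[2] - g.lo[2]) / g.v[2]);
    double len = (an - alpha) * L;
    if (len > 0.0 &&
        ix >= 0 && ix < g.n[0] && iy >= 0 && iy < g.n[1] &&
        iz >= 0 && iz < g.n[2]) {
      emit(ix + g.n[0] * (iy + (R_xlen_t)g.n[1] * iz), len);
    }
    for (int a = 0; a < 3; ++a) {
      if (anext[a] <= an + 1e-15) anext[a] += dalpha[a];
    }
    alpha = an;
  }
}

// [[Rcpp::export]]
List cpp_siddon_path(NumericVector p1, NumericVector p2, IntegerVector dims,
                     NumericVector voxsize, NumericVector origin) {
  Grid g = make_grid(dims, voxsize, origin);
  std::vector<int> vox;
  std::vector<double> len;
  traverse(&p1[0], &p2[0], g, [&](R_xlen_t lin, double l) {
    vox.push_back((int)lin);
    len.push_back(l);
  });
  return List::create(_["voxel"] = wrap(vox), _["length"] = wrap(len));
}

// symmetric tangential ray offsets spanning one crystal pitch
static void ray_offsets(int n_rays, double pitch, std::vector<double>& off) {
  off.resize(n_rays);
  if (n_rays == 1) {
    off[0] = 0.0;
    return;
  }
  for (int k = 0; k < n_rays; ++k) {
    off[k] = pitch * ((k + 0.5) / n_rays - 0.5);
  }
}

// unit vector perpendicular to the LOR within the transaxial plane
static void tang_dir(const double* p1, const double* p2, double* t) {
  double dx = p2[0] - p1[0], dy = p2[1] - p1[1];
  double nrm = std::sqrt(dx * dx + dy * dy);
  if (nrm < 1e-12) {
    t[0] = 1.0;
    t[1] = 0.0;
  } else {
    t[0] = -dy / nrm;
    t[1] = dx / nrm;
  }
  t[2] = 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_forward_rays(NumericVector img, IntegerVector dims,
                               NumericVector voxsize, NumericVector origin,
                               NumericMatrix P1, NumericMatrix P2,
                               int n_rays, double pitch) {
  Grid g = make_grid(dims, voxsize, origin);
  R_xlen_t nb = P1.nrow();
  NumericVector out(nb);
  std::vector<double> off;
  ray_offsets(n_rays, pitch, off);
  const double* im = &img[0];
  for (R_xlen_t b = 0; b < nb; ++b) {
    double p1[3] = { P1(b, 0), P1(b, 1), P1(b, 2) };
    double p2[3] = { P2(b, 0), P2(b, 1), P2(b, 2) };
    double td[3];
    tang_dir(p1, p2, td);
    double acc = 0.0;
    for (int k = 0; k < n_rays; ++k) {
      double q1[3] = { p1[0] + off[k] * td[0], p1[1] + off[k] * td[1], p1[2] };
      double q2[3] = { p2[0] + off[k] * td[0], p2[1] + off[k] * td[1], p2[2] };
      traverse(q1, q2, g, [&](R_xlen_t lin, double l) { acc += l * im[lin]; });
    }
    out[b] = acc / n_rays;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_back_rays(NumericVector q, IntegerVector dims,
                            NumericVector voxsize, NumericVector origin,
                            NumericMatrix P1, NumericMatrix P2,
                            int n_rays, double pitch) {
  Grid g = make_grid(dims, voxsize, origin);
  R_xlen_t nb = P1.nrow();
  R_xlen_t nvox = (R_xlen_t)dims[0] * dims[1] * dims[2];
  NumericVector out(nvox);
  double* im = &out[0];
  std::vector<double> off;
  ray_offsets(n_rays, pitch, off);
  for (R_xlen_t b = 0; b < nb; ++b) {
    double w = q[b] / n_rays;
    if (w == 0.0) continue;
    double p1[3] = { P1(b, 0), P1(b, 1), P1(b, 2) };
    double p2[3] = { P2(b, 0), P2(b, 1), P2(b, 2) };
    double td[3];
    tang_dir(p1, p2, td);
    for (int k = 0; k < n_rays; ++k) {
      double q1[3] = { p1[0] + off[k] * td[0], p1[1] + off[k] * td[1], p1[2] };
      double q2[3] = { p2[0] + off[k] * td[0], p2[1] + off[k] * td[1], p2[2] };
      traverse(q1, q2, g, [&](R_xlen_t lin, double l) { im[lin] += w * l; });
    }
  }
  return out;
}

// sparse system-matrix triplets for a bin subset (row caching support)
// [[Rcpp::export]]
List cpp_system_rows(IntegerVector dims, NumericVector voxsize,
                     NumericVector origin, NumericMatrix P1, NumericMatrix P2,
                     int n_rays, double pitch) {
  Grid g = make_grid(dims, voxsize, origin);
  R_xlen_t nb = P1.nrow();
  std::vector<int> bi, vj;
  std::vector<double> x;
  std::vector<double> off;
  ray_offsets(n_rays, pitch, off);
  for (R_xlen_t b = 0; b < nb; ++b) {
    double p1[3] = { P1(b, 0), P1(b, 1), P1(b, 2) };
    double p2[3] = { P2(b, 0), P2(b, 1), P2(b, 2) };
    double td[3];
    tang_dir(p1, p2, td);
    for (int k = 0; k < n_rays; ++k) {
      double q1[3] = { p1[0] + off[k] * td[0], p1[1] + off[k] * td[1], p1[2] };
      double q2[3] = { p2[0] + off[k] * td[0], p2[1] + off[k] * td[1], p2[2] };
      traverse(q1, q2, g, [&](R_xlen_t lin, double l) {
        bi.push_back((int)b);
        vj.push_back((int)lin);
        x.push_back(l / n_rays);
      });
    }
  }
  return List::create(_["i"] = wrap(bi), _["j"] = wrap(vj),
                      _["x"] = wrap(x));
}
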