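#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Parametric traversal of a 2D regular grid (Siddon). The grid is described by
// the world position of the centre of voxel (0,0) and the voxel pitch; the ray
// runs from p1 to p2 and the visitor receives each traversed voxel with the
// exact intersection length in mm.
template <typename F>
static inline void siddon_walk(double ex, double ey, double dx, double dy,
                               int nx, int ny,
                               double p1x, double p1y, double p2x, double p2y,
                               F&& visit) {
  const double ux = p2x - p1x, uy = p2y - p1y;
  const double L = std::sqrt(ux * ux + uy * uy);
  if (L <= 0.0) return;

  double tmin = 0.0, tmax = 1.0;
  const double gx1 = ex + nx * dx, gy1 = ey + ny * dy;

  if (std::abs(ux) < 1e-14) {
    if (p1x <= ex || p1x >= gx1) return;
  } else {
    double t1 = (ex - p1x) / ux, t2 = (gx1 - p1x) / ux;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  }
  if (std::abs(uy) < 1e-14) {
    if (p1y <= ey || p1y >= gy1) return;
  } else {
    double t1 = (ey - p1y) / uy, t2 = (gy1 - p1y) / uy;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  }
  if (tmin >= tmax) return;

  // entry voxel, nudged inside to dodge exact-boundary floor ambiguity
  const double tnudge = tmin + 1e-12 * (tmax - tmin);
  int ix = (int)std::floor((p1x + tnudge * ux - ex) / dx);
  int iy = (int)std::floor((p1y + tnudge * uy - ey) / dy);
  ix = std::min(std::max(ix, 0), nx - 1);
  iy = std::min(std::max(iy, 0), ny - 1);

  const double INF = std::numeric_limits<double>::infinity();
  int sx = 0, sy = 0;
  double tx = INF, ty = INF, dtx = INF, dty = INF;
  if (ux > 0) { sx = 1;  tx = (ex + (ix + 1) * dx - p1x) / ux; dtx = dx / ux; }
  if (ux < 0) { sx = -1; tx = (ex + ix * dx - p1x) / ux;       dtx = -dx / ux; }
  if (uy > 0) { sy = 1;  ty = (ey + (iy + 1) * dy - p1y) / uy; dty = dy / uy; }
  if (uy < 0) { sy = -1; ty = (ey + iy * dy - p1y) / uy;       dty = -dy / uy; }

  double t = tmin;
  while (t < tmax - 1e-13) {
    double tn = std::min(std::min(tx, ty), tmax);
    if (tn > t) visit(ix, iy, (tn - t) * L);
    if (tn >= tmax) break;
    if (tx <= ty) { ix += sx; tx += dtx; }
    else          { iy += sy; ty += dty; }
    t = tn;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
  }
}

// Line integrals of a piecewise-constant image along each ray.
// [[Rcpp::export]]
NumericVector cpp_siddon_integral(NumericMatrix img,
                                  double x0, double y0, double dx, double dy,
                                  NumericVector p1x, NumericVector p1y,
                                  NumericVector p2x, NumericVector p2y) {
  const int nx = img.nrow(), ny = img.ncol();
  const double ex = x0 - 0.5 * dx, ey = y0 - 0.5 * dy;
  const double* v = REAL(img);
  const R_xlen_t n = p1x.size();
  NumericVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    double acc = 0.0;
    siddon_walk(ex, ey, dx, dy, nx, ny, p1x[r], p1y[r], p2x[r], p2y[r],
                [&](int ix, int iy, double seg) { acc += v[ix + (R_xlen_t)nx * iy] * seg; });
    out[r] = acc;
  }
  return out;
}

// Weighted forward projection of many rays accumulated into bins:
// out[bin[r]] += w[r] * integral(ray r). bin is 0-based.
// [[Rcpp::export]]
NumericVector cpp_siddon_forward(NumericMatrix img,
                                 double x0, double y0, double dx, double dy,
                                 NumericVector p1x, NumericVector p1y,
                                 NumericVector p2x, NumericVector p2y,
                                 IntegerVector bin, NumericVector w, int nbins) {
  const int nx = img.nrow(), ny = img.ncol();
  const double ex = x0 - 0.5 * dx, ey = y0 - 0.5 * dy;
  const double* v = REAL(img);
  const R_xlen_t n = p1x.size();
  NumericVector out(nbins);
  double* o = REAL(out);
  for (R_xlen_t r = 0; r < n; ++r) {
    double acc = 0.0;
    siddon_walk(ex, ey, dx, dy, nx, ny, p1x[r], p1y[r], p2x[r], p2y[r],
                [&](int ix, int iy, double seg) { acc += v[ix + (R_xlen_t)nx * iy] * seg; });
    o[bin[r]] += w[r] * acc;
  }
  return out;
}

// Exact adjoint of cpp_siddon_forward: deposits w[r] * vals[bin[r]] * seglen.
// [[Rcpp::export]]
NumericMatrix cpp_siddon_back(NumericVector vals, int nx, int ny,
                              double x0, double y0, double dx, double dy,
                              NumericVector p1x, NumericVector p1y,
                              NumericVector p2x, NumericVector p2y,
                              IntegerVector bin, NumericVector w) {
  const double ex = x0 - 0.5 * dx, ey = y0 - 0.5 * dy;
  NumericMatrix out(nx, ny);
  double* o = REAL(out);
  const R_xlen_t n = p1x.size();
  for (R_xlen_t r = 0; r < n; ++r) {
    const double c = w[r] * vals[bin[r]];
    if (c == 0.0) continue;
    siddon_walk(ex, ey, dx, dy, nx, ny, p1x[r], p1y[r], p2x[r], p2y[r],
                [&](int ix, int iy, double seg) { o[ix + (R_xlen_t)nx * iy] += c * seg; });
  }
  return out;
}

// Traversal record of a single ray: 0-based voxel indices and lengths.
// [[Rcpp::export]]
List cpp_siddon_trace(int nx, int ny,
                      double x0, double y0, double dx, double dy,
                      double p1x, double p1y, double p2x, double p2y) {
  const double ex = x0 - 0.5 * dx, ey = y0 - 0.5 * dy;
  std::vector<int> vix, viy;
  std::vector<double> vlen;
  siddon_walk(ex, ey, dx, dy, nx, ny, p1x, p1y, p2x, p2y,
              [&](int ix, int iy, double seg) {
                vix.push_back(ix); viy.push_back(iy); vlen.push_back(seg);
              });
  return List::create(_["ix"] = wrap(vix), _["iy"] = wrap(viy), _["len"] = wrap(vlen));
}
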