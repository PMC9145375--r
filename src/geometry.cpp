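#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Closest-point-on-triangle after Ericson, "Real-Time Collision Detection",
// ch. 5.1.5. Returns squared distance from p to triangle (a,b,c).
static double point_triangle_sqdist(const double *p, const double *a,
                                    const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    return ap[0] * ap[0] + ap[1] * ap[1] + ap[2] * ap[2];
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    return bp[0] * bp[0] + bp[1] * bp[1] + bp[2] * bp[2];
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    double dd = 0.0;
    for (int k = 0; k < 3; ++k) {
      double q = a[k] + v * ab[k] - p[k];
      dd += q * q;
    }
    return dd;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    return cp[0] * cp[0] + cp[1] * cp[1] + cp[2] * cp[2];
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    double dd = 0.0;
    for (int k = 0; k < 3; ++k) {
      double q = a[k] + w * ac[k] - p[k];
      dd += q * q;
    }
    return dd;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double dd = 0.0;
    for (int k = 0; k < 3; ++k) {
      double q = b[k] + w * (c[k] - b[k]) - p[k];
      dd += q * q;
    }
    return dd;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double dd = 0.0;
  for (int k = 0; k < 3; ++k) {
    double q = a[k] + v * ab[k] + w * ac[k] - p[k];
    dd += q * q;
  }
  return dd;
}

// Exact unsigned distance from each query point to the triangle surface.
// Brute force over faces with a centroid-radius reject to skip most of them.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix points, NumericMatrix V,
                                      IntegerMatrix F) {
  const int np = points.nrow(), nf = F.nrow();
  if (V.ncol() != 3 || points.ncol() != 3 || F.ncol() != 3)
    stop("points, V must be n x 3 and F m x 3");
  std::vector<double> tri(9 * (size_t)nf), cen(3 * (size_t)nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    double cx = 0, cy = 0, cz = 0;
    for (int j = 0; j < 3; ++j) {
      int vi = F(f, j) - 1;
      if (vi < 0 || vi >= V.nrow()) stop("face index out of range");
      tri[9 * (size_t)f + 3 * j + 0] = V(vi, 0);
      tri[9 * (size_t)f + 3 * j + 1] = V(vi, 1);
      tri[9 * (size_t)f + 3 * j + 2] = V(vi, 2);
      cx += V(vi, 0); cy += V(vi, 1); cz += V(vi, 2);
    }
    cx /= 3.0; cy /= 3.0; cz /= 3.0;
    cen[3 * (size_t)f + 0] = cx;
    cen[3 * (size_t)f + 1] = cy;
    cen[3 * (size_t)f + 2] = cz;
    double r2 = 0.0;
    for (int j = 0; j < 3; ++j) {
      double dx = tri[9 * (size_t)f + 3 * j + 0] - cx;
      double dy = tri[9 * (size_t)f + 3 * j + 1] - cy;
      double dz = tri[9 * (size_t)f + 3 * j + 2] - cz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double best = std::numeric_limits<double>::infinity();
    double bestd = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      double dx = p[0] - cen[3 * (size_t)f + 0];
      double dy = p[1] - cen[3 * (size_t)f + 1];
      double dz = p[2] - cen[3 * (size_t)f + 2];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[f];
      if (dc >= bestd) continue;
      double d2 = point_triangle_sqdist(p, &tri[9 * (size_t)f],
                                        &tri[9 * (size_t)f + 3],
                                        &tri[9 * (size_t)f + 6]);
      if (d2 < best) {
        best = d2;
        bestd = std::sqrt(d2);
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Generalized winding number of each query point with respect to a closed
// oriented triangle mesh; ~1 inside, ~0 outside. Solid angle per triangle by
// the van Oosterom & Strackee formula.
// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix points, NumericMatrix V,
                                 IntegerMatrix F) {
  const int np = points.nrow(), nf = F.nrow();
  std::vector<double> tri(9 * (size_t)nf);
  for (int f = 0; f < nf; ++f)
    for (int j = 0; j < 3; ++j) {
      int vi = F(f, j) - 1;
      if (vi < 0 || vi >= V.nrow()) stop("face index out of range");
      tri[9 * (size_t)f + 3 * j + 0] = V(vi, 0);
      tri[9 * (size_t)f + 3 * j + 1] = V(vi, 1);
      tri[9 * (size_t)f + 3 * j + 2] = V(vi, 2);
    }
  const double fourpi = 4.0 * M_PI;
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double total = 0.0;
    for (int f = 0; f < nf; ++f) {
      double a[3], b[3], c[3];
      for (int k = 0; k < 3; ++k) {
        a[k] = tri[9 * (size_t)f + 0 + k] - p[k];
        b[k] = tri[9 * (size_t)f + 3 + k] - p[k];
        c[k] = tri[9 * (size_t)f + 6 + k] - p[k];
      }
      double la = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
      double lb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
      double lc = std::sqrt(c[0] * c[0] + c[1] * c[1] + c[2] * c[2]);
      double num = a[0] * (b[1] * c[2] - b[2] * c[1]) -
                   a[1] * (b[0] * c[2] - b[2] * c[0]) +
                   a[2] * (b[0] * c[1] - b[1] * c[0]);
      double den = la * lb * lc +
                   (a[0] * b[0] + a[1] * b[1] + a[2] * b[2]) * lc +
                   (b[0] * c[0] + b[1] * c[1] + b[2] * c[2]) * la +
                   (c[0] * a[0] + c[1] * a[1] + c[2] * a[2]) * lb;
      total += 2.0 * std::atan2(num, den);
    }
    out[i] = total / fourpi;
  }
  return out;
}
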