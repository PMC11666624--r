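#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One-sided quadratic fit shared by the row-level operation and the full
// volume Laplacian. x in voxel units (target at 0), y phase in radians.
struct SideFit {
  double d2;      // second derivative, rad / voxel^2
  double corr;    // Pearson corr between fitted and measured phase
  bool usable;    // >= 3 points and well-posed normal equations
};

static SideFit fit_quadratic_side(const std::vector<double> &x,
                                  const std::vector<double> &y) {
  SideFit out;
  out.d2 = NA_REAL;
  out.corr = NA_REAL;
  out.usable = false;
  const int n = (int)x.size();
  if (n < 3) return out;

  double s1 = 0, s2 = 0, s3 = 0, s4 = 0, t0 = 0, t1 = 0, t2 = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], x2 = xi * xi;
    s1 += xi; s2 += x2; s3 += x2 * xi; s4 += x2 * x2;
    t0 += y[i]; t1 += y[i] * xi; t2 += y[i] * x2;
  }
  // Normal equations M c = t for c = (c0, c1, c2), phi ~ c0 + c1 x + c2 x^2
  const double m00 = n,  m01 = s1, m02 = s2;
  const double m11 = s2, m12 = s3, m22 = s4;
  const double det = m00 * (m11 * m22 - m12 * m12)
                   - m01 * (m01 * m22 - m12 * m02)
                   + m02 * (m01 * m12 - m11 * m02);
  if (std::fabs(det) < 1e-12) return out;
  const double c0 = ( t0 * (m11 * m22 - m12 * m12)
                    - m01 * (t1 * m22 - m12 * t2)
                    + m02 * (t1 * m12 - m11 * t2)) / det;
  const double c1 = ( m00 * (t1 * m22 - t2 * m12)
                    - t0 * (m01 * m22 - m12 * m02)
                    + m02 * (m01 * t2 - t1 * m02)) / det;
  const double c2 = ( m00 * (m11 * t2 - m12 * t1)
                    - m01 * (m01 * t2 - t1 * m02)
                    + t0 * (m01 * m12 - m11 * m02)) / det;

  // Pearson correlation between fitted and measured values over the side.
  double my = t0 / n, mf = 0;
  std::vector<double> f(n);
  for (int i = 0; i < n; ++i) {
    f[i] = c0 + c1 * x[i] + c2 * x[i] * x[i];
    mf += f[i];
  }
  mf /= n;
  double vy = 0, vf = 0, cv = 0;
  for (int i = 0; i < n; ++i) {
    const double dy = y[i] - my, df = f[i] - mf;
    vy += dy * dy; vf += df * df; cv += dy * df;
  }
  double corr;
  if (vy < 1e-24) {
    corr = 1.0;          // constant measured phase: an exact (constant) fit
  } else if (vf < 1e-24) {
    corr = 0.0;          // fit flat while data vary: reject
  } else {
    corr = cv / std::sqrt(vy * vf);
  }
  out.d2 = 2.0 * c2;
  out.corr = corr;
  out.usable = true;
  return out;
}

struct AxisFit {
  double d2;       // mean of usable one-sided second derivatives, rad/voxel^2
  bool accepted;   // >= 1 usable side and every used side corr > min_corr
  double corr;     // min corr over used sides (NA if none usable)
};

// One axis through a target: left/right phase samples ordered outward from
// the target (position 1..reach). NA entries mark excluded/missing voxels.
static AxisFit fit_axis(double target,
                        const std::vector<double> &left,
                        const std::vector<double> &right,
                        double min_corr) {
  AxisFit out;
  out.d2 = NA_REAL;
  out.accepted = false;
  out.corr = NA_REAL;

  std::vector<double> xs, ys;
  double sum_d2 = 0, min_c = 2.0;
  int used = 0;
  for (int side = 0; side < 2; ++side) {
    const std::vector<double> &s = side == 0 ? left : right;
    const double sgn = side == 0 ? -1.0 : 1.0;
    xs.clear(); ys.clear();
    xs.push_back(0.0); ys.push_back(target);
    for (size_t k = 0; k < s.size(); ++k) {
      if (!ISNAN(s[k])) {
        xs.push_back(sgn * (double)(k + 1));
        ys.push_back(s[k]);
      }
    }
    if ((int)xs.size() < 3) continue;  // < 2 usable side voxels: side dropped
    SideFit f = fit_quadratic_side(xs, ys);
    if (!f.usable) continue;
    sum_d2 += f.d2;
    if (f.corr < min_c) min_c = f.corr;
    ++used;
  }
  if (used == 0) return out;
  out.d2 = sum_d2 / used;
  out.corr = min_c;
  out.accepted = (min_c > min_corr);
  return out;
}

inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
List cpp_parfit_row(NumericVector samples, int center, double spacing,
                    double min_corr, int reach) {
  // center is 0-based index of the target within `samples`
  const int n = samples.size();
  if (center < 0 || center >= n) stop("target index out of range");
  if (ISNAN(samples[center])) stop("target sample is NA");
  std::vector<double> left, right;
  for (int k = 1; k <= reach; ++k) {
    left.push_back(center - k >= 0 ? samples[center - k] : NA_REAL);
    right.push_back(center + k < n ? samples[center + k] : NA_REAL);
  }
  AxisFit f = fit_axis(samples[center], left, right, min_corr);
  double d2 = ISNAN(f.d2) ? NA_REAL : f.d2 / (spacing * spacing);
  return List::create(_["second_derivative"] = d2,
                      _["accepted"] = f.accepted,
                      _["fit_corr"] = f.corr);
}

// [[Rcpp::export]]
List cpp_laplacian(NumericVector phase, NumericVector mag, IntegerVector labels,
                   IntegerVector dim, NumericVector spacing_m,
                   IntegerVector reach, double amp_tol, double min_corr,
                   int min_neighbors) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int N = nx * ny * nz;
  NumericVector lap(N, NA_REAL);
  LogicalVector valid(N, false);
  IntegerVector ncount(N, 0);
  const int rx = reach[0], ry = reach[1], rz = reach[2];
  const double *ph = REAL(phase), *mg = REAL(mag);
  const int *lb = INTEGER(labels);

  // precomputed linear offsets of the kernel box (target excluded)
  std::vector<int> boxOff;
  boxOff.reserve((2 * rx + 1) * (2 * ry + 1) * (2 * rz + 1) - 1);
  for (int dk = -rz; dk <= rz; ++dk)
    for (int dj = -ry; dj <= ry; ++dj)
      for (int di = -rx; di <= rx; ++di)
        if (di || dj || dk) boxOff.push_back(di + nx * (dj + ny * dk));
  const int nBox = (int)boxOff.size();

  std::vector<double> left, right;
  left.reserve(8); right.reserve(8);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = idx3(i, j, k, nx, ny);
        const int lab = lb[v];
        if (lab <= 0) continue;
        const double pm = mg[v];
        const double pt = ph[v];
        if (ISNAN(pt)) continue;
        const double tol = amp_tol * pm;
        const bool interior = i >= rx && i < nx - rx && j >= ry &&
                              j < ny - ry && k >= rz && k < nz - rz;

        // 3D neighbourhood count inside the kernel box, same tissue,
        // amplitude within amp_tol of the target.
        int cnt = 0;
        if (interior) {
          for (int b = 0; b < nBox; ++b) {
            const int w = v + boxOff[b];
            if (lb[w] == lab && std::fabs(mg[w] - pm) <= tol &&
                !ISNAN(ph[w]))
              ++cnt;
          }
        } else {
          for (int dk = -rz; dk <= rz; ++dk) {
            const int kk = k + dk;
            if (kk < 0 || kk >= nz) continue;
            for (int dj = -ry; dj <= ry; ++dj) {
              const int jj = j + dj;
              if (jj < 0 || jj >= ny) continue;
              for (int di = -rx; di <= rx; ++di) {
                const int ii = i + di;
                if (ii < 0 || ii >= nx) continue;
                if (di == 0 && dj == 0 && dk == 0) continue;
                const int w = idx3(ii, jj, kk, nx, ny);
                if (lb[w] != lab) continue;
                if (std::fabs(mg[w] - pm) > tol) continue;
                if (ISNAN(ph[w])) continue;
                ++cnt;
              }
            }
          }
        }
        ncount[v] = cnt;

        double sum = 0;
        bool all_ok = true;
        for (int ax = 0; ax < 3 && all_ok; ++ax) {
          const int r = ax == 0 ? rx : (ax == 1 ? ry : rz);
          const int stride = ax == 0 ? 1 : (ax == 1 ? nx : nx * ny);
          const int pos = ax == 0 ? i : (ax == 1 ? j : k);
          const int npos = ax == 0 ? nx : (ax == 1 ? ny : nz);
          left.assign(r, NA_REAL);
          right.assign(r, NA_REAL);
          for (int s = 1; s <= r; ++s) {
            if (pos - s >= 0) {
              const int w = v - s * stride;
              if (lb[w] == lab && std::fabs(mg[w] - pm) <= tol &&
                  !ISNAN(ph[w]))
                left[s - 1] = ph[w];
            }
            if (pos + s < npos) {
              const int w = v + s * stride;
              if (lb[w] == lab && std::fabs(mg[w] - pm) <= tol &&
                  !ISNAN(ph[w]))
                right[s - 1] = ph[w];
            }
          }
          AxisFit f = fit_axis(pt, left, right, min_corr);
          if (!f.accepted) { all_ok = false; break; }
          const double h = spacing_m[ax];
          sum += f.d2 / (h * h);
        }
        if (all_ok) {
          lap[v] = sum;
          valid[v] = (cnt >= min_neighbors);
        }
      }

  return List::create(_["values"] = lap, _["valid"] = valid,
                      _["neighbor_count"] = ncount);
}
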