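#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Explicit Perona-Malik diffusion with sigmoid conductance
// g(|d|) = 1 / (1 + exp((|d| - kappa) / slope)), face differences d in
// rad/voxel, masked updates, reflecting (no-flux) boundaries: flux only
// between pairs of in-mask voxels, so the in-mask mean is conserved.
// [[Rcpp::export]]
NumericVector cpp_diffuse(NumericVector phase, LogicalVector mask,
                          IntegerVector dim, int iters, double dt,
                          double kappa, double slope) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int N = nx * ny * nz;
  NumericVector cur = clone(phase);
  NumericVector nxt(N);
  const int off_i[3] = {1, 0, 0};
  const int off_j[3] = {0, 1, 0};
  const int off_k[3] = {0, 0, 1};

  for (int it = 0; it < iters; ++it) {
    for (int v = 0; v < N; ++v) nxt[v] = cur[v];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int v = idx3(i, j, k, nx, ny);
          if (!mask[v]) continue;
          double acc = 0;
          for (int a = 0; a < 3; ++a) {
            for (int s = -1; s <= 1; s += 2) {
              const int ii = i + s * off_i[a];
              const int jj = j + s * off_j[a];
              const int kk = k + s * off_k[a];
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
                  kk < 0 || kk >= nz)
                continue;
              const int w = idx3(ii, jj, kk, nx, ny);
              if (!mask[w]) continue;
              const double d = cur[w] - cur[v];
              const double g = 1.0 / (1.0 + std::exp((std::fabs(d) - kappa) / slope));
              acc += g * d;
            }
          }
          nxt[v] = cur[v] + dt * acc;
        }
    std::swap(cur, nxt);
  }
  return cur;
}
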