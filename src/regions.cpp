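#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// 6-connected components of equal-class voxels (class 0 = outside mask).
// Returns labels 1..R, 0 outside.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector cls, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int N = nx * ny * nz;
  IntegerVector lab(N, 0);
  std::vector<int> stack;
  int next = 0;
  const int off_i[3] = {1, 0, 0}, off_j[3] = {0, 1, 0}, off_k[3] = {0, 0, 1};

  for (int v0 = 0; v0 < N; ++v0) {
    if (cls[v0] == 0 || lab[v0] != 0) continue;
    const int c = cls[v0];
    ++next;
    lab[v0] = next;
    stack.clear();
    stack.push_back(v0);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int k = v / (nx * ny);
      const int j = (v - k * nx * ny) / nx;
      const int i = v - nx * (j + ny * k);
      for (int a = 0; a < 3; ++a)
        for (int s = -1; s <= 1; s += 2) {
          const int ii = i + s * off_i[a];
          const int jj = j + s * off_j[a];
          const int kk = k + s * off_k[a];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          const int w = idx3(ii, jj, kk, nx, ny);
          if (cls[w] == c && lab[w] == 0) {
            lab[w] = next;
            stack.push_back(w);
          }
        }
    }
  }
  return lab;
}

// All face-adjacent voxel pairs whose region labels differ (both > 0),
// each unordered pair once, with the two wrapped phase values.
// [[Rcpp::export]]
List cpp_region_faces(IntegerVector lab, NumericVector phase,
                      IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> ra, rb;
  std::vector<double> pa, pb;
  const int off_i[3] = {1, 0, 0}, off_j[3] = {0, 1, 0}, off_k[3] = {0, 0, 1};

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = idx3(i, j, k, nx, ny);
        if (lab[v] == 0) continue;
        for (int a = 0; a < 3; ++a) {
          const int ii = i + off_i[a], jj = j + off_j[a], kk = k + off_k[a];
          if (ii >= nx || jj >= ny || kk >= nz) continue;
          const int w = idx3(ii, jj, kk, nx, ny);
          if (lab[w] == 0 || lab[w] == lab[v]) continue;
          ra.push_back(lab[v]);
          rb.push_back(lab[w]);
          pa.push_back(phase[v]);
          pb.push_back(phase[w]);
        }
      }
  return List::create(_["a"] = wrap(ra), _["b"] = wrap(rb),
                      _["pa"] = wrap(pa), _["pb"] = wrap(pb));
}
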