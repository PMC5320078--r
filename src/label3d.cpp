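#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling on a logical array stored in R's
// column-major order (x fastest, then y, then z). Components are labeled
// 1, 2, ... in raster order of their first voxel, which makes the labeling
// (and any smallest-label tie-break downstream) deterministic.
//
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// A single-slice volume with connectivity 26 reduces to 2D 8-connectivity.

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // build neighbour offset table
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int nonzero = (cx != 0) + (cy != 0) + (cz != 0);
        if (nonzero == 0) continue;
        if (connectivity == 6 && nonzero > 1) continue;
        if (connectivity == 18 && nonzero > 2) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nnb = (int)dx.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++current;
    labels[i] = current;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int vx = (int)(v % nx);
      int vy = (int)((v / nx) % ny);
      int vz = (int)(v / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nnb; ++k) {
        int ux = vx + dx[k], uy = vy + dy[k], uz = vz + dz[k];
        if (ux < 0 || ux >= nx || uy < 0 || uy >= ny || uz < 0 || uz >= nz)
          continue;
        R_xlen_t u = ux + (R_xlen_t)nx * (uy + (R_xlen_t)ny * uz);
        if (mask[u] && labels[u] == 0) {
          labels[u] = current;
          stack.push_back(u);
        }
      }
    }
  }
  labels.attr("max_label") = current;
  return labels;
}
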