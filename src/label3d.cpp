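#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling on a logical (z,y,x) array.
// connectivity: 6 (faces) or 26 (faces+edges+corners). Iterative BFS so
// deep components cannot overflow the C stack. Labels are dense 1..K in
// first-voxel scan order, background stays 0.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;

  // neighbour offsets in (dz,dy,dx)
  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        if (az == 0 && ay == 0 && ax == 0) continue;
        int manh = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const size_t nnb = dz.size();

  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> queue;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    lab[i] = ++next;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int cz = (int)(cur % nz);
      int cy = (int)((cur / nz) % ny);
      int cx = (int)(cur / ((R_xlen_t)nz * ny));
      for (size_t k = 0; k < nnb; ++k) {
        int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t j = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] == TRUE && lab[j] == 0) {
          lab[j] = next;
          queue.push_back(j);
        }
      }
    }
  }
  return lab;
}
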