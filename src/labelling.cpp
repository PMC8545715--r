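#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Offsets for 6- (face) and 26- (face+edge+vertex) neighbourhoods.
static void neighbour_offsets(int connectivity, std::vector<int>& dx,
                              std::vector<int>& dy, std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  if (connectivity == 6) {
    const int ox[6] = {-1, 1, 0, 0, 0, 0};
    const int oy[6] = {0, 0, -1, 1, 0, 0};
    const int oz[6] = {0, 0, 0, 0, -1, 1};
    for (int i = 0; i < 6; ++i) { dx.push_back(ox[i]); dy.push_back(oy[i]); dz.push_back(oz[i]); }
  } else {
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
        }
  }
}

// Label connected components of a 3D logical mask (column-major, dims nx,ny,nz).
// Labels are assigned in scan order of each component's first voxel, so label 1
// is the component containing the smallest linear index: deterministic and
// equivalent to lexicographic (z, y, x) ordering for column-major storage.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();

  IntegerVector labels(n, 0);
  int next_label = 0;
  std::queue<R_xlen_t> q;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      const int x = (int)(v % nx);
      const int y = (int)((v / nx) % ny);
      const int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nn; ++k) {
        const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          q.push(w);
        }
      }
    }
  }
  return labels;
}

// Count voxels of a 3D mask having at least one face-adjacent neighbour that
// is outside the mask; the volume boundary counts as outside.
// [[Rcpp::export]]
double perimeter_count_cpp(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  double count = 0;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    const int x = (int)(v % nx);
    const int y = (int)((v / nx) % ny);
    const int z = (int)(v / ((R_xlen_t)nx * ny));
    bool boundary =
      (x == 0 || !mask[v - 1]) || (x == nx - 1 || !mask[v + 1]) ||
      (y == 0 || !mask[v - nx]) || (y == ny - 1 || !mask[v + nx]) ||
      (z == 0 || !mask[v - (R_xlen_t)nx * ny]) ||
      (z == nz - 1 || !mask[v + (R_xlen_t)nx * ny]);
    if (boundary) count += 1;
  }
  return count;
}
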