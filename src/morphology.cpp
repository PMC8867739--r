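#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Arrays are R arrays indexed [z, y, x] (column-major): idx = z + nz*(y + ny*x).

// Label connected components of a binary volume (26- or 6-connectivity).
// Returns integer labels, 0 = background, components numbered from 1.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity = 26) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dz, dy, dx});
      }

  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int z = (int)(idx % nz);
      int y = (int)((idx / nz) % ny);
      int x = (int)(idx / ((R_xlen_t)nz * ny));
      for (const auto &o : offs) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] && labels[j] == 0) {
          labels[j] = current;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}

// Fill 2D holes on each axial slice (fixed z): background pixels (4-connected)
// not reachable from the slice border become foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_slicewise_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  LogicalVector out = clone(mask);
  std::vector<char> reach((size_t)ny * nx);
  std::vector<int> stack;

  for (int z = 0; z < nz; ++z) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    auto idx3 = [&](int y, int x) {
      return (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
    };
    // seed from slice border
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; x += (y == 0 || y == ny - 1) ? 1 : nx - 1) {
        if (!mask[idx3(y, x)] && !reach[(size_t)y + (size_t)ny * x]) {
          reach[(size_t)y + (size_t)ny * x] = 1;
          stack.push_back(y + ny * x);
        }
      }
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int y = p % ny, x = p / ny;
      const int dy[4] = {1, -1, 0, 0}, dx[4] = {0, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        int yy = y + dy[k], xx = x + dx[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        size_t q = (size_t)yy + (size_t)ny * xx;
        if (!reach[q] && !mask[idx3(yy, xx)]) {
          reach[q] = 1;
          stack.push_back(yy + ny * xx);
        }
      }
    }
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        if (!mask[idx3(y, x)] && !reach[(size_t)y + (size_t)ny * x])
          out[idx3(y, x)] = true;
  }
  return out;
}
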