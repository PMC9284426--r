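#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Cube median filter with border clamping; radii per axis.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector v, IntegerVector dim,
                                 int rx, int ry, int rz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(v.size());
  std::vector<double> buf;
  buf.reserve((2 * rx + 1) * (2 * ry + 1) * (2 * rz + 1));
  for (int z = 0; z < nz; ++z) {
    const int z0 = std::max(0, z - rz), z1 = std::min(nz - 1, z + rz);
    for (int y = 0; y < ny; ++y) {
      const int y0 = std::max(0, y - ry), y1 = std::min(ny - 1, y + ry);
      for (int x = 0; x < nx; ++x) {
        const int x0 = std::max(0, x - rx), x1 = std::min(nx - 1, x + rx);
        buf.clear();
        for (int zz = z0; zz <= z1; ++zz)
          for (int yy = y0; yy <= y1; ++yy)
            for (int xx = x0; xx <= x1; ++xx)
              buf.push_back(v[idx3(xx, yy, zz, nx, ny)]);
        const size_t h = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + h, buf.end());
        double med = buf[h];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + h - 1, buf.begin() + h);
          med = 0.5 * (med + buf[h - 1]);
        }
        out[idx3(x, y, z, nx, ny)] = med;
      }
    }
  }
  return out;
}

// Local maxima above a threshold within a cube neighborhood. A voxel
// qualifies when no neighbor exceeds it; equal-valued plateaus (median
// filtering flattens peaks into small plateaus) yield a single seed, the
// plateau voxel with the lowest linear index. Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima3(NumericVector v, IntegerVector dim,
                                double threshold, int rx, int ry, int rz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> hits;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = idx3(x, y, z, nx, ny);
        const double val = v[i];
        if (val <= threshold) continue;
        bool is_max = true;
        for (int zz = std::max(0, z - rz); zz <= std::min(nz - 1, z + rz) && is_max; ++zz)
          for (int yy = std::max(0, y - ry); yy <= std::min(ny - 1, y + ry) && is_max; ++yy)
            for (int xx = std::max(0, x - rx); xx <= std::min(nx - 1, x + rx); ++xx) {
              if (xx == x && yy == y && zz == z) continue;
              const int j = idx3(xx, yy, zz, nx, ny);
              if (v[j] > val || (v[j] == val && j < i)) { is_max = false; break; }
            }
        if (is_max) hits.push_back(i + 1);
      }
  return wrap(hits);
}

// Connected-component labeling of a logical mask (6- or 26-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < mask.size(); ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int z = cur / (nx * ny), rem = cur % (nx * ny);
      const int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
              continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            const int j = idx3(xx, yy, zz, nx, ny);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

// Seeded watershed by intensity-ordered flooding: seeds keep their labels,
// unlabeled foreground voxels are claimed by the highest-intensity front
// reaching them first, so boundaries between touching structures follow
// intensity valleys between their maxima. 6-connectivity growth.
// [[Rcpp::export]]
IntegerVector cpp_seeded_watershed3(NumericVector v, IntegerVector dim,
                                    LogicalVector mask, IntegerVector seed_idx,
                                    IntegerVector seed_label) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(v.size(), 0);
  typedef std::pair<double, int> Node; // (intensity, voxel)
  std::priority_queue<Node> pq;
  for (int s = 0; s < seed_idx.size(); ++s) {
    const int i = seed_idx[s] - 1;
    if (i < 0 || i >= v.size() || !mask[i]) continue;
    lab[i] = seed_label[s];
    pq.push(Node(v[i], i));
  }
  const int dx6[6] = {1, -1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, 1, -1, 0, 0};
  const int dz6[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    const int cur = pq.top().second;
    pq.pop();
    const int z = cur / (nx * ny), rem = cur % (nx * ny);
    const int y = rem / nx, x = rem % nx;
    for (int d = 0; d < 6; ++d) {
      const int xx = x + dx6[d], yy = y + dy6[d], zz = z + dz6[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const int j = idx3(xx, yy, zz, nx, ny);
      if (!mask[j] || lab[j]) continue;
      lab[j] = lab[cur];
      pq.push(Node(v[j], j));
    }
  }
  return lab;
}
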