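#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher), ----
// ---- 1D lower envelope of parabolas, applied separably per axis with   ----
// ---- anisotropic voxel spacing                                          ----

static void dt1d(std::vector<double>& f, std::vector<double>& d, double w2) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// squared Euclidean distance (physical units) from every voxel to the
// nearest TRUE voxel of `obstacle`; dims = c(nx, ny, nz), voxel sizes in um
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector obstacle, IntegerVector dim, NumericVector voxel) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double INF = 1e30;
  NumericVector d(obstacle.size());
  for (R_xlen_t i = 0; i < obstacle.size(); ++i)
    d[i] = obstacle[i] ? 0.0 : INF;
  // x pass
  {
    std::vector<double> f(nx), g(nx);
    double w2 = voxel[0] * voxel[0];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) f[x] = d[base + x];
        dt1d(f, g, w2);
        for (int x = 0; x < nx; ++x) d[base + x] = g[x];
      }
  }
  // y pass
  {
    std::vector<double> f(ny), g(ny);
    double w2 = voxel[1] * voxel[1];
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)y * nx];
        dt1d(f, g, w2);
        for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)y * nx] = g[y];
      }
  }
  // z pass
  {
    std::vector<double> f(nz), g(nz);
    double w2 = voxel[2] * voxel[2];
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = d[base + (R_xlen_t)z * nx * ny];
        dt1d(f, g, w2);
        for (int z = 0; z < nz; ++z) d[base + (R_xlen_t)z * nx * ny] = g[z];
      }
  }
  return d;
}

// ---- seeded watershed by immersion: flood the masked region from the ----
// ---- seed voxels in order of decreasing priority (6-connectivity);   ----
// ---- deterministic tie-break on voxel index                          ----

struct QItem {
  double pri;
  R_xlen_t idx;
  long order;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.pri != b.pri) return a.pri < b.pri;   // max-heap on priority
    return a.order > b.order;                   // FIFO on ties
  }
};

// [[Rcpp::export(name = ".watershed3d_cpp")]]
IntegerVector watershed3d_cpp(NumericVector priority, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = priority.size();
  IntegerVector lab(n);
  for (R_xlen_t i = 0; i < n; ++i) lab[i] = seeds[i];
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long counter = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) pq.push({priority[i], i, counter++});
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    R_xlen_t i = it.idx;
    int z = (int)(i / ((R_xlen_t)nx * ny));
    int rem = (int)(i % ((R_xlen_t)nx * ny));
    int y = rem / nx, x = rem % nx;
    int li = lab[i];
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = li;
      pq.push({priority[j], j, counter++});
    }
  }
  return lab;
}

// ---- binary erosion / dilation with an arbitrary structuring element ----
// ---- given as integer offsets (n x 3, zero-centred)                  ----

// [[Rcpp::export(name = ".morph_binary_cpp")]]
LogicalVector morph_binary_cpp(LogicalVector mask, IntegerVector dim,
                               IntegerMatrix offsets, bool erode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = mask.size();
  LogicalVector out(n);
  int m = offsets.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        bool acc = erode;
        for (int k = 0; k < m; ++k) {
          int xx = x + offsets(k, 0), yy = y + offsets(k, 1), zz = z + offsets(k, 2);
          bool v;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            v = false;                       // outside = background
          else
            v = mask[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
          if (erode) { if (!v) { acc = false; break; } }
          else       { if (v)  { acc = true;  break; } }
        }
        out[i] = acc;
      }
  return out;
}

// ---- connected components (6-connectivity) of a logical mask ----

// [[Rcpp::export(name = ".cc3d_cpp")]]
IntegerVector cc3d_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back(); stack.pop_back();
      int z = (int)(i / ((R_xlen_t)nx * ny));
      int rem = (int)(i % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// ---- regional maxima of an integer-valued map: label maximal connected ----
// ---- plateaus of equal value (6-connectivity) that have no higher      ----
// ---- neighbor; returns plateau labels (>0) for regional-max voxels     ----

// [[Rcpp::export(name = ".regmax_cpp")]]
IntegerVector regmax_cpp(IntegerVector vals, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = vals.size();
  IntegerVector lab(n, 0);
  std::vector<char> visited(n, 0);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  int next = 0;
  std::vector<R_xlen_t> stack, members;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (visited[s] || vals[s] <= 0) continue;
    int v = vals[s];
    bool is_regional = true;
    members.clear();
    stack.push_back(s);
    visited[s] = 1;
    while (!stack.empty()) {
      R_xlen_t i = stack.back(); stack.pop_back();
      members.push_back(i);
      int z = (int)(i / ((R_xlen_t)nx * ny));
      int rem = (int)(i % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (vals[j] > v) { is_regional = false; }
        else if (vals[j] == v && !visited[j]) { visited[j] = 1; stack.push_back(j); }
      }
    }
    if (is_regional) {
      ++next;
      for (size_t m = 0; m < members.size(); ++m) lab[members[m]] = next;
    }
  }
  return lab;
}
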