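// Counting kernels for gray-level texture matrices on 3D masked images.
// Inputs are integer level arrays (column-major, dims nx*ny*nz) with 0
// marking voxels outside the region and 1..ng inside.
#include <Rcpp.h>
#include <vector>
#include <cfloat>
using namespace Rcpp;

static const int OFF13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int at(const IntegerVector& lv, int x, int y, int z,
                     int nx, int ny, int nz) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return -1;
  return lv[x + nx * (y + (R_xlen_t)ny * z)];
}

// Symmetric GLCM counts at distance 1: ng x ng x 13 array.
// [[Rcpp::export(name = ".glcm_counts")]]
IntegerVector glcm_counts(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(Dimension(ng, ng, 13));
  for (int d = 0; d < 13; ++d) {
    int dx = OFF13[d][0], dy = OFF13[d][1], dz = OFF13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = at(levels, x, y, z, nx, ny, nz);
          if (a <= 0) continue;
          int b = at(levels, x + dx, y + dy, z + dz, nx, ny, nz);
          if (b <= 0) continue;
          out[(a - 1) + ng * (b - 1) + ng * ng * d] += 1;
          out[(b - 1) + ng * (a - 1) + ng * ng * d] += 1;
        }
  }
  return out;
}

// GLRLM counts: ng x max_run x 13. Runs are maximal same-level segments of
// in-region voxels along each direction's parallel lines.
// [[Rcpp::export(name = ".glrlm_counts")]]
IntegerVector glrlm_counts(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxrun = nx + ny + nz; // safe upper bound for any line length
  IntegerVector out(Dimension(ng, maxrun, 13));
  for (int d = 0; d < 13; ++d) {
    int dx = OFF13[d][0], dy = OFF13[d][1], dz = OFF13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          // line starts where the backward neighbour is out of grid
          if (at(levels, x - dx, y - dy, z - dz, nx, ny, nz) != -1) continue;
          int cx = x, cy = y, cz = z;
          int cur = -1, len = 0;
          while (true) {
            int v = at(levels, cx, cy, cz, nx, ny, nz);
            if (v == -1) break;
            if (v > 0 && v == cur) {
              ++len;
            } else {
              if (cur > 0 && len > 0)
                out[(cur - 1) + ng * (len - 1) + (R_xlen_t)ng * maxrun * d] += 1;
              cur = v;
              len = (v > 0) ? 1 : 0;
            }
            cx += dx; cy += dy; cz += dz;
          }
          if (cur > 0 && len > 0)
            out[(cur - 1) + ng * (len - 1) + (R_xlen_t)ng * maxrun * d] += 1;
        }
  }
  return out;
}

// GLSZM zones: 26-connected components of equal level. Returns a matrix
// with one row per zone: (level, size).
// [[Rcpp::export(name = ".glszm_zones")]]
IntegerMatrix glszm_zones(IntegerVector levels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (seen[s] || levels[s] <= 0) continue;
    int lvl = levels[s];
    int size = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      ++size;
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            R_xlen_t q = xx + nx * (yy + (R_xlen_t)ny * zz);
            if (!seen[q] && levels[q] == lvl) {
              seen[q] = 1;
              stack.push_back(q);
            }
          }
    }
    zl.push_back(lvl);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) {
    out(i, 0) = zl[i];
    out(i, 1) = zs[i];
  }
  return out;
}

// Per-voxel gray-level dependence: for each in-region voxel, the number of
// in-region 26-neighbours whose level differs by at most alpha. Returns a
// matrix (level, dependent-neighbour count) with one row per voxel.
// [[Rcpp::export(name = ".gldm_voxels")]]
IntegerMatrix gldm_voxels(IntegerVector levels, IntegerVector dims, int alpha) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> vl, vd;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = at(levels, x, y, z, nx, ny, nz);
        if (a <= 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int b = at(levels, x + dx, y + dy, z + dz, nx, ny, nz);
              if (b > 0 && std::abs(b - a) <= alpha) ++dep;
            }
        vl.push_back(a);
        vd.push_back(dep);
      }
  IntegerMatrix out(vl.size(), 2);
  for (size_t i = 0; i < vl.size(); ++i) {
    out(i, 0) = vl[i];
    out(i, 1) = vd[i];
  }
  return out;
}

// NGTDM per-voxel statistics: (level, has_valid_neighbourhood,
// |level - mean of in-region 26-neighbour levels|).
// [[Rcpp::export(name = ".ngtdm_voxels")]]
NumericMatrix ngtdm_voxels(IntegerVector levels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> vl, vh, vs;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = at(levels, x, y, z, nx, ny, nz);
        if (a <= 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int b = at(levels, x + dx, y + dy, z + dz, nx, ny, nz);
              if (b > 0) { sum += b; ++cnt; }
            }
        vl.push_back(a);
        vh.push_back(cnt > 0 ? 1.0 : 0.0);
        vs.push_back(cnt > 0 ? std::fabs(a - sum / cnt) : 0.0);
      }
  NumericMatrix out(vl.size(), 3);
  for (size_t i = 0; i < vl.size(); ++i) {
    out(i, 0) = vl[i];
    out(i, 1) = vh[i];
    out(i, 2) = vs[i];
  }
  return out;
}

// Lloyd iterations for k-means: x is n x p (column-major), centers k x p.
// Empty clusters are repaired by reseeding at the point farthest from its
// centre (deterministic). Returns labels (1-based), centers, inertia,
// iterations.
// [[Rcpp::export(name = ".lloyd")]]
List lloyd(NumericMatrix x, NumericMatrix centers0, int max_iter, double tol) {
  const int n = x.nrow(), p = x.ncol(), k = centers0.nrow();
  const double* X = x.begin(); // column-major n x p
  std::vector<double> C(k * p); // row-major k x p for cache-friendly access
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < p; ++c) C[j * p + c] = centers0(j, c);
  std::vector<double> xi(p), cnt(k), dist(n), newC(k * p);
  std::vector<int> lab(n, 0);
  double inertia = 0.0, inertia_prev = R_PosInf;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    inertia = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < p; ++c) xi[c] = X[i + (R_xlen_t)n * c];
      double best = R_PosInf; int bj = 0;
      for (int j = 0; j < k; ++j) {
        double d = 0.0;
        const double* cj = &C[j * p];
        for (int c = 0; c < p; ++c) {
          double t = xi[c] - cj[c];
          d += t * t;
        }
        if (d < best) { best = d; bj = j; }
      }
      lab[i] = bj;
      dist[i] = best;
    }
    // repair empty clusters at the farthest point
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = 0; i < n; ++i) cnt[lab[i]] += 1.0;
    for (int j = 0; j < k; ++j) {
      if (cnt[j] > 0.0) continue;
      int far = 0; double fd = -1.0;
      for (int i = 0; i < n; ++i) if (dist[i] > fd) { fd = dist[i]; far = i; }
      for (int c = 0; c < p; ++c) C[j * p + c] = X[far + (R_xlen_t)n * c];
      cnt[lab[far]] -= 1.0;
      lab[far] = j;
      cnt[j] = 1.0;
      dist[far] = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = 0.0;
        for (int c = 0; c < p; ++c) {
          double t = X[i + (R_xlen_t)n * c] - C[j * p + c];
          d += t * t;
        }
        if (d < dist[i]) {
          cnt[lab[i]] -= 1.0;
          lab[i] = j;
          cnt[j] += 1.0;
          dist[i] = d;
        }
      }
    }
    // update centres and inertia about the new centres
    std::fill(newC.begin(), newC.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < p; ++c) newC[lab[i] * p + c] += X[i + (R_xlen_t)n * c];
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < p; ++c) C[j * p + c] = newC[j * p + c] / cnt[j];
    for (int i = 0; i < n; ++i) {
      double d = 0.0;
      const double* cj = &C[lab[i] * p];
      for (int c = 0; c < p; ++c) {
        double t = X[i + (R_xlen_t)n * c] - cj[c];
        d += t * t;
      }
      inertia += d;
    }
    if (R_finite(inertia_prev) &&
        (inertia_prev - inertia) <= tol * std::max(inertia_prev, DBL_EPSILON))
      break;
    inertia_prev = inertia;
  }
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) labels[i] = lab[i] + 1;
  NumericMatrix centers(k, p);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < p; ++c) centers(j, c) = C[j * p + c];
  return List::create(_["labels"] = labels, _["centers"] = centers,
                      _["inertia"] = inertia, _["n_iter"] = iter);
}
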