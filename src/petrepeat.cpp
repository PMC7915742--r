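#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 3D grids are passed as flat vectors in R's column-major layout:
// idx = x + nx * (y + ny * z), 0-based. Gray-level arrays use 0 for
// out-of-mask voxels and 1..Ng inside the mask.

// The 13 unique 3D direction vectors (positive half of the 26-neighborhood).
static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int wrap_index(int i, int n, int mode) {
  // mode: 0 = reflect (symmetric, half-sample), 1 = wrap (periodic), 2 = nearest
  if (i >= 0 && i < n) return i;
  if (mode == 1) {
    i %= n;
    if (i < 0) i += n;
    return i;
  }
  if (mode == 2) return i < 0 ? 0 : n - 1;
  // symmetric reflection with period 2n: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  int p = 2 * n;
  i %= p;
  if (i < 0) i += p;
  return i < n ? i : p - 1 - i;
}

// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector arr, IntegerVector dim,
                            NumericVector kernel, int axis, int origin,
                            int mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int K = kernel.size();
  NumericVector out(arr.size());
  const int n_axis = dim[axis];
  // strides for the three axes in the flat layout
  const int stride[3] = {1, nx, nx * ny};
  const int s = stride[axis];

  // iterate over all lines along `axis`
  int d1 = (axis == 0) ? 1 : 0;
  int d2 = (axis == 2) ? 1 : 2;
  const int n1 = dim[d1], n2 = dim[d2];
  const int s1 = stride[d1], s2 = stride[d2];

  std::vector<double> line(n_axis);
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      const int base = j1 * s1 + j2 * s2;
      for (int i = 0; i < n_axis; ++i) line[i] = arr[base + i * s];
      for (int i = 0; i < n_axis; ++i) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k) {
          int src = wrap_index(i + k - origin, n_axis, mode);
          acc += kernel[k] * line[src];
        }
        out[base + i * s] = acc;
      }
    }
  }
  return out;
}

// Label connected components of equal non-zero value.
// connectivity: 26 or 6.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector levels, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = levels.size();
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::queue<int> q;

  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
          continue;
        offs.push_back({{dx, dy, dz}});
      }

  for (int idx = 0; idx < (int)n; ++idx) {
    if (levels[idx] == 0 || labels[idx] != 0) continue;
    const int val = levels[idx];
    labels[idx] = ++next_label;
    q.push(idx);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (size_t o = 0; o < offs.size(); ++o) {
        int xx = x + offs[o][0], yy = y + offs[o][1], zz = z + offs[o][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int nb = xx + nx * (yy + ny * zz);
        if (levels[nb] == val && labels[nb] == 0) {
          labels[nb] = next_label;
          q.push(nb);
        }
      }
    }
  }
  return labels;
}

// Symmetric GLCM at distance 1 for each of the 13 unique directions.
// Returns a list of Ng x Ng count matrices (each pair counted in both orders).
// [[Rcpp::export]]
List cpp_glcm(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  List out(13);
  for (int d = 0; d < 13; ++d) {
    NumericMatrix m(ng, ng);
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = levels[x + nx * (y + ny * z)];
          if (i == 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int j = levels[xx + nx * (yy + ny * zz)];
          if (j == 0) continue;
          m(i - 1, j - 1) += 1.0;
          m(j - 1, i - 1) += 1.0;
        }
    out[d] = m;
  }
  return out;
}

// GLRLM per direction: counts of maximal runs of equal gray level.
// Returns a list of Ng x Lmax matrices (Lmax = longest possible run).
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int lmax = std::max(nx, std::max(ny, nz));
  List out(13);
  for (int d = 0; d < 13; ++d) {
    NumericMatrix m(ng, lmax);
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int idx = x + nx * (y + ny * z);
          int lev = levels[idx];
          if (lev == 0) continue;
          // run start: predecessor along -d is outside grid/mask or different level
          int px = x - dx, py = y - dy, pz = z - dz;
          bool start = true;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz) {
            if (levels[px + nx * (py + ny * pz)] == lev) start = false;
          }
          if (!start) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz &&
                 levels[cx + nx * (cy + ny * cz)] == lev) {
            ++len;
            cx += dx; cy += dy; cz += dz;
          }
          m(lev - 1, len - 1) += 1.0;
        }
    out[d] = m;
  }
  return out;
}

// GLDM: dependence = number of 26-neighbors (distance 1) inside the mask with
// the same gray level (tolerance alpha = 0). Column index = dependence + 1,
// so the matrix is Ng x 27.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int lev = levels[x + nx * (y + ny * z)];
        if (lev == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
              if (levels[xx + nx * (yy + ny * zz)] == lev) ++dep;
            }
        m(lev - 1, dep) += 1.0;
      }
  return m;
}

// NGTDM: per gray level i, n_i = number of in-mask voxels of level i having at
// least one in-mask 26-neighbor, s_i = sum over those voxels of
// |i - mean(level of in-mask neighbors)|. Returns Ng x 2 matrix (n_i, s_i).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int lev = levels[x + nx * (y + ny * z)];
        if (lev == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
              int nb = levels[xx + nx * (yy + ny * zz)];
              if (nb != 0) { sum += nb; ++cnt; }
            }
        if (cnt == 0) continue;
        m(lev - 1, 0) += 1.0;
        m(lev - 1, 1) += std::fabs((double)lev - sum / cnt);
      }
  return m;
}
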