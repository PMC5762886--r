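#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Binary 3D morphology on column-major arrays, dims (nx, ny, nz).
// 26-connectivity = full 3x3x3 structuring element.

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// [[Rcpp::export(name = ".cpp_dilate26")]]
LogicalVector cpp_dilate26(LogicalVector mask, IntegerVector dims, int iterations) {
  if (iterations < 0) stop("iterations must be >= 0");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> cur(mask.begin(), mask.end()), nxt(cur.size());
  for (int it = 0; it < iterations; ++it) {
    std::copy(cur.begin(), cur.end(), nxt.begin());
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if (cur[idx3(i, j, k, nx, ny)]) continue;
          bool hit = false;
          for (int dk = -1; dk <= 1 && !hit; ++dk) {
            int kk = k + dk; if (kk < 0 || kk >= nz) continue;
            for (int dj = -1; dj <= 1 && !hit; ++dj) {
              int jj = j + dj; if (jj < 0 || jj >= ny) continue;
              for (int di = -1; di <= 1; ++di) {
                int ii = i + di; if (ii < 0 || ii >= nx) continue;
                if (cur[idx3(ii, jj, kk, nx, ny)]) { hit = true; break; }
              }
            }
          }
          if (hit) nxt[idx3(i, j, k, nx, ny)] = 1;
        }
    cur.swap(nxt);
  }
  LogicalVector out(mask.size());
  for (R_xlen_t t = 0; t < (R_xlen_t)cur.size(); ++t) out[t] = cur[t] != 0;
  out.attr("dim") = dims;
  return out;
}

// 26-connected component containing seed voxel (0-based flat index).
// [[Rcpp::export(name = ".cpp_flood26")]]
LogicalVector cpp_flood26(LogicalVector mask, IntegerVector dims, double seed_flat) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = mask.size(), s = (R_xlen_t)seed_flat;
  if (s < 0 || s >= n) stop("seed index out of grid");
  if (!mask[s]) stop("seed voxel is not inside the mask");
  std::vector<char> in(mask.begin(), mask.end());
  std::vector<char> vis(n, 0);
  std::queue<R_xlen_t> q;
  vis[s] = 1; q.push(s);
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx * ny));
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk; if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj; if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di; if (ii < 0 || ii >= nx) continue;
          R_xlen_t nb = idx3(ii, jj, kk, nx, ny);
          if (in[nb] && !vis[nb]) { vis[nb] = 1; q.push(nb); }
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = vis[t] != 0;
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labelling; labels 1..ncomp, 0 = background.
// [[Rcpp::export(name = ".cpp_label26")]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = mask.size();
  std::vector<char> in(mask.begin(), mask.end());
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!in[s] || lab[s]) continue;
    lab[s] = ++next; q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            R_xlen_t nb = idx3(ii, jj, kk, nx, ny);
            if (in[nb] && !lab[nb]) { lab[nb] = next; q.push(nb); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("ncomp") = next;
  return lab;
}

// Gradient magnitude in grey-units per voxel: Euclidean norm of central
// differences (one-sided at grid borders).
// [[Rcpp::export(name = ".cpp_gradmag")]]
NumericVector cpp_gradmag(NumericVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double gx, gy, gz;
        if (nx == 1) gx = 0.0;
        else if (i == 0) gx = vol[idx3(1, j, k, nx, ny)] - vol[idx3(0, j, k, nx, ny)];
        else if (i == nx - 1) gx = vol[idx3(nx - 1, j, k, nx, ny)] - vol[idx3(nx - 2, j, k, nx, ny)];
        else gx = 0.5 * (vol[idx3(i + 1, j, k, nx, ny)] - vol[idx3(i - 1, j, k, nx, ny)]);
        if (ny == 1) gy = 0.0;
        else if (j == 0) gy = vol[idx3(i, 1, k, nx, ny)] - vol[idx3(i, 0, k, nx, ny)];
        else if (j == ny - 1) gy = vol[idx3(i, ny - 1, k, nx, ny)] - vol[idx3(i, ny - 2, k, nx, ny)];
        else gy = 0.5 * (vol[idx3(i, j + 1, k, nx, ny)] - vol[idx3(i, j - 1, k, nx, ny)]);
        if (nz == 1) gz = 0.0;
        else if (k == 0) gz = vol[idx3(i, j, 1, nx, ny)] - vol[idx3(i, j, 0, nx, ny)];
        else if (k == nz - 1) gz = vol[idx3(i, j, nz - 1, nx, ny)] - vol[idx3(i, j, nz - 2, nx, ny)];
        else gz = 0.5 * (vol[idx3(i, j, k + 1, nx, ny)] - vol[idx3(i, j, k - 1, nx, ny)]);
        out[idx3(i, j, k, nx, ny)] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  out.attr("dim") = dims;
  return out;
}

// Round-synchronous grey-window + gradient-capped region expansion.
// Each round adds every 26-neighbour of the current region whose grey lies
// in [glo, ghi] and whose gradient magnitude is <= gradcap; at most
// max_step rounds.
// [[Rcpp::export(name = ".cpp_smart_expand")]]
LogicalVector cpp_smart_expand(NumericVector vol, LogicalVector seed, IntegerVector dims,
                               double glo, double ghi, double gradcap, int max_step) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = vol.size();
  NumericVector grad = cpp_gradmag(vol, dims);
  std::vector<char> reg(seed.begin(), seed.end());
  std::vector<R_xlen_t> frontier;
  for (R_xlen_t t = 0; t < n; ++t) if (reg[t]) frontier.push_back(t);
  for (int step = 0; step < max_step && !frontier.empty(); ++step) {
    std::vector<R_xlen_t> added;
    for (R_xlen_t cur : frontier) {
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            R_xlen_t nb = idx3(ii, jj, kk, nx, ny);
            if (reg[nb]) continue;
            double g = vol[nb];
            if (g >= glo && g <= ghi && grad[nb] <= gradcap) {
              reg[nb] = 1; added.push_back(nb);
            }
          }
        }
      }
    }
    frontier.swap(added);
  }
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = reg[t] != 0;
  out.attr("dim") = dims;
  return out;
}
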