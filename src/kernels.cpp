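// Low-level 3D image and tensor kernels.
//
// Array conventions (matching the R side):
//   * 3D images:   dim = (ny, nx, nz), column-major, voxel (y, x, z)
//   * 4D tensors:  dim = (ny, nx, nz, channels)
//   * conv weights: matrix (9 * kz * cin) x cout, column order
//       ((c*kz + kzi)*3 + kx)*3 + ky  for tap offsets (ky, kx) in {0,1,2},
//       kzi in {0..kz-1}
// Convolutions are 3x3 in-plane with a configurable z extent kz (1 or 3),
// stride 1, zero-padded ("same").

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline long idx3(int y, int x, int z, int ny, int nx) {
  return y + (long)ny * (x + (long)nx * z);
}

// Internals run in single precision: the column (im2col) matrices dominate
// memory traffic, and the forward pass hands its column matrix to the
// backward pass through an external pointer so it is built exactly once.

static arma::fmat im2col3(const double* x, int ny, int nx, int nz, int cin,
                          int kz) {
  const long nvox = (long)ny * nx * nz;
  const int rz = kz / 2;
  arma::fmat M(nvox, 9 * kz * cin, arma::fill::none);
  for (int c = 0; c < cin; c++) {
    const double* xc = x + nvox * c;
    for (int kzi = 0; kzi < kz; kzi++)
      for (int kx = 0; kx < 3; kx++)
        for (int ky = 0; ky < 3; ky++) {
          int col = ((c * kz + kzi) * 3 + kx) * 3 + ky;
          int dy = ky - 1, dx = kx - 1, dz = kzi - rz;
          float* dst = M.colptr(col);
          for (int z = 0; z < nz; z++) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) {
              std::memset(dst + (long)z * nx * ny, 0,
                          sizeof(float) * nx * ny);
              continue;
            }
            for (int xq = 0; xq < nx; xq++) {
              int xx = xq + dx;
              float* d = dst + idx3(0, xq, z, ny, nx);
              if (xx < 0 || xx >= nx) {
                std::memset(d, 0, sizeof(float) * ny);
                continue;
              }
              int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
              const double* s = xc + idx3(0, xx, zz, ny, nx);
              if (y0 > 0) d[0] = 0.0f;
              for (int y = y0; y < y1; y++) d[y] = (float)s[y + dy];
              if (y1 < ny) d[ny - 1] = 0.0f;
            }
          }
        }
  }
  return M;
}

// [[Rcpp::export]]
List conv3d_fwd(NumericVector x, IntegerVector dims, const arma::mat& w,
                const arma::rowvec& b, int kz, bool keep_cols) {
  int ny = dims[0], nx = dims[1], nz = dims[2], cin = dims[3];
  int cout = w.n_cols;
  arma::fmat* M = new arma::fmat(im2col3(x.begin(), ny, nx, nz, cin, kz));
  arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b);
  arma::fmat Y = (*M) * wf;
  Y.each_row() += bf;
  NumericVector out(Y.n_elem);
  std::copy(Y.begin(), Y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(ny, nx, nz, cout);
  if (keep_cols) {
    Rcpp::XPtr<arma::fmat> p(M, true);
    return List::create(_["y"] = out, _["cols"] = p);
  }
  delete M;
  return List::create(_["y"] = out);
}

// [[Rcpp::export]]
List conv3d_bwd(SEXP cols, IntegerVector dims, const arma::mat& w,
                NumericVector gy, int kz, int cin_keep) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  int cout = w.n_cols;
  const long nvox = (long)ny * nx * nz;
  const int rz = kz / 2;
  Rcpp::XPtr<arma::fmat> M(cols);
  arma::fmat GY(nvox, cout, arma::fill::none);
  std::copy(gy.begin(), gy.end(), GY.begin());
  arma::fmat gwf = M->t() * GY;
  arma::frowvec gbf = arma::sum(GY, 0);
  // input gradients only for the first cin_keep channels (the rest are
  // coordinate channels, or the raw image at the first layer)
  NumericVector gx((long)nvox * std::max(cin_keep, 0));
  if (cin_keep > 0) {
  arma::fmat wf = arma::conv_to<arma::fmat>::from(
      w.rows(0, (arma::uword)(9 * kz * cin_keep) - 1));
  arma::fmat Gcols = GY * wf.t();  // nvox x 9*kz*cin_keep
  double* g = gx.begin();
  for (int c = 0; c < cin_keep; c++) {
    double* gc = g + nvox * c;
    for (int kzi = 0; kzi < kz; kzi++)
      for (int kx = 0; kx < 3; kx++)
        for (int ky = 0; ky < 3; ky++) {
          int col = ((c * kz + kzi) * 3 + kx) * 3 + ky;
          int dy = ky - 1, dx = kx - 1, dz = kzi - rz;
          const float* src = Gcols.colptr(col);
          for (int z = 0; z < nz; z++) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            for (int xq = 0; xq < nx; xq++) {
              int xx = xq + dx;
              if (xx < 0 || xx >= nx) continue;
              int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
              const float* s = src + idx3(0, xq, z, ny, nx);
              double* d = gc + idx3(0, xx, zz, ny, nx);
              for (int y = y0; y < y1; y++) d[y + dy] += s[y];
            }
          }
        }
  }
  }
  gx.attr("dim") = IntegerVector::create(ny, nx, nz, std::max(cin_keep, 0));
  NumericVector gwo(gwf.n_elem);
  std::copy(gwf.begin(), gwf.end(), gwo.begin());
  gwo.attr("dim") = IntegerVector::create(gwf.n_rows, gwf.n_cols);
  return List::create(_["gx"] = gx, _["gw"] = gwo,
                      _["gb"] = NumericVector(gbf.begin(), gbf.end()));
}

// 2x2 max pooling over (y, x), z and channels untouched
// [[Rcpp::export]]
List pool2_fwd(NumericVector x, IntegerVector dims) {
  int ny = dims[0], nx = dims[1], nz = dims[2], nc = dims[3];
  int py = ny / 2, px = nx / 2;
  const long nvox = (long)ny * nx * nz;
  NumericVector y((long)py * px * nz * nc);
  IntegerVector arg((long)py * px * nz * nc);
  const double* xp = x.begin();
  long o = 0;
  for (int c = 0; c < nc; c++)
    for (int z = 0; z < nz; z++)
      for (int xx = 0; xx < px; xx++)
        for (int yy = 0; yy < py; yy++) {
          long base = nvox * c;
          double best = -1e300; long besti = -1;
          for (int ddx = 0; ddx < 2; ddx++)
            for (int ddy = 0; ddy < 2; ddy++) {
              long ii = base + idx3(2 * yy + ddy, 2 * xx + ddx, z, ny, nx);
              if (xp[ii] > best) { best = xp[ii]; besti = ii; }
            }
          y[o] = best; arg[o] = (int)besti; o++;
        }
  y.attr("dim") = IntegerVector::create(py, px, nz, nc);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector pool2_bwd(IntegerVector arg, NumericVector gy, IntegerVector xdims) {
  long n = (long)xdims[0] * xdims[1] * xdims[2] * xdims[3];
  NumericVector gx(n);
  for (long k = 0; k < (long)arg.size(); k++) gx[arg[k]] += gy[k];
  gx.attr("dim") = xdims;
  return gx;
}

// separable convolution of a 3D image along one axis, reflect padding
// [[Rcpp::export]]
NumericVector conv_axis(NumericVector x, IntegerVector dims,
                        NumericVector kernel, int axis) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  int r = (kernel.size() - 1) / 2;
  NumericVector out((long)ny * nx * nz);
  const double* xp = x.begin();
  const double* kp = kernel.begin();
  int n_axis = axis == 0 ? ny : (axis == 1 ? nx : nz);
  for (int z = 0; z < nz; z++)
    for (int xx = 0; xx < nx; xx++)
      for (int y = 0; y < ny; y++) {
        double acc = 0;
        int pos = axis == 0 ? y : (axis == 1 ? xx : z);
        for (int k = -r; k <= r; k++) {
          int p = pos + k;
          if (p < 0) p = -p;                       // reflect
          if (p >= n_axis) p = 2 * n_axis - 2 - p;
          if (p < 0) p = 0;
          long ii = axis == 0 ? idx3(p, xx, z, ny, nx)
                  : axis == 1 ? idx3(y, p, z, ny, nx)
                              : idx3(y, xx, p, ny, nx);
          acc += kp[k + r] * xp[ii];
        }
        out[idx3(y, xx, z, ny, nx)] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// local maxima (>= all 26 neighbours, value > threshold); returns 1-based (y,x,z)
// [[Rcpp::export]]
IntegerMatrix local_max_3d(NumericVector v, IntegerVector dims, double threshold) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  const double* p = v.begin();
  std::vector<int> ys, xs, zs;
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++) {
        double val = p[idx3(y, x, z, ny, nx)];
        if (val <= threshold) continue;
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; dz++)
          for (int dx = -1; dx <= 1 && ok; dx++)
            for (int dy = -1; dy <= 1 && ok; dy++) {
              if (!dy && !dx && !dz) continue;
              int yy = y + dy, xx = x + dx, zz = z + dz;
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
                continue;
              if (p[idx3(yy, xx, zz, ny, nx)] > val) ok = false;
            }
        if (ok) { ys.push_back(y + 1); xs.push_back(x + 1); zs.push_back(z + 1); }
      }
  IntegerMatrix out(ys.size(), 3);
  for (size_t k = 0; k < ys.size(); k++) {
    out(k, 0) = ys[k]; out(k, 1) = xs[k]; out(k, 2) = zs[k];
  }
  return out;
}

// connected components of a binary mask, 6-connectivity
// [[Rcpp::export]]
IntegerVector label3d(LogicalVector mask, IntegerVector dims) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  long n = (long)ny * nx * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<long> q;
  const int dys[6] = {1, -1, 0, 0, 0, 0};
  const int dxs[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  for (long s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    cur++;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      long v = q.front(); q.pop();
      int y = v % ny, x = (v / ny) % nx, z = v / ((long)ny * nx);
      for (int d = 0; d < 6; d++) {
        int yy = y + dys[d], xx = x + dxs[d], zz = z + dzs[d];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
        long w = idx3(yy, xx, zz, ny, nx);
        if (mask[w] && !lab[w]) { lab[w] = cur; q.push(w); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// fill 3D holes: background components (6-conn) not touching the border
// [[Rcpp::export]]
LogicalVector fill_holes_3d(LogicalVector mask, IntegerVector dims) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  long n = (long)ny * nx * nz;
  std::vector<char> outside(n, 0);
  std::queue<long> q;
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++) {
        if (y == 0 || y == ny - 1 || x == 0 || x == nx - 1 || z == 0 || z == nz - 1) {
          long v = idx3(y, x, z, ny, nx);
          if (!mask[v] && !outside[v]) { outside[v] = 1; q.push(v); }
        }
      }
  const int dys[6] = {1, -1, 0, 0, 0, 0};
  const int dxs[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    long v = q.front(); q.pop();
    int y = v % ny, x = (v / ny) % nx, z = v / ((long)ny * nx);
    for (int d = 0; d < 6; d++) {
      int yy = y + dys[d], xx = x + dxs[d], zz = z + dzs[d];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      long w = idx3(yy, xx, zz, ny, nx);
      if (!mask[w] && !outside[w]) { outside[w] = 1; q.push(w); }
    }
  }
  LogicalVector out(n);
  for (long v = 0; v < n; v++) out[v] = mask[v] || !outside[v];
  out.attr("dim") = dims;
  return out;
}

// grow labels into an allowed mask by multi-source BFS (6-conn);
// unlabeled allowed voxels reachable from a label get that label
// [[Rcpp::export]]
IntegerVector grow_labels(IntegerVector labels, LogicalVector allowed,
                          IntegerVector dims) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  long n = (long)ny * nx * nz;
  IntegerVector out(clone(labels));
  std::queue<long> q;
  for (long v = 0; v < n; v++) if (out[v] > 0) q.push(v);
  const int dys[6] = {1, -1, 0, 0, 0, 0};
  const int dxs[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    long v = q.front(); q.pop();
    int y = v % ny, x = (v / ny) % nx, z = v / ((long)ny * nx);
    for (int d = 0; d < 6; d++) {
      int yy = y + dys[d], xx = x + dxs[d], zz = z + dzs[d];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      long w = idx3(yy, xx, zz, ny, nx);
      if (allowed[w] && out[w] == 0) { out[w] = out[v]; q.push(w); }
    }
  }
  out.attr("dim") = dims;
  return out;
}
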