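// Compute kernels for the patch-pyramid segmentation stack.
//
// Tensor layout convention (column-major R arrays):
//   feature maps are (C, nx, ny, nz, B)  -- channel fastest, batch slowest.
// Convolution weights are matrices (Cout x Cin*k^3) with column index
//   cin + Cin*(kx + 3*(ky + 3*kz))  for the 3^3 kernels, and
//   cin + Cin*(dx + 2*(dy + 2*dz)) for the 2^3 transposed-conv kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t idx4(int c, int x, int y, int z, int C, int nx, int ny) {
  return c + (R_xlen_t)C * (x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z));
}

// ---------------------------------------------------------------------------
// im2col / col2im for 3x3x3 convolution, stride 1, zero padding 1
// ---------------------------------------------------------------------------

static void im2col3(const double* X, int C, int nx, int ny, int nz, arma::mat& col) {
  // col must be (C*27) x (nx*ny*nz)
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int rbase = C * (kx + 3 * (ky + 3 * kz));
        for (int z = 0; z < nz; ++z) {
          const int zz = z + kz - 1;
          for (int y = 0; y < ny; ++y) {
            const int yy = y + ky - 1;
            const R_xlen_t jbase = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            const bool planeOut = (zz < 0 || zz >= nz || yy < 0 || yy >= ny);
            for (int x = 0; x < nx; ++x) {
              double* d = col.colptr(jbase + x) + rbase;
              const int xx = x + kx - 1;
              if (planeOut || xx < 0 || xx >= nx) {
                for (int c = 0; c < C; ++c) d[c] = 0.0;
              } else {
                const double* s = X + idx4(0, xx, yy, zz, C, nx, ny);
                for (int c = 0; c < C; ++c) d[c] = s[c];
              }
            }
          }
        }
      }
}

static void col2im3_add(const arma::mat& col, int C, int nx, int ny, int nz, double* X) {
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int rbase = C * (kx + 3 * (ky + 3 * kz));
        for (int z = 0; z < nz; ++z) {
          const int zz = z + kz - 1;
          if (zz < 0 || zz >= nz) continue;
          for (int y = 0; y < ny; ++y) {
            const int yy = y + ky - 1;
            if (yy < 0 || yy >= ny) continue;
            const R_xlen_t jbase = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            for (int x = 0; x < nx; ++x) {
              const int xx = x + kx - 1;
              if (xx < 0 || xx >= nx) continue;
              const double* s = col.colptr(jbase + x) + rbase;
              double* d = X + idx4(0, xx, yy, zz, C, nx, ny);
              for (int c = 0; c < C; ++c) d[c] += s[c];
            }
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector X, NumericMatrix W, NumericVector b,
                             IntegerVector dims) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3], B = dims[4];
  const int Cout = W.nrow();
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  if (W.ncol() != C * 27) stop("conv3d: weight/input channel mismatch");
  arma::mat Wm(W.begin(), Cout, W.ncol(), false);
  arma::vec bv(b.begin(), Cout);
  NumericVector Y((R_xlen_t)Cout * N * B);
  arma::mat col(C * 27, N);
  for (int bb = 0; bb < B; ++bb) {
    im2col3(X.begin() + (R_xlen_t)C * N * bb, C, nx, ny, nz, col);
    arma::mat Yb(Y.begin() + (R_xlen_t)Cout * N * bb, Cout, N, false, true);
    Yb = Wm * col;
    Yb.each_col() += bv;
  }
  Y.attr("dim") = IntegerVector::create(Cout, nx, ny, nz, B);
  return Y;
}

// Variant that returns the im2col matrix (all batches side by side) so the
// backward pass can reuse it instead of rebuilding it.
// [[Rcpp::export]]
List cpp_conv3d_fwd_cache(NumericVector X, NumericMatrix W, NumericVector b,
                          IntegerVector dims) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3], B = dims[4];
  const int Cout = W.nrow();
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  if (W.ncol() != C * 27) stop("conv3d: weight/input channel mismatch");
  arma::mat Wm(W.begin(), Cout, W.ncol(), false);
  arma::vec bv(b.begin(), Cout);
  NumericVector Y((R_xlen_t)Cout * N * B);
  NumericMatrix col(C * 27, N * B);
  for (int bb = 0; bb < B; ++bb) {
    arma::mat colb(col.begin() + (R_xlen_t)(C * 27) * N * bb, C * 27, N, false, true);
    im2col3(X.begin() + (R_xlen_t)C * N * bb, C, nx, ny, nz, colb);
  }
  arma::mat colm(col.begin(), C * 27, N * B, false);
  arma::mat Ym(Y.begin(), Cout, N * B, false, true);
  Ym = Wm * colm;
  Ym.each_col() += bv;
  Y.attr("dim") = IntegerVector::create(Cout, nx, ny, nz, B);
  return List::create(_["Y"] = Y, _["col"] = col);
}

// Backward using a cached im2col matrix: one GEMM for dW, one for dcol.
// [[Rcpp::export]]
List cpp_conv3d_bwd_col(NumericMatrix col, NumericVector dY, NumericMatrix W,
                        IntegerVector dims) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3], B = dims[4];
  const int Cout = W.nrow();
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  arma::mat Wm(W.begin(), Cout, W.ncol(), false);
  arma::mat colm(col.begin(), C * 27, N * B, false);
  arma::mat dYm(const_cast<double*>(dY.begin()), Cout, N * B, false);
  arma::mat dW = dYm * colm.t();
  arma::vec db = arma::sum(dYm, 1);
  arma::mat dcol = Wm.t() * dYm;
  NumericVector dX((R_xlen_t)C * N * B);
  for (int bb = 0; bb < B; ++bb) {
    arma::mat dcolb(dcol.colptr((R_xlen_t)N * bb), C * 27, N, false);
    col2im3_add(dcolb, C, nx, ny, nz, dX.begin() + (R_xlen_t)C * N * bb);
  }
  dX.attr("dim") = IntegerVector::create(C, nx, ny, nz, B);
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dX"] = dX);
}

// Per-(channel, sample) mean and mean-of-squares for instance normalisation.
// [[Rcpp::export]]
List cpp_chan_moments(NumericVector X, IntegerVector dims) {
  const int C = dims[0], B = dims[4];
  const R_xlen_t N = (R_xlen_t)dims[1] * dims[2] * dims[3];
  NumericMatrix mu(C, B), m2(C, B);
  const double* xp = X.begin();
  for (int bb = 0; bb < B; ++bb) {
    double* mup = &mu(0, bb);
    double* m2p = &m2(0, bb);
    const double* base = xp + (R_xlen_t)C * N * bb;
    for (R_xlen_t j = 0; j < N; ++j) {
      const double* s = base + (R_xlen_t)C * j;
      for (int c = 0; c < C; ++c) { mup[c] += s[c]; m2p[c] += s[c] * s[c]; }
    }
    for (int c = 0; c < C; ++c) { mup[c] /= N; m2p[c] /= N; }
  }
  return List::create(_["mu"] = mu, _["m2"] = m2);
}

// y = (x - mu) * istd * gamma + beta, fused; returns y and xhat
// [[Rcpp::export]]
List cpp_inorm_apply(NumericVector X, IntegerVector dims, NumericMatrix mu,
                     NumericMatrix istd, NumericVector gamma, NumericVector beta) {
  const int C = dims[0], B = dims[4];
  const R_xlen_t N = (R_xlen_t)dims[1] * dims[2] * dims[3];
  NumericVector Y(X.size()), XH(X.size());
  const double* xp = X.begin();
  double* yp = Y.begin();
  double* hp = XH.begin();
  for (int bb = 0; bb < B; ++bb) {
    const double* mup = &mu(0, bb);
    const double* ip = &istd(0, bb);
    const R_xlen_t off = (R_xlen_t)C * N * bb;
    for (R_xlen_t j = 0; j < N; ++j) {
      const double* s = xp + off + (R_xlen_t)C * j;
      double* d = yp + off + (R_xlen_t)C * j;
      double* h = hp + off + (R_xlen_t)C * j;
      for (int c = 0; c < C; ++c) {
        h[c] = (s[c] - mup[c]) * ip[c];
        d[c] = h[c] * gamma[c] + beta[c];
      }
    }
  }
  Y.attr("dim") = dims;
  XH.attr("dim") = dims;
  return List::create(_["y"] = Y, _["xhat"] = XH);
}

// dz = istd * (dxhat - m1 - xhat * m2), all stats per (channel, sample)
// [[Rcpp::export]]
NumericVector cpp_inorm_bwd(NumericVector dxhat, NumericVector xhat,
                            IntegerVector dims, NumericMatrix m1,
                            NumericMatrix m2, NumericMatrix istd) {
  const int C = dims[0], B = dims[4];
  const R_xlen_t N = (R_xlen_t)dims[1] * dims[2] * dims[3];
  NumericVector dz(dxhat.size());
  const double* dp = dxhat.begin();
  const double* hp = xhat.begin();
  double* op = dz.begin();
  for (int bb = 0; bb < B; ++bb) {
    const double* m1p = &m1(0, bb);
    const double* m2p = &m2(0, bb);
    const double* ip = &istd(0, bb);
    const R_xlen_t off = (R_xlen_t)C * N * bb;
    for (R_xlen_t j = 0; j < N; ++j) {
      const double* s = dp + off + (R_xlen_t)C * j;
      const double* h = hp + off + (R_xlen_t)C * j;
      double* o = op + off + (R_xlen_t)C * j;
      for (int c = 0; c < C; ++c)
        o[c] = ip[c] * (s[c] - m1p[c] - h[c] * m2p[c]);
    }
  }
  dz.attr("dim") = dims;
  return dz;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector X, NumericVector dY, NumericMatrix W,
                    IntegerVector dims) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3], B = dims[4];
  const int Cout = W.nrow();
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  arma::mat Wm(W.begin(), Cout, W.ncol(), false);
  arma::mat dW(Cout, C * 27, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dX((R_xlen_t)C * N * B);
  arma::mat col(C * 27, N);
  for (int bb = 0; bb < B; ++bb) {
    im2col3(X.begin() + (R_xlen_t)C * N * bb, C, nx, ny, nz, col);
    arma::mat dYb(const_cast<double*>(dY.begin()) + (R_xlen_t)Cout * N * bb,
                  Cout, N, false, true);
    dW += dYb * col.t();
    db += arma::sum(dYb, 1);
    arma::mat dcol = Wm.t() * dYb;
    col2im3_add(dcol, C, nx, ny, nz, dX.begin() + (R_xlen_t)C * N * bb);
  }
  dX.attr("dim") = IntegerVector::create(C, nx, ny, nz, B);
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dX"] = dX);
}

// ---------------------------------------------------------------------------
// 2x2x2 max pooling, stride 2
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector X, IntegerVector dims) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3], B = dims[4];
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool3d: odd spatial size");
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const R_xlen_t N = (R_xlen_t)ox * oy * oz;
  NumericVector Y((R_xlen_t)C * N * B);
  IntegerVector arg((R_xlen_t)C * N * B);  // linear index into X (0-based)
  const double* xp = X.begin();
  double* yp = Y.begin();
  int* ap = arg.begin();
  for (int bb = 0; bb < B; ++bb) {
    const R_xlen_t xoff = (R_xlen_t)C * nx * ny * nz * bb;
    const R_xlen_t yoff = (R_xlen_t)C * N * bb;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x)
          for (int c = 0; c < C; ++c) {
            double best = -HUGE_VAL; R_xlen_t bestIdx = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const R_xlen_t ii = xoff + idx4(c, 2 * x + dx, 2 * y + dy, 2 * z + dz, C, nx, ny);
                  if (xp[ii] > best) { best = xp[ii]; bestIdx = ii; }
                }
            const R_xlen_t jj = yoff + idx4(c, x, y, z, C, ox, oy);
            yp[jj] = best; ap[jj] = (int)bestIdx;
          }
  }
  Y.attr("dim") = IntegerVector::create(C, ox, oy, oz, B);
  return List::create(_["Y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector dY, IntegerVector arg, IntegerVector dims) {
  // dims: input dims (C, nx, ny, nz, B)
  const R_xlen_t n = (R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3] * dims[4];
  NumericVector dX(n);
  double* dxp = dX.begin();
  const double* dyp = dY.begin();
  const int* ap = arg.begin();
  const R_xlen_t m = dY.size();
  for (R_xlen_t i = 0; i < m; ++i) dxp[ap[i]] += dyp[i];
  dX.attr("dim") = dims;
  return dX;
}

// ---------------------------------------------------------------------------
// 2x2x2 transposed convolution, stride 2 (upsampling)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_upconv3d_fwd(NumericVector X, NumericMatrix W, NumericVector b,
                               IntegerVector dims) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3], B = dims[4];
  const int Cout = W.nrow();
  if (W.ncol() != C * 8) stop("upconv3d: weight/input channel mismatch");
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const R_xlen_t Nin = (R_xlen_t)nx * ny * nz;
  const R_xlen_t Nout = (R_xlen_t)ox * oy * oz;
  arma::mat Wm(W.begin(), Cout, W.ncol(), false);
  NumericVector Y((R_xlen_t)Cout * Nout * B);
  double* yp = Y.begin();
  for (int bb = 0; bb < B; ++bb) {
    arma::mat Xb(const_cast<double*>(X.begin()) + (R_xlen_t)C * Nin * bb, C, Nin, false, true);
    const R_xlen_t yoff = (R_xlen_t)Cout * Nout * bb;
    for (int o = 0; o < 8; ++o) {
      const int dx = o & 1, dy = (o >> 1) & 1, dz = (o >> 2) & 1;
      arma::mat Yo = Wm.cols(o * C, (o + 1) * C - 1) * Xb;  // Cout x Nin
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            const double* s = Yo.colptr(x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z));
            double* d = yp + yoff + idx4(0, 2 * x + dx, 2 * y + dy, 2 * z + dz, Cout, ox, oy);
            for (int c = 0; c < Cout; ++c) d[c] += s[c];
          }
    }
    for (R_xlen_t j = 0; j < Nout; ++j) {
      double* d = yp + yoff + (R_xlen_t)Cout * j;
      for (int c = 0; c < Cout; ++c) d[c] += b[c];
    }
  }
  Y.attr("dim") = IntegerVector::create(Cout, ox, oy, oz, B);
  return Y;
}

// [[Rcpp::export]]
List cpp_upconv3d_bwd(NumericVector X, NumericVector dY, NumericMatrix W,
                      IntegerVector dims) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3], B = dims[4];
  const int Cout = W.nrow();
  const int ox = 2 * nx, oy = 2 * ny;
  const R_xlen_t Nin = (R_xlen_t)nx * ny * nz;
  const R_xlen_t Nout = Nin * 8;
  arma::mat Wm(W.begin(), Cout, W.ncol(), false);
  arma::mat dW(Cout, C * 8, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dX((R_xlen_t)C * Nin * B);
  const double* dyp = dY.begin();
  arma::mat dYo(Cout, Nin);
  for (int bb = 0; bb < B; ++bb) {
    arma::mat Xb(const_cast<double*>(X.begin()) + (R_xlen_t)C * Nin * bb, C, Nin, false, true);
    arma::mat dXb(dX.begin() + (R_xlen_t)C * Nin * bb, C, Nin, false, true);
    const R_xlen_t yoff = (R_xlen_t)Cout * Nout * bb;
    for (int o = 0; o < 8; ++o) {
      const int dx = o & 1, dy = (o >> 1) & 1, dz = (o >> 2) & 1;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            const double* s = dyp + yoff + idx4(0, 2 * x + dx, 2 * y + dy, 2 * z + dz, Cout, ox, oy);
            double* d = dYo.colptr(x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z));
            for (int c = 0; c < Cout; ++c) d[c] = s[c];
          }
      dW.cols(o * C, (o + 1) * C - 1) += dYo * Xb.t();
      dXb += Wm.cols(o * C, (o + 1) * C - 1).t() * dYo;
      db += arma::sum(dYo, 1);
    }
  }
  dX.attr("dim") = IntegerVector::create(C, nx, ny, nz, B);
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dX"] = dX);
}

// ---------------------------------------------------------------------------
// Trilinear / nearest-neighbour samplers (coords are 0-based voxel units)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_trilinear_gather(NumericVector A, IntegerVector dims,
                                   NumericMatrix coords, double fill) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3];
  const R_xlen_t N = coords.ncol();
  NumericMatrix out(C, N);
  const double* ap = A.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const double cx = coords(0, j), cy = coords(1, j), cz = coords(2, j);
    const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
    const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    double* d = &out(0, j);
    for (int c = 0; c < C; ++c) d[c] = 0.0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          if (w == 0.0) continue;
          const int xx = x0 + dx, yy = y0 + dy, zz = z0 + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) {
            for (int c = 0; c < C; ++c) d[c] += w * fill;
          } else {
            const double* s = ap + idx4(0, xx, yy, zz, C, nx, ny);
            for (int c = 0; c < C; ++c) d[c] += w * s[c];
          }
        }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear_scatter(NumericMatrix dV, IntegerVector dims,
                                    NumericMatrix coords) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3];
  const R_xlen_t N = coords.ncol();
  NumericVector dA((R_xlen_t)C * nx * ny * nz);
  double* ap = dA.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const double cx = coords(0, j), cy = coords(1, j), cz = coords(2, j);
    const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
    const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    const double* s = &dV(0, j);
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          if (w == 0.0) continue;
          const int xx = x0 + dx, yy = y0 + dy, zz = z0 + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          double* d = ap + idx4(0, xx, yy, zz, C, nx, ny);
          for (int c = 0; c < C; ++c) d[c] += w * s[c];
        }
  }
  dA.attr("dim") = IntegerVector::create(C, nx, ny, nz);
  return dA;
}

// [[Rcpp::export]]
NumericMatrix cpp_nearest_gather(NumericVector A, IntegerVector dims,
                                 NumericMatrix coords, double fill) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3];
  const R_xlen_t N = coords.ncol();
  NumericMatrix out(C, N);
  const double* ap = A.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const int xx = (int)std::lround(coords(0, j));
    const int yy = (int)std::lround(coords(1, j));
    const int zz = (int)std::lround(coords(2, j));
    double* d = &out(0, j);
    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) {
      for (int c = 0; c < C; ++c) d[c] = fill;
    } else {
      const double* s = ap + idx4(0, xx, yy, zz, C, nx, ny);
      for (int c = 0; c < C; ++c) d[c] = s[c];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic spacing, seeds are the zero-distance set.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb, int n, double h) {
  // squared distance transform along one axis with sample spacing h (mm);
  // only finite parabolas enter the lower envelope
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == HUGE_VAL) continue;
    const double pq = q * h;
    if (k < 0) {
      k = 0; v[0] = q; zb[0] = -HUGE_VAL; zb[1] = HUGE_VAL;
      continue;
    }
    double s;
    while (true) {
      const double pv = v[k] * h;
      s = ((f[q] + pq * pq) - (f[v[k]] + pv * pv)) / (2 * h * (q - v[k]));
      if (s <= zb[k] && k > 0) { --k; } else break;
    }
    if (s <= zb[k]) { // displaced the only remaining parabola
      v[k] = q; zb[k] = -HUGE_VAL; zb[k + 1] = HUGE_VAL;
    } else {
      ++k; v[k] = q; zb[k] = s; zb[k + 1] = HUGE_VAL;
    }
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = HUGE_VAL; return; }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    const double pq = q * h;
    while (zb[j + 1] < pq) ++j;
    const double pv = v[j] * h;
    d[q] = (pq - pv) * (pq - pv) + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector seed, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  double* dp = D.begin();
  for (R_xlen_t i = 0; i < n; ++i) dp[i] = seed[i] ? 0.0 : HUGE_VAL;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t off = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = dp[off + x];
      dt1d(f, d, v, zb, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) dp[off + x] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t off = x + (R_xlen_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = dp[off + (R_xlen_t)nx * y];
      dt1d(f, d, v, zb, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) dp[off + (R_xlen_t)nx * y] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t off = x + (R_xlen_t)nx * y;
      const R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int z = 0; z < nz; ++z) f[z] = dp[off + stride * z];
      dt1d(f, d, v, zb, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) dp[off + stride * z] = d[z];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    dp[i] = (dp[i] == HUGE_VAL) ? R_PosInf : std::sqrt(dp[i]);
  D.attr("dim") = dims;
  return D;
}
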