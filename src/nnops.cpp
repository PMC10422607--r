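// Dense-tensor kernels for the 3D Res-UNet and image operators.
// Feature maps are stacked-batch (B*nvox x channels) matrices over a
// column-major (nx, ny, nz) voxel grid: within a sample, voxel
// v = x + nx*(y + ny*z), 0-based; sample b occupies rows [b*nvox, (b+1)*nvox).
// Convolution arithmetic runs in single precision (the training path is
// bandwidth-bound); interfaces stay double on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3x3 neighborhood, zero padding, stride 1, batch-stacked.
// Column layout: j = c*27 + k with k = (dx+1) + 3*(dy+1) + 9*(dz+1).
static void im2col3(const arma::fmat& X, int nx, int ny, int nz, int B,
                    arma::fmat& C) {
  const int cin = X.n_cols;
  const long nvox = (long)nx * ny * nz;
  C.set_size(B * nvox, 27 * cin);
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
  for (int dy = -1; dy <= 1; ++dy)
  for (int dx = -1; dx <= 1; ++dx, ++k) {
    for (int c = 0; c < cin; ++c) {
      const float* src0 = X.colptr(c);
      float* dst0 = C.colptr(c * 27 + k);
      for (int b = 0; b < B; ++b) {
        const float* src = src0 + b * nvox;
        float* dst = dst0 + b * nvox;
        for (int z = 0; z < nz; ++z) {
          const int sz = z + dz;
          float* drow0 = dst + (long)nx * (long)ny * z;
          if (sz < 0 || sz >= nz) {
            std::memset(drow0, 0, sizeof(float) * (size_t)nx * ny);
            continue;
          }
          for (int y = 0; y < ny; ++y) {
            const int sy = y + dy;
            float* d = drow0 + (long)nx * y;
            if (sy < 0 || sy >= ny) {
              std::memset(d, 0, sizeof(float) * nx);
              continue;
            }
            const float* s = src + (long)dx + (long)nx * (sy + (long)ny * sz);
            if (dx >= 0) {
              std::memcpy(d, s, sizeof(float) * (nx - dx));
              for (int x = nx - dx; x < nx; ++x) d[x] = 0.0f;
            } else {
              d[0] = 0.0f;
              std::memcpy(d + 1, s + 1, sizeof(float) * (nx - 1));
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd(const arma::mat& X, IntegerVector dims, int B,
                         const arma::mat& W, const arma::vec& b) {
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::fmat C;
  im2col3(Xf, dims[0], dims[1], dims[2], B, C);
  arma::fmat Y = C * Wf;
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b.t());
  Y.each_row() += bf;
  return arma::conv_to<arma::mat>::from(Y);
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(const arma::mat& dY, const arma::mat& X, IntegerVector dims,
                    int B, const arma::mat& W) {
  const int cin = X.n_cols, cout = dY.n_cols;
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat dYf = arma::conv_to<arma::fmat>::from(dY);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::fmat C;
  im2col3(Xf, dims[0], dims[1], dims[2], B, C);
  arma::fmat dWf = C.t() * dYf;
  arma::frowvec dbf = arma::sum(dYf, 0);
  // dX is itself a 3^3 convolution of dY with the spatially flipped,
  // channel-transposed kernel (keeps the GEMM in its efficient shape)
  arma::fmat Wflip(27 * cout, cin);
  for (int co = 0; co < cout; ++co)
    for (int k = 0; k < 27; ++k)
      for (int ci = 0; ci < cin; ++ci)
        Wflip(co * 27 + (26 - k), ci) = Wf(ci * 27 + k, co);
  im2col3(dYf, dims[0], dims[1], dims[2], B, C);
  arma::fmat dXf = C * Wflip;
  return List::create(_["dX"] = arma::conv_to<arma::mat>::from(dXf),
                      _["dW"] = arma::conv_to<arma::mat>::from(dWf),
                      _["db"] = arma::conv_to<arma::vec>::from(dbf.t()));
}

// 2x2x2 max pooling, stride 2; dims must be even. Returns pooled map and
// 1-based argmax row indices (into the stacked input) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool3d(const arma::mat& X, IntegerVector dims, int B) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int nc = X.n_cols;
  const long nvox = (long)nx * ny * nz;
  const long novox = (long)ox * oy * oz;
  arma::mat Y(B * novox, nc);
  IntegerMatrix IDX(B * novox, nc);
  for (int c = 0; c < nc; ++c) {
    const double* src0 = X.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* src = src0 + b * nvox;
      for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        double best = -std::numeric_limits<double>::infinity();
        long bidx = 0;
        for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          const long v = (2 * x + dx) + (long)nx * ((2 * y + dy) + (long)ny * (2 * z + dz));
          if (src[v] > best) { best = src[v]; bidx = v; }
        }
        const long o = b * novox + x + (long)ox * (y + (long)oy * z);
        Y(o, c) = best;
        IDX(o, c) = (int)(b * nvox + bidx + 1);
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = IDX);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool3d_bwd(const arma::mat& dY, const IntegerMatrix& idx, int nrow_in) {
  arma::mat dX(nrow_in, dY.n_cols, arma::fill::zeros);
  for (unsigned c = 0; c < dY.n_cols; ++c)
    for (unsigned o = 0; o < dY.n_rows; ++o)
      dX(idx(o, c) - 1, c) += dY(o, c);
  return dX;
}

// 2x2x2 transposed convolution, stride 2, batch-stacked.
// W is (cin x 8*cout), column j = co*8 + k with k = dx + 2*dy + 4*dz.
// [[Rcpp::export]]
arma::mat cpp_tconv3d_fwd(const arma::mat& X, IntegerVector dims, int B,
                          const arma::mat& W, const arma::vec& b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cout = W.n_cols / 8;
  const long nvox = (long)nx * ny * nz;
  arma::mat Col = X * W;  // B*nvox x 8*cout
  const long novox = 8L * nvox;
  arma::mat Y(B * novox, cout);
  for (int co = 0; co < cout; ++co) {
    double* dst0 = Y.colptr(co);
    for (long i = 0; i < B * novox; ++i) dst0[i] = b[co];
    int k = 0;
    for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
    for (int dx = 0; dx < 2; ++dx, ++k) {
      const double* src0 = Col.colptr(co * 8 + k);
      for (int b2 = 0; b2 < B; ++b2) {
        const double* src = src0 + b2 * nvox;
        double* dst = dst0 + b2 * novox;
        for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          const double* s = src + (long)nx * (y + (long)ny * z);
          double* d = dst + (long)(2 * nx) * ((2 * y + dy) + (long)(2 * ny) * (2 * z + dz)) + dx;
          for (int x = 0; x < nx; ++x) d[2 * x] += s[x];
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_tconv3d_bwd(const arma::mat& dY, const arma::mat& X, IntegerVector dims,
                     int B, const arma::mat& W) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cout = W.n_cols / 8;
  const long nvox = (long)nx * ny * nz;
  const long novox = 8L * nvox;
  arma::mat dCol(B * nvox, 8 * cout);
  for (int co = 0; co < cout; ++co) {
    const double* src0 = dY.colptr(co);
    int k = 0;
    for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
    for (int dx = 0; dx < 2; ++dx, ++k) {
      double* dst0 = dCol.colptr(co * 8 + k);
      for (int b = 0; b < B; ++b) {
        double* d0 = dst0 + b * nvox;
        const double* s0 = src0 + b * novox;
        for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          double* d = d0 + (long)nx * (y + (long)ny * z);
          const double* s = s0 + (long)(2 * nx) * ((2 * y + dy) + (long)(2 * ny) * (2 * z + dz)) + dx;
          for (int x = 0; x < nx; ++x) d[x] = s[2 * x];
        }
      }
    }
  }
  arma::mat dX = dCol * W.t();
  arma::mat dW = X.t() * dCol;
  arma::vec db = arma::sum(dY, 0).t();
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Batch-norm affine transform: out = (X - mu) * invstd * gamma + beta.
// [[Rcpp::export]]
arma::mat cpp_bn_apply(const arma::mat& X, const arma::vec& mu, const arma::vec& invstd,
                       const arma::vec& gamma, const arma::vec& beta) {
  arma::mat Y(X.n_rows, X.n_cols);
  for (unsigned c = 0; c < X.n_cols; ++c) {
    const double a = invstd[c] * gamma[c];
    const double off = beta[c] - mu[c] * a;
    const double* s = X.colptr(c);
    double* d = Y.colptr(c);
    for (unsigned i = 0; i < X.n_rows; ++i) d[i] = s[i] * a + off;
  }
  return Y;
}

// Batch-norm backward; xhat is recomputed from the cached input.
// [[Rcpp::export]]
List cpp_bn_bwd(const arma::mat& dY, const arma::mat& X, const arma::vec& mu,
                const arma::vec& invstd, const arma::vec& gamma) {
  const double N = (double)dY.n_rows;
  arma::vec dgamma(dY.n_cols), dbeta(dY.n_cols);
  arma::mat dX(dY.n_rows, dY.n_cols);
  for (unsigned c = 0; c < dY.n_cols; ++c) {
    const double* dy = dY.colptr(c);
    const double* x = X.colptr(c);
    const double m = mu[c], is = invstd[c];
    double s_dy = 0, s_dyxh = 0;
    for (unsigned i = 0; i < dY.n_rows; ++i) {
      const double xh = (x[i] - m) * is;
      s_dy += dy[i];
      s_dyxh += dy[i] * xh;
    }
    dgamma[c] = s_dyxh;
    dbeta[c] = s_dy;
    const double g = gamma[c];
    const double t1 = s_dy / N, t2 = s_dyxh / N;
    double* dx = dX.colptr(c);
    for (unsigned i = 0; i < dY.n_rows; ++i) {
      const double xh = (x[i] - m) * is;
      dx[i] = g * is * (dy[i] - t1 - xh * t2);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
arma::mat cpp_lrelu_fwd(const arma::mat& X, double slope) {
  arma::mat Y(X.n_rows, X.n_cols);
  const double* s = X.memptr();
  double* d = Y.memptr();
  const long n = (long)X.n_elem;
  for (long i = 0; i < n; ++i) d[i] = s[i] > 0 ? s[i] : slope * s[i];
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_lrelu_bwd(const arma::mat& dY, const arma::mat& X, double slope) {
  arma::mat dX(dY.n_rows, dY.n_cols);
  const double* dy = dY.memptr();
  const double* x = X.memptr();
  double* d = dX.memptr();
  const long n = (long)dY.n_elem;
  for (long i = 0; i < n; ++i) d[i] = x[i] > 0 ? dy[i] : slope * dy[i];
  return dX;
}

// 2x average pooling over all three axes (floor semantics: trailing odd
// voxels dropped), used between MS-SSIM scales.
// [[Rcpp::export]]
arma::vec cpp_avgpool2(const arma::vec& X, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  arma::vec Y((long)ox * oy * oz);
  for (int z = 0; z < oz; ++z)
  for (int y = 0; y < oy; ++y)
  for (int x = 0; x < ox; ++x) {
    double s = 0;
    for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
    for (int dx = 0; dx < 2; ++dx)
      s += X[(2 * x + dx) + (long)nx * ((2 * y + dy) + (long)ny * (2 * z + dz))];
    Y[x + (long)ox * (y + (long)oy * z)] = s / 8.0;
  }
  return Y;
}

// [[Rcpp::export]]
arma::vec cpp_avgpool2_bwd(const arma::vec& dY, IntegerVector dims_in) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  arma::vec dX((long)nx * ny * nz, arma::fill::zeros);
  for (int z = 0; z < oz; ++z)
  for (int y = 0; y < oy; ++y)
  for (int x = 0; x < ox; ++x) {
    const double gv = dY[x + (long)ox * (y + (long)oy * z)] / 8.0;
    for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
    for (int dx = 0; dx < 2; ++dx)
      dX[(2 * x + dx) + (long)nx * ((2 * y + dy) + (long)ny * (2 * z + dz))] += gv;
  }
  return dX;
}

static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable 3D correlation with a symmetric 1D kernel, symmetric
// (mirror) boundary handling. Kernel length must be odd.
// [[Rcpp::export]]
arma::vec cpp_gauss3(const arma::vec& X, IntegerVector dims, const arma::vec& kern) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int hw = ((int)kern.n_elem - 1) / 2;
  const long nvox = (long)nx * ny * nz;
  arma::vec A = X, B(nvox);
  for (int z = 0; z < nz; ++z)
  for (int y = 0; y < ny; ++y) {
    const long base = (long)nx * (y + (long)ny * z);
    for (int x = 0; x < nx; ++x) {
      double s = 0;
      for (int t = -hw; t <= hw; ++t) s += kern[t + hw] * A[base + reflect_idx(x + t, nx)];
      B[base + x] = s;
    }
  }
  for (int z = 0; z < nz; ++z)
  for (int x = 0; x < nx; ++x) {
    const long base = x + (long)nx * (long)ny * z;
    for (int y = 0; y < ny; ++y) {
      double s = 0;
      for (int t = -hw; t <= hw; ++t) s += kern[t + hw] * B[base + (long)nx * reflect_idx(y + t, ny)];
      A[base + (long)nx * y] = s;
    }
  }
  for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    const long base = x + (long)nx * y;
    const long strz = (long)nx * ny;
    for (int z = 0; z < nz; ++z) {
      double s = 0;
      for (int t = -hw; t <= hw; ++t) s += kern[t + hw] * A[base + strz * reflect_idx(z + t, nz)];
      B[base + strz * z] = s;
    }
  }
  return B;
}

// Catmull-Rom cubic kernel (a = -0.5).
static inline double cubic_cr(double x) {
  x = std::fabs(x);
  if (x < 1.0) return 1.5 * x * x * x - 2.5 * x * x + 1.0;
  if (x < 2.0) return -0.5 * x * x * x + 2.5 * x * x - 4.0 * x + 2.0;
  return 0.0;
}

// Bicubic resize of each coronal (x-y) slice; antialiased when shrinking
// (kernel support widened by the scale factor, weights renormalized).
// [[Rcpp::export]]
NumericVector cpp_resize_bicubic_xy(const NumericVector& X, IntegerVector dims,
                                    int nx_out, int ny_out) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = (double)nx / nx_out, sy = (double)ny / ny_out;
  const double kx = std::max(1.0, sx), ky = std::max(1.0, sy);
  const int wx = (int)std::ceil(2 * kx) * 2 + 1, wy = (int)std::ceil(2 * ky) * 2 + 1;
  std::vector<std::vector<double> > WX(nx_out), WY(ny_out);
  std::vector<std::vector<int> > IX(nx_out), IY(ny_out);
  for (int i = 0; i < nx_out; ++i) {
    const double xc = (i + 0.5) * sx - 0.5;
    const int j0 = (int)std::floor(xc - 2 * kx);
    double tot = 0;
    for (int j = j0; j <= j0 + wx; ++j) {
      const double w = cubic_cr((j - xc) / kx);
      if (w != 0.0) { WX[i].push_back(w); IX[i].push_back(reflect_idx(j, nx)); tot += w; }
    }
    for (size_t t = 0; t < WX[i].size(); ++t) WX[i][t] /= tot;
  }
  for (int i = 0; i < ny_out; ++i) {
    const double yc = (i + 0.5) * sy - 0.5;
    const int j0 = (int)std::floor(yc - 2 * ky);
    double tot = 0;
    for (int j = j0; j <= j0 + wy; ++j) {
      const double w = cubic_cr((j - yc) / ky);
      if (w != 0.0) { WY[i].push_back(w); IY[i].push_back(reflect_idx(j, ny)); tot += w; }
    }
    for (size_t t = 0; t < WY[i].size(); ++t) WY[i][t] /= tot;
  }
  NumericVector out((long)nx_out * ny_out * nz);
  std::vector<double> tmp((long)nx_out * ny);
  for (int z = 0; z < nz; ++z) {
    const double* slab = &X[(long)nx * ny * z];
    for (int y = 0; y < ny; ++y)
      for (int i = 0; i < nx_out; ++i) {
        double s = 0;
        for (size_t t = 0; t < WX[i].size(); ++t) s += WX[i][t] * slab[IX[i][t] + (long)nx * y];
        tmp[i + (long)nx_out * y] = s;
      }
    double* oslab = &out[(long)nx_out * ny_out * z];
    for (int i = 0; i < nx_out; ++i)
      for (int j = 0; j < ny_out; ++j) {
        double s = 0;
        for (size_t t = 0; t < WY[j].size(); ++t) s += WY[j][t] * tmp[i + (long)nx_out * IY[j][t]];
        oslab[i + (long)nx_out * j] = s;
      }
  }
  return out;
}
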