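// Low-level numerical kernels for the 3D CNN and volume resampling.
//
// Batches of feature maps are stored as (S*B) x C matrices, where S is the
// number of voxels on the current spatial grid (column-major, x fastest),
// B the batch size and C the channel count.  Volume b occupies the
// contiguous row block [b*S, (b+1)*S).  3x3x3 convolutions use an im2col
// gather followed by a BLAS matrix product; the patch matrix is rebuilt in
// the backward pass rather than cached, trading FLOPs for memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void im2col3(const arma::mat& X, const int b, const int S,
                           const int nx, const int ny, const int nz,
                           arma::mat& P) {
  const int cin = X.n_cols;
  const int nxy = nx * ny;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = X.colptr(ci) + (std::size_t)b * S;
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          const int k = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          double* pc = P.colptr(ci * 27 + k);
          const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int z = 0; z < nz; ++z) {
            const int zs = z + dz;
            const bool zok = zs >= 0 && zs < nz;
            for (int y = 0; y < ny; ++y) {
              const int ys = y + dy;
              const bool yok = zok && ys >= 0 && ys < ny;
              const int row0 = y * nx + z * nxy;
              const int src0 = ys * nx + zs * nxy;
              if (!yok) {
                std::memset(pc + row0, 0, sizeof(double) * nx);
              } else {
                if (x0 > 0) pc[row0] = 0.0;
                if (x1 < nx) pc[row0 + nx - 1] = 0.0;
                std::memcpy(pc + row0 + x0, xc + src0 + x0 + dx,
                            sizeof(double) * (x1 - x0));
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fw(const arma::mat& X, const IntegerVector dims,
                        const int B, const arma::mat& W,
                        const arma::rowvec& bias) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int S = nx * ny * nz;
  const int cout = W.n_cols;
  arma::mat Y((std::size_t)S * B, cout);
  arma::mat P(S, W.n_rows);
  for (int b = 0; b < B; ++b) {
    im2col3(X, b, S, nx, ny, nz, P);
    Y.rows((std::size_t)b * S, (std::size_t)(b + 1) * S - 1) = P * W;
  }
  Y.each_row() += bias;
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(const arma::mat& X, const IntegerVector dims, const int B,
                   const arma::mat& W, const arma::mat& dY,
                   const bool need_dx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int S = nx * ny * nz;
  const int cin = X.n_cols;
  const int nxy = nx * ny;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat dX(need_dx ? X.n_rows : 0, need_dx ? cin : 0, arma::fill::zeros);
  arma::mat P(S, W.n_rows);
  for (int b = 0; b < B; ++b) {
    im2col3(X, b, S, nx, ny, nz, P);
    const arma::mat dYb = dY.rows((std::size_t)b * S, (std::size_t)(b + 1) * S - 1);
    dW += P.t() * dYb;
    if (!need_dx) continue;
    arma::mat dP = dYb * W.t();
    // col2im: scatter-add each patch column back to its shifted location
    for (int ci = 0; ci < cin; ++ci) {
      double* xc = dX.colptr(ci) + (std::size_t)b * S;
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            const int k = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
            const double* pc = dP.colptr(ci * 27 + k);
            for (int z = 0; z < nz; ++z) {
              const int zs = z + dz;
              if (zs < 0 || zs >= nz) continue;
              for (int y = 0; y < ny; ++y) {
                const int ys = y + dy;
                if (ys < 0 || ys >= ny) continue;
                const int row0 = y * nx + z * nxy;
                const int src0 = ys * nx + zs * nxy;
                const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
                for (int x = x0; x < x1; ++x) xc[src0 + x + dx] += pc[row0 + x];
              }
            }
          }
        }
      }
    }
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fw(const arma::mat& X, const IntegerVector dims,
                      const int B) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int S = nx * ny * nz;
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int So = ox * oy * oz;
  const int C = X.n_cols;
  arma::mat Y((std::size_t)So * B, C);
  arma::imat idx((std::size_t)So * B, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    arma::sword* ic = idx.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* xb = xc + (std::size_t)b * S;
      for (int z = 0; z < oz; ++z) {
        for (int y = 0; y < oy; ++y) {
          for (int x = 0; x < ox; ++x) {
            double best = -std::numeric_limits<double>::infinity();
            int bi = 0;
            for (int kz = 0; kz < 2; ++kz)
              for (int ky = 0; ky < 2; ++ky)
                for (int kx = 0; kx < 2; ++kx) {
                  const int s = (2 * x + kx) + (2 * y + ky) * nx +
                                (2 * z + kz) * nx * ny;
                  if (xb[s] > best) { best = xb[s]; bi = s; }
                }
            const std::size_t o = (std::size_t)b * So + x + y * ox + z * ox * oy;
            yc[o] = best;
            ic[o] = bi;  // within-volume 0-based voxel index
          }
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool3d_bw(const arma::mat& dY, const arma::imat& idx,
                           const int S, const int B) {
  const int C = dY.n_cols;
  const int So = dY.n_rows / B;
  arma::mat dX((std::size_t)S * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* gc = dY.colptr(c);
    const arma::sword* ic = idx.colptr(c);
    double* xc = dX.colptr(c);
    for (int b = 0; b < B; ++b)
      for (int o = 0; o < So; ++o) {
        const std::size_t r = (std::size_t)b * So + o;
        xc[(std::size_t)b * S + ic[r]] += gc[r];
      }
  }
  return dX;
}

// per-column batch-norm kernels

// [[Rcpp::export]]
List cpp_col_stats(const arma::mat& Z) {
  const int n = Z.n_rows, C = Z.n_cols;
  arma::rowvec mu(C), va(C);
  for (int j = 0; j < C; ++j) {
    const double* z = Z.colptr(j);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += z[i]; s2 += z[i] * z[i]; }
    mu[j] = s / n;
    va[j] = s2 / n - mu[j] * mu[j];
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}

// y = (x - mu) * a + b, column-wise
// [[Rcpp::export]]
arma::mat cpp_col_affine(const arma::mat& X, const arma::rowvec& mu,
                         const arma::rowvec& a, const arma::rowvec& b) {
  const int n = X.n_rows, C = X.n_cols;
  arma::mat Y(n, C);
  for (int j = 0; j < C; ++j) {
    const double* x = X.colptr(j);
    double* y = Y.colptr(j);
    const double m = mu[j], aj = a[j], bj = b[j];
    for (int i = 0; i < n; ++i) y[i] = (x[i] - m) * aj + bj;
  }
  return Y;
}

// batch-norm backward; training=false reduces to the affine eval-mode case
// [[Rcpp::export]]
List cpp_bn_backward(const arma::mat& dOut, const arma::mat& Z,
                     const arma::rowvec& mu, const arma::rowvec& va,
                     const arma::rowvec& gamma, const double eps,
                     const bool training) {
  const int n = Z.n_rows, C = Z.n_cols;
  arma::mat dZ(n, C);
  arma::rowvec dgamma(C), dbeta(C);
  for (int j = 0; j < C; ++j) {
    const double isd = 1.0 / std::sqrt(va[j] + eps);
    const double* d = dOut.colptr(j);
    const double* z = Z.colptr(j);
    double* o = dZ.colptr(j);
    double sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      sg += d[i] * (z[i] - mu[j]) * isd;
      sb += d[i];
    }
    dgamma[j] = sg;
    dbeta[j] = sb;
    const double g = gamma[j] * isd;
    if (training) {
      const double mb = sb / n, mg = sg / n;
      for (int i = 0; i < n; ++i)
        o[i] = g * (d[i] - mb - (z[i] - mu[j]) * isd * mg);
    } else {
      for (int i = 0; i < n; ++i) o[i] = g * d[i];
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Rigid resampling.  rot (degrees) and trans (mm) define the forward map
// T(p) = R p + t in physical coordinates centred on each volume
// (R = Rz Ry Rx).  The output at physical point p samples the input at
// T^{-1}(p), so the returned volume is the input moved by T.
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(const NumericVector vol,
                                 const IntegerVector sdims,
                                 const NumericVector svox,
                                 const IntegerVector ddims,
                                 const NumericVector dvox,
                                 const NumericVector rot,
                                 const NumericVector trans,
                                 const bool nearest) {
  const int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  const int dx = ddims[0], dy = ddims[1], dz = ddims[2];
  const double d2r = M_PI / 180.0;
  const double ax = rot[0] * d2r, ay = rot[1] * d2r, az = rot[2] * d2r;
  const double cx = cos(ax), sxr = sin(ax);
  const double cy = cos(ay), syr = sin(ay);
  const double cz = cos(az), szr = sin(az);
  // R = Rz * Ry * Rx
  double R[3][3] = {
    {cz * cy, cz * syr * sxr - szr * cx, cz * syr * cx + szr * sxr},
    {szr * cy, szr * syr * sxr + cz * cx, szr * syr * cx - cz * sxr},
    {-syr, cy * sxr, cy * cx}};
  // inverse rotation = transpose
  const double scx = (sx - 1) / 2.0, scy = (sy - 1) / 2.0, scz = (sz - 1) / 2.0;
  const double dcx = (dx - 1) / 2.0, dcy = (dy - 1) / 2.0, dcz = (dz - 1) / 2.0;
  NumericVector out((std::size_t)dx * dy * dz);
  const double* v = vol.begin();
  double* o = out.begin();
  std::size_t n = 0;
  for (int k = 0; k < dz; ++k) {
    const double pz = (k - dcz) * dvox[2] - trans[2];
    for (int j = 0; j < dy; ++j) {
      const double py = (j - dcy) * dvox[1] - trans[1];
      for (int i = 0; i < dx; ++i, ++n) {
        const double px = (i - dcx) * dvox[0] - trans[0];
        const double qx = R[0][0] * px + R[1][0] * py + R[2][0] * pz;
        const double qy = R[0][1] * px + R[1][1] * py + R[2][1] * pz;
        const double qz = R[0][2] * px + R[1][2] * py + R[2][2] * pz;
        const double fx = qx / svox[0] + scx;
        const double fy = qy / svox[1] + scy;
        const double fz = qz / svox[2] + scz;
        if (nearest) {
          const int xi = (int)std::lround(fx), yi = (int)std::lround(fy),
                    zi = (int)std::lround(fz);
          o[n] = (xi >= 0 && xi < sx && yi >= 0 && yi < sy && zi >= 0 &&
                  zi < sz)
                     ? v[xi + (std::size_t)yi * sx + (std::size_t)zi * sx * sy]
                     : 0.0;
        } else {
          const int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
                    z0 = (int)std::floor(fz);
          if (x0 < -1 || x0 >= sx || y0 < -1 || y0 >= sy || z0 < -1 ||
              z0 >= sz) {
            o[n] = 0.0;
            continue;
          }
          const double wx = fx - x0, wy = fy - y0, wz = fz - z0;
          double acc = 0.0;
          for (int kz2 = 0; kz2 <= 1; ++kz2) {
            const int zz = z0 + kz2;
            if (zz < 0 || zz >= sz) continue;
            const double wzk = kz2 ? wz : 1.0 - wz;
            for (int ky2 = 0; ky2 <= 1; ++ky2) {
              const int yy = y0 + ky2;
              if (yy < 0 || yy >= sy) continue;
              const double wyk = ky2 ? wy : 1.0 - wy;
              for (int kx2 = 0; kx2 <= 1; ++kx2) {
                const int xx = x0 + kx2;
                if (xx < 0 || xx >= sx) continue;
                const double wxk = kx2 ? wx : 1.0 - wx;
                acc += wxk * wyk * wzk *
                       v[xx + (std::size_t)yy * sx + (std::size_t)zz * sx * sy];
              }
            }
          }
          o[n] = acc;
        }
      }
    }
  }
  out.attr("dim") = ddims;
  return out;
}
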