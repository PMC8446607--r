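// Numerical core: tensor primitives for the encoder-decoder networks and the
// strain engine. Volumes are stored as arma::mat with N = nx*ny*nz rows
// (column-major voxel linear index v = x + nx*(y + ny*z)) and one column per
// channel, which is the in-memory layout of an R array dim (nx, ny, nz, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Copy a shifted view of one channel into a destination buffer (zero pad):
// dst(v) = src(v - d).
static void shift_into(const double* src, double* dst, int nx, int ny, int nz,
                       int dx, int dy, int dz) {
  std::fill(dst, dst + (size_t)nx * ny * nz, 0.0);
  const int x0 = std::max(0, dx), x1 = std::min(nx, nx + dx);
  for (int z = 0; z < nz; ++z) {
    const int zs = z - dz;
    if (zs < 0 || zs >= nz) continue;
    for (int y = 0; y < ny; ++y) {
      const int ys = y - dy;
      if (ys < 0 || ys >= ny) continue;
      const double* s = src + (size_t)nx * (ys + (size_t)ny * zs) - dx;
      double* d = dst + (size_t)nx * (y + (size_t)ny * z);
      for (int xi = x0; xi < x1; ++xi) d[xi] = s[xi];
    }
  }
}

// Scatter-add the adjoint of shift_into: dst(v - d) += src(v).
static void shift_add_adjoint(const double* src, double* dst, int nx, int ny,
                              int nz, int dx, int dy, int dz) {
  const int x0 = std::max(0, dx), x1 = std::min(nx, nx + dx);
  for (int z = 0; z < nz; ++z) {
    const int zs = z - dz;
    if (zs < 0 || zs >= nz) continue;
    for (int y = 0; y < ny; ++y) {
      const int ys = y - dy;
      if (ys < 0 || ys >= ny) continue;
      double* d = dst + (size_t)nx * (ys + (size_t)ny * zs) - dx;
      const double* s = src + (size_t)nx * (y + (size_t)ny * z);
      for (int xi = x0; xi < x1; ++xi) d[xi] += s[xi];
    }
  }
}

// 3x3xkz same-padding convolution. w has dim (3,3,kz,Cin,Cout) flattened
// column-major; offsets run dx,dy in -1..1 and dz in -(kz-1)/2..(kz-1)/2.
// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd(const arma::mat& x, IntegerVector dims,
                         const arma::vec& w, const arma::vec& b, int kz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = x.n_cols;
  const int Cout = b.n_elem;
  const int hz = (kz - 1) / 2;
  const int ntap = 9 * kz;
  arma::mat y(x.n_rows, Cout, arma::fill::zeros);
  y.each_row() += b.t();
  arma::mat xs(x.n_rows, Cin);
  int k = 0;
  // column-major order of (3,3,kz): dx fastest, then dy, then dz
  for (int dz = -hz; dz <= hz; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        // W slice for this offset: (Cin, Cout), strided within w
        arma::mat Wk(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wk(ci, co) = w[k + ntap * (ci + (size_t)Cin * co)];
        for (int ci = 0; ci < Cin; ++ci)
          shift_into(x.colptr(ci), xs.colptr(ci), nx, ny, nz, dx, dy, dz);
        y += xs * Wk;
      }
  return y;
}

// Backward pass: returns gx (N x Cin), gw (same layout as w), gb (Cout).
// [[Rcpp::export]]
List cpp_conv3d_bwd(const arma::mat& x, IntegerVector dims, const arma::vec& w,
                    const arma::mat& gy, int kz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = x.n_cols;
  const int Cout = gy.n_cols;
  const int hz = (kz - 1) / 2;
  const int ntap = 9 * kz;
  arma::mat gx(x.n_rows, Cin, arma::fill::zeros);
  arma::vec gw(w.n_elem, arma::fill::zeros);
  arma::vec gb = arma::sum(gy, 0).t();
  arma::mat xs(x.n_rows, Cin);
  int k = 0;
  for (int dz = -hz; dz <= hz; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        for (int ci = 0; ci < Cin; ++ci)
          shift_into(x.colptr(ci), xs.colptr(ci), nx, ny, nz, dx, dy, dz);
        arma::mat gWk = xs.t() * gy; // (Cin, Cout)
        arma::mat Wk(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci) {
            gw[k + ntap * (ci + (size_t)Cin * co)] = gWk(ci, co);
            Wk(ci, co) = w[k + ntap * (ci + (size_t)Cin * co)];
          }
        // gx(v - d) += gy(v) * Wk^T (adjoint of the shifted gather)
        arma::mat gk = gy * Wk.t();
        for (int ci = 0; ci < Cin; ++ci)
          shift_add_adjoint(gk.colptr(ci), gx.colptr(ci), nx, ny, nz,
                            dx, dy, dz);
      }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 in-plane average pooling (stride 2); nx, ny must be even.
// [[Rcpp::export]]
arma::mat cpp_avgpool_fwd(const arma::mat& x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = x.n_cols, mx = nx / 2, my = ny / 2;
  arma::mat y((size_t)mx * my * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = y.colptr(c);
    for (int z = 0; z < nz; ++z)
      for (int yy = 0; yy < my; ++yy)
        for (int xx = 0; xx < mx; ++xx) {
          const size_t s = 2 * xx + (size_t)nx * (2 * yy + (size_t)ny * z);
          dst[xx + (size_t)mx * (yy + (size_t)my * z)] =
            0.25 * (src[s] + src[s + 1] + src[s + nx] + src[s + nx + 1]);
        }
  }
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_avgpool_bwd(const arma::mat& gy, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = gy.n_cols, mx = nx / 2, my = ny / 2;
  arma::mat gx((size_t)nx * ny * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* g = gy.colptr(c);
    double* d = gx.colptr(c);
    for (int z = 0; z < nz; ++z)
      for (int yy = 0; yy < my; ++yy)
        for (int xx = 0; xx < mx; ++xx) {
          const double v = 0.25 * g[xx + (size_t)mx * (yy + (size_t)my * z)];
          const size_t s = 2 * xx + (size_t)nx * (2 * yy + (size_t)ny * z);
          d[s] += v; d[s + 1] += v; d[s + nx] += v; d[s + nx + 1] += v;
        }
  }
  return gx;
}

// 2x in-plane nearest-neighbour upsampling.
// [[Rcpp::export]]
arma::mat cpp_upsample_fwd(const arma::mat& x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = x.n_cols, mx = nx * 2, my = ny * 2;
  arma::mat y((size_t)mx * my * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = y.colptr(c);
    for (int z = 0; z < nz; ++z)
      for (int yy = 0; yy < my; ++yy)
        for (int xx = 0; xx < mx; ++xx)
          dst[xx + (size_t)mx * (yy + (size_t)my * z)] =
            src[(xx / 2) + (size_t)nx * ((yy / 2) + (size_t)ny * z)];
  }
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_upsample_bwd(const arma::mat& gy, IntegerVector dims) {
  // dims are the dims of the (smaller) input
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = gy.n_cols, mx = nx * 2, my = ny * 2;
  arma::mat gx((size_t)nx * ny * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* g = gy.colptr(c);
    double* d = gx.colptr(c);
    for (int z = 0; z < nz; ++z)
      for (int yy = 0; yy < my; ++yy)
        for (int xx = 0; xx < mx; ++xx)
          d[(xx / 2) + (size_t)nx * ((yy / 2) + (size_t)ny * z)] +=
            g[xx + (size_t)mx * (yy + (size_t)my * z)];
  }
  return gx;
}

// Trilinear warp: y(v) = x(v + u(v)), border clamped. u in voxel units.
// [[Rcpp::export]]
arma::mat cpp_warp_fwd(const arma::mat& x, IntegerVector dims,
                       const arma::mat& u) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = x.n_cols;
  const size_t N = x.n_rows;
  arma::mat y(N, C, arma::fill::zeros);
  for (size_t v = 0; v < N; ++v) {
    const int vx = v % nx, vy = (v / nx) % ny, vz = v / ((size_t)nx * ny);
    double px = vx + u(v, 0), py = vy + u(v, 1), pz = vz + u(v, 2);
    px = std::min(std::max(px, 0.0), (double)(nx - 1));
    py = std::min(std::max(py, 0.0), (double)(ny - 1));
    pz = std::min(std::max(pz, 0.0), (double)(nz - 1));
    const int x0 = clampi((int)std::floor(px), 0, nx - 2);
    const int y0 = clampi((int)std::floor(py), 0, ny - 2);
    const int z0 = clampi((int)std::floor(pz), 0, nz - 2);
    const double fx = px - x0, fy = py - y0, fz = pz - z0;
    for (int c = 0; c < C; ++c) {
      const double* s = x.colptr(c);
      double acc = 0.0;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                               (dz ? fz : 1 - fz);
            acc += wgt * s[(x0 + dx) + (size_t)nx * ((y0 + dy) +
                           (size_t)ny * (z0 + dz))];
          }
      y(v, c) = acc;
    }
  }
  return y;
}

// Backward of the warp wrt both the sampled image x and the field u.
// [[Rcpp::export]]
List cpp_warp_bwd(const arma::mat& x, IntegerVector dims, const arma::mat& u,
                  const arma::mat& gy) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = x.n_cols;
  const size_t N = x.n_rows;
  arma::mat gx(N, C, arma::fill::zeros);
  arma::mat gu(N, 3, arma::fill::zeros);
  for (size_t v = 0; v < N; ++v) {
    const int vx = v % nx, vy = (v / nx) % ny, vz = v / ((size_t)nx * ny);
    const double rx = vx + u(v, 0), ry = vy + u(v, 1), rz = vz + u(v, 2);
    const double px = std::min(std::max(rx, 0.0), (double)(nx - 1));
    const double py = std::min(std::max(ry, 0.0), (double)(ny - 1));
    const double pz = std::min(std::max(rz, 0.0), (double)(nz - 1));
    // clamped coordinates have zero derivative wrt u
    const double mx_ = (rx > 0.0 && rx < nx - 1) ? 1.0 : 0.0;
    const double my_ = (ry > 0.0 && ry < ny - 1) ? 1.0 : 0.0;
    const double mz_ = (rz > 0.0 && rz < nz - 1) ? 1.0 : 0.0;
    const int x0 = clampi((int)std::floor(px), 0, nx - 2);
    const int y0 = clampi((int)std::floor(py), 0, ny - 2);
    const int z0 = clampi((int)std::floor(pz), 0, nz - 2);
    const double fx = px - x0, fy = py - y0, fz = pz - z0;
    double gux = 0, guy = 0, guz = 0;
    for (int c = 0; c < C; ++c) {
      const double g = gy(v, c);
      if (g == 0.0) continue;
      const double* s = x.colptr(c);
      double* d = gx.colptr(c);
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const size_t idx = (x0 + dx) + (size_t)nx * ((y0 + dy) +
                               (size_t)ny * (z0 + dz));
            const double wx = dx ? fx : 1 - fx, wy = dy ? fy : 1 - fy,
                         wz = dz ? fz : 1 - fz;
            d[idx] += g * wx * wy * wz;
            const double sv = s[idx];
            gux += g * sv * (dx ? 1.0 : -1.0) * wy * wz;
            guy += g * sv * wx * (dy ? 1.0 : -1.0) * wz;
            guz += g * sv * wx * wy * (dz ? 1.0 : -1.0);
          }
    }
    gu(v, 0) = gux * mx_; gu(v, 1) = guy * my_; gu(v, 2) = guz * mz_;
  }
  return List::create(_["gx"] = gx, _["gu"] = gu);
}

// Sample channels of a volume at arbitrary (voxel-coordinate) points.
// mode 0 = trilinear, 1 = nearest neighbour. pts is (m, 3), 0-based.
// [[Rcpp::export]]
arma::mat cpp_sample_points(const arma::mat& x, IntegerVector dims,
                            const arma::mat& pts, int mode) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = x.n_cols;
  const size_t m = pts.n_rows;
  arma::mat y(m, C, arma::fill::zeros);
  for (size_t i = 0; i < m; ++i) {
    double px = std::min(std::max(pts(i, 0), 0.0), (double)(nx - 1));
    double py = std::min(std::max(pts(i, 1), 0.0), (double)(ny - 1));
    double pz = std::min(std::max(pts(i, 2), 0.0), (double)(nz - 1));
    if (mode == 1) {
      const int xi = clampi((int)std::lround(px), 0, nx - 1);
      const int yi = clampi((int)std::lround(py), 0, ny - 1);
      const int zi = clampi((int)std::lround(pz), 0, nz - 1);
      const size_t idx = xi + (size_t)nx * (yi + (size_t)ny * zi);
      for (int c = 0; c < C; ++c) y(i, c) = x(idx, c);
    } else {
      const int x0 = clampi((int)std::floor(px), 0, nx - 2);
      const int y0 = clampi((int)std::floor(py), 0, ny - 2);
      const int z0 = (nz > 1) ? clampi((int)std::floor(pz), 0, nz - 2) : 0;
      const double fx = px - x0, fy = py - y0, fz = (nz > 1) ? pz - z0 : 0.0;
      for (int c = 0; c < C; ++c) {
        const double* s = x.colptr(c);
        double acc = 0.0;
        for (int dz = 0; dz < (nz > 1 ? 2 : 1); ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                                 (dz ? fz : 1 - fz);
              acc += wgt * s[(x0 + dx) + (size_t)nx * ((y0 + dy) +
                             (size_t)ny * (z0 + dz))];
            }
        y(i, c) = acc;
      }
    }
  }
  return y;
}

// Central-difference derivative along axis (0,1,2) in voxel units,
// one-sided at the borders. Works on every channel column.
// [[Rcpp::export]]
arma::mat cpp_fd(const arma::mat& x, IntegerVector dims, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int C = x.n_cols;
  arma::mat g(x.n_rows, C, arma::fill::zeros);
  const int na = n[axis];
  const size_t st = stride[axis];
  for (int c = 0; c < C; ++c) {
    const double* s = x.colptr(c);
    double* d = g.colptr(c);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int xx = 0; xx < nx; ++xx) {
          const size_t v = xx + (size_t)nx * (y + (size_t)ny * z);
          const int a = (axis == 0) ? xx : (axis == 1 ? y : z);
          if (na == 1) { d[v] = 0.0; continue; }
          if (a == 0) d[v] = s[v + st] - s[v];
          else if (a == na - 1) d[v] = s[v] - s[v - st];
          else d[v] = 0.5 * (s[v + st] - s[v - st]);
        }
  }
  return g;
}

// Adjoint of cpp_fd: g given on outputs, accumulate onto inputs.
// [[Rcpp::export]]
arma::mat cpp_fd_adjoint(const arma::mat& g, IntegerVector dims, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int C = g.n_cols;
  arma::mat out(g.n_rows, C, arma::fill::zeros);
  const int na = n[axis];
  const size_t st = stride[axis];
  if (na == 1) return out;
  for (int c = 0; c < C; ++c) {
    const double* s = g.colptr(c);
    double* d = out.colptr(c);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int xx = 0; xx < nx; ++xx) {
          const size_t v = xx + (size_t)nx * (y + (size_t)ny * z);
          const int a = (axis == 0) ? xx : (axis == 1 ? y : z);
          const double gv = s[v];
          if (gv == 0.0) continue;
          if (a == 0) { d[v + st] += gv; d[v] -= gv; }
          else if (a == na - 1) { d[v] += gv; d[v - st] -= gv; }
          else { d[v + st] += 0.5 * gv; d[v - st] -= 0.5 * gv; }
        }
  }
  return out;
}

// PReLU with a single shared slope.
// [[Rcpp::export]]
arma::mat cpp_prelu_fwd(const arma::mat& x, double alpha) {
  arma::mat y = x;
  y.for_each([alpha](double& v) { if (v < 0) v *= alpha; });
  return y;
}

// [[Rcpp::export]]
List cpp_prelu_bwd(const arma::mat& x, double alpha, const arma::mat& g) {
  arma::mat gx(x.n_rows, x.n_cols);
  double galpha = 0.0;
  const size_t n = x.n_elem;
  const double* xp = x.memptr();
  const double* gp = g.memptr();
  double* dp = gx.memptr();
  for (size_t i = 0; i < n; ++i) {
    if (xp[i] > 0) dp[i] = gp[i];
    else { dp[i] = alpha * gp[i]; galpha += gp[i] * xp[i]; }
  }
  return List::create(_["gx"] = gx, _["galpha"] = galpha);
}

// Batch norm over rows (batch + space), per channel column; training mode.
// [[Rcpp::export]]
List cpp_bn_fwd_train(const arma::mat& x, const arma::vec& gamma,
                      const arma::vec& beta, double eps) {
  arma::rowvec mu = arma::mean(x, 0);
  arma::mat xhat = x.each_row() - mu;
  arma::rowvec va = arma::mean(arma::square(xhat), 0);
  arma::rowvec sdv = arma::sqrt(va + eps);
  xhat.each_row() /= sdv;
  arma::mat y = xhat.each_row() % gamma.t();
  y.each_row() += beta.t();
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = va, _["sdv"] = sdv);
}

// [[Rcpp::export]]
arma::mat cpp_bn_fwd_infer(const arma::mat& x, const arma::vec& mean,
                           const arma::vec& var, const arma::vec& gamma,
                           const arma::vec& beta, double eps) {
  arma::rowvec sdv = arma::sqrt(var.t() + eps);
  arma::mat y = x.each_row() - mean.t();
  y.each_row() /= sdv;
  y.each_row() %= gamma.t();
  y.each_row() += beta.t();
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(const arma::mat& xhat, const arma::rowvec& sdv,
                const arma::vec& gamma, const arma::mat& g) {
  arma::rowvec gbeta = arma::sum(g, 0);
  arma::rowvec ggamma = arma::sum(g % xhat, 0);
  arma::mat dxhat = g.each_row() % gamma.t();
  arma::rowvec m1 = arma::mean(dxhat, 0);
  arma::rowvec m2 = arma::mean(dxhat % xhat, 0);
  arma::mat gx = dxhat.each_row() - m1;
  gx -= xhat.each_row() % m2;
  gx.each_row() /= sdv;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma.t(),
                      _["gbeta"] = gbeta.t());
}
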