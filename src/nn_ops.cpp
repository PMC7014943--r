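#include <RcppArmadillo.h>

using namespace arma;

// Dense feature maps are C x N matrices with voxel index v = x + X*(y + Y*z)
// (column-major volume order, x fastest). Convolutions use symmetric zero
// padding of (k-1)/2, so stride-1 output extents equal input extents and a
// stride-2 axis of even extent halves exactly.

static inline int out_extent(int n, int k, int s) {
  const int p = (k - 1) / 2;
  return (n + 2 * p - k) / s + 1;
}

// Column chunking bounds the im2col buffer (C*k^3 x CHUNK) so large volumes
// never materialize a full unfolded matrix.
static const long CHUNK = 4096;

static void im2col_range(const mat& x, int X, int Y, int Z,
                         int k, int sx, int sy, int sz,
                         int Xo, int Yo,
                         long c0, long c1, mat& cols) {
  const int C = x.n_rows;
  const int pad = (k - 1) / 2;
  cols.zeros();
  for (long c = c0; c < c1; ++c) {
    long rem = c;
    const int ox = (int)(rem % Xo); rem /= Xo;
    const int oy = (int)(rem % Yo); rem /= Yo;
    const int oz = (int)rem;
    const int bx = ox * sx - pad, by = oy * sy - pad, bz = oz * sz - pad;
    double* col = cols.colptr(c - c0);
    int off = 0;
    for (int dz = 0; dz < k; ++dz) {
      const int z = bz + dz;
      for (int dy = 0; dy < k; ++dy) {
        const int y = by + dy;
        for (int dx = 0; dx < k; ++dx, off += C) {
          const int xx = bx + dx;
          if (xx < 0 || y < 0 || z < 0 || xx >= X || y >= Y || z >= Z) continue;
          const double* src = x.colptr((long)xx + (long)X * (y + (long)Y * z));
          std::copy(src, src + C, col + off);
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv3d_fwd(const arma::mat& x, int X, int Y, int Z,
                     const arma::mat& W, int k, int sx, int sy, int sz) {
  if (k == 1 && sx == 1 && sy == 1 && sz == 1) return W * x;
  const int Xo = out_extent(X, k, sx);
  const int Yo = out_extent(Y, k, sy);
  const int Zo = out_extent(Z, k, sz);
  const long No = (long)Xo * Yo * Zo;
  mat y(W.n_rows, No);
  mat cols(x.n_rows * k * k * k, (uword)std::min(CHUNK, No));
  for (long c0 = 0; c0 < No; c0 += CHUNK) {
    const long c1 = std::min(No, c0 + CHUNK);
    mat sub(cols.memptr(), cols.n_rows, (uword)(c1 - c0), false, true);
    im2col_range(x, X, Y, Z, k, sx, sy, sz, Xo, Yo, c0, c1, sub);
    y.cols((uword)c0, (uword)(c1 - 1)) = W * sub;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bwd(const arma::mat& x, int X, int Y, int Z,
                      const arma::mat& W, int k, int sx, int sy, int sz,
                      const arma::mat& dy) {
  if (k == 1 && sx == 1 && sy == 1 && sz == 1) {
    return Rcpp::List::create(Rcpp::Named("dW") = dy * x.t(),
                              Rcpp::Named("dx") = W.t() * dy);
  }
  const int C = x.n_rows;
  const int pad = (k - 1) / 2;
  const int Xo = out_extent(X, k, sx);
  const int Yo = out_extent(Y, k, sy);
  const int Zo = out_extent(Z, k, sz);
  const long No = (long)Xo * Yo * Zo;
  mat dW(size(W), fill::zeros);
  mat dx(size(x), fill::zeros);
  mat cols(C * k * k * k, (uword)std::min(CHUNK, No));
  for (long c0 = 0; c0 < No; c0 += CHUNK) {
    const long c1 = std::min(No, c0 + CHUNK);
    mat sub(cols.memptr(), cols.n_rows, (uword)(c1 - c0), false, true);
    im2col_range(x, X, Y, Z, k, sx, sy, sz, Xo, Yo, c0, c1, sub);
    dW += dy.cols((uword)c0, (uword)(c1 - 1)) * sub.t();
    mat dcols = W.t() * dy.cols((uword)c0, (uword)(c1 - 1));
    for (long c = c0; c < c1; ++c) {
      long rem = c;
      const int ox = (int)(rem % Xo); rem /= Xo;
      const int oy = (int)(rem % Yo); rem /= Yo;
      const int oz = (int)rem;
      const int bx = ox * sx - pad, by = oy * sy - pad, bz = oz * sz - pad;
      const double* col = dcols.colptr(c - c0);
      int off = 0;
      for (int dz = 0; dz < k; ++dz) {
        const int z = bz + dz;
        for (int dyy = 0; dyy < k; ++dyy) {
          const int y = by + dyy;
          for (int dxx = 0; dxx < k; ++dxx, off += C) {
            const int xx = bx + dxx;
            if (xx < 0 || y < 0 || z < 0 || xx >= X || y >= Y || z >= Z) continue;
            double* dst = dx.colptr((long)xx + (long)X * (y + (long)Y * z));
            const double* s = col + off;
            for (int ch = 0; ch < C; ++ch) dst[ch] += s[ch];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("dx") = dx);
}

// Per-axis interpolation map for x2 upsampling (or identity when f = 1).
// Linear mode uses the half-voxel-centre convention: input position of
// output voxel o is (o + 0.5)/f - 0.5, clamped at the volume border.
struct AxisMap {
  std::vector<int> i0, i1;
  std::vector<double> t;
  int n_out;
};

static AxisMap axis_map(int n_in, int f, bool nearest) {
  AxisMap m;
  m.n_out = n_in * f;
  m.i0.resize(m.n_out);
  m.i1.resize(m.n_out);
  m.t.resize(m.n_out);
  for (int o = 0; o < m.n_out; ++o) {
    if (f == 1) { m.i0[o] = o; m.i1[o] = o; m.t[o] = 0.0; continue; }
    if (nearest) { m.i0[o] = o / f; m.i1[o] = m.i0[o]; m.t[o] = 0.0; continue; }
    double pos = (o + 0.5) / f - 0.5;
    int f0 = (int)std::floor(pos);
    double t = pos - f0;
    if (f0 < 0) { f0 = 0; t = 0.0; }
    if (f0 >= n_in - 1) { f0 = n_in - 1; t = 0.0; }
    m.i0[o] = f0;
    m.i1[o] = std::min(f0 + 1, n_in - 1);
    m.t[o] = t;
  }
  return m;
}

// [[Rcpp::export]]
arma::mat upsample3d_fwd(const arma::mat& x, int X, int Y, int Z,
                         int fx, int fy, int fz, bool nearest) {
  const AxisMap mx = axis_map(X, fx, nearest);
  const AxisMap my = axis_map(Y, fy, nearest);
  const AxisMap mz = axis_map(Z, fz, nearest);
  const long No = (long)mx.n_out * my.n_out * mz.n_out;
  mat y(x.n_rows, No, fill::zeros);
  for (int oz = 0; oz < mz.n_out; ++oz) {
    for (int oy = 0; oy < my.n_out; ++oy) {
      for (int ox = 0; ox < mx.n_out; ++ox) {
        const long vo = ox + (long)mx.n_out * (oy + (long)my.n_out * oz);
        for (int cz = 0; cz < 2; ++cz) {
          const double wz = cz ? mz.t[oz] : 1.0 - mz.t[oz];
          if (wz == 0.0) continue;
          const int iz = cz ? mz.i1[oz] : mz.i0[oz];
          for (int cy = 0; cy < 2; ++cy) {
            const double wy = cy ? my.t[oy] : 1.0 - my.t[oy];
            if (wy == 0.0) continue;
            const int iy = cy ? my.i1[oy] : my.i0[oy];
            for (int cx = 0; cx < 2; ++cx) {
              const double wx = cx ? mx.t[ox] : 1.0 - mx.t[ox];
              if (wx == 0.0) continue;
              const int ix = cx ? mx.i1[ox] : mx.i0[ox];
              const long vi = ix + (long)X * (iy + (long)Y * iz);
              y.col(vo) += (wx * wy * wz) * x.col(vi);
            }
          }
        }
      }
    }
  }
  return y;
}

// Adjoint of upsample3d_fwd; X, Y, Z are the *input* (coarse) extents and dy
// has fx*X * fy*Y * fz*Z columns.
// [[Rcpp::export]]
arma::mat upsample3d_adj(const arma::mat& dy, int X, int Y, int Z,
                         int fx, int fy, int fz, bool nearest) {
  const AxisMap mx = axis_map(X, fx, nearest);
  const AxisMap my = axis_map(Y, fy, nearest);
  const AxisMap mz = axis_map(Z, fz, nearest);
  mat dx(dy.n_rows, (uword)((long)X * Y * Z), fill::zeros);
  for (int oz = 0; oz < mz.n_out; ++oz) {
    for (int oy = 0; oy < my.n_out; ++oy) {
      for (int ox = 0; ox < mx.n_out; ++ox) {
        const long vo = ox + (long)mx.n_out * (oy + (long)my.n_out * oz);
        for (int cz = 0; cz < 2; ++cz) {
          const double wz = cz ? mz.t[oz] : 1.0 - mz.t[oz];
          if (wz == 0.0) continue;
          const int iz = cz ? mz.i1[oz] : mz.i0[oz];
          for (int cy = 0; cy < 2; ++cy) {
            const double wy = cy ? my.t[oy] : 1.0 - my.t[oy];
            if (wy == 0.0) continue;
            const int iy = cy ? my.i1[oy] : my.i0[oy];
            for (int cx = 0; cx < 2; ++cx) {
              const double wx = cx ? mx.t[ox] : 1.0 - mx.t[ox];
              if (wx == 0.0) continue;
              const int ix = cx ? mx.i1[ox] : mx.i0[ox];
              const long vi = ix + (long)X * (iy + (long)Y * iz);
              dx.col(vi) += (wx * wy * wz) * dy.col(vo);
            }
          }
        }
      }
    }
  }
  return dx;
}

// First (lowest) index of the per-column maximum, 0-based.
// [[Rcpp::export]]
arma::ivec argmax_cols(const arma::mat& p) {
  arma::ivec out(p.n_cols);
  for (uword j = 0; j < p.n_cols; ++j) {
    const double* c = p.colptr(j);
    int best = 0;
    double bv = c[0];
    for (uword i = 1; i < p.n_rows; ++i) {
      if (c[i] > bv) { bv = c[i]; best = (int)i; }
    }
    out[(uword)j] = best;
  }
  return out;
}
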