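// Hot loops of the volumetric convolutions: per-kernel-offset slice
// extraction and scatter-accumulation. Tensors arrive as flat numeric
// vectors in (X, Y, Z, N, C) column-major layout; weights as matrices with
// k^3*Cin rows in offset-major order (channel fastest within an offset),
// matching the R-side layout. BLAS does the channel contraction per offset,
// so no im2col buffer larger than one (voxel*batch) x Cin block is live.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Gather the strided spatial slice for kernel offset (dx,dy,dz) into
// Xs (rows: voxel-within-sample then sample; cols: input channel).
// Zero padding is implicit: out-of-range voxels stay 0.
void gather_offset(const double* x, const int* d, int k, int stride, int pad,
                   int dx, int dy, int dz, const int* od, arma::mat& Xs) {
  const int X = d[0], Y = d[1], Z = d[2], N = d[3], C = d[4];
  const int ox = od[0], oy = od[1], oz = od[2];
  const long plane = (long)X * Y, vol = plane * Z;
  Xs.zeros();
  for (int c = 0; c < C; ++c) {
    double* dst = Xs.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* src = x + vol * (n + (long)N * c);
      for (int vz = 0; vz < oz; ++vz) {
        const int iz = vz * stride + dz - pad;
        if (iz < 0 || iz >= Z) continue;
        for (int vy = 0; vy < oy; ++vy) {
          const int iy = vy * stride + dy - pad;
          if (iy < 0 || iy >= Y) continue;
          double* drow = dst + (long)ox * (vy + (long)oy * (vz + (long)oz * n));
          const double* srow = src + (long)X * (iy + (long)Y * iz);
          if (stride == 1) {
            int v0 = std::max(0, pad - dx);
            int v1 = std::min(ox, X + pad - dx);
            for (int vx = v0; vx < v1; ++vx) drow[vx] = srow[vx + dx - pad];
          } else {
            for (int vx = 0; vx < ox; ++vx) {
              const int ix = vx * stride + dx - pad;
              if (ix >= 0 && ix < X) drow[vx] = srow[ix];
            }
          }
        }
      }
    }
  }
}

// Scatter-accumulate G (same layout as Xs) back into dx at the strided
// positions of kernel offset (dx,dy,dz).
void scatter_offset(double* gx, const int* d, int k, int stride, int pad,
                    int dx, int dy, int dz, const int* od, const arma::mat& G) {
  const int X = d[0], Y = d[1], Z = d[2], N = d[3], C = d[4];
  const int ox = od[0], oy = od[1], oz = od[2];
  const long plane = (long)X * Y, vol = plane * Z;
  for (int c = 0; c < C; ++c) {
    const double* src = G.colptr(c);
    for (int n = 0; n < N; ++n) {
      double* dst = gx + vol * (n + (long)N * c);
      for (int vz = 0; vz < oz; ++vz) {
        const int iz = vz * stride + dz - pad;
        if (iz < 0 || iz >= Z) continue;
        for (int vy = 0; vy < oy; ++vy) {
          const int iy = vy * stride + dy - pad;
          if (iy < 0 || iy >= Y) continue;
          const double* srow = src + (long)ox * (vy + (long)oy * (vz + (long)oz * n));
          double* drow = dst + (long)X * (iy + (long)Y * iz);
          if (stride == 1) {
            int v0 = std::max(0, pad - dx);
            int v1 = std::min(ox, X + pad - dx);
            for (int vx = v0; vx < v1; ++vx) drow[vx + dx - pad] += srow[vx];
          } else {
            for (int vx = 0; vx < ox; ++vx) {
              const int ix = vx * stride + dx - pad;
              if (ix >= 0 && ix < X) drow[ix] += srow[vx];
            }
          }
        }
      }
    }
  }
}

void out_dims(const int* d, int k, int stride, int pad, int* od) {
  for (int a = 0; a < 3; ++a) od[a] = (d[a] + 2 * pad - k) / stride + 1;
}

}  // namespace

// [[Rcpp::export]]
NumericVector ds_conv3_fwd(NumericVector x, IntegerVector dims, arma::mat W,
                           Nullable<NumericVector> bias, int k, int stride, int pad) {
  const int* d = dims.begin();
  int od[3];
  out_dims(d, k, stride, pad, od);
  const int N = d[3], C = d[4], cout = W.n_cols;
  const long V = (long)od[0] * od[1] * od[2] * N;
  arma::mat Y(V, cout, arma::fill::zeros);
  arma::mat Xs(V, C);
  int o = 0;
  for (int dz = 0; dz < k; ++dz)
    for (int dy = 0; dy < k; ++dy)
      for (int dx = 0; dx < k; ++dx, ++o) {
        // offset index must match R: expand.grid(dx, dy, dz) -> dx fastest
        int oo = dx + k * (dy + k * dz);
        gather_offset(x.begin(), d, k, stride, pad, dx, dy, dz, od, Xs);
        Y += Xs * W.rows(oo * C, (oo + 1) * C - 1);
      }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int c = 0; c < cout; ++c) Y.col(c) += b[c];
  }
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(od[0], od[1], od[2], N, cout);
  return out;
}

// [[Rcpp::export]]
List ds_conv3_bwd(NumericVector x, IntegerVector dims, arma::mat W,
                  NumericVector gy, int k, int stride, int pad, bool need_dx) {
  const int* d = dims.begin();
  int od[3];
  out_dims(d, k, stride, pad, od);
  const int N = d[3], C = d[4], cout = W.n_cols;
  const long V = (long)od[0] * od[1] * od[2] * N;
  arma::mat G(gy.begin(), V, cout, false);
  arma::mat dW(W.n_rows, cout, arma::fill::zeros);
  NumericVector dx;
  double* gx = nullptr;
  if (need_dx) {
    dx = NumericVector((long)d[0] * d[1] * d[2] * N * C);
    gx = dx.begin();
  }
  arma::mat Xs(V, C);
  for (int dz = 0; dz < k; ++dz)
    for (int dy = 0; dy < k; ++dy)
      for (int dx_ = 0; dx_ < k; ++dx_) {
        int oo = dx_ + k * (dy + k * dz);
        gather_offset(x.begin(), d, k, stride, pad, dx_, dy, dz, od, Xs);
        dW.rows(oo * C, (oo + 1) * C - 1) = Xs.t() * G;
        if (need_dx) {
          arma::mat Gi = G * W.rows(oo * C, (oo + 1) * C - 1).t();
          scatter_offset(gx, d, k, stride, pad, dx_, dy, dz, od, Gi);
        }
      }
  arma::rowvec db = arma::sum(G, 0);
  List out = List::create(Named("dW") = dW,
                          Named("db") = NumericVector(db.begin(), db.end()));
  if (need_dx) {
    dx.attr("dim") = dims;
    out["dx"] = dx;
  }
  return out;
}

// Transposed convolution, kernel 2, stride 2: each input voxel writes a
// disjoint 2x2x2 output block.
// [[Rcpp::export]]
NumericVector ds_convT2_fwd(NumericVector x, IntegerVector dims, arma::mat W,
                            Nullable<NumericVector> bias) {
  const int* d = dims.begin();
  const int N = d[3], C = d[4], cout = W.n_cols;
  const long Vin = (long)d[0] * d[1] * d[2] * N;
  arma::mat Xm(x.begin(), Vin, C, false);
  int od[5] = {2 * d[0], 2 * d[1], 2 * d[2], N, cout};
  NumericVector y((long)od[0] * od[1] * od[2] * N * cout);
  double b0 = 0;
  NumericVector b;
  if (bias.isNotNull()) b = NumericVector(bias);
  int idim[3] = {d[0], d[1], d[2]};
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        int oo = dx + 2 * (dy + 2 * dz);
        arma::mat Yo = Xm * W.rows(oo * C, (oo + 1) * C - 1);
        if (bias.isNotNull())
          for (int c = 0; c < cout; ++c) Yo.col(c) += b[c];
        // scatter: y[2*vx+dx, 2*vy+dy, 2*vz+dz, n, c] = Yo[(vx,vy,vz,n), c]
        const long ovol = (long)od[0] * od[1] * od[2];
        for (int c = 0; c < cout; ++c) {
          const double* src = Yo.colptr(c);
          for (int n = 0; n < N; ++n) {
            double* dst = y.begin() + ovol * (n + (long)N * c);
            for (int vz = 0; vz < idim[2]; ++vz)
              for (int vy = 0; vy < idim[1]; ++vy) {
                const double* srow = src + (long)idim[0] * (vy + (long)idim[1] * (vz + (long)idim[2] * n));
                double* drow = dst + (long)od[0] * ((2 * vy + dy) + (long)od[1] * (2 * vz + dz)) + dx;
                for (int vx = 0; vx < idim[0]; ++vx) drow[2 * vx] = srow[vx];
              }
          }
        }
      }
  (void)b0;
  y.attr("dim") = IntegerVector::create(od[0], od[1], od[2], N, cout);
  return y;
}

// [[Rcpp::export]]
List ds_convT2_bwd(NumericVector x, IntegerVector dims, arma::mat W,
                   NumericVector gy, bool need_dx) {
  const int* d = dims.begin();
  const int N = d[3], C = d[4], cout = W.n_cols;
  const long Vin = (long)d[0] * d[1] * d[2] * N;
  arma::mat Xm(x.begin(), Vin, C, false);
  const int odx = 2 * d[0], ody = 2 * d[1], odz = 2 * d[2];
  const long ovol = (long)odx * ody * odz;
  arma::mat dW(W.n_rows, cout, arma::fill::zeros);
  arma::mat dX(Vin, C, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  arma::mat Go(Vin, cout);
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        int oo = dx + 2 * (dy + 2 * dz);
        // gather gy slice
        for (int c = 0; c < cout; ++c) {
          double* dst = Go.colptr(c);
          for (int n = 0; n < N; ++n) {
            const double* src = gy.begin() + ovol * (n + (long)N * c);
            for (int vz = 0; vz < d[2]; ++vz)
              for (int vy = 0; vy < d[1]; ++vy) {
                double* drow = dst + (long)d[0] * (vy + (long)d[1] * (vz + (long)d[2] * n));
                const double* srow = src + (long)odx * ((2 * vy + dy) + (long)ody * (2 * vz + dz)) + dx;
                for (int vx = 0; vx < d[0]; ++vx) drow[vx] = srow[2 * vx];
              }
          }
        }
        dW.rows(oo * C, (oo + 1) * C - 1) = Xm.t() * Go;
        if (need_dx) dX += Go * W.rows(oo * C, (oo + 1) * C - 1).t();
        db += arma::sum(Go, 0).t();
      }
  List out = List::create(Named("dW") = dW,
                          Named("db") = NumericVector(db.begin(), db.end()));
  if (need_dx) {
    NumericVector dx(dX.begin(), dX.end());
    dx.attr("dim") = dims;
    out["dx"] = dx;
  }
  return out;
}

// 2x2x2 max pooling, stride 2. Returns the pooled values and the argmax
// offset (1..8) for the backward scatter.
// [[Rcpp::export]]
List ds_maxpool2_fwd(NumericVector x, IntegerVector dims) {
  const int* d = dims.begin();
  const int N = d[3], C = d[4];
  const int ox = d[0] / 2, oy = d[1] / 2, oz = d[2] / 2;
  const long Vo = (long)ox * oy * oz * N * C;
  NumericVector y(Vo);
  IntegerVector arg(Vo);
  const long plane = (long)d[0] * d[1];
  long r = 0;
  for (long nc = 0; nc < (long)N * C; ++nc) {
    const double* src = x.begin() + (long)plane * d[2] * nc;
    for (int vz = 0; vz < oz; ++vz)
      for (int vy = 0; vy < oy; ++vy)
        for (int vx = 0; vx < ox; ++vx, ++r) {
          double best = -INFINITY;
          int ab = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                double v = src[(2 * vx + dx) + (long)d[0] * ((2 * vy + dy) + (long)d[1] * (2 * vz + dz))];
                int o = 1 + dx + 2 * (dy + 2 * dz);
                if (v > best) { best = v; ab = o; }
              }
          y[r] = best;
          arg[r] = ab;
        }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, N, C);
  return List::create(Named("y") = y, Named("arg") = arg);
}

// [[Rcpp::export]]
NumericVector ds_maxpool2_bwd(NumericVector gy, IntegerVector arg, IntegerVector dims) {
  const int* d = dims.begin();
  const int N = d[3], C = d[4];
  const int ox = d[0] / 2, oy = d[1] / 2, oz = d[2] / 2;
  NumericVector dx((long)d[0] * d[1] * d[2] * N * C);
  const long plane = (long)d[0] * d[1];
  long r = 0;
  for (long nc = 0; nc < (long)N * C; ++nc) {
    double* dst = dx.begin() + plane * d[2] * nc;
    for (int vz = 0; vz < oz; ++vz)
      for (int vy = 0; vy < oy; ++vy)
        for (int vx = 0; vx < ox; ++vx, ++r) {
          int o = arg[r] - 1;
          int px = 2 * vx + (o & 1), py = 2 * vy + ((o >> 1) & 1), pz = 2 * vz + (o >> 2);
          dst[px + (long)d[0] * (py + (long)d[1] * pz)] += gy[r];
        }
  }
  dx.attr("dim") = dims;
  return dx;
}

// Contract a matrix M (m x n) along one axis of an array without permuting:
// viewing x as (pre, n, post) in column-major order, returns (pre, m, post)
// with y[p, i, q] = sum_a M[i, a] * x[p, a, q]. Each post-slab is a
// contiguous (pre x n) block, so the contraction is one BLAS gemm per slab.
// [[Rcpp::export]]
NumericVector ds_axismap(NumericVector x, IntegerVector dims, arma::mat M, int axis) {
  const int nd = dims.size();
  long pre = 1, post = 1;
  for (int i = 0; i < axis - 1; ++i) pre *= dims[i];
  for (int i = axis; i < nd; ++i) post *= dims[i];
  const int n = dims[axis - 1], m = M.n_rows;
  NumericVector y(pre * m * post);
  arma::mat Mt = M.t();  // (n x m)
  if (pre == 1) {
    // first axis: one gemm over the whole array viewed as (n x post)
    arma::mat Xb(const_cast<double*>(x.begin()), n, post, false, true);
    arma::mat Yb(y.begin(), m, post, false, true);
    Yb = M * Xb;
  } else if (post == 1) {
    arma::mat Xb(const_cast<double*>(x.begin()), pre, n, false, true);
    arma::mat Yb(y.begin(), pre, m, false, true);
    Yb = Xb * Mt;
  } else {
    for (long q = 0; q < post; ++q) {
      arma::mat Xb(const_cast<double*>(x.begin()) + q * pre * n, pre, n, false, true);
      arma::mat Yb(y.begin() + q * pre * m, pre, m, false, true);
      Yb = Xb * Mt;
    }
  }
  IntegerVector od(nd);
  for (int i = 0; i < nd; ++i) od[i] = dims[i];
  od[axis - 1] = m;
  y.attr("dim") = od;
  return y;
}
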