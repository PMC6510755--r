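// Compiled kernels for the CNN layers and the MIP projector.
//
// Activation layout: a feature map of height H, width W and C channels is
// stored as one column of length H*W*C per sample, flattened column-major
// over (row h, col w, channel c): flat = h + H*w + H*W*c.  Convolution
// weights are (k*k*Cin) x Cout with patch order dh + k*dw + k*k*cin.
// All convolutions are stride 1 with zero padding (k-1)/2 ("same").

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill the im2col matrix P (HW x K) for one sample.  Column q of P holds,
// for every output position p = h + H*w, the input value at spatial offset
// (dh - pad, dw - pad) in channel c, where q = dh + k*dw + k*k*c.  Interior
// runs are contiguous in both source and destination, so each (q, w) block
// is a straight memcpy with zeroed borders.
static void im2col_t(const double* xs, arma::mat& P, int H, int W, int Cin,
                     int k) {
  const int pad = (k - 1) / 2;
  const int HW = H * W;
  for (int c = 0; c < Cin; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      const int ow = dw - pad;
      for (int dh = 0; dh < k; ++dh) {
        const int oh = dh - pad;
        const int q = dh + k * dw + k * k * c;
        double* dst = P.colptr(q);
        const int h0 = std::max(0, -oh);
        const int h1 = std::min(H, H - oh);
        for (int w = 0; w < W; ++w) {
          double* dcol = dst + (size_t)H * w;
          const int ww = w + ow;
          if (ww < 0 || ww >= W || h1 <= h0) {
            std::memset(dcol, 0, sizeof(double) * H);
            continue;
          }
          if (h0 > 0) std::memset(dcol, 0, sizeof(double) * h0);
          std::memcpy(dcol + h0, xs + (h0 + oh) + (size_t)H * ww + (size_t)HW * c,
                      sizeof(double) * (h1 - h0));
          if (h1 < H) std::memset(dcol + h1, 0, sizeof(double) * (H - h1));
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv_forward_cpp(const arma::mat& X, const arma::mat& W,
                           const arma::vec& b, int H, int Wd, int Cin) {
  const int K = W.n_rows;
  const int Cout = W.n_cols;
  const int k = (int)std::lround(std::sqrt((double)K / Cin));
  const int HW = H * Wd;
  const int B = X.n_cols;
  arma::mat Y(HW * Cout, B);
  arma::mat P(HW, K);
  const arma::rowvec bt = b.t();
  for (int s = 0; s < B; ++s) {
    im2col_t(X.colptr(s), P, H, Wd, Cin, k);
    arma::mat Ys(Y.colptr(s), HW, Cout, false, true);
    Ys = P * W;  // flattens to p + HW*co
    Ys.each_row() += bt;
  }
  return Y;
}

// [[Rcpp::export]]
List conv_backward_cpp(const arma::mat& X, const arma::mat& W,
                       const arma::mat& dY, int H, int Wd, int Cin) {
  const int K = W.n_rows;
  const int Cout = W.n_cols;
  const int k = (int)std::lround(std::sqrt((double)K / Cin));
  const int pad = (k - 1) / 2;
  const int HW = H * Wd;
  const int B = X.n_cols;
  arma::mat dX(X.n_rows, B, arma::fill::zeros);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat P(HW, K);
  arma::mat dP(HW, K);
  for (int s = 0; s < B; ++s) {
    im2col_t(X.colptr(s), P, H, Wd, Cin, k);
    const arma::mat dYs(const_cast<double*>(dY.colptr(s)), HW, Cout, false,
                        true);
    dW += P.t() * dYs;
    db += arma::sum(dYs, 0);
    dP = dYs * W.t();  // HW x K
    // scatter-add dP columns back onto dX (reverse of im2col_t)
    double* dxs = dX.colptr(s);
    for (int c = 0; c < Cin; ++c) {
      for (int dw = 0; dw < k; ++dw) {
        const int ow = dw - pad;
        for (int dh = 0; dh < k; ++dh) {
          const int oh = dh - pad;
          const int q = dh + k * dw + k * k * c;
          const double* src = dP.colptr(q);
          const int h0 = std::max(0, -oh);
          const int h1 = std::min(H, H - oh);
          if (h1 <= h0) continue;
          for (int w = 0; w < Wd; ++w) {
            const int ww = w + ow;
            if (ww < 0 || ww >= Wd) continue;
            double* dcol = dxs + (h0 + oh) + (size_t)H * ww + (size_t)HW * c;
            const double* scol = src + (size_t)H * w + h0;
            const int len = h1 - h0;
            for (int t = 0; t < len; ++t) dcol[t] += scol[t];
          }
        }
      }
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW,
                      Named("db") = db.t());
}

// Local response normalization across channels:
// out_c = a_c * S_c^(-beta),  S_c = bias + alpha * sum_{|j-c|<=r} a_j^2.
// X is (hw*C) x B with spatial index fastest.  Returns out and S.
// [[Rcpp::export]]
List lrn_forward_cpp(const arma::mat& X, int hw, int C, int radius,
                     double alpha, double beta, double bias) {
  const int B = X.n_cols;
  arma::mat out(X.n_rows, B), S(X.n_rows, B);
  std::vector<double> acc(hw);
  for (int s = 0; s < B; ++s) {
    const double* xs = X.colptr(s);
    double* Ss = S.colptr(s);
    double* os = out.colptr(s);
    for (int c = 0; c < C; ++c) {
      const int lo = std::max(0, c - radius), hi = std::min(C - 1, c + radius);
      std::fill(acc.begin(), acc.end(), bias);
      for (int j = lo; j <= hi; ++j) {
        const double* xc = xs + (size_t)hw * j;
        for (int i = 0; i < hw; ++i) acc[i] += alpha * xc[i] * xc[i];
      }
      const double* xc = xs + (size_t)hw * c;
      double* Sc = Ss + (size_t)hw * c;
      double* oc = os + (size_t)hw * c;
      for (int i = 0; i < hw; ++i) {
        Sc[i] = acc[i];
        oc[i] = xc[i] * std::pow(acc[i], -beta);
      }
    }
  }
  return List::create(Named("out") = out, Named("S") = S);
}

// [[Rcpp::export]]
arma::mat lrn_backward_cpp(const arma::mat& dY, const arma::mat& A,
                           const arma::mat& S, int hw, int C, int radius,
                           double alpha, double beta) {
  const int B = dY.n_cols;
  arma::mat dA(dY.n_rows, B);
  std::vector<double> Tm((size_t)hw * C), acc(hw);
  for (int s = 0; s < B; ++s) {
    const double* dy = dY.colptr(s);
    const double* as = A.colptr(s);
    const double* Ss = S.colptr(s);
    double* da = dA.colptr(s);
    for (size_t i = 0; i < (size_t)hw * C; ++i) {
      const double p = std::pow(Ss[i], -beta);
      Tm[i] = dy[i] * as[i] * p / Ss[i];
      da[i] = dy[i] * p;  // first term; window term subtracted below
    }
    for (int c = 0; c < C; ++c) {
      const int lo = std::max(0, c - radius), hi = std::min(C - 1, c + radius);
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int j = lo; j <= hi; ++j) {
        const double* tc = Tm.data() + (size_t)hw * j;
        for (int i = 0; i < hw; ++i) acc[i] += tc[i];
      }
      const size_t off = (size_t)hw * c;
      for (int i = 0; i < hw; ++i) {
        da[off + i] -= 2.0 * alpha * beta * as[off + i] * acc[i];
      }
    }
  }
  return dA;
}

// 2x2 max pooling, stride 2.  Ties go to the first element in
// (h, h+1) x (w, w+1) scan order so the backward pass routes the gradient
// to exactly one input.
// [[Rcpp::export]]
List maxpool_forward_cpp(const arma::mat& X, int H, int Wd, int C) {
  const int Ho = H / 2, Wo = Wd / 2;
  const int B = X.n_cols;
  const int HWo = Ho * Wo;
  arma::mat Y(HWo * C, B);
  arma::umat arg(HWo * C, B);
  for (int s = 0; s < B; ++s) {
    const double* xs = X.colptr(s);
    double* ys = Y.colptr(s);
    arma::uword* as = arg.colptr(s);
    for (int c = 0; c < C; ++c) {
      const int in_off = H * Wd * c;
      const int out_off = HWo * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int base = in_off + 2 * ho + H * 2 * wo;
          int best = base;
          double m = xs[base];
          const int cand[3] = {base + 1, base + H, base + H + 1};
          for (int t = 0; t < 3; ++t) {
            if (xs[cand[t]] > m) { m = xs[cand[t]]; best = cand[t]; }
          }
          ys[out_off + ho + Ho * wo] = m;
          as[out_off + ho + Ho * wo] = (arma::uword)best;
        }
      }
    }
  }
  return List::create(Named("Y") = Y, Named("arg") = arg);
}

// [[Rcpp::export]]
arma::mat maxpool_backward_cpp(const arma::mat& dY, const arma::umat& arg,
                               int insize) {
  const int B = dY.n_cols;
  const int n = dY.n_rows;
  arma::mat dX(insize, B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    const double* dys = dY.colptr(s);
    const arma::uword* as = arg.colptr(s);
    double* dxs = dX.colptr(s);
    for (int j = 0; j < n; ++j) dxs[as[j]] += dys[j];
  }
  return dX;
}

// Maximum intensity projection of a volume rotated about its z
// (craniocaudal) axis.  The caller supplies cos/sin of the rotation angle
// (use cospi/sinpi in R so axis-aligned angles are exact).  In-plane voxels
// must be square for an index-space rotation to equal a physical one; the
// R wrapper enforces that.  Rays run along y after rotation; samples are
// bilinear within each slice; samples outside the volume contribute 0.
// `rmax` (voxel units) is the radius of the volume's in-plane nonzero
// support: rotation preserves radius, so sample points beyond it are
// exactly zero and are skipped.  Pass a large value to disable culling.
// Output: nz x nx matrix, rows = z slices, cols = x.
// [[Rcpp::export]]
NumericMatrix mip_project_cpp(const NumericVector& vol, int nx, int ny,
                              int nz, double ct, double st, double rmax) {
  const double cx = (nx - 1) / 2.0;
  const double cy = (ny - 1) / 2.0;
  const double r2max = (rmax + 1.5) * (rmax + 1.5);
  // Precompute bilinear footprints of the rotated sampling grid (shared by
  // all slices), packed per grid row yj with consecutive xi for locality.
  struct Ent { int xi; int base; double w00, w10, w01, w11; };
  std::vector<std::vector<Ent>> rows(ny);
  for (int yj = 0; yj < ny; ++yj) {
    const double dy = yj - cy;
    for (int xi = 0; xi < nx; ++xi) {
      const double dx = xi - cx;
      if (dx * dx + dy * dy > r2max) continue;
      double xs = cx + ct * dx + st * dy;
      double ys = cy - st * dx + ct * dy;
      if (xs < 0.0 || xs > nx - 1 || ys < 0.0 || ys > ny - 1) continue;
      int i0 = (int)std::floor(xs);
      int j0 = (int)std::floor(ys);
      if (i0 >= nx - 1) i0 = nx - 2;
      if (j0 >= ny - 1) j0 = ny - 2;
      double fx = xs - i0;
      double fy = ys - j0;
      if (nx == 1) { i0 = 0; fx = 0.0; }
      if (ny == 1) { j0 = 0; fy = 0.0; }
      Ent e;
      e.xi = xi;
      e.base = i0 + nx * j0;
      e.w00 = (1 - fx) * (1 - fy);
      e.w10 = fx * (1 - fy);
      e.w01 = (1 - fx) * fy;
      e.w11 = fx * fy;
      rows[yj].push_back(e);
    }
  }
  const int dx1 = nx == 1 ? 0 : 1;        // guard degenerate single-voxel axes
  const int dyn = ny == 1 ? 0 : nx;
  NumericMatrix out(nz, nx);
  std::vector<double> m(nx);
  const double* v = vol.begin();
  for (int z = 0; z < nz; ++z) {
    const double* slice = v + (size_t)z * nx * ny;
    std::fill(m.begin(), m.end(), 0.0);
    for (int yj = 0; yj < ny; ++yj) {
      for (const Ent& e : rows[yj]) {
        const double val = e.w00 * slice[e.base] + e.w10 * slice[e.base + dx1] +
                           e.w01 * slice[e.base + dyn] +
                           e.w11 * slice[e.base + dx1 + dyn];
        if (val > m[e.xi]) m[e.xi] = val;
      }
    }
    for (int xi = 0; xi < nx; ++xi) out(z, xi) = m[xi];
  }
  return out;
}

// In-place-style Poisson-like noise: v -> max(0, v + eps * scale *
// sqrt(v + floor)) with eps ~ N(0,1) drawn from R's RNG (so results follow
// set.seed).  Voxels that are exactly zero (air) stay zero.
// [[Rcpp::export]]
NumericVector add_phantom_noise_cpp(NumericVector vol, double scale,
                                    double floor_) {
  const R_xlen_t n = vol.size();
  NumericVector out(n);
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = vol[i];
    if (v > 0) {
      const double nv = v + norm_rand() * scale * std::sqrt(v + floor_);
      out[i] = nv > 0 ? nv : 0.0;
    } else {
      out[i] = 0.0;
    }
  }
  PutRNGstate();
  return out;
}
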