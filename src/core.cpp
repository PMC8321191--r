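// Numerical cores: dilated 3x3 convolutions (forward + backward), 2x2 max
// pooling, bilinear x2 resampling, and the analytic cone-beam ray-cylinder
// projector. Arrays are (H, W, C) cubes, matching R's column-major layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// dst[ys0..ys1, xs0..xs1] += wk * src[ys0+oy .., xs0+ox ..], column-major
// H x W matrices addressed through raw pointers (no temporaries).
static inline void saxpy_shift(double* dst, const double* src, double wk,
                               int H, int ys0, int ys1, int xs0, int xs1,
                               int oy, int ox) {
  for (int x = xs0; x <= xs1; ++x) {
    double* d = dst + (size_t)x * H + ys0;
    const double* s = src + (size_t)(x + ox) * H + ys0 + oy;
    int n = ys1 - ys0 + 1;
    for (int i = 0; i < n; ++i) d[i] += wk * s[i];
  }
}

// Zero-padded 3x3 convolution with dilation. weights dim (3,3,Cin,Cout).
// [[Rcpp::export]]
arma::cube conv3x3_fw(const arma::cube& x, const NumericVector& w,
                      const NumericVector& b, int dil) {
  IntegerVector wd = w.attr("dim");
  int cin = wd[2], cout = wd[3];
  int H = x.n_rows, W = x.n_cols;
  arma::cube y(H, W, cout);
  for (int co = 0; co < cout; ++co) y.slice(co).fill(b[co]);
  for (int co = 0; co < cout; ++co) {
    double* ys = y.slice_memptr(co);
    for (int ci = 0; ci < cin; ++ci) {
      const double* xs = x.slice_memptr(ci);
      for (int kx = 0; kx < 3; ++kx) {
        int ox = (kx - 1) * dil;
        int xs0 = std::max(0, -ox), xs1 = W - 1 - std::max(0, ox);
        if (xs0 > xs1) continue;
        for (int ky = 0; ky < 3; ++ky) {
          int oy = (ky - 1) * dil;
          int ys0 = std::max(0, -oy), ys1 = H - 1 - std::max(0, oy);
          if (ys0 > ys1) continue;
          double wk = w[ky + 3 * (kx + 3 * (ci + cin * co))];
          if (wk == 0.0) continue;
          saxpy_shift(ys, xs, wk, H, ys0, ys1, xs0, xs1, oy, ox);
        }
      }
    }
  }
  return y;
}

// Gradient w.r.t. the convolution input.
// [[Rcpp::export]]
arma::cube conv3x3_bw_input(const arma::cube& dy, const NumericVector& w,
                            int dil) {
  IntegerVector wd = w.attr("dim");
  int cin = wd[2], cout = wd[3];
  int H = dy.n_rows, W = dy.n_cols;
  arma::cube dx(H, W, cin, arma::fill::zeros);
  for (int co = 0; co < cout; ++co) {
    const double* ds = dy.slice_memptr(co);
    for (int ci = 0; ci < cin; ++ci) {
      double* xs = dx.slice_memptr(ci);
      for (int kx = 0; kx < 3; ++kx) {
        int ox = (kx - 1) * dil;
        int xs0 = std::max(0, -ox), xs1 = W - 1 - std::max(0, ox);
        if (xs0 > xs1) continue;
        for (int ky = 0; ky < 3; ++ky) {
          int oy = (ky - 1) * dil;
          int ys0 = std::max(0, -oy), ys1 = H - 1 - std::max(0, oy);
          if (ys0 > ys1) continue;
          double wk = w[ky + 3 * (kx + 3 * (ci + cin * co))];
          if (wk == 0.0) continue;
          // scatter: dx[shifted] += wk * dy[base]
          for (int xcol = xs0; xcol <= xs1; ++xcol) {
            double* d = xs + (size_t)(xcol + ox) * H + ys0 + oy;
            const double* s = ds + (size_t)xcol * H + ys0;
            int n = ys1 - ys0 + 1;
            for (int i = 0; i < n; ++i) d[i] += wk * s[i];
          }
        }
      }
    }
  }
  return dx;
}

// Gradient w.r.t. weights and biases; returns list(dw, db).
// [[Rcpp::export]]
List conv3x3_bw_weights(const arma::cube& x, const arma::cube& dy, int dil) {
  int cin = x.n_slices, cout = dy.n_slices;
  int H = x.n_rows, W = x.n_cols;
  NumericVector dw(3 * 3 * cin * cout);
  dw.attr("dim") = IntegerVector::create(3, 3, cin, cout);
  NumericVector db(cout);
  for (int co = 0; co < cout; ++co) {
    const arma::mat& ds = dy.slice(co);
    db[co] = arma::accu(ds);
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat& xs = x.slice(ci);
      for (int kx = 0; kx < 3; ++kx) {
        int ox = (kx - 1) * dil;
        int xs0 = std::max(0, -ox), xs1 = W - 1 - std::max(0, ox);
        if (xs0 > xs1) continue;
        for (int ky = 0; ky < 3; ++ky) {
          int oy = (ky - 1) * dil;
          int ys0 = std::max(0, -oy), ys1 = H - 1 - std::max(0, oy);
          if (ys0 > ys1) continue;
          dw[ky + 3 * (kx + 3 * (ci + cin * co))] = arma::accu(
            xs.submat(ys0 + oy, xs0 + ox, ys1 + oy, xs1 + ox) %
            ds.submat(ys0, xs0, ys1, xs1));
        }
      }
    }
  }
  return List::create(_["dw"] = dw, _["db"] = db);
}

// Dense mixed-scale forward pass, entirely in place: `stack` is an
// (H, W, c0 + d*width) array whose first c0 slices hold the input; layer i
// writes ReLU(conv3x3_dil(stack[.., 1..cin])) into its own slices.
// Ws[i] has dim (3, 3, cin_i, width); bs is the per-layer bias matrix
// (width x d).
// [[Rcpp::export]]
void msd_fw_cpp(NumericVector stack, int H, int W, int c0, int width,
                List Ws, const NumericMatrix& bs,
                const IntegerVector& dils) {
  int d = Ws.size();
  double* S = REAL(stack);
  size_t plane = (size_t)H * W;
  for (int i = 0; i < d; ++i) {
    int cin = c0 + i * width;
    NumericVector w = Ws[i];
    const double* wp = REAL(w);
    int dil = dils[i % dils.size()];
    for (int co = 0; co < width; ++co) {
      double* out = S + plane * (cin + co);
      double b = bs(co, i);
      for (size_t k = 0; k < plane; ++k) out[k] = b;
      for (int ci = 0; ci < cin; ++ci) {
        const double* src = S + plane * ci;
        for (int kx = 0; kx < 3; ++kx) {
          int ox = (kx - 1) * dil;
          int xs0 = std::max(0, -ox), xs1 = W - 1 - std::max(0, ox);
          if (xs0 > xs1) continue;
          for (int ky = 0; ky < 3; ++ky) {
            int oy = (ky - 1) * dil;
            int ys0 = std::max(0, -oy), ys1 = H - 1 - std::max(0, oy);
            if (ys0 > ys1) continue;
            double wk = wp[ky + 3 * (kx + 3 * (ci + cin * co))];
            if (wk == 0.0) continue;
            saxpy_shift(out, src, wk, H, ys0, ys1, xs0, xs1, oy, ox);
          }
        }
      }
      for (size_t k = 0; k < plane; ++k) if (out[k] < 0) out[k] = 0;
    }
  }
}

// Dense mixed-scale backward pass. `g` is the (H, W, ctot) gradient w.r.t.
// the full post-activation stack (seeded from the final 1x1 layer) and is
// accumulated in place down to the input slices; returns per-layer
// weight/bias gradients.
// [[Rcpp::export]]
List msd_bw_cpp(const NumericVector& stack, NumericVector g, int H, int W,
                int c0, int width, List Ws, const IntegerVector& dils) {
  int d = Ws.size();
  const double* S = REAL(stack);
  double* G = REAL(g);
  size_t plane = (size_t)H * W;
  List dWs(d);
  NumericMatrix dbs(width, d);
  std::vector<double> dy(plane * width);
  for (int i = d - 1; i >= 0; --i) {
    int cin = c0 + i * width;
    NumericVector w = Ws[i];
    const double* wp = REAL(w);
    int dil = dils[i % dils.size()];
    NumericVector dw(9 * cin * width);
    dw.attr("dim") = IntegerVector::create(3, 3, cin, width);
    double* dwp = REAL(dw);
    for (int co = 0; co < width; ++co) {
      const double* act = S + plane * (cin + co);
      const double* gs = G + plane * (cin + co);
      double* dyc = dy.data() + plane * co;
      double db = 0.0;
      for (size_t k = 0; k < plane; ++k) {
        dyc[k] = act[k] > 0 ? gs[k] : 0.0;
        db += dyc[k];
      }
      dbs(co, i) = db;
      for (int ci = 0; ci < cin; ++ci) {
        const double* src = S + plane * ci;
        double* gsrc = G + plane * ci;
        for (int kx = 0; kx < 3; ++kx) {
          int ox = (kx - 1) * dil;
          int xs0 = std::max(0, -ox), xs1 = W - 1 - std::max(0, ox);
          if (xs0 > xs1) continue;
          for (int ky = 0; ky < 3; ++ky) {
            int oy = (ky - 1) * dil;
            int ys0 = std::max(0, -oy), ys1 = H - 1 - std::max(0, oy);
            if (ys0 > ys1) continue;
            // weight gradient: correlate shifted input with dy
            double acc = 0.0;
            double wk = wp[ky + 3 * (kx + 3 * (ci + cin * co))];
            for (int xcol = xs0; xcol <= xs1; ++xcol) {
              const double* sp = src + (size_t)(xcol + ox) * H + ys0 + oy;
              const double* dp = dyc + (size_t)xcol * H + ys0;
              double* gp = gsrc + (size_t)(xcol + ox) * H + ys0 + oy;
              int n = ys1 - ys0 + 1;
              if (wk != 0.0) {
                for (int r = 0; r < n; ++r) {
                  acc += sp[r] * dp[r];
                  gp[r] += wk * dp[r];
                }
              } else {
                for (int r = 0; r < n; ++r) acc += sp[r] * dp[r];
              }
            }
            dwp[ky + 3 * (kx + 3 * (ci + cin * co))] = acc;
          }
        }
      }
    }
    dWs[i] = dw;
  }
  return List::create(_["dWs"] = dWs, _["dbs"] = dbs);
}

// 2x2 max pooling, stride 2; returns pooled cube and argmax code (0..3).
// [[Rcpp::export]]
List maxpool2_fw(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  arma::ucube idx(h, w, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double v00 = x(2 * i, 2 * j, c), v10 = x(2 * i + 1, 2 * j, c);
        double v01 = x(2 * i, 2 * j + 1, c), v11 = x(2 * i + 1, 2 * j + 1, c);
        double best = v00; unsigned k = 0;
        if (v10 > best) { best = v10; k = 1; }
        if (v01 > best) { best = v01; k = 2; }
        if (v11 > best) { best = v11; k = 3; }
        y(i, j, c) = best; idx(i, j, c) = k;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::cube& dy, const arma::ucube& idx) {
  int h = dy.n_rows, w = dy.n_cols, C = dy.n_slices;
  arma::cube dx(2 * h, 2 * w, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        unsigned k = idx(i, j, c);
        dx(2 * i + (k & 1u), 2 * j + (k >> 1u), c) = dy(i, j, c);
      }
  return dx;
}

static inline void bilin_coef(int i, int n_in, int& i0, int& i1, double& f) {
  double src = (i + 0.5) / 2.0 - 0.5;
  if (src < 0) src = 0;
  if (src > n_in - 1) src = n_in - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, n_in - 1);
  f = src - i0;
}

// Bilinear x2 upsampling (half-pixel centre alignment).
// [[Rcpp::export]]
arma::cube upsample2_fw(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho = 2 * H, Wo = 2 * W;
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      int j0, j1; double fx; bilin_coef(j, W, j0, j1, fx);
      for (int i = 0; i < Ho; ++i) {
        int i0, i1; double fy; bilin_coef(i, H, i0, i1, fy);
        y(i, j, c) = (1 - fy) * (1 - fx) * x(i0, j0, c) +
                     fy * (1 - fx) * x(i1, j0, c) +
                     (1 - fy) * fx * x(i0, j1, c) +
                     fy * fx * x(i1, j1, c);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bw(const arma::cube& dy) {
  int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  int H = Ho / 2, W = Wo / 2;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      int j0, j1; double fx; bilin_coef(j, W, j0, j1, fx);
      for (int i = 0; i < Ho; ++i) {
        int i0, i1; double fy; bilin_coef(i, H, i0, i1, fy);
        double g = dy(i, j, c);
        dx(i0, j0, c) += (1 - fy) * (1 - fx) * g;
        dx(i1, j0, c) += fy * (1 - fx) * g;
        dx(i0, j1, c) += (1 - fy) * fx * g;
        dx(i1, j1, c) += fy * fx * g;
      }
    }
  }
  return dx;
}

// Euclidean length of the intersection of ray o + t*d (t in R, d unit) with a
// finite capped cylinder. Closed form: quadratic for the infinite tube
// intersected with the slab between the two cap planes.
static double ray_cyl_len(const double* o, const double* d, const double* c,
                          const double* a, double r, double hl) {
  double del[3] = {o[0] - c[0], o[1] - c[1], o[2] - c[2]};
  double da = d[0] * a[0] + d[1] * a[1] + d[2] * a[2];
  double ea = del[0] * a[0] + del[1] * a[1] + del[2] * a[2];
  double dp[3] = {d[0] - da * a[0], d[1] - da * a[1], d[2] - da * a[2]};
  double ep[3] = {del[0] - ea * a[0], del[1] - ea * a[1], del[2] - ea * a[2]};
  double A = dp[0] * dp[0] + dp[1] * dp[1] + dp[2] * dp[2];
  double B = 2.0 * (dp[0] * ep[0] + dp[1] * ep[1] + dp[2] * ep[2]);
  double C = ep[0] * ep[0] + ep[1] * ep[1] + ep[2] * ep[2] - r * r;
  double t0, t1;
  const double inf = std::numeric_limits<double>::infinity();
  if (A < 1e-14) {            // ray parallel to the axis
    if (C > 0) return 0.0;
    t0 = -inf; t1 = inf;
  } else {
    double disc = B * B - 4 * A * C;
    if (disc <= 0) return 0.0; // miss or tangent
    double sq = std::sqrt(disc);
    t0 = (-B - sq) / (2 * A);
    t1 = (-B + sq) / (2 * A);
  }
  // slab |ea + t*da| <= hl
  double s0, s1;
  if (std::fabs(da) < 1e-14) {
    if (std::fabs(ea) > hl) return 0.0;
    s0 = -inf; s1 = inf;
  } else {
    s0 = (-hl - ea) / da;
    s1 = (hl - ea) / da;
    if (s0 > s1) std::swap(s0, s1);
  }
  double lo = std::max(t0, s0), hi = std::min(t1, s1);
  return hi > lo ? hi - lo : 0.0;
}

// [[Rcpp::export]]
double ray_cyl_pathlength_cpp(const NumericVector& origin,
                              const NumericVector& dir,
                              const NumericVector& center,
                              const NumericVector& axis,
                              double radius, double half_length) {
  return ray_cyl_len(origin.begin(), dir.begin(), center.begin(), axis.begin(),
                     radius, half_length);
}

// Cone-beam projection of capped cylinders onto a square detector.
// cyls: n x 8 matrix (cx, cy, cz, ax, ay, az, radius, half_length);
// mat_idx: 1-based material index per cylinder; n_mat materials.
// Source on -y axis, detector plane at +y; raw pixels traced with central
// rays, then box-averaged down to out_res.
// [[Rcpp::export]]
arma::cube project_cylinders_cpp(const NumericMatrix& cyls,
                                 const IntegerVector& mat_idx, int n_mat,
                                 int raw_res, int out_res, double sod,
                                 double odd, double det_size) {
  int n = cyls.nrow();
  int f = raw_res / out_res;
  arma::cube out(out_res, out_res, n_mat, arma::fill::zeros);
  double src[3] = {0.0, -sod, 0.0};
  double px = det_size / raw_res;
  double norm_f = 1.0 / (f * f);
  for (int j = 0; j < raw_res; ++j) {
    double x = -det_size / 2.0 + (j + 0.5) * px;
    int jo = j / f;
    for (int i = 0; i < raw_res; ++i) {
      double z = det_size / 2.0 - (i + 0.5) * px;
      int io = i / f;
      double d[3] = {x - src[0], odd - src[1], z - src[2]};
      double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
      for (int k = 0; k < n; ++k) {
        double cc[3] = {cyls(k, 0), cyls(k, 1), cyls(k, 2)};
        double aa[3] = {cyls(k, 3), cyls(k, 4), cyls(k, 5)};
        double len = ray_cyl_len(src, d, cc, aa, cyls(k, 6), cyls(k, 7));
        if (len > 0) out(io, jo, mat_idx[k] - 1) += len * norm_f;
      }
    }
  }
  return out;
}

// Beer-Lambert clean transmittance: exp(-sum_m mu_m(b) * L_m(p)) for every
// pixel and bin. paths: (H, W, n_mat); mu: n_bins x n_mat. Returns (H*W) x
// n_bins matrix to keep the R-side reshape trivial.
// [[Rcpp::export]]
arma::mat beer_lambert_cpp(const arma::cube& paths, const arma::mat& mu) {
  int H = paths.n_rows, W = paths.n_cols, M = paths.n_slices;
  arma::mat L(H * W, M);
  for (int m = 0; m < M; ++m)
    L.col(m) = arma::vectorise(paths.slice(m));
  arma::mat tau = L * mu.t();     // (H*W) x B optical depth
  return arma::exp(-tau);
}
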