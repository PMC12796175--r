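// Bilinear image resampling primitives shared by the grid-embedding and
// registration code.  All grids are row-major 64x64 (or HxW) R matrices;
// coordinates are (row, col) with pixel centres at integer positions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double bilinear_at(const arma::mat& img, double r, double c) {
  const int H = img.n_rows, W = img.n_cols;
  if (r < -1.0 || r > H || c < -1.0 || c > W) return 0.0;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  double v00 = 0, v01 = 0, v10 = 0, v11 = 0;
  if (r0 >= 0 && r0 < H) {
    if (c0 >= 0 && c0 < W) v00 = img(r0, c0);
    if (c0 + 1 >= 0 && c0 + 1 < W) v01 = img(r0, c0 + 1);
  }
  if (r0 + 1 >= 0 && r0 + 1 < H) {
    if (c0 >= 0 && c0 < W) v10 = img(r0 + 1, c0);
    if (c0 + 1 >= 0 && c0 + 1 < W) v11 = img(r0 + 1, c0 + 1);
  }
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
}

// Resize to out_h x out_w with half-pixel-centre alignment (the convention
// used by standard image libraries), bilinear interpolation.
// [[Rcpp::export(name = ".resize_bilinear_cpp")]]
arma::mat resize_bilinear_cpp(const arma::mat& img, int out_h, int out_w) {
  const double sr = (double)img.n_rows / out_h;
  const double sc = (double)img.n_cols / out_w;
  arma::mat out(out_h, out_w);
  for (int r = 0; r < out_h; ++r) {
    double srcr = (r + 0.5) * sr - 0.5;
    for (int c = 0; c < out_w; ++c) {
      double srcc = (c + 0.5) * sc - 0.5;
      out(r, c) = bilinear_at(img, srcr, srcc);
    }
  }
  return out;
}

// Affine warp: rotate by `angle` degrees about the canvas centre, scale by
// `zoom`, then translate by (shift_r, shift_c) pixels.  Implemented by
// inverse mapping with bilinear interpolation; out-of-canvas samples are 0.
// [[Rcpp::export(name = ".warp_affine_cpp")]]
arma::mat warp_affine_cpp(const arma::mat& img, double angle, double shift_r,
                          double shift_c, double zoom) {
  const int H = img.n_rows, W = img.n_cols;
  const double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  const double th = angle * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  arma::mat out(H, W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      // undo translation, then undo zoom+rotation about the centre
      double yr = (r - shift_r) - cr, yc = (c - shift_c) - cc;
      double sr_ = (ct * yr + st * yc) / zoom + cr;
      double sc_ = (-st * yr + ct * yc) / zoom + cc;
      out(r, c) = bilinear_at(img, sr_, sc_);
    }
  }
  out.clamp(0.0, 1.0);
  return out;
}
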