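// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Feature maps are stored as [H, W, B, C] column-major arrays throughout the
// package. im2col3 lowers a 3x3, pad-1, stride-1 convolution to one GEMM:
// it returns a [H*W*B, 9*C] matrix whose column block k holds the input
// shifted by the k-th kernel offset (zero padding outside the image).

// [[Rcpp::export]]
arma::mat im2col3(const arma::vec& x, int H, int W, int B, int C) {
  mat out(static_cast<size_t>(H) * W * B, 9 * C, fill::none);
  const double* xp = x.memptr();
  for (int k = 0; k < 9; ++k) {
    int dy = k % 3 - 1, dx = k / 3 - 1;
    for (int c = 0; c < C; ++c) {
      double* o = out.colptr(static_cast<size_t>(k) * C + c);
      for (int b = 0; b < B; ++b) {
        const double* xc = xp + (static_cast<size_t>(c) * B + b) * H * W;
        double* ob = o + static_cast<size_t>(b) * H * W;
        for (int w = 0; w < W; ++w) {
          int ws = w + dx;
          double* ocol = ob + static_cast<size_t>(w) * H;
          if (ws < 0 || ws >= W) {
            std::fill(ocol, ocol + H, 0.0);
            continue;
          }
          const double* xcol = xc + static_cast<size_t>(ws) * H;
          int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          if (h0 > 0) ocol[0] = 0.0;
          if (h1 < H) ocol[H - 1] = 0.0;
          std::copy(xcol + h0 + dy, xcol + h1 + dy, ocol + h0);
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-adds a [H*W*B, 9*C] gradient back onto the
// [H, W, B, C] input layout (contributions falling in the padding are
// dropped).

// [[Rcpp::export]]
arma::vec col2im3(const arma::mat& g, int H, int W, int B, int C) {
  vec out(static_cast<size_t>(H) * W * B * C, fill::zeros);
  double* op = out.memptr();
  for (int k = 0; k < 9; ++k) {
    int dy = k % 3 - 1, dx = k / 3 - 1;
    for (int c = 0; c < C; ++c) {
      const double* gc = g.colptr(static_cast<size_t>(k) * C + c);
      for (int b = 0; b < B; ++b) {
        double* oc = op + (static_cast<size_t>(c) * B + b) * H * W;
        const double* gb = gc + static_cast<size_t>(b) * H * W;
        for (int w = 0; w < W; ++w) {
          int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          double* ocol = oc + static_cast<size_t>(ws) * H;
          const double* gcol = gb + static_cast<size_t>(w) * H;
          int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          for (int h = h0; h < h1; ++h) ocol[h + dy] += gcol[h];
        }
      }
    }
  }
  return out;
}
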