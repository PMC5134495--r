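// Convolution primitives for the three-layer SR network, plus 8-connected
// component labelling used by the flow-counting detector.
//
// Convolutions use the cross-correlation convention with 'same'-size output
// and replicate (clamp-to-edge) padding. Feature maps are arma::cube with
// layout (rows, cols, channels); filter banks are matrices of shape
// (C_out, C_in * f * f), the row for output channel o holding weights
// indexed by ci * f * f + fy * f + fx.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat im2col_replicate(const cube& x, const int f) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (f - 1) / 2;
  mat col(C * f * f, H * W);
  for (int c = 0; c < C; ++c) {
    for (int fy = 0; fy < f; ++fy) {
      for (int fx = 0; fx < f; ++fx) {
        const int r = c * f * f + fy * f + fx;
        for (int xx = 0; xx < W; ++xx) {
          int sx = xx + fx - pad; sx = sx < 0 ? 0 : (sx >= W ? W - 1 : sx);
          for (int yy = 0; yy < H; ++yy) {
            int sy = yy + fy - pad; sy = sy < 0 ? 0 : (sy >= H ? H - 1 : sy);
            col(r, yy + H * xx) = x(sy, sx, c);
          }
        }
      }
    }
  }
  return col;
}

// Forward pass of one convolution layer (pre-activation).
// [[Rcpp::export]]
arma::cube conv2d_fw_cpp(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, const int f) {
  if ((int)W.n_cols != (int)x.n_slices * f * f)
    Rcpp::stop("filter bank expects %d input values per patch, got %d",
               (int)W.n_cols, (int)x.n_slices * f * f);
  const int H = x.n_rows, Wd = x.n_cols, Cout = W.n_rows;
  mat col = im2col_replicate(x, f);
  mat out = W * col;          // Cout x (H*W)
  out.each_col() += b;
  cube z(H, Wd, Cout);
  for (int o = 0; o < Cout; ++o)
    z.slice(o) = reshape(out.row(o).t(), H, Wd);
  return z;
}

// Gradients of one convolution layer. gz is dLoss/d(pre-activation).
// Returns dW, db and dLoss/dx (padding adjoint folds edge gradients back).
// [[Rcpp::export]]
Rcpp::List conv2d_bw_cpp(const arma::cube& x, const arma::mat& W,
                         const int f, const arma::cube& gz) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_rows, pad = (f - 1) / 2;
  mat gz_mat(Cout, H * Wd);
  for (int o = 0; o < Cout; ++o)
    gz_mat.row(o) = vectorise(gz.slice(o)).t();
  mat col = im2col_replicate(x, f);
  mat dW = gz_mat * col.t();
  vec db = sum(gz_mat, 1);
  mat dcol = W.t() * gz_mat;  // (Cin*f*f) x (H*W)
  cube dx(H, Wd, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int fy = 0; fy < f; ++fy) {
      for (int fx = 0; fx < f; ++fx) {
        const int r = c * f * f + fy * f + fx;
        for (int xx = 0; xx < Wd; ++xx) {
          int sx = xx + fx - pad; sx = sx < 0 ? 0 : (sx >= Wd ? Wd - 1 : sx);
          for (int yy = 0; yy < H; ++yy) {
            int sy = yy + fy - pad; sy = sy < 0 ? 0 : (sy >= H ? H - 1 : sy);
            dx(sy, sx, c) += dcol(r, yy + H * xx);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}

// Connected-component labelling of a binary mask (iterative flood fill),
// with 8- or 4-connectivity.
// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components_cpp(const Rcpp::LogicalMatrix& mask,
                                         const int conn = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int>> stack;
  int next = 0;
  for (int x0 = 0; x0 < W; ++x0) {
    for (int y0 = 0; y0 < H; ++y0) {
      if (!mask(y0, x0) || lab(y0, x0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({y0, x0});
      lab(y0, x0) = next;
      while (!stack.empty()) {
        auto [y, x] = stack.back(); stack.pop_back();
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (conn == 4 && dy != 0 && dx != 0) continue;
            const int ny = y + dy, nx = x + dx;
            if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            if (mask(ny, nx) && lab(ny, nx) == 0) {
              lab(ny, nx) = next;
              stack.push_back({ny, nx});
            }
          }
        }
      }
    }
  }
  return lab;
}
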