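// Compute kernels for the compact CNN engine: 3x3 same-padding convolution
// (im2col + GEMM), 2x2 max pooling with argmax, and 8-connected component
// labelling. Layout: images and feature maps are arma::cube (H, W, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for a 3x3 kernel, stride 1, zero padding 1.
// Output: (H*W) x (9*Cin); column block k*9 + (dy*3+dx) holds channel k
// shifted by (dy-1, dx-1).
static arma::mat im2col3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(H * W, 9 * C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        arma::uword col = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (arma::uword j = 0; j < W; ++j) {
          int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          for (arma::uword i = 0; i < H; ++i) {
            int is = (int)i + dy;
            if (is < 0 || is >= (int)H) continue;
            out(j * H + i, col) = xc(is, js);
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add transpose of im2col3: cols is (H*W) x (9*Cin) of gradients
// w.r.t. the patches; returns gradient cube w.r.t. the input.
static arma::cube col2im3(const arma::mat& cols, arma::uword H, arma::uword W,
                          arma::uword C) {
  arma::cube out(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    arma::mat& oc = out.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        arma::uword col = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (arma::uword j = 0; j < W; ++j) {
          int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          for (arma::uword i = 0; i < H; ++i) {
            int is = (int)i + dy;
            if (is < 0 || is >= (int)H) continue;
            oc(is, js) += cols(j * H + i, col);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3_forward")]]
arma::cube conv3_forward(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b) {
  // W: (9*Cin) x Cout, b: Cout
  const arma::uword H = x.n_rows, Wd = x.n_cols;
  arma::mat cols = im2col3(x);          // (H*W) x (9*Cin)
  arma::mat y = cols * W;               // (H*W) x Cout
  y.each_row() += b.t();
  arma::cube out(H, Wd, W.n_cols);
  for (arma::uword c = 0; c < W.n_cols; ++c)
    out.slice(c) = arma::reshape(y.col(c), H, Wd);
  return out;
}

// [[Rcpp::export(name = ".conv3_backward")]]
List conv3_backward(const arma::cube& x, const arma::mat& W,
                    const arma::cube& dout) {
  const arma::uword H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const arma::uword Cout = dout.n_slices;
  arma::mat dY(H * Wd, Cout);
  for (arma::uword c = 0; c < Cout; ++c)
    dY.col(c) = arma::vectorise(dout.slice(c));
  arma::mat cols = im2col3(x);
  arma::mat dW = cols.t() * dY;         // (9*Cin) x Cout
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dcols = dY * W.t();         // (H*W) x (9*Cin)
  arma::cube dx = col2im3(dcols, H, Wd, Cin);
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  arma::cube arg(Ho, Wo, C);            // linear index into input slice
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (arma::uword j = 0; j < Wo; ++j) {
      for (arma::uword i = 0; i < Ho; ++i) {
        arma::uword bi = 2 * i, bj = 2 * j;
        double best = xc(bi, bj);
        arma::uword besti = bi, bestj = bj;
        for (int a = 0; a < 2; ++a)
          for (int bcol = 0; bcol < 2; ++bcol) {
            double v = xc(bi + a, bj + bcol);
            if (v > best) { best = v; besti = bi + a; bestj = bj + bcol; }
          }
        out(i, j, c) = best;
        arg(i, j, c) = (double)(bestj * H + besti);
      }
    }
  }
  return List::create(Named("out") = out, Named("argmax") = arg);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
arma::cube maxpool2_backward(const arma::cube& dout, const arma::cube& argmax,
                             int H, int W) {
  const arma::uword C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    arma::mat& dxc = dx.slice(c);
    const arma::mat& dc = dout.slice(c);
    const arma::mat& ac = argmax.slice(c);
    for (arma::uword j = 0; j < dout.n_cols; ++j)
      for (arma::uword i = 0; i < dout.n_rows; ++i)
        dxc((arma::uword)ac(i, j)) += dc(i, j);
  }
  return dx;
}

// 8-connected component labelling of a logical matrix by iterative BFS.
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  stack.reserve((size_t)H * W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(j * H + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % H, cj = idx / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(nj * H + ni);
            }
          }
        }
      }
    }
  }
  return lab;
}
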