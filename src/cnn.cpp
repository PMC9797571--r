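// Small dilated-context encoder-decoder CNN for 4-class per-pixel slice
// classification, with Adam and softmax cross-entropy, written directly on
// Armadillo GEMM. The design follows the common semantic-segmentation
// pattern: a strided encoder whose deepest stage uses dilated 3x3
// convolutions for context, a nearest-neighbour upsampling decoder, and a
// full-resolution skip connection for boundary accuracy.
//
//   input (H,W,3) -> conv3(3->8) -> conv3(8->8) [skip]
//   -> pool2 -> conv3(8->16) -> pool2 -> conv3 d2 (16->32) -> conv3 d4 (32->32)
//   -> upsample x4 -> concat skip (40) -> conv3(40->12) -> conv1(12->4)
//   -> softmax
//
// Weight init draws from R's RNG so training is reproducible under set.seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;

// dst(i,j) = src(i+a, j+b), zero outside; column-major H x W images
static void shift_copy(const double* src, double* dst, int H, int W, int a,
                       int b) {
  std::fill(dst, dst + (size_t)H * W, 0.0);
  int j0 = std::max(0, -b), j1 = std::min(W, W - b);
  int i0 = std::max(0, -a), i1 = std::min(H, H - a);
  if (i1 <= i0) return;
  for (int j = j0; j < j1; ++j) {
    const double* s = src + (size_t)(j + b) * H + (i0 + a);
    double* d = dst + (size_t)j * H + i0;
    std::copy(s, s + (i1 - i0), d);
  }
}

// dst(i+a, j+b) += src(i,j) for in-range targets (reverse of shift_copy)
static void shift_add(const double* src, double* dst, int H, int W, int a,
                      int b) {
  int j0 = std::max(0, -b), j1 = std::min(W, W - b);
  int i0 = std::max(0, -a), i1 = std::min(H, H - a);
  if (i1 <= i0) return;
  for (int j = j0; j < j1; ++j) {
    const double* s = src + (size_t)j * H + i0;
    double* d = dst + (size_t)(j + b) * H + (i0 + a);
    for (int i = 0; i < i1 - i0; ++i) d[i] += s[i];
  }
}

struct Conv {
  int cin, cout, ksz, dil; // ksz: 1 or 3
  mat W;                   // (taps*cin, cout)
  rowvec b;
  mat gW, mW, vW;
  rowvec gb, mb, vb;
  mat Xc; // cached im2col input of last forward

  void init(int cin_, int cout_, int ksz_, int dil_) {
    cin = cin_; cout = cout_; ksz = ksz_; dil = dil_;
    int taps = ksz * ksz;
    double sd = std::sqrt(2.0 / (taps * cin));
    W.set_size(taps * cin, cout);
    for (arma::uword i = 0; i < W.n_elem; ++i) W[i] = sd * R::norm_rand();
    b.zeros(cout);
    gW.zeros(arma::size(W)); mW.zeros(arma::size(W)); vW.zeros(arma::size(W));
    gb.zeros(cout); mb.zeros(cout); vb.zeros(cout);
  }

  // X: (H*W, cin) column-major images; returns (H*W, cout)
  mat forward(const mat& X, int H, int Wd) {
    int taps = ksz * ksz;
    Xc.set_size(X.n_rows, taps * cin);
    if (ksz == 1) {
      Xc = X;
    } else {
      int t = 0;
      for (int db = -1; db <= 1; ++db)
        for (int da = -1; da <= 1; ++da, ++t)
          for (int c = 0; c < cin; ++c)
            shift_copy(X.colptr(c), Xc.colptr((size_t)t * cin + c), H, Wd,
                       da * dil, db * dil);
    }
    mat Y = Xc * W;
    Y.each_row() += b;
    return Y;
  }

  // accumulates gradients; returns dX
  mat backward(const mat& dY, int H, int Wd) {
    gW += Xc.t() * dY;
    gb += arma::sum(dY, 0);
    mat dXc = dY * W.t();
    if (ksz == 1) return dXc;
    mat dX(dXc.n_rows, cin, arma::fill::zeros);
    int t = 0;
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da, ++t)
        for (int c = 0; c < cin; ++c)
          shift_add(dXc.colptr((size_t)t * cin + c), dX.colptr(c), H, Wd,
                    da * dil, db * dil);
    return dX;
  }

  void adam(double lr, double b1, double b2, double eps, int t, double scale) {
    gW *= scale; gb *= scale;
    mW = b1 * mW + (1 - b1) * gW;
    vW = b2 * vW + (1 - b2) * (gW % gW);
    mb = b1 * mb + (1 - b1) * gb;
    vb = b2 * vb + (1 - b2) * (gb % gb);
    double c1 = 1.0 / (1 - std::pow(b1, t)), c2 = 1.0 / (1 - std::pow(b2, t));
    W -= lr * (c1 * mW) / (arma::sqrt(c2 * vW) + eps);
    b -= lr * (c1 * mb) / (arma::sqrt(c2 * vb) + eps);
    gW.zeros(); gb.zeros();
  }
};

static mat relu(const mat& X) { return arma::clamp(X, 0.0, arma::datum::inf); }

struct CNN {
  Conv L1, L2, L3, L4, L5, L6, L7;
  // caches
  mat a1, a2, p1, a3, p2, a4, a5, up, cc, a6;
  arma::uvec arg1, arg2; // pool argmax (linear into pre-pool rows)
  int H, Wd;

  CNN() {
    L1.init(3, 8, 3, 1);
    L2.init(8, 8, 3, 1);
    L3.init(8, 16, 3, 1);
    L4.init(16, 32, 3, 2);
    L5.init(32, 32, 3, 4);
    L6.init(40, 12, 3, 1);
    L7.init(12, 4, 1, 1);
  }

  static mat pool2(const mat& X, int H, int Wd, arma::uvec& argmax) {
    int h = H / 2, w = Wd / 2, C = X.n_cols;
    mat Y(h * (size_t)w, C);
    argmax.set_size((size_t)h * w * C);
    for (int c = 0; c < C; ++c) {
      const double* s = X.colptr(c);
      double* d = Y.colptr(c);
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          size_t i00 = (size_t)(2 * j) * H + 2 * i;
          size_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          int best = 0;
          for (int k = 1; k < 4; ++k) if (s[cand[k]] > s[cand[best]]) best = k;
          d[(size_t)j * h + i] = s[cand[best]];
          argmax[(size_t)c * h * w + (size_t)j * h + i] = cand[best];
        }
    }
    return Y;
  }

  static mat unpool2(const mat& dY, int H, int Wd, const arma::uvec& argmax) {
    int h = H / 2, w = Wd / 2, C = dY.n_cols;
    mat dX((size_t)H * Wd, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
      const double* s = dY.colptr(c);
      double* d = dX.colptr(c);
      for (size_t p = 0; p < (size_t)h * w; ++p)
        d[argmax[(size_t)c * h * w + p]] += s[p];
    }
    return dX;
  }

  static mat upsample4(const mat& X, int h, int w) {
    int H = 4 * h, Wd = 4 * w, C = X.n_cols;
    mat Y((size_t)H * Wd, C);
    for (int c = 0; c < C; ++c) {
      const double* s = X.colptr(c);
      double* d = Y.colptr(c);
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i)
          d[(size_t)j * H + i] = s[(size_t)(j / 4) * h + i / 4];
    }
    return Y;
  }

  static mat downsum4(const mat& dY, int h, int w) {
    int H = 4 * h, Wd = 4 * w, C = dY.n_cols;
    mat dX((size_t)h * w, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
      const double* s = dY.colptr(c);
      double* d = dX.colptr(c);
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i)
          d[(size_t)(j / 4) * h + i / 4] += s[(size_t)j * H + i];
    }
    return dX;
  }

  // x: (H*W, 3); returns per-pixel class probabilities (H*W, 4)
  mat forward(const mat& x, int H_, int W_) {
    H = H_; Wd = W_;
    int h2 = H / 2, w2 = Wd / 2, h4 = H / 4, w4 = Wd / 4;
    a1 = relu(L1.forward(x, H, Wd));
    a2 = relu(L2.forward(a1, H, Wd));
    p1 = pool2(a2, H, Wd, arg1);
    a3 = relu(L3.forward(p1, h2, w2));
    p2 = pool2(a3, h2, w2, arg2);
    a4 = relu(L4.forward(p2, h4, w4));
    a5 = relu(L5.forward(a4, h4, w4));
    up = upsample4(a5, h4, w4);
    cc = arma::join_rows(up, a2);
    a6 = relu(L6.forward(cc, H, Wd));
    mat logits = L7.forward(a6, H, Wd);
    logits.each_col() -= arma::max(logits, 1);
    mat e = arma::exp(logits);
    e.each_col() /= arma::sum(e, 1);
    return e;
  }

  // y: 0..3 labels per pixel; returns CE loss, accumulates gradients
  double backward(const mat& probs, const arma::ivec& y) {
    size_t n = probs.n_rows;
    mat dlog = probs;
    double loss = 0;
    for (size_t p = 0; p < n; ++p) {
      dlog(p, y[p]) -= 1.0;
      loss -= std::log(std::max(probs(p, y[p]), 1e-12));
    }
    dlog /= (double)n;
    loss /= (double)n;
    int h2 = H / 2, w2 = Wd / 2, h4 = H / 4, w4 = Wd / 4;
    mat d6 = L7.backward(dlog, H, Wd);
    d6 %= arma::conv_to<mat>::from(a6 > 0);
    mat dcc = L6.backward(d6, H, Wd);
    mat dup = dcc.cols(0, 31);
    mat da2_skip = dcc.cols(32, 39);
    mat da5 = downsum4(dup, h4, w4);
    da5 %= arma::conv_to<mat>::from(a5 > 0);
    mat da4 = L5.backward(da5, h4, w4);
    da4 %= arma::conv_to<mat>::from(a4 > 0);
    mat dp2 = L4.backward(da4, h4, w4);
    mat da3 = unpool2(dp2, h2, w2, arg2);
    da3 %= arma::conv_to<mat>::from(a3 > 0);
    mat dp1 = L3.backward(da3, h2, w2);
    mat da2 = unpool2(dp1, H, Wd, arg1) + da2_skip;
    da2 %= arma::conv_to<mat>::from(a2 > 0);
    mat da1 = L2.backward(da2, H, Wd);
    da1 %= arma::conv_to<mat>::from(a1 > 0);
    L1.backward(da1, H, Wd);
    return loss;
  }

  void step(double lr, int t, int batch) {
    double s = 1.0 / batch;
    for (Conv* L : {&L1, &L2, &L3, &L4, &L5, &L6, &L7})
      L->adam(lr, 0.9, 0.999, 1e-8, t, s);
  }

  List weights() {
    List out;
    const char* nm[7] = {"L1", "L2", "L3", "L4", "L5", "L6", "L7"};
    Conv* Ls[7] = {&L1, &L2, &L3, &L4, &L5, &L6, &L7};
    for (int i = 0; i < 7; ++i)
      out[nm[i]] = List::create(_["W"] = wrap(Ls[i]->W), _["b"] = wrap(Ls[i]->b));
    return out;
  }

  void set_weights(List w) {
    const char* nm[7] = {"L1", "L2", "L3", "L4", "L5", "L6", "L7"};
    Conv* Ls[7] = {&L1, &L2, &L3, &L4, &L5, &L6, &L7};
    for (int i = 0; i < 7; ++i) {
      List li = w[nm[i]];
      Ls[i]->W = as<mat>(li["W"]);
      Ls[i]->b = as<rowvec>(li["b"]);
    }
  }
};

// [[Rcpp::export]]
SEXP cpp_cnn_new() {
  XPtr<CNN> p(new CNN(), true);
  return p;
}

// xs: list of (H*W x 3) matrices (values already in [0,1]); ys: list of
// integer vectors of per-pixel labels 0..3. One Adam step on the batch.
// [[Rcpp::export]]
double cpp_cnn_train_batch(SEXP ptr, List xs, List ys, double lr, int t,
                           IntegerVector hw) {
  XPtr<CNN> p(ptr);
  int H = hw[0], Wd = hw[1];
  double loss = 0;
  for (int i = 0; i < xs.size(); ++i) {
    mat x = as<mat>(xs[i]);
    arma::ivec y = as<arma::ivec>(ys[i]);
    mat probs = p->forward(x, H, Wd);
    loss += p->backward(probs, y);
  }
  p->step(lr, t, xs.size());
  return loss / xs.size();
}

// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(SEXP ptr, NumericMatrix x, IntegerVector hw) {
  XPtr<CNN> p(ptr);
  mat probs = p->forward(as<mat>(x), hw[0], hw[1]);
  return wrap(probs);
}

// [[Rcpp::export]]
List cpp_cnn_get_weights(SEXP ptr) {
  XPtr<CNN> p(ptr);
  return p->weights();
}

// [[Rcpp::export]]
void cpp_cnn_set_weights(SEXP ptr, List w) {
  XPtr<CNN> p(ptr);
  p->set_weights(w);
}
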