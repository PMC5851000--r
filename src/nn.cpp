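// Convolutional regression core: forward, backward and the SGD loop for the
// two-conv / two-maxpool / fc-ReLU-dropout-fc scalar regression network.
//
// Images are vectorized in R array order: index = y + H*(x + W*c). Feature
// maps use the same convention. Convolutions are "same"-padded (pad = K/2,
// odd K), pooling is non-overlapping 2x2 with floor division. All conv and
// fc arithmetic is single precision, expressed as large BLAS GEMMs over
// batch-stacked im2col matrices: a whole mini-batch's patches form one
// (B*H*W) x (K*K*C) block, so each layer is two or three GEMMs per
// iteration regardless of batch size.
//
// Randomness (shuffling, flip augmentation, dropout) uses a self-contained
// mt19937 stream so training is bit-reproducible for a given seed
// regardless of platform or R's RNG state.

#include <RcppArmadillo.h>
#include <cfloat>
#include <memory>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;

namespace {

struct Shape {
  int H, W, C, F1, K1, F2, K2, FC;
  double drop;
  int H1, W1, H2, W2, flat, npx, pad1, pad2;
};

Shape make_shape(const List& s) {
  Shape sh;
  sh.H = s["h"]; sh.W = s["w"]; sh.C = s["c"];
  sh.F1 = s["conv1_maps"]; sh.K1 = s["conv1_kernel"];
  sh.F2 = s["conv2_maps"]; sh.K2 = s["conv2_kernel"];
  sh.FC = s["fc_hidden"]; sh.drop = s["dropout_rate"];
  if (sh.K1 % 2 == 0 || sh.K2 % 2 == 0) stop("kernel sizes must be odd");
  sh.pad1 = sh.K1 / 2; sh.pad2 = sh.K2 / 2;
  sh.H1 = sh.H / 2; sh.W1 = sh.W / 2;
  if (sh.H1 < 1 || sh.W1 < 1)
    stop("spatial dimensions collapse to zero at the first pooling layer");
  sh.H2 = sh.H1 / 2; sh.W2 = sh.W1 / 2;
  if (sh.H2 < 1 || sh.W2 < 1)
    stop("spatial dimensions collapse to zero at the second pooling layer");
  sh.flat = sh.H2 * sh.W2 * sh.F2;
  sh.npx = sh.H * sh.W * sh.C;
  return sh;
}

// Internally conv kernels are kept transposed, (K*K*C) x F, so that the
// forward pass is (patches) x (kernels) with contiguous patch columns.
struct Weights {
  fmat W1t, W2t, W3, W4;  // (K1²C x F1), (K2²F1 x F2), (FC x flat), (1 x FC)
  fvec b1, b2, b3, b4;
};

fmat as_fmat(SEXP m) {
  NumericMatrix nm(m);
  fmat out(nm.nrow(), nm.ncol());
  for (int j = 0; j < nm.ncol(); ++j)
    for (int i = 0; i < nm.nrow(); ++i) out.at(i, j) = (float)nm(i, j);
  return out;
}

fvec as_fvec(SEXP v) {
  NumericVector nv(v);
  fvec out(nv.size());
  for (int i = 0; i < nv.size(); ++i) out[i] = (float)nv[i];
  return out;
}

Weights read_weights(const List& w, const Shape& sh) {
  Weights ww;
  ww.W1t = as_fmat(w["W1"]).t(); ww.b1 = as_fvec(w["b1"]);
  ww.W2t = as_fmat(w["W2"]).t(); ww.b2 = as_fvec(w["b2"]);
  ww.W3 = as_fmat(w["W3"]); ww.b3 = as_fvec(w["b3"]);
  ww.W4 = as_fmat(w["W4"]); ww.b4 = as_fvec(w["b4"]);
  if ((int)ww.W1t.n_cols != sh.F1 || (int)ww.W1t.n_rows != sh.K1 * sh.K1 * sh.C)
    stop("W1 has the wrong shape for this configuration");
  if ((int)ww.W2t.n_cols != sh.F2 || (int)ww.W2t.n_rows != sh.K2 * sh.K2 * sh.F1)
    stop("W2 has the wrong shape for this configuration");
  if ((int)ww.W3.n_rows != sh.FC || (int)ww.W3.n_cols != sh.flat)
    stop("W3 has the wrong shape for this configuration");
  if ((int)ww.W4.n_rows != 1 || (int)ww.W4.n_cols != sh.FC)
    stop("W4 has the wrong shape for this configuration");
  return ww;
}

NumericMatrix to_R(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i) out(i, j) = m.at(i, j);
  return out;
}

NumericVector to_R(const fvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = v[i];
  return out;
}

List weights_to_R(const Weights& w) {
  return List::create(
      Named("W1") = to_R(fmat(w.W1t.t())), Named("b1") = to_R(w.b1),
      Named("W2") = to_R(fmat(w.W2t.t())), Named("b2") = to_R(w.b2),
      Named("W3") = to_R(w.W3), Named("b3") = to_R(w.b3),
      Named("W4") = to_R(w.W4), Named("b4") = to_R(w.b4));
}

struct RNG {
  std::mt19937 g;
  explicit RNG(uint32_t seed) : g(seed) {}
  double unif() { return (g() + 0.5) * (1.0 / 4294967296.0); }
  int below(int n) { return (int)(g() % (uint32_t)n); }
  void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i)
      std::swap(v[i], v[below(i + 1)]);
  }
};

// Append image i's padded patches to the block im2col matrix M at row
// offset off: M(off + y + H*x, ky + K*(kx + K*c)) = in(y+ky-pad, x+kx-pad, c)
void im2col(const float* in, int H, int W, int C, int K, int pad, fmat& M,
            arma::uword off) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const float* ic = in + (size_t)HW * c;
    for (int kx = 0; kx < K; ++kx) {
      for (int ky = 0; ky < K; ++ky) {
        float* col = M.colptr(ky + K * (kx + K * c)) + off;
        for (int x = 0; x < W; ++x) {
          const int sx = x + kx - pad;
          float* dst = col + (size_t)H * x;
          if (sx < 0 || sx >= W) {
            std::fill(dst, dst + H, 0.0f);
          } else {
            const float* src = ic + (size_t)H * sx;
            const int y0 = std::max(0, pad - ky);
            const int y1 = std::min(H, H + pad - ky);
            for (int y = 0; y < y0; ++y) dst[y] = 0.0f;
            for (int y = y0; y < y1; ++y) dst[y] = src[y + ky - pad];
            for (int y = y1; y < H; ++y) dst[y] = 0.0f;
          }
        }
      }
    }
  }
}

// Adjoint: accumulate image i's rows of dM back into a (H, W, C) gradient.
void col2im(const fmat& dM, arma::uword off, int H, int W, int C, int K,
            int pad, float* dIn) {
  const int HW = H * W;
  std::fill(dIn, dIn + (size_t)HW * C, 0.0f);
  for (int c = 0; c < C; ++c) {
    float* ic = dIn + (size_t)HW * c;
    for (int kx = 0; kx < K; ++kx) {
      for (int ky = 0; ky < K; ++ky) {
        const float* col = dM.colptr(ky + K * (kx + K * c)) + off;
        for (int x = 0; x < W; ++x) {
          const int sx = x + kx - pad;
          if (sx < 0 || sx >= W) continue;
          const float* src = col + (size_t)H * x;
          float* dst = ic + (size_t)H * sx;
          const int y0 = std::max(0, pad - ky);
          const int y1 = std::min(H, H + pad - ky);
          for (int y = y0; y < y1; ++y) dst[y + ky - pad] += src[y];
        }
      }
    }
  }
}

// 2x2 non-overlapping max pooling over one image's slab of the stacked
// activation matrix A (rows off..off+H*W-1, one column per feature map).
// out: (H/2 * W/2 * F) vector; amax: spatial argmax index in [0, H*W).
void maxpool(const fmat& A, arma::uword off, int H, int W, int F, float* out,
             int* amax) {
  const int Ho = H / 2, Wo = W / 2;
  for (int f = 0; f < F; ++f) {
    const float* in = A.colptr(f) + off;
    const size_t offo = (size_t)Ho * Wo * f;
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        int bi = 2 * yo + H * (2 * xo);
        float bv = in[bi];
        const int cand[3] = {2 * yo + 1 + H * (2 * xo),
                             2 * yo + H * (2 * xo + 1),
                             2 * yo + 1 + H * (2 * xo + 1)};
        for (int k = 0; k < 3; ++k)
          if (in[cand[k]] > bv) { bv = in[cand[k]]; bi = cand[k]; }
        out[offo + yo + (size_t)Ho * xo] = bv;
        amax[offo + yo + (size_t)Ho * xo] = bi;
      }
    }
  }
}

// Workspace sized for a maximum batch of B images.
struct Batch {
  fmat XB;            // npx x B inputs (after any flip)
  fmat M1, M2;        // stacked im2col blocks
  fmat C1, C2;        // stacked conv outputs (pre-pool)
  fmat dC1, dC2;      // their gradients
  fmat P1;            // pooled conv1 output, (H1*W1*F1) x B
  fmat P2;            // pooled conv2 output, flat x B
  arma::Mat<int> am1, am2;
  fvec dP1;           // one image's unpooled gradient buffer
  Batch(const Shape& sh, int B)
      : XB(sh.npx, B),
        M1((arma::uword)B * sh.H * sh.W, sh.K1 * sh.K1 * sh.C),
        M2((arma::uword)B * sh.H1 * sh.W1, sh.K2 * sh.K2 * sh.F1),
        C1((arma::uword)B * sh.H * sh.W, sh.F1),
        C2((arma::uword)B * sh.H1 * sh.W1, sh.F2),
        dC1((arma::uword)B * sh.H * sh.W, sh.F1),
        dC2((arma::uword)B * sh.H1 * sh.W1, sh.F2),
        P1((arma::uword)sh.H1 * sh.W1 * sh.F1, B), P2(sh.flat, B),
        am1((arma::uword)sh.H1 * sh.W1 * sh.F1, B), am2(sh.flat, B),
        dP1((arma::uword)sh.H1 * sh.W1 * sh.F1) {}
};

// Conv stack forward for all columns of bt.XB; fills bt.P2.
void conv_forward(const Weights& w, const Shape& sh, Batch& bt) {
  const int B = bt.XB.n_cols;
  const arma::uword HW = (arma::uword)sh.H * sh.W;
  const arma::uword HW1 = (arma::uword)sh.H1 * sh.W1;
  for (int i = 0; i < B; ++i)
    im2col(bt.XB.colptr(i), sh.H, sh.W, sh.C, sh.K1, sh.pad1, bt.M1, i * HW);
  bt.C1 = bt.M1 * w.W1t;
  bt.C1.each_row() += w.b1.t();
  for (int i = 0; i < B; ++i) {
    maxpool(bt.C1, i * HW, sh.H, sh.W, sh.F1, bt.P1.colptr(i),
            bt.am1.colptr(i));
    im2col(bt.P1.colptr(i), sh.H1, sh.W1, sh.F1, sh.K2, sh.pad2, bt.M2,
           i * HW1);
  }
  bt.C2 = bt.M2 * w.W2t;
  bt.C2.each_row() += w.b2.t();
  for (int i = 0; i < B; ++i)
    maxpool(bt.C2, i * HW1, sh.H1, sh.W1, sh.F2, bt.P2.colptr(i),
            bt.am2.colptr(i));
}

struct Grads {
  fmat W1t, W2t, W3, W4;
  fvec b1, b2, b3, b4;
  explicit Grads(const Weights& w) {
    W1t.zeros(w.W1t.n_rows, w.W1t.n_cols); b1.zeros(w.b1.n_elem);
    W2t.zeros(w.W2t.n_rows, w.W2t.n_cols); b2.zeros(w.b2.n_elem);
    W3.zeros(w.W3.n_rows, w.W3.n_cols); b3.zeros(w.b3.n_elem);
    W4.zeros(w.W4.n_rows, w.W4.n_cols); b4.zeros(w.b4.n_elem);
  }
};

// Forward + Euclidean loss (+ optional full backward) for one mini-batch.
// mask: dropout keep mask scaled by 1/(1-p), or empty for none.
double batch_loss_grad(const fvec& tB, const Weights& w, const Shape& sh,
                       Batch& bt, const fmat& mask, Grads* g) {
  const int B = bt.XB.n_cols;
  conv_forward(w, sh, bt);
  fmat A1 = w.W3 * bt.P2;
  A1.each_col() += w.b3;
  fmat Z = arma::clamp(A1, 0.0f, FLT_MAX);  // ReLU
  if (mask.n_elem) Z %= mask;
  frowvec Y = w.W4 * Z + w.b4[0];
  frowvec diff = Y - tB.t();
  const double loss = arma::accu(arma::square(diff)) / (2.0 * B);
  if (!g) return loss;

  const arma::uword HW = (arma::uword)sh.H * sh.W;
  const arma::uword HW1 = (arma::uword)sh.H1 * sh.W1;
  frowvec dY = diff / (float)B;
  g->W4 += dY * Z.t();
  g->b4[0] += arma::accu(dY);
  fmat dZ = w.W4.t() * dY;
  if (mask.n_elem) dZ %= mask;
  dZ.elem(arma::find(A1 <= 0)).zeros();  // now dZ = dA1
  g->W3 += dZ * bt.P2.t();
  g->b3 += arma::sum(dZ, 1);
  const fmat dP2B = w.W3.t() * dZ;

  bt.dC2.zeros();
  for (int i = 0; i < B; ++i) {
    const int* am = bt.am2.colptr(i);
    const float* dp = dP2B.colptr(i);
    for (int f = 0; f < sh.F2; ++f) {
      float* dst = bt.dC2.colptr(f) + (arma::uword)i * HW1;
      const size_t offo = (size_t)sh.H2 * sh.W2 * f;
      for (int j = 0; j < sh.H2 * sh.W2; ++j) dst[am[offo + j]] += dp[offo + j];
    }
  }
  g->W2t += bt.M2.t() * bt.dC2;
  g->b2 += arma::sum(bt.dC2, 0).t();
  const fmat dM2 = bt.dC2 * w.W2t.t();

  bt.dC1.zeros();
  for (int i = 0; i < B; ++i) {
    col2im(dM2, (arma::uword)i * HW1, sh.H1, sh.W1, sh.F1, sh.K2, sh.pad2,
           bt.dP1.memptr());
    const int* am = bt.am1.colptr(i);
    const float* dp = bt.dP1.memptr();
    for (int f = 0; f < sh.F1; ++f) {
      float* dst = bt.dC1.colptr(f) + (arma::uword)i * HW;
      const size_t offo = (size_t)sh.H1 * sh.W1 * f;
      for (int j = 0; j < sh.H1 * sh.W1; ++j) dst[am[offo + j]] += dp[offo + j];
    }
  }
  g->W1t += bt.M1.t() * bt.dC1;
  g->b1 += arma::sum(bt.dC1, 0).t();
  return loss;
}

std::vector<int> flip_perm(const Shape& sh) {
  std::vector<int> fp(sh.npx);
  for (int c = 0; c < sh.C; ++c)
    for (int x = 0; x < sh.W; ++x)
      for (int y = 0; y < sh.H; ++y)
        fp[y + sh.H * (x + sh.W * c)] =
            y + sh.H * ((sh.W - 1 - x) + sh.W * c);
  return fp;
}

}  // namespace

// [[Rcpp::export]]
List cnn_train_core(NumericMatrix X, NumericVector y, List w0, List shape,
                    List tcfg, int seed) {
  const Shape sh = make_shape(shape);
  if (X.nrow() != sh.npx)
    stop("image matrix has %d rows; configuration expects %d", X.nrow(),
         sh.npx);
  const int N = X.ncol();
  if (N < 1) stop("training requires at least one sample");
  Weights w = read_weights(w0, sh);

  const double base_lr = tcfg["base_lr"], momentum = tcfg["momentum"],
               wd = tcfg["weight_decay"], lr_power = tcfg["lr_power"],
               lr_gamma = tcfg["lr_gamma"];
  const int batch = tcfg["batch_size"], epochs = tcfg["epochs"];
  const bool flip = tcfg["augment_flip"];

  fmat Xf(sh.npx, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < sh.npx; ++i) Xf.at(i, j) = (float)X(i, j);
  fvec yf = as_fvec(y);
  if (!yf.is_finite()) stop("targets must be finite");

  RNG rng((uint32_t)seed);
  const std::vector<int> fp = flip_perm(sh);
  const int bmax = std::min(batch, N);
  const int brem = N % batch;  // size of a trailing partial batch, if any
  Batch bt_full(sh, bmax);
  std::unique_ptr<Batch> bt_rem;
  if (brem > 0 && brem != bmax) bt_rem.reset(new Batch(sh, brem));
  Grads vel(w), g(w);
  fmat mask;

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<double> loss_log, lr_log;
  loss_log.reserve((size_t)epochs * ((N + batch - 1) / batch));
  lr_log.reserve(loss_log.capacity());

  long iter = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    rng.shuffle(order);
    for (int b0 = 0; b0 < N; b0 += batch) {
      const int B = std::min(batch, N - b0);
      Batch& bt = (B == bmax) ? bt_full : *bt_rem;
      fvec tB(B);
      for (int i = 0; i < B; ++i) {
        const int src = order[b0 + i];
        if (flip && rng.unif() < 0.5) {
          float* dst = bt.XB.colptr(i);
          const float* s = Xf.colptr(src);
          for (int k = 0; k < sh.npx; ++k) dst[k] = s[fp[k]];
        } else {
          bt.XB.col(i) = Xf.col(src);
        }
        tB[i] = yf[src];
      }
      if (sh.drop > 0) {
        mask.set_size(sh.FC, B);
        const float scale = 1.0f / (1.0f - (float)sh.drop);
        for (arma::uword k = 0; k < mask.n_elem; ++k)
          mask[k] = (rng.unif() < sh.drop) ? 0.0f : scale;
      } else {
        mask.reset();
      }
      g.W1t.zeros(); g.b1.zeros(); g.W2t.zeros(); g.b2.zeros();
      g.W3.zeros(); g.b3.zeros(); g.W4.zeros(); g.b4.zeros();
      const double loss = batch_loss_grad(tB, w, sh, bt, mask, &g);
      if (!std::isfinite(loss))
        stop("non-finite training loss at iteration %ld", iter);
      const double lr = base_lr * std::pow(1.0 + lr_gamma * iter, -lr_power);
      loss_log.push_back(loss);
      lr_log.push_back(lr);
#define SGD_STEP(P)                                                        \
  vel.P = (float)momentum * vel.P - (float)lr * (g.P + (float)wd * w.P);   \
  w.P += vel.P;
      SGD_STEP(W1t) SGD_STEP(b1) SGD_STEP(W2t) SGD_STEP(b2)
      SGD_STEP(W3) SGD_STEP(b3) SGD_STEP(W4) SGD_STEP(b4)
#undef SGD_STEP
      ++iter;
    }
    Rcpp::checkUserInterrupt();
  }
  if (!w.W1t.is_finite() || !w.W2t.is_finite() || !w.W3.is_finite() ||
      !w.W4.is_finite())
    stop("non-finite weights after training");
  return List::create(
      Named("weights") = weights_to_R(w),
      Named("loss") = NumericVector(loss_log.begin(), loss_log.end()),
      Named("lr") = NumericVector(lr_log.begin(), lr_log.end()));
}

// [[Rcpp::export]]
NumericVector cnn_predict_core(NumericMatrix X, List w0, List shape) {
  const Shape sh = make_shape(shape);
  if (X.nrow() != sh.npx)
    stop("image matrix has %d rows; configuration expects %d (h*w*c)",
         X.nrow(), sh.npx);
  const Weights w = read_weights(w0, sh);
  const int N = X.ncol();
  const int chunk = 128;
  Batch bt_full(sh, std::min(N, chunk));
  std::unique_ptr<Batch> bt_rem;
  const int brem = (N > chunk) ? N % chunk : 0;
  if (brem > 0) bt_rem.reset(new Batch(sh, brem));
  NumericVector out(N);
  for (int c0 = 0; c0 < N; c0 += chunk) {
    const int B = std::min(chunk, N - c0);
    Batch& bt = (B == (int)bt_full.XB.n_cols) ? bt_full : *bt_rem;
    for (int j = 0; j < B; ++j)
      for (int i = 0; i < sh.npx; ++i)
        bt.XB.at(i, j) = (float)X(i, c0 + j);
    conv_forward(w, sh, bt);
    fmat A1 = w.W3 * bt.P2;
    A1.each_col() += w.b3;
    const fmat Z = arma::clamp(A1, 0.0f, FLT_MAX);
    const frowvec Y = w.W4 * Z + w.b4[0];
    for (int j = 0; j < B; ++j) out[c0 + j] = Y[j];
  }
  return out;
}

// Full-batch Euclidean loss and exact gradients with dropout disabled;
// used for finite-difference verification of the backward pass.
// [[Rcpp::export]]
List cnn_loss_grad_core(NumericMatrix X, NumericVector y, List w0,
                        List shape) {
  const Shape sh = make_shape(shape);
  if (X.nrow() != sh.npx)
    stop("image matrix has %d rows; configuration expects %d", X.nrow(),
         sh.npx);
  const Weights w = read_weights(w0, sh);
  const int N = X.ncol();
  if (N < 1) stop("empty batch");
  Batch bt(sh, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < sh.npx; ++i) bt.XB.at(i, j) = (float)X(i, j);
  Grads g(w);
  const fmat no_mask;
  const double loss = batch_loss_grad(as_fvec(y), w, sh, bt, no_mask, &g);
  Weights gw;
  gw.W1t = g.W1t; gw.b1 = g.b1; gw.W2t = g.W2t; gw.b2 = g.b2;
  gw.W3 = g.W3; gw.b3 = g.b3; gw.W4 = g.W4; gw.b4 = g.b4;
  return List::create(Named("loss") = loss,
                      Named("grads") = weights_to_R(gw));
}
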