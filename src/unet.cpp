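// Encoder-decoder segmentation network over C-alpha distance-matrix tiles.
//
// The network maps a TxTx1 tile to a (T/2)x(T/2)x5 per-pixel class
// probability stack: encoder blocks of two 3x3 stride-1 convolutions (ELU)
// with dropout and 2x2 stride-2 max pooling, a bottleneck, a fully mirrored
// decoder of 2x2 stride-2 transposed-convolution upsampling blocks with
// skip concatenation from the matching encoder stage, then a central crop
// to the half-size target window and a final 1x1 softmax convolution.
// Cropping (rather than truncating the decoder) keeps every output pixel's
// receptive field aligned with its full-resolution target pixel, which a
// translation-equivariant network requires.
//
// Convolutions are im2col + GEMM, one sample at a time so the im2col
// buffers stay cache-resident. Everything is templated on the real type:
// training runs in single precision, finite-difference gradient checks in
// the tests use double.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// xorshift128+ generator: deterministic and much cheaper than mt19937 for
// the millions of dropout/noise draws a training step makes.
struct FastRng {
  uint64_t s0, s1;
  explicit FastRng(uint64_t seed) {
    auto next = [&seed]() {  // splitmix64 seeding
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    s0 = next();
    s1 = next();
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {  // Box-Muller, caching the second value of each pair
    if (have_) { have_ = false; return cached_; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    cached_ = r * std::sin(2.0 * M_PI * u2);
    have_ = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  bool have_ = false;
  double cached_ = 0.0;
};

// ---------------------------------------------------------------- primitives

template <typename T>
static void im2col(const arma::Cube<T>& X, int k, arma::Mat<T>& col) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices, p = (k - 1) / 2;
  col.zeros(k * k * C, (size_t)H * W);
  for (int c = 0; c < C; ++c)
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr) {
        const int row = kr + k * (kc + k * c);
        const int r0 = std::max(0, p - kr), r1 = std::min(H, H + p - kr);
        for (int cc = 0; cc < W; ++cc) {
          const int sc = cc + kc - p;
          if (sc < 0 || sc >= W) continue;
          const T* src = X.slice_colptr(c, sc);
          T* dst = col.colptr((size_t)H * cc);
          const size_t stride = col.n_rows;
          for (int r = r0; r < r1; ++r)
            dst[(size_t)r * stride + row] = src[r + kr - p];
        }
      }
}

template <typename T>
static void col2im_add(const arma::Mat<T>& col, int k, arma::Cube<T>& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices, p = (k - 1) / 2;
  for (int c = 0; c < C; ++c)
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr) {
        const int row = kr + k * (kc + k * c);
        const int r0 = std::max(0, p - kr), r1 = std::min(H, H + p - kr);
        for (int cc = 0; cc < W; ++cc) {
          const int sc = cc + kc - p;
          if (sc < 0 || sc >= W) continue;
          T* dst = X.slice_colptr(c, sc);
          const T* srcc = col.colptr((size_t)H * cc);
          const size_t stride = col.n_rows;
          for (int r = r0; r < r1; ++r)
            dst[r + kr - p] += srcc[(size_t)r * stride + row];
        }
      }
}

template <typename T>
static inline void elu_inplace(T* x, size_t n) {
  for (size_t i = 0; i < n; ++i)
    if (x[i] <= T(0)) x[i] = std::expm1(x[i]);
}

// y = ELU(conv_k(x)); caches the im2col matrix for the backward pass.
template <typename T>
static void conv_elu_forward(const arma::Cube<T>& X, const arma::Mat<T>& W,
                             const arma::Col<T>& b, int k,
                             arma::Mat<T>& col, arma::Cube<T>& Y,
                             bool elu = true) {
  const int H = X.n_rows, Wd = X.n_cols;
  im2col(X, k, col);
  arma::Mat<T> P = col.t() * W;  // (H*W) x Cout
  P.each_row() += b.t();
  if (elu) elu_inplace(P.memptr(), P.n_elem);
  Y = arma::Cube<T>(P.memptr(), H, Wd, W.n_cols);
}

// Backward through ELU (using the cached post-activation Y) and the
// convolution. Accumulates dW/db, overwrites dX.
template <typename T>
static void conv_elu_backward(const arma::Cube<T>& Y, arma::Cube<T>& dY,
                              const arma::Mat<T>& col, const arma::Mat<T>& W,
                              int k, arma::Mat<T>& dW, arma::Col<T>& db,
                              arma::Cube<T>& dX, int Cin, bool elu = true) {
  const int H = Y.n_rows, Wd = Y.n_cols, Cout = Y.n_slices;
  if (elu) {
    const T* y = Y.memptr();
    T* d = dY.memptr();
    for (size_t i = 0; i < Y.n_elem; ++i)
      d[i] *= (y[i] > T(0) ? T(1) : y[i] + T(1));
  }
  const arma::Mat<T> dYm(const_cast<T*>(dY.memptr()), (size_t)H * Wd, Cout,
                         false, true);
  dW += col * dYm;
  db += arma::sum(dYm, 0).t();
  arma::Mat<T> dcol = W * dYm.t();  // kkCin x HW
  dX.zeros(H, Wd, Cin);
  col2im_add(dcol, k, dX);
}

template <typename T>
static void maxpool2(const arma::Cube<T>& X, arma::Cube<T>& Y,
                     arma::ucube& M) {
  const int H2 = X.n_rows / 2, W2 = X.n_cols / 2, C = X.n_slices;
  Y.set_size(H2, W2, C);
  M.set_size(H2, W2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j) {
      const T* c0 = X.slice_colptr(c, 2 * j);
      const T* c1 = X.slice_colptr(c, 2 * j + 1);
      for (int i = 0; i < H2; ++i) {
        T best = c0[2 * i];
        unsigned q = 0;
        if (c0[2 * i + 1] > best) { best = c0[2 * i + 1]; q = 1; }
        if (c1[2 * i] > best) { best = c1[2 * i]; q = 2; }
        if (c1[2 * i + 1] > best) { best = c1[2 * i + 1]; q = 3; }
        Y(i, j, c) = best;
        M(i, j, c) = q;
      }
    }
}

template <typename T>
static void maxpool2_backward(const arma::Cube<T>& dY, const arma::ucube& M,
                              arma::Cube<T>& dX, int H, int W) {
  const int H2 = dY.n_rows, W2 = dY.n_cols, C = dY.n_slices;
  dX.zeros(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const unsigned q = M(i, j, c);
        dX(2 * i + (q & 1), 2 * j + (q >> 1), c) += dY(i, j, c);
      }
}

// 2x2 stride-2 transposed convolution (+ ELU). Weight rows are stacked by
// output quadrant q = a + 2*b: rows [q*Cin, (q+1)*Cin).
template <typename T>
static void convt2_elu_forward(const arma::Cube<T>& X, const arma::Mat<T>& W,
                               const arma::Col<T>& b, arma::Cube<T>& Y) {
  const int H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices;
  const int Cout = W.n_cols;
  const arma::Mat<T> Xm(const_cast<T*>(X.memptr()), (size_t)H * Wd, Cin,
                        false, true);
  Y.set_size(2 * H, 2 * Wd, Cout);
  for (int q = 0; q < 4; ++q) {
    const int a = q & 1, bb = q >> 1;
    arma::Mat<T> P = Xm * W.rows(q * Cin, (q + 1) * Cin - 1);
    P.each_row() += b.t();
    elu_inplace(P.memptr(), P.n_elem);
    for (int co = 0; co < Cout; ++co)
      for (int j = 0; j < Wd; ++j) {
        T* dst = Y.slice_colptr(co, 2 * j + bb) + a;
        const T* sc = P.colptr(co) + (size_t)H * j;
        for (int i = 0; i < H; ++i) dst[2 * i] = sc[i];
      }
  }
}

template <typename T>
static void convt2_elu_backward(const arma::Cube<T>& X, const arma::Cube<T>& Y,
                                arma::Cube<T>& dY, const arma::Mat<T>& W,
                                arma::Mat<T>& dW, arma::Col<T>& db,
                                arma::Cube<T>& dX) {
  const int H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices;
  const int Cout = Y.n_slices;
  {
    const T* y = Y.memptr();
    T* d = dY.memptr();
    for (size_t i = 0; i < Y.n_elem; ++i)
      d[i] *= (y[i] > T(0) ? T(1) : y[i] + T(1));
  }
  const arma::Mat<T> Xm(const_cast<T*>(X.memptr()), (size_t)H * Wd, Cin,
                        false, true);
  arma::Mat<T> dXm((size_t)H * Wd, Cin, arma::fill::zeros);
  arma::Mat<T> dP((size_t)H * Wd, Cout);
  for (int q = 0; q < 4; ++q) {
    const int a = q & 1, bb = q >> 1;
    for (int co = 0; co < Cout; ++co)
      for (int j = 0; j < Wd; ++j) {
        const T* sc = dY.slice_colptr(co, 2 * j + bb) + a;
        T* dc = dP.colptr(co) + (size_t)H * j;
        for (int i = 0; i < H; ++i) dc[i] = sc[2 * i];
      }
    dW.rows(q * Cin, (q + 1) * Cin - 1) += Xm.t() * dP;
    db += arma::sum(dP, 0).t();
    dXm += dP * W.rows(q * Cin, (q + 1) * Cin - 1).t();
  }
  dX = arma::Cube<T>(dXm.memptr(), H, Wd, Cin);
}

// ------------------------------------------------------------- network pass

template <typename T>
struct Params {
  std::vector<arma::Mat<T>> W;
  std::vector<arma::Col<T>> b;
};

template <typename T>
static Params<T> parse_params(const List& params) {
  Params<T> P;
  const int n = params.size();
  for (int i = 0; i < n; i += 2) {
    NumericMatrix w = params[i];
    NumericVector bv = params[i + 1];
    arma::Mat<T> wm(w.nrow(), w.ncol());
    for (size_t j = 0; j < wm.n_elem; ++j) wm(j) = (T)w[j];
    arma::Col<T> bb(bv.size());
    for (int j = 0; j < bv.size(); ++j) bb(j) = (T)bv[j];
    P.W.push_back(std::move(wm));
    P.b.push_back(std::move(bb));
  }
  return P;
}

// Per-sample tape of everything the backward pass needs.
template <typename T>
struct Tape {
  std::vector<arma::Mat<T>> cols;     // one per 3x3/1x1 conv, forward order
  std::vector<arma::Cube<T>> outs;    // post-activation output of each conv
  std::vector<arma::Cube<T>> convt_in, convt_out;
  std::vector<arma::ucube> pool_masks;
  std::vector<arma::Cube<T>> drop_masks;
  std::vector<arma::Cube<T>> skips;   // post-dropout pre-pool
  arma::Cube<T> probs;
};

// Forward pass for one sample; fills the tape. Layer pair indices follow the
// parameter layout produced by unet_init_params() on the R side:
//   enc i: conv1, conv2            (2 per block, depth blocks)
//   bottleneck: conv1, conv2
//   dec i: convT, conv1, conv2     (3 per block, depth blocks)
//   out: 1x1 conv on the central crop
template <typename T>
static void forward_sample(const Params<T>& P, arma::Cube<T> cur, int depth,
                           const std::vector<double>& dropout, double noise_sd,
                           bool training, FastRng& rng, Tape<T>& tp) {
  if (training && noise_sd > 0) {
    T* x = cur.memptr();
    for (size_t i = 0; i < cur.n_elem; ++i) x[i] += (T)(noise_sd * rng.norm());
  }
  int pi = 0;  // pair index
  auto do_dropout = [&](arma::Cube<T>& X, double p) {
    arma::Cube<T> mask;
    if (training && p > 0) {
      mask.set_size(arma::size(X));
      const T scale = (T)(1.0 / (1.0 - p));
      T* m = mask.memptr();
      T* x = X.memptr();
      for (size_t i = 0; i < X.n_elem; ++i) {
        m[i] = (rng.unif() < p) ? T(0) : scale;
        x[i] *= m[i];
      }
    }
    tp.drop_masks.push_back(std::move(mask));
  };
  // encoder
  for (int i = 0; i < depth; ++i) {
    for (int cl = 0; cl < 2; ++cl, ++pi) {
      tp.cols.emplace_back();
      tp.outs.emplace_back();
      conv_elu_forward(cur, P.W[pi], P.b[pi], 3, tp.cols.back(), tp.outs.back());
      cur = tp.outs.back();
    }
    do_dropout(cur, dropout[i]);
    tp.skips.push_back(cur);
    arma::Cube<T> pooled;
    tp.pool_masks.emplace_back();
    maxpool2(cur, pooled, tp.pool_masks.back());
    cur = std::move(pooled);
  }
  // bottleneck
  for (int cl = 0; cl < 2; ++cl, ++pi) {
    tp.cols.emplace_back();
    tp.outs.emplace_back();
    conv_elu_forward(cur, P.W[pi], P.b[pi], 3, tp.cols.back(), tp.outs.back());
    cur = tp.outs.back();
  }
  do_dropout(cur, dropout[depth - 1]);
  // decoder (fully mirrored: one upsampling per pooling)
  for (int i = 0; i < depth; ++i) {
    tp.convt_in.push_back(cur);
    tp.convt_out.emplace_back();
    convt2_elu_forward(cur, P.W[pi], P.b[pi], tp.convt_out.back());
    ++pi;
    cur = arma::join_slices(tp.skips[depth - 1 - i], tp.convt_out.back());
    for (int cl = 0; cl < 2; ++cl, ++pi) {
      tp.cols.emplace_back();
      tp.outs.emplace_back();
      conv_elu_forward(cur, P.W[pi], P.b[pi], 3, tp.cols.back(), tp.outs.back());
      cur = tp.outs.back();
    }
    do_dropout(cur, dropout[depth - 1 - i]);
  }
  // central crop to the target window, then 1x1 conv + per-pixel softmax
  {
    const int TT = cur.n_rows, q = TT / 4;
    arma::Cube<T> cropped = cur.subcube(q, q, 0, q + TT / 2 - 1,
                                        q + TT / 2 - 1, cur.n_slices - 1);
    cur = std::move(cropped);
  }
  tp.cols.emplace_back();
  tp.outs.emplace_back();
  conv_elu_forward(cur, P.W[pi], P.b[pi], 1, tp.cols.back(), tp.outs.back(),
                   /*elu=*/false);
  arma::Cube<T>& logits = tp.outs.back();
  const int h = logits.n_rows, w = logits.n_cols, K = logits.n_slices;
  tp.probs.set_size(h, w, K);
  for (int j = 0; j < w; ++j)
    for (int i2 = 0; i2 < h; ++i2) {
      T mx = logits(i2, j, 0);
      for (int c = 1; c < K; ++c) mx = std::max(mx, logits(i2, j, c));
      T s = 0;
      for (int c = 0; c < K; ++c) {
        const T e = std::exp(logits(i2, j, c) - mx);
        tp.probs(i2, j, c) = e;
        s += e;
      }
      for (int c = 0; c < K; ++c) tp.probs(i2, j, c) /= s;
    }
}

// Backward pass for one sample given dlogits; accumulates into gW/gb.
template <typename T>
static void backward_sample(const Params<T>& P, int depth,
                            arma::Cube<T> dlogits, Tape<T>& tp,
                            std::vector<arma::Mat<T>>& gW,
                            std::vector<arma::Col<T>>& gb) {
  const int n_pairs = (int)P.W.size();
  int pi = n_pairs - 1;             // pair index, walking backwards
  int ci = (int)tp.cols.size() - 1; // conv cache index
  int di = (int)tp.drop_masks.size() - 1;
  arma::Cube<T> d;                  // gradient flowing backwards
  auto conv_in_channels = [&](int pair) {
    return (int)(P.W[pair].n_rows / (pair == n_pairs - 1 ? 1 : 9));
  };
  // output conv (no ELU)
  conv_elu_backward(tp.outs[ci], dlogits, tp.cols[ci], P.W[pi], 1, gW[pi],
                    gb[pi], d, conv_in_channels(pi), /*elu=*/false);
  --pi; --ci;
  {
    // un-crop: pad the gradient back into the full-resolution feature map
    const int half = d.n_rows, q = half / 2;
    arma::Cube<T> full(2 * half, 2 * half, d.n_slices, arma::fill::zeros);
    full.subcube(q, q, 0, q + half - 1, q + half - 1, d.n_slices - 1) = d;
    d = std::move(full);
  }
  auto undrop = [&](arma::Cube<T>& g) {
    if (tp.drop_masks[di].n_elem > 0) g %= tp.drop_masks[di];
    --di;
  };
  // decoder blocks in reverse
  std::vector<arma::Cube<T>> skip_grads(depth);
  for (int i = depth - 1; i >= 0; --i) {
    undrop(d);
    arma::Cube<T> d2;
    conv_elu_backward(tp.outs[ci], d, tp.cols[ci], P.W[pi], 3, gW[pi], gb[pi],
                      d2, conv_in_channels(pi));
    --pi; --ci;
    conv_elu_backward(tp.outs[ci], d2, tp.cols[ci], P.W[pi], 3, gW[pi], gb[pi],
                      d, conv_in_channels(pi));
    --pi; --ci;
    // split concat gradient: [skip | upsampled]
    const int f_skip = tp.skips[depth - 1 - i].n_slices;
    skip_grads[depth - 1 - i] = d.slices(0, f_skip - 1);
    arma::Cube<T> d_up = d.slices(f_skip, d.n_slices - 1);
    convt2_elu_backward(tp.convt_in[i], tp.convt_out[i], d_up, P.W[pi], gW[pi],
                        gb[pi], d);
    --pi;
  }
  // bottleneck
  undrop(d);
  for (int cl = 0; cl < 2; ++cl) {
    arma::Cube<T> dprev;
    conv_elu_backward(tp.outs[ci], d, tp.cols[ci], P.W[pi], 3, gW[pi], gb[pi],
                      dprev, conv_in_channels(pi));
    d = std::move(dprev);
    --pi; --ci;
  }
  // encoder blocks in reverse
  for (int i = depth - 1; i >= 0; --i) {
    const arma::Cube<T>& skip = tp.skips[i];
    arma::Cube<T> dpre;
    maxpool2_backward(d, tp.pool_masks[i], dpre, skip.n_rows, skip.n_cols);
    if (skip_grads[i].n_elem > 0) dpre += skip_grads[i];
    undrop(dpre);
    arma::Cube<T> d2;
    conv_elu_backward(tp.outs[ci], dpre, tp.cols[ci], P.W[pi], 3, gW[pi],
                      gb[pi], d2, conv_in_channels(pi));
    --pi; --ci;
    conv_elu_backward(tp.outs[ci], d2, tp.cols[ci], P.W[pi], 3, gW[pi], gb[pi],
                      d, conv_in_channels(pi));
    --pi; --ci;
  }
}

template <typename T>
static List unet_pass_impl(const List& params, const NumericVector& x,
                           const Nullable<NumericVector>& y, const List& cfg,
                           bool training, int seed, bool want_grad,
                           bool want_probs) {
  const int depth = as<int>(cfg["depth"]);
  const std::vector<double> dropout =
      as<std::vector<double>>(cfg["dropout"]);
  const double noise_sd = as<double>(cfg["noise_sd"]);
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("input must be a 4-d array (H, W, 1, B)");
  const int H = xd[0], W = xd[1], B = xd[3];
  Params<T> P = parse_params<T>(params);
  std::vector<arma::Mat<T>> gW;
  std::vector<arma::Col<T>> gb;
  if (want_grad) {
    for (size_t i = 0; i < P.W.size(); ++i) {
      gW.emplace_back(arma::size(P.W[i]), arma::fill::zeros);
      gb.emplace_back(P.b[i].n_elem, arma::fill::zeros);
    }
  }
  const bool have_y = y.isNotNull();
  NumericVector yv;
  int h2 = H / 2, w2 = W / 2, K = 5;
  if (have_y) {
    yv = y.get();
    IntegerVector yd = yv.attr("dim");
    h2 = yd[0]; w2 = yd[1]; K = yd[2];
  }
  NumericVector probs_out;
  if (want_probs) {
    probs_out = NumericVector((size_t)h2 * w2 * K * B);
    probs_out.attr("dim") = IntegerVector::create(h2, w2, K, B);
  }
  FastRng rng((uint64_t)(uint32_t)seed);
  double loss = 0.0;
  const double denom = (double)B * h2 * w2;
  for (int s = 0; s < B; ++s) {
    arma::Cube<T> xs(H, W, 1);
    for (size_t j = 0; j < (size_t)H * W; ++j)
      xs(j) = (T)x[(size_t)s * H * W + j];
    Tape<T> tp;
    forward_sample(P, std::move(xs), depth, dropout, noise_sd, training, rng,
                   tp);
    if (want_probs)
      for (size_t j = 0; j < tp.probs.n_elem; ++j)
        probs_out[(size_t)s * tp.probs.n_elem + j] = (double)tp.probs(j);
    if (have_y) {
      arma::Cube<T> dlogits(h2, w2, K);
      const size_t off = (size_t)s * h2 * w2 * K;
      for (size_t j = 0; j < dlogits.n_elem; ++j) {
        const T yj = (T)yv[off + j];
        const T pj = tp.probs(j);
        if (yj > T(0))
          loss -= (double)yj * std::log(std::max((double)pj, 1e-12)) / denom;
        dlogits(j) = (pj - yj) / (T)denom;
      }
      if (want_grad) backward_sample(P, depth, std::move(dlogits), tp, gW, gb);
    }
  }
  List out = List::create(_["loss"] = loss);
  if (want_grad) {
    List g(params.size());
    for (size_t i = 0; i < gW.size(); ++i) {
      NumericMatrix w((int)gW[i].n_rows, (int)gW[i].n_cols);
      for (size_t j = 0; j < gW[i].n_elem; ++j) w[j] = (double)gW[i](j);
      NumericVector bb((int)gb[i].n_elem);
      for (size_t j = 0; j < gb[i].n_elem; ++j) bb[j] = (double)gb[i](j);
      g[2 * i] = w;
      g[2 * i + 1] = bb;
    }
    out["grads"] = g;
  }
  if (want_probs) out["probs"] = probs_out;
  return out;
}

// [[Rcpp::export]]
List cpp_unet_pass(List params, NumericVector x, Nullable<NumericVector> y,
                   List cfg, bool training, int seed, bool want_grad,
                   bool want_probs, bool use_double) {
  if (use_double)
    return unet_pass_impl<double>(params, x, y, cfg, training, seed, want_grad,
                                  want_probs);
  return unet_pass_impl<float>(params, x, y, cfg, training, seed, want_grad,
                               want_probs);
}

// Fused Adam update with global-norm gradient clipping: one pass over the
// parameters, no intermediate temporaries. Returns fresh vectors so that
// checkpointed parameter lists are never mutated in place.
// [[Rcpp::export]]
List cpp_adam_update(List params, List grads, List m, List v, int t,
                     double lr, double clip, double beta1, double beta2,
                     double eps) {
  const int K = params.size();
  double gn2 = 0.0;
  if (R_finite(clip)) {
    for (int k = 0; k < K; ++k) {
      NumericVector g = grads[k];
      for (R_xlen_t j = 0; j < g.size(); ++j) gn2 += g[j] * g[j];
    }
  }
  const double scale = (R_finite(clip) && gn2 > clip * clip)
                           ? clip / std::sqrt(gn2) : 1.0;
  const double b1t = 1.0 - std::pow(beta1, t);
  const double b2t = 1.0 - std::pow(beta2, t);
  List p_out(K), m_out(K), v_out(K);
  for (int k = 0; k < K; ++k) {
    NumericVector p = params[k], g = grads[k], mk = m[k], vk = v[k];
    const R_xlen_t n = p.size();
    NumericVector pn(n), mn(n), vn(n);
    for (R_xlen_t j = 0; j < n; ++j) {
      const double gj = g[j] * scale;
      mn[j] = beta1 * mk[j] + (1.0 - beta1) * gj;
      vn[j] = beta2 * vk[j] + (1.0 - beta2) * gj * gj;
      pn[j] = p[j] - lr * (mn[j] / b1t) / (std::sqrt(vn[j] / b2t) + eps);
    }
    pn.attr("dim") = p.attr("dim");
    p_out[k] = pn; m_out[k] = mn; v_out[k] = vn;
  }
  return List::create(_["params"] = p_out, _["m"] = m_out, _["v"] = v_out);
}
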