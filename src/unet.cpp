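// Self-contained CPU 2D U-Net: encoder-decoder with two 3x3 conv+ReLU layers
// per block, 2x2 max pooling, nearest-neighbour upsampling with a 3x3
// "up-conv", skip concatenation, element dropout after each block, linear
// 1x1 output head, whole-batch Adam on an MSE loss.
//
// Tensors are arma::cube (H x W x C); images are processed one at a time and
// gradients accumulated, which matches a single whole-batch gradient step
// per epoch.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
using namespace Rcpp;
// single precision internally: training at this scale is bandwidth-bound
using cube = arma::fcube;
using mat = arma::fmat;
using rowvec = arma::frowvec;

struct Conv {
  mat W;        // (k*k*Cin) x Cout
  rowvec b;     // Cout
  mat gW; rowvec gb;           // accumulated gradients
  mat mW, vW; rowvec mb, vb;   // Adam state
  int k, cin, cout;
};

static mat im2col(const cube &X, int k) {
  int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  if (k == 1) {
    mat out(H * (size_t)W, C);
    for (int c = 0; c < C; ++c)
      out.col(c) = arma::vectorise(X.slice(c));
    return out;
  }
  mat out(H * (size_t)W, 9 * (size_t)C, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const mat &S = X.slice(c);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy, ++col) {
        // out(p, col) = S(y+dy, x+dx) with zero padding
        int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        for (int x = x0; x < x1; ++x) {
          float *dst = out.colptr(col) + (size_t)x * H;
          const float *src = S.colptr(x + dx);
          for (int y = y0; y < y1; ++y) dst[y] = src[y + dy];
        }
      }
  }
  return out;
}

// scatter-add transpose of im2col
static cube col2im(const mat &dcol, int H, int W, int C, int k) {
  cube dX(H, W, C, arma::fill::zeros);
  if (k == 1) {
    for (int c = 0; c < C; ++c)
      dX.slice(c) = arma::reshape(dcol.col(c), H, W);
    return dX;
  }
  int col = 0;
  for (int c = 0; c < C; ++c) {
    mat &S = dX.slice(c);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy, ++col) {
        int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        for (int x = x0; x < x1; ++x) {
          float *dst = S.colptr(x + dx);
          const float *src = dcol.colptr(col) + (size_t)x * H;
          for (int y = y0; y < y1; ++y) dst[y + dy] += src[y];
        }
      }
  }
  return dX;
}

struct ConvCache { mat col; cube out; int H, W, C; };

static cube conv_fwd(Conv &cv, const cube &X, bool relu, ConvCache *cache) {
  mat col = im2col(X, cv.k);
  mat Y = col * cv.W;
  Y.each_row() += cv.b;
  if (relu) Y.for_each([](float &v) { if (v < 0) v = 0; });
  cube out(X.n_rows, X.n_cols, cv.cout);
  for (int c = 0; c < cv.cout; ++c)
    out.slice(c) = arma::reshape(Y.col(c), X.n_rows, X.n_cols);
  if (cache) {
    cache->col = std::move(col);
    cache->out = out;
    cache->H = X.n_rows; cache->W = X.n_cols; cache->C = X.n_slices;
  }
  return out;
}

static cube conv_bwd(Conv &cv, const cube &dY_in, const ConvCache &cache,
                     bool relu) {
  int H = cache.H, W = cache.W;
  mat dY(H * (size_t)W, cv.cout);
  for (int c = 0; c < cv.cout; ++c) {
    mat g = dY_in.slice(c);
    if (relu) {
      const mat &o = cache.out.slice(c);
      g.elem(arma::find(o == 0)).zeros();
    }
    dY.col(c) = arma::vectorise(g);
  }
  cv.gW += cache.col.t() * dY;
  cv.gb += arma::sum(dY, 0);
  mat dcol = dY * cv.W.t();
  return col2im(dcol, H, W, cache.C, cv.k);
}

static cube maxpool(const cube &X, arma::umat &arg) {
  int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube out(H, W, C);
  arg.set_size(H * (size_t)W, C);
  for (int c = 0; c < C; ++c) {
    const mat &S = X.slice(c);
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        float best = S(2 * y, 2 * x); arma::uword bi = 2 * y + S.n_rows * (2 * x);
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            float v = S(2 * y + i, 2 * x + j);
            if (v > best) { best = v; bi = 2 * y + i + S.n_rows * (2 * x + j); }
          }
        out(y, x, c) = best;
        arg(y + (size_t)H * x, c) = bi;
      }
  }
  return out;
}

static cube maxpool_bwd(const cube &dY, const arma::umat &arg, int H, int W) {
  int C = dY.n_slices;
  cube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat &S = dX.slice(c);
    const mat &G = dY.slice(c);
    for (size_t p = 0; p < G.n_elem; ++p)
      S(arg(p, c)) += G(p);
  }
  return dX;
}

static cube upsample2(const cube &X) {
  int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        float v = X(y, x, c);
        out(2 * y, 2 * x, c) = v; out(2 * y + 1, 2 * x, c) = v;
        out(2 * y, 2 * x + 1, c) = v; out(2 * y + 1, 2 * x + 1, c) = v;
      }
  return out;
}

static cube upsample2_bwd(const cube &dY) {
  int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  cube dX(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y)
        dX(y, x, c) = dY(2 * y, 2 * x, c) + dY(2 * y + 1, 2 * x, c) +
                      dY(2 * y, 2 * x + 1, c) + dY(2 * y + 1, 2 * x + 1, c);
  return dX;
}

struct Net {
  std::vector<Conv> params;
  int levels, F;
  double dropout;
};

static void add_conv(Net &net, int k, int cin, int cout, std::mt19937_64 &rng) {
  Conv cv;
  cv.k = k; cv.cin = cin; cv.cout = cout;
  double sd = std::sqrt(2.0 / (k * k * cin));
  std::normal_distribution<double> N(0.0, sd);
  cv.W.set_size((size_t)k * k * cin, cout);
  for (size_t i = 0; i < cv.W.n_elem; ++i) cv.W(i) = (float)N(rng);
  cv.b.zeros(cout);
  cv.gW.zeros(arma::size(cv.W)); cv.gb.zeros(cout);
  cv.mW.zeros(arma::size(cv.W)); cv.vW.zeros(arma::size(cv.W));
  cv.mb.zeros(cout); cv.vb.zeros(cout);
  net.params.push_back(std::move(cv));
}

static Net build_net(int levels, int F, double dropout, std::mt19937_64 &rng) {
  Net net; net.levels = levels; net.F = F; net.dropout = dropout;
  int prev = 1;
  for (int b = 0; b < levels; ++b) {           // encoder blocks
    int c = F << b;
    add_conv(net, 3, prev, c, rng);
    add_conv(net, 3, c, c, rng);
    prev = c;
  }
  int cb = F << levels;                        // bottleneck
  add_conv(net, 3, prev, cb, rng);
  add_conv(net, 3, cb, cb, rng);
  for (int b = levels - 1; b >= 0; --b) {      // decoder blocks
    int c = F << b;
    add_conv(net, 3, c * 2, c, rng);           // up-conv after upsample
    add_conv(net, 3, c * 2, c, rng);           // after skip concat
    add_conv(net, 3, c, c, rng);
  }
  add_conv(net, 1, F, 1, rng);                 // linear head
  return net;
}

struct FwdCache {
  std::vector<ConvCache> conv;
  std::vector<arma::umat> pool;
  std::vector<std::pair<int, int>> poolDims;
  std::vector<cube> dropMask;
};

static cube concat(const cube &A, const cube &B) {
  cube out(A.n_rows, A.n_cols, A.n_slices + B.n_slices);
  for (size_t c = 0; c < A.n_slices; ++c) out.slice(c) = A.slice(c);
  for (size_t c = 0; c < B.n_slices; ++c) out.slice(A.n_slices + c) = B.slice(c);
  return out;
}

static void apply_dropout(cube &X, double p, std::mt19937_64 &rng,
                          FwdCache *cache) {
  if (p <= 0) return;
  std::uniform_real_distribution<double> U(0.0, 1.0);
  cube mask(X.n_rows, X.n_cols, X.n_slices);
  float scale = 1.0f / (float)(1.0 - p);
  for (size_t i = 0; i < mask.n_elem; ++i)
    mask(i) = (U(rng) < p) ? 0.0f : scale;
  X %= mask;
  if (cache) cache->dropMask.push_back(std::move(mask));
}

// Forward pass; when training, caches everything needed for backward.
static cube net_fwd(Net &net, const cube &input, bool training,
                    std::mt19937_64 &rng, FwdCache *cache,
                    std::vector<cube> *skipsOut) {
  int L = net.levels;
  cube cur = input;
  std::vector<cube> skips;
  int pi = 0;
  auto CF = [&](const cube &X, bool relu) {
    ConvCache cc;
    cube out = conv_fwd(net.params[pi++], X, relu, cache ? &cc : nullptr);
    if (cache) cache->conv.push_back(std::move(cc));
    return out;
  };
  for (int b = 0; b < L; ++b) {
    cur = CF(cur, true);
    cur = CF(cur, true);
    if (training) apply_dropout(cur, net.dropout, rng, cache);
    skips.push_back(cur);
    arma::umat arg;
    if (cache) cache->poolDims.push_back({(int)cur.n_rows, (int)cur.n_cols});
    cur = maxpool(cur, arg);
    if (cache) cache->pool.push_back(std::move(arg));
  }
  cur = CF(cur, true);
  cur = CF(cur, true);
  if (training) apply_dropout(cur, net.dropout, rng, cache);
  for (int b = L - 1; b >= 0; --b) {
    cur = upsample2(cur);
    cur = CF(cur, true);
    cur = concat(cur, skips[b]);
    cur = CF(cur, true);
    cur = CF(cur, true);
  }
  cur = CF(cur, false);  // linear 1x1 head
  if (skipsOut) *skipsOut = std::move(skips);
  return cur;
}

// Backward pass mirroring net_fwd; accumulates gradients into net.params.
static void net_bwd(Net &net, const cube &dOut, FwdCache &cache) {
  int L = net.levels;
  int pi = (int)net.params.size() - 1;
  int ci = (int)cache.conv.size() - 1;
  int di = (int)cache.dropMask.size() - 1;
  auto CB = [&](const cube &g, bool relu) {
    cube out = conv_bwd(net.params[pi], g, cache.conv[ci], relu);
    --pi; --ci;
    return out;
  };
  cube g = CB(dOut, false);                    // head
  std::vector<cube> skipGrads(L);
  for (int b = 0; b <= L - 1; ++b) {           // decoder, reverse order
    g = CB(g, true);
    g = CB(g, true);
    // split concat: first half went to upsampled path, second to skip
    int c = net.F << b;
    cube gskip(g.n_rows, g.n_cols, c);
    cube gup(g.n_rows, g.n_cols, c);
    for (int s = 0; s < c; ++s) {
      gup.slice(s) = g.slice(s);
      gskip.slice(s) = g.slice(c + s);
    }
    skipGrads[b] = std::move(gskip);
    g = CB(gup, true);
    g = upsample2_bwd(g);
  }
  if (net.dropout > 0) { g %= cache.dropMask[di]; --di; }
  g = CB(g, true);                             // bottleneck
  g = CB(g, true);
  for (int b = 0; b < L; ++b) {                // encoder, reverse order
    g = maxpool_bwd(g, cache.pool[L - 1 - b], cache.poolDims[L - 1 - b].first,
                    cache.poolDims[L - 1 - b].second);
    g += skipGrads[L - 1 - b];
    if (net.dropout > 0) { g %= cache.dropMask[di]; --di; }
    g = CB(g, true);
    g = CB(g, true);
  }
}

static void adam_step(Net &net, double lr, int t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  float c1 = 1.0f - std::pow(b1, t), c2 = 1.0f - std::pow(b2, t);
  float flr = (float)lr;
  for (auto &cv : net.params) {
    cv.mW = b1 * cv.mW + (1 - b1) * cv.gW;
    cv.vW = b2 * cv.vW + (1 - b2) * arma::square(cv.gW);
    cv.W -= flr * (cv.mW / c1) / (arma::sqrt(cv.vW / c2) + eps);
    cv.mb = b1 * cv.mb + (1 - b1) * cv.gb;
    cv.vb = b2 * cv.vb + (1 - b2) * arma::square(cv.gb);
    cv.b -= flr * (cv.mb / c1) / (arma::sqrt(cv.vb / c2) + eps);
    cv.gW.zeros(); cv.gb.zeros();
  }
}

static List export_weights(const Net &net) {
  List out(net.params.size() * 2);
  CharacterVector nm(net.params.size() * 2);
  for (size_t i = 0; i < net.params.size(); ++i) {
    out[2 * i] = wrap(arma::conv_to<arma::mat>::from(net.params[i].W));
    out[2 * i + 1] =
      wrap(arma::conv_to<arma::mat>::from(mat(net.params[i].b)));
    nm[2 * i] = "W" + std::to_string(i);
    nm[2 * i + 1] = "b" + std::to_string(i);
  }
  out.attr("names") = nm;
  return out;
}

static Net import_net(List weights, int levels, int F, double dropout) {
  std::mt19937_64 rng(0);
  Net net = build_net(levels, F, dropout, rng);
  for (size_t i = 0; i < net.params.size(); ++i) {
    arma::mat W = as<arma::mat>(weights["W" + std::to_string(i)]);
    net.params[i].W = arma::conv_to<mat>::from(W);
    arma::mat bm = as<arma::mat>(weights["b" + std::to_string(i)]);
    arma::rowvec bv(bm.memptr(), bm.n_elem);
    net.params[i].b = arma::conv_to<rowvec>::from(bv);
  }
  return net;
}

// mr, ct: H x W x N cubes of normalized slices. batchSize 0 = whole batch
// (one Adam step per epoch); otherwise fixed-order mini-batches. init may
// carry weights from a previous run to continue training (Adam state is
// reset).
// [[Rcpp::export]]
List cpp_unet_train(arma::cube mrD, arma::cube ctD, int levels,
                    int baseFilters, double dropout, double lr, int epochs,
                    int seed, int batchSize = 0,
                    Rcpp::Nullable<List> init = R_NilValue) {
  cube mr = arma::conv_to<cube>::from(mrD);
  cube ct = arma::conv_to<cube>::from(ctD);
  std::mt19937_64 rng((uint64_t)seed);
  Net net = build_net(levels, baseFilters, dropout, rng);
  if (init.isNotNull()) {
    List iw(init);
    for (size_t i = 0; i < net.params.size(); ++i) {
      arma::mat W = as<arma::mat>(iw["W" + std::to_string(i)]);
      net.params[i].W = arma::conv_to<mat>::from(W);
      arma::mat bm = as<arma::mat>(iw["b" + std::to_string(i)]);
      arma::rowvec bv(bm.memptr(), bm.n_elem);
      net.params[i].b = arma::conv_to<rowvec>::from(bv);
    }
  }
  int N = mr.n_slices;
  int bs = (batchSize <= 0 || batchSize > N) ? N : batchSize;
  NumericVector lossTrace(epochs);
  int t = 0;
  for (int e = 0; e < epochs; ++e) {
    double loss = 0;
    for (int b0 = 0; b0 < N; b0 += bs) {
      int b1 = std::min(b0 + bs, N);
      for (int i = b0; i < b1; ++i) {
        cube x(mr.n_rows, mr.n_cols, 1);
        x.slice(0) = mr.slice(i);
        FwdCache cache;
        cube pred = net_fwd(net, x, true, rng, &cache, nullptr);
        cube resid = pred;
        resid.slice(0) -= ct.slice(i);
        loss += arma::accu(arma::square(resid.slice(0))) / resid.n_elem;
        cube dOut = resid * (float)(2.0 / (resid.n_elem * (double)(b1 - b0)));
        net_bwd(net, dOut, cache);
      }
      adam_step(net, lr, ++t);
    }
    lossTrace[e] = loss / N;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = export_weights(net),
                      _["loss"] = lossTrace);
}

// [[Rcpp::export]]
arma::cube cpp_unet_infer(List weights, arma::cube mrD, int levels,
                          int baseFilters) {
  cube mr = arma::conv_to<cube>::from(mrD);
  Net net = import_net(weights, levels, baseFilters, 0.0);
  std::mt19937_64 rng(0);
  arma::cube out(mr.n_rows, mr.n_cols, mr.n_slices);
  for (size_t i = 0; i < mr.n_slices; ++i) {
    cube x(mr.n_rows, mr.n_cols, 1);
    x.slice(0) = mr.slice(i);
    cube pred = net_fwd(net, x, false, rng, nullptr, nullptr);
    out.slice(i) = arma::conv_to<arma::mat>::from(pred.slice(0));
  }
  return out;
}
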