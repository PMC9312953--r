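// Network core for the binary convolutional autoencoder (BCAE) and the
// residual error compensation network (RECN).
//
// All convolutions are stride-1 "same"-padded 1-D operators realized as
// im2col gathers followed by BLAS gemm, in single precision.  The transposed
// convolution is the exact adjoint of the forward convolution: taps flipped,
// channel axes swapped, padding mirrored.  The binary encoding layer uses a
// step activation in the forward pass and a straight-through surrogate
// gradient (1 on [-0.5, 0.5), 0 elsewhere) in the backward pass.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::fcube;

enum Kind { CONV = 0, TCONV = 1, MAXPOOL = 2, UPSAMPLE = 3, BEL = 4, LINEAR = 5 };
enum Act { NONE = 0, TANH = 1, RELU = 2, STEP = 3 };

struct Lay {
  int kind, K, cin, cout, Lin, Lout, act;
  bool bn, drop;
  int padF;    // left padding of the forward gather
  bool flipF;  // tap order of the forward gather
};

struct LayParams {
  fmat W;                        // (K*cin) x cout, or (in x out) for linear
  fvec b, gamma, beta, rmean, rvar;
  bool has_w = false, has_bn = false;
};

struct LayGrads {
  fmat dW;
  fvec db, dgamma, dbeta;
};

struct LayCache {
  fcube out;       // layer output (post-activation, post-dropout)
  fcube actout;    // post-activation, pre-dropout (dropout layers only)
  fcube xhat;      // batch-norm normalized values
  fvec invstd;     // batch-norm inverse std per channel
  fcube mask;      // dropout mask
  arma::ucube arg; // max-pool argmax offsets
};

static std::vector<Lay> parse_spec(const List& spec) {
  std::vector<Lay> ls;
  for (int i = 0; i < spec.size(); ++i) {
    List e = spec[i];
    Lay l;
    std::string kind = as<std::string>(e["kind"]);
    if (kind == "conv") l.kind = CONV;
    else if (kind == "tconv") l.kind = TCONV;
    else if (kind == "maxpool") l.kind = MAXPOOL;
    else if (kind == "upsample") l.kind = UPSAMPLE;
    else if (kind == "bel") l.kind = BEL;
    else if (kind == "linear") l.kind = LINEAR;
    else stop("unknown layer kind");
    l.K = as<int>(e["size"]);
    l.cin = as<int>(e["cin"]);
    l.cout = as<int>(e["cout"]);
    l.Lin = as<int>(e["len_in"]);
    l.Lout = as<int>(e["len_out"]);
    std::string act = as<std::string>(e["activation"]);
    l.act = (act == "tanh") ? TANH : (act == "relu") ? RELU :
            (act == "step") ? STEP : NONE;
    l.bn = as<bool>(e["bn"]);
    l.drop = as<bool>(e["dropout"]);
    int p = (l.K - 1) / 2;  // "same" padding, left gets the floor
    if (l.kind == CONV) { l.padF = p; l.flipF = false; }
    else { l.padF = l.K - 1 - p; l.flipF = true; }  // adjoint for tconv
    ls.push_back(l);
  }
  return ls;
}

static std::vector<LayParams> parse_params(const List& params,
                                           const std::vector<Lay>& ls) {
  std::vector<LayParams> ps(ls.size());
  for (size_t i = 0; i < ls.size(); ++i) {
    if (ls[i].kind == MAXPOOL || ls[i].kind == UPSAMPLE || ls[i].kind == BEL)
      continue;
    List e = params[i];
    LayParams p;
    p.W = arma::conv_to<fmat>::from(as<arma::mat>(e["W"]));
    p.b = arma::conv_to<fvec>::from(as<arma::vec>(e["b"]));
    p.has_w = true;
    if (ls[i].bn) {
      p.gamma = arma::conv_to<fvec>::from(as<arma::vec>(e["gamma"]));
      p.beta  = arma::conv_to<fvec>::from(as<arma::vec>(e["beta"]));
      p.rmean = arma::conv_to<fvec>::from(as<arma::vec>(e["rmean"]));
      p.rvar  = arma::conv_to<fvec>::from(as<arma::vec>(e["rvar"]));
      p.has_bn = true;
    }
    ps[i] = std::move(p);
  }
  return ps;
}

static List params_to_r(const std::vector<LayParams>& ps,
                        const std::vector<Lay>& ls) {
  List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    if (!ps[i].has_w) { out[i] = R_NilValue; continue; }
    List e = List::create(
      Named("W") = arma::conv_to<arma::mat>::from(ps[i].W),
      Named("b") = arma::conv_to<arma::vec>::from(ps[i].b));
    if (ps[i].has_bn) {
      e["gamma"] = arma::conv_to<arma::vec>::from(ps[i].gamma);
      e["beta"]  = arma::conv_to<arma::vec>::from(ps[i].beta);
      e["rmean"] = arma::conv_to<arma::vec>::from(ps[i].rmean);
      e["rvar"]  = arma::conv_to<arma::vec>::from(ps[i].rvar);
    }
    out[i] = e;
  }
  return out;
}

// im2col gather: out(t, k*C + c) = src(t - padL + tap, c), tap = k or K-1-k.
static fmat gather(const fmat& src, int K, int padL, bool flip) {
  const int L = src.n_rows, C = src.n_cols;
  fmat out(L, K * C, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    int tap = flip ? (K - 1 - k) : k;
    int s0 = tap - padL;  // src row = t + s0
    int tlo = std::max(0, -s0), thi = std::min(L - 1, L - 1 - s0);
    if (tlo > thi) continue;
    out.submat(tlo, k * C, thi, (k + 1) * C - 1) =
      src.rows(tlo + s0, thi + s0);
  }
  return out;
}

// Weight permutation used by the input-gradient pass:
// Wperm(k*cout + o, c) = W(k*cin + c, o).
static fmat perm_weights(const fmat& W, int K, int cin, int cout) {
  fmat Wp(K * cout, cin);
  for (int k = 0; k < K; ++k)
    for (int o = 0; o < cout; ++o)
      for (int c = 0; c < cin; ++c)
        Wp(k * cout + o, c) = W(k * cin + c, o);
  return Wp;
}

static void batchnorm_forward(fcube& Z, const Lay& l, LayParams& p,
                              LayCache& cache, bool training, float momentum,
                              float eps) {
  const int L = Z.n_rows, C = Z.n_cols, B = Z.n_slices;
  const float N = static_cast<float>(L) * B;
  cache.xhat.set_size(L, C, B);
  cache.invstd.set_size(C);
  for (int c = 0; c < C; ++c) {
    float mean, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int b = 0; b < B; ++b)
        for (int t = 0; t < L; ++t) { float v = Z(t, c, b); s += v; s2 += v * v; }
      mean = static_cast<float>(s / N);
      var = static_cast<float>(s2 / N) - mean * mean;
      if (var < 0) var = 0;
      p.rmean(c) = momentum * p.rmean(c) + (1.0f - momentum) * mean;
      p.rvar(c)  = momentum * p.rvar(c)  + (1.0f - momentum) * var;
    } else {
      mean = p.rmean(c);
      var = p.rvar(c);
    }
    float inv = 1.0f / std::sqrt(var + eps);
    cache.invstd(c) = inv;
    float g = p.gamma(c), be = p.beta(c);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < L; ++t) {
        float xh = (Z(t, c, b) - mean) * inv;
        cache.xhat(t, c, b) = xh;
        Z(t, c, b) = g * xh + be;
      }
  }
}

static void batchnorm_backward(fcube& dZ, const Lay& l, const LayParams& p,
                               const LayCache& cache, LayGrads& g) {
  const int L = dZ.n_rows, C = dZ.n_cols, B = dZ.n_slices;
  const float N = static_cast<float>(L) * B;
  for (int c = 0; c < C; ++c) {
    double sdy = 0.0, sdyx = 0.0;
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < L; ++t) {
        float dy = dZ(t, c, b);
        sdy += dy;
        sdyx += dy * cache.xhat(t, c, b);
      }
    g.dgamma(c) += static_cast<float>(sdyx);
    g.dbeta(c)  += static_cast<float>(sdy);
    float inv = cache.invstd(c), ga = p.gamma(c);
    float msdy = static_cast<float>(sdy) / N;
    float msdyx = static_cast<float>(sdyx) / N;
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < L; ++t) {
        float dxhat = dZ(t, c, b) * ga;
        dZ(t, c, b) = inv * (dxhat - msdy * ga - cache.xhat(t, c, b) * msdyx * ga);
      }
  }
}

// Forward through one layer; `in` is the previous layer's output.
static void layer_forward(const Lay& l, LayParams& p, const fcube& in,
                          LayCache& cache, bool training, float drop_rate,
                          std::mt19937& rng, float bn_momentum, float bn_eps) {
  const int B = in.n_slices;
  switch (l.kind) {
  case CONV:
  case TCONV: {
    cache.out.set_size(l.Lout, l.cout, B);
    for (int b = 0; b < B; ++b) {
      fmat Xc = gather(in.slice(b), l.K, l.padF, l.flipF);
      fmat Y = Xc * p.W;
      Y.each_row() += p.b.t();
      cache.out.slice(b) = Y;
    }
    if (l.bn)
      batchnorm_forward(cache.out, l, p, cache, training, bn_momentum, bn_eps);
    if (l.act == TANH) cache.out = arma::tanh(cache.out);
    else if (l.act == RELU) cache.out = arma::clamp(cache.out, 0.0f, arma::Datum<float>::inf);
    if (l.drop && training) {
      cache.actout = cache.out;
      cache.mask.set_size(arma::size(cache.out));
      std::uniform_real_distribution<float> unif(0.0f, 1.0f);
      const float keep = 1.0f - drop_rate;
      for (arma::uword i = 0; i < cache.mask.n_elem; ++i)
        cache.mask(i) = (unif(rng) < keep) ? 1.0f / keep : 0.0f;
      cache.out %= cache.mask;
    }
    break;
  }
  case MAXPOOL: {
    const int S = l.K;
    cache.out.set_size(l.Lout, l.cin, B);
    cache.arg.set_size(l.Lout, l.cin, B);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < l.cin; ++c)
        for (int n = 0; n < l.Lout; ++n) {
          float best = in(n * S, c, b);
          int arg = 0;
          for (int r = 1; r < S; ++r) {
            float v = in(n * S + r, c, b);
            if (v > best) { best = v; arg = r; }
          }
          cache.out(n, c, b) = best;
          cache.arg(n, c, b) = arg;
        }
    break;
  }
  case UPSAMPLE: {
    const int S = l.K;
    cache.out.zeros(l.Lout, l.cin, B);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < l.cin; ++c)
        for (int n = 0; n < l.Lin; ++n)
          cache.out(n * S, c, b) = in(n, c, b);
    break;
  }
  case BEL: {
    cache.out.set_size(arma::size(in));
    for (arma::uword i = 0; i < in.n_elem; ++i)
      cache.out(i) = (in(i) >= 0.0f) ? 1.0f : 0.0f;
    break;
  }
  case LINEAR: {
    cache.out.set_size(l.Lout, 1, B);
    for (int b = 0; b < B; ++b) {
      fvec x = arma::vectorise(in.slice(b));
      cache.out.slice(b) = p.W.t() * x + p.b;
    }
    break;
  }
  }
}

// Backward through one layer: receives dOut, returns dIn; accumulates grads.
static fcube layer_backward(const Lay& l, const LayParams& p, const fcube& in,
                            const LayCache& cache, fcube dOut, LayGrads& g,
                            bool surrogate) {
  const int B = in.n_slices;
  switch (l.kind) {
  case CONV:
  case TCONV: {
    if (l.drop && cache.mask.n_elem > 0) dOut %= cache.mask;
    if (l.act == TANH) {
      const fcube& a = (l.drop && cache.actout.n_elem > 0) ? cache.actout : cache.out;
      dOut %= (1.0f - arma::square(a));
    } else if (l.act == RELU) {
      const fcube& a = (l.drop && cache.actout.n_elem > 0) ? cache.actout : cache.out;
      for (arma::uword i = 0; i < dOut.n_elem; ++i)
        if (a(i) <= 0.0f) dOut(i) = 0.0f;
    }
    if (l.bn) batchnorm_backward(dOut, l, p, cache, g);
    fmat Wp = perm_weights(p.W, l.K, l.cin, l.cout);
    const int padB = l.K - 1 - l.padF;
    fcube dIn(l.Lin, l.cin, B);
    for (int b = 0; b < B; ++b) {
      const fmat& dY = dOut.slice(b);
      fmat Xc = gather(in.slice(b), l.K, l.padF, l.flipF);
      g.dW += Xc.t() * dY;
      g.db += arma::sum(dY, 0).t();
      fmat G = gather(dY, l.K, padB, !l.flipF);
      dIn.slice(b) = G * Wp;
    }
    return dIn;
  }
  case MAXPOOL: {
    const int S = l.K;
    fcube dIn(l.Lin, l.cin, B, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < l.cin; ++c)
        for (int n = 0; n < l.Lout; ++n)
          dIn(n * S + cache.arg(n, c, b), c, b) = dOut(n, c, b);
    return dIn;
  }
  case UPSAMPLE: {
    const int S = l.K;
    fcube dIn(l.Lin, l.cin, B);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < l.cin; ++c)
        for (int n = 0; n < l.Lin; ++n)
          dIn(n, c, b) = dOut(n * S, c, b);
    return dIn;
  }
  case BEL: {
    fcube dIn(arma::size(dOut), arma::fill::zeros);
    if (surrogate)
      for (arma::uword i = 0; i < dOut.n_elem; ++i)
        dIn(i) = (in(i) >= -0.5f && in(i) < 0.5f) ? dOut(i) : 0.0f;
    return dIn;
  }
  case LINEAR: {
    fcube dIn(l.Lin / 1, l.cin, B);  // cin channels, Lin rows
    for (int b = 0; b < B; ++b) {
      fvec x = arma::vectorise(in.slice(b));
      fvec dy = dOut.slice(b).col(0);
      g.dW += x * dy.t();
      g.db += dy;
      fvec dx = p.W * dy;
      dIn.slice(b) = arma::reshape(dx, l.Lin, l.cin);
    }
    return dIn;
  }
  }
  return fcube();
}

static fcube mat_to_cube(const fmat& X) {
  // columns of X are samples; cube slices are (L x 1) single-channel signals
  fcube c(X.n_rows, 1, X.n_cols);
  for (arma::uword b = 0; b < X.n_cols; ++b) c.slice(b).col(0) = X.col(b);
  return c;
}

struct ForwardResult {
  std::vector<LayCache> caches;
};

static void forward_all(const std::vector<Lay>& ls, std::vector<LayParams>& ps,
                        const fcube& X, std::vector<LayCache>& caches,
                        bool training, float drop_rate, std::mt19937& rng) {
  caches.resize(ls.size());
  const fcube* cur = &X;
  for (size_t i = 0; i < ls.size(); ++i) {
    layer_forward(ls[i], ps[i], *cur, caches[i], training, drop_rate, rng,
                  0.9f, 1e-5f);
    cur = &caches[i].out;
  }
}

// Pseudo-Huber loss (mean over elements) and its gradient wrt the output.
static double ph_loss(const fcube& Y, const fcube& T, float delta,
                      fcube* dY = nullptr) {
  double loss = 0.0;
  if (dY) dY->set_size(arma::size(Y));
  const double d2 = static_cast<double>(delta) * delta;
  const double n = static_cast<double>(Y.n_elem);
  for (arma::uword i = 0; i < Y.n_elem; ++i) {
    double r = static_cast<double>(T(i)) - Y(i);
    double s = std::sqrt(1.0 + r * r / d2);
    loss += d2 * (s - 1.0);
    if (dY) (*dY)(i) = static_cast<float>(-r / s / n);
  }
  return loss / n;
}

struct Adagrad {
  std::vector<LayGrads> acc;
  float lr, eps;
  void init(const std::vector<Lay>& ls, const std::vector<LayParams>& ps,
            float lr_, float acc0, float eps_) {
    lr = lr_; eps = eps_;
    acc.resize(ps.size());
    for (size_t i = 0; i < ps.size(); ++i) {
      if (!ps[i].has_w) continue;
      acc[i].dW = fmat(arma::size(ps[i].W), arma::fill::value(acc0));
      acc[i].db = fvec(arma::size(ps[i].b), arma::fill::value(acc0));
      if (ps[i].has_bn) {
        acc[i].dgamma = fvec(arma::size(ps[i].gamma), arma::fill::value(acc0));
        acc[i].dbeta  = fvec(arma::size(ps[i].beta),  arma::fill::value(acc0));
      }
    }
  }
  void step(std::vector<LayParams>& ps, std::vector<LayGrads>& g) {
    for (size_t i = 0; i < ps.size(); ++i) {
      if (!ps[i].has_w) continue;
      acc[i].dW += arma::square(g[i].dW);
      ps[i].W -= lr * g[i].dW / (arma::sqrt(acc[i].dW) + eps);
      acc[i].db += arma::square(g[i].db);
      ps[i].b -= lr * g[i].db / (arma::sqrt(acc[i].db) + eps);
      if (ps[i].has_bn) {
        acc[i].dgamma += arma::square(g[i].dgamma);
        ps[i].gamma -= lr * g[i].dgamma / (arma::sqrt(acc[i].dgamma) + eps);
        acc[i].dbeta += arma::square(g[i].dbeta);
        ps[i].beta -= lr * g[i].dbeta / (arma::sqrt(acc[i].dbeta) + eps);
      }
    }
  }
};

static std::vector<LayGrads> zero_grads(const std::vector<Lay>& ls,
                                        const std::vector<LayParams>& ps) {
  std::vector<LayGrads> g(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    if (!ps[i].has_w) continue;
    g[i].dW = fmat(arma::size(ps[i].W), arma::fill::zeros);
    g[i].db = fvec(arma::size(ps[i].b), arma::fill::zeros);
    if (ps[i].has_bn) {
      g[i].dgamma = fvec(arma::size(ps[i].gamma), arma::fill::zeros);
      g[i].dbeta  = fvec(arma::size(ps[i].beta),  arma::fill::zeros);
    }
  }
  return g;
}

static void backward_all(const std::vector<Lay>& ls,
                         const std::vector<LayParams>& ps, const fcube& X,
                         const std::vector<LayCache>& caches, fcube dOut,
                         std::vector<LayGrads>& g, bool surrogate,
                         int stop_at = 0) {
  for (int i = static_cast<int>(ls.size()) - 1; i >= stop_at; --i) {
    const fcube& in = (i == 0) ? X : caches[i - 1].out;
    dOut = layer_backward(ls[i], ps[i], in, caches[i], std::move(dOut), g[i],
                          surrogate);
  }
}

static double eval_loss(const std::vector<Lay>& ls, std::vector<LayParams>& ps,
                        const fmat& X, float delta, int batch) {
  std::mt19937 rng(0);
  double total = 0.0;
  arma::uword n = X.n_cols;
  for (arma::uword lo = 0; lo < n; lo += batch) {
    arma::uword hi = std::min(n - 1, lo + batch - 1);
    fcube Xc = mat_to_cube(X.cols(lo, hi));
    std::vector<LayCache> caches;
    forward_all(ls, ps, Xc, caches, false, 0.0f, rng);
    total += ph_loss(caches.back().out, Xc, delta) * (hi - lo + 1);
  }
  return total / n;
}

// [[Rcpp::export]]
List cpp_bcae_train(List spec, List params, const arma::mat& Xtr,
                    const arma::mat& Xval, List cfg) {
  std::vector<Lay> ls = parse_spec(spec);
  std::vector<LayParams> ps = parse_params(params, ls);
  const float lr = as<double>(cfg["learning_rate"]);
  const int batch = as<int>(cfg["batch_size"]);
  const int epochs = as<int>(cfg["epochs"]);
  const float delta = as<double>(cfg["delta"]);
  const float drop_rate = as<double>(cfg["dropout_rate"]);
  const int seed = as<int>(cfg["seed"]);
  const bool keep_best = as<bool>(cfg["keep_best"]);

  fmat X = arma::conv_to<fmat>::from(Xtr);
  fmat Xv = arma::conv_to<fmat>::from(Xval);
  const arma::uword n = X.n_cols;
  std::mt19937 rng(static_cast<unsigned>(seed));
  Adagrad opt;
  opt.init(ls, ps, lr, 0.1f, 1e-7f);

  std::vector<double> tr_hist, val_hist;
  std::vector<LayParams> best = ps;
  double best_val = std::numeric_limits<double>::infinity();
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    for (arma::uword lo = 0; lo < n; lo += batch) {
      arma::uword hi = std::min(n - 1, lo + static_cast<arma::uword>(batch) - 1);
      arma::uword B = hi - lo + 1;
      fmat Xb(X.n_rows, B);
      for (arma::uword j = 0; j < B; ++j) Xb.col(j) = X.col(idx[lo + j]);
      fcube Xc = mat_to_cube(Xb);
      std::vector<LayCache> caches;
      forward_all(ls, ps, Xc, caches, true, drop_rate, rng);
      fcube dY;
      double loss = ph_loss(caches.back().out, Xc, delta, &dY);
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      ep_loss += loss * B;
      std::vector<LayGrads> g = zero_grads(ls, ps);
      backward_all(ls, ps, Xc, caches, std::move(dY), g, true);
      opt.step(ps, g);
    }
    tr_hist.push_back(ep_loss / n);
    double vl = Xv.n_cols > 0 ? eval_loss(ls, ps, Xv, delta, batch)
                              : ep_loss / n;
    val_hist.push_back(vl);
    if (vl < best_val) { best_val = vl; best = ps; }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    Named("params") = params_to_r(keep_best ? best : ps, ls),
    Named("final_params") = params_to_r(ps, ls),
    Named("train_loss") = tr_hist,
    Named("val_loss") = val_hist);
}

// [[Rcpp::export]]
List cpp_bcae_forward(List spec, List params, const arma::mat& X,
                      int code_layer) {
  std::vector<Lay> ls = parse_spec(spec);
  std::vector<LayParams> ps = parse_params(params, ls);
  fcube Xc = mat_to_cube(arma::conv_to<fmat>::from(X));
  std::mt19937 rng(0);
  std::vector<LayCache> caches;
  forward_all(ls, ps, Xc, caches, false, 0.0f, rng);
  const fcube& code = caches[code_layer - 1].out;
  const fcube& out = caches.back().out;
  arma::mat codem(code.n_rows, code.n_slices), outm(out.n_rows, out.n_slices);
  for (arma::uword b = 0; b < code.n_slices; ++b) {
    codem.col(b) = arma::conv_to<arma::vec>::from(code.slice(b).col(0));
    outm.col(b) = arma::conv_to<arma::vec>::from(out.slice(b).col(0));
  }
  return List::create(Named("code") = codem, Named("output") = outm);
}

// [[Rcpp::export]]
arma::mat cpp_bcae_run(List spec, List params, const arma::mat& X) {
  // run an arbitrary sub-stack (used for encode on layers 1..14 and
  // decode on layers 15..28); X columns are input vectors
  std::vector<Lay> ls = parse_spec(spec);
  std::vector<LayParams> ps = parse_params(params, ls);
  fcube Xc(ls[0].Lin, ls[0].cin, X.n_cols);
  fmat Xf = arma::conv_to<fmat>::from(X);
  for (arma::uword b = 0; b < X.n_cols; ++b)
    Xc.slice(b) = arma::reshape(Xf.col(b), ls[0].Lin, ls[0].cin);
  std::mt19937 rng(0);
  std::vector<LayCache> caches;
  forward_all(ls, ps, Xc, caches, false, 0.0f, rng);
  const fcube& out = caches.back().out;
  arma::mat outm(out.n_rows * out.n_cols, out.n_slices);
  for (arma::uword b = 0; b < out.n_slices; ++b)
    outm.col(b) = arma::conv_to<arma::vec>::from(arma::vectorise(out.slice(b)));
  return outm;
}

// [[Rcpp::export]]
double cpp_encoder_grad_norm(List spec, List params, const arma::mat& X,
                             bool surrogate) {
  std::vector<Lay> ls = parse_spec(spec);
  std::vector<LayParams> ps = parse_params(params, ls);
  fcube Xc = mat_to_cube(arma::conv_to<fmat>::from(X));
  std::mt19937 rng(1);
  std::vector<LayCache> caches;
  forward_all(ls, ps, Xc, caches, true, 0.0f, rng);
  fcube dY;
  ph_loss(caches.back().out, Xc, 0.9f, &dY);
  std::vector<LayGrads> g = zero_grads(ls, ps);
  backward_all(ls, ps, Xc, caches, std::move(dY), g, surrogate);
  // sum |dW| over encoder layers (everything before the BEL)
  double s = 0.0;
  for (size_t i = 0; i < ls.size(); ++i) {
    if (ls[i].kind == BEL) break;
    if (ps[i].has_w) s += arma::accu(arma::abs(g[i].dW));
  }
  return s;
}

// ----------------------------------------------------------------------------
// RECN: plain fully connected network, relu hidden layers, linear output.

static std::vector<fmat> recn_w(const List& params, std::vector<fvec>& bs) {
  std::vector<fmat> ws;
  for (int i = 0; i < params.size(); ++i) {
    List e = params[i];
    ws.push_back(arma::conv_to<fmat>::from(as<arma::mat>(e["W"])));
    bs.push_back(arma::conv_to<fvec>::from(as<arma::vec>(e["b"])));
  }
  return ws;
}

static fmat recn_fwd(const std::vector<fmat>& ws, const std::vector<fvec>& bs,
                     const fmat& X, std::vector<fmat>* acts = nullptr) {
  // X: (n_in x B); weights W_i: (in x out)
  fmat A = X;
  if (acts) acts->push_back(A);
  for (size_t i = 0; i < ws.size(); ++i) {
    A = ws[i].t() * A;
    A.each_col() += bs[i];
    if (i + 1 < ws.size())
      A = arma::clamp(A, 0.0f, arma::Datum<float>::inf);
    if (acts) acts->push_back(A);
  }
  return A;
}

// [[Rcpp::export]]
arma::mat cpp_recn_forward(List params, const arma::mat& X) {
  std::vector<fvec> bs;
  std::vector<fmat> ws = recn_w(params, bs);
  fmat Y = recn_fwd(ws, bs, arma::conv_to<fmat>::from(X));
  return arma::conv_to<arma::mat>::from(Y);
}

// [[Rcpp::export]]
List cpp_recn_train(List params, const arma::mat& Xtr, const arma::mat& Ttr,
                    const arma::mat& Xval, const arma::mat& Tval, List cfg) {
  std::vector<fvec> bs;
  std::vector<fmat> ws = recn_w(params, bs);
  const float lr = as<double>(cfg["learning_rate"]);
  const int batch = as<int>(cfg["batch_size"]);
  const int epochs = as<int>(cfg["epochs"]);
  const float delta = as<double>(cfg["delta"]);
  const int seed = as<int>(cfg["seed"]);
  const bool keep_best = as<bool>(cfg["keep_best"]);
  const double d2 = static_cast<double>(delta) * delta;

  fmat X = arma::conv_to<fmat>::from(Xtr), T = arma::conv_to<fmat>::from(Ttr);
  fmat Xv = arma::conv_to<fmat>::from(Xval), Tv = arma::conv_to<fmat>::from(Tval);
  const arma::uword n = X.n_cols;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<fmat> accW;
  std::vector<fvec> accB;
  for (size_t i = 0; i < ws.size(); ++i) {
    accW.push_back(fmat(arma::size(ws[i]), arma::fill::value(0.1f)));
    accB.push_back(fvec(arma::size(bs[i]), arma::fill::value(0.1f)));
  }
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> tr_hist, val_hist;
  std::vector<fmat> best_w = ws;
  std::vector<fvec> best_b = bs;
  double best_val = std::numeric_limits<double>::infinity();

  auto loss_of = [&](const fmat& Y, const fmat& Tgt, fmat* dY) {
    double loss = 0.0;
    if (dY) dY->set_size(arma::size(Y));
    const double nn = static_cast<double>(Y.n_elem);
    for (arma::uword i = 0; i < Y.n_elem; ++i) {
      double r = static_cast<double>(Tgt(i)) - Y(i);
      double s = std::sqrt(1.0 + r * r / d2);
      loss += d2 * (s - 1.0);
      if (dY) (*dY)(i) = static_cast<float>(-r / s / nn);
    }
    return loss / nn;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    for (arma::uword lo = 0; lo < n; lo += batch) {
      arma::uword hi = std::min(n - 1, lo + static_cast<arma::uword>(batch) - 1);
      arma::uword B = hi - lo + 1;
      fmat Xb(X.n_rows, B), Tb(T.n_rows, B);
      for (arma::uword j = 0; j < B; ++j) {
        Xb.col(j) = X.col(idx[lo + j]);
        Tb.col(j) = T.col(idx[lo + j]);
      }
      std::vector<fmat> acts;
      fmat Y = recn_fwd(ws, bs, Xb, &acts);
      fmat dY;
      double loss = loss_of(Y, Tb, &dY);
      if (!std::isfinite(loss))
        stop("RECN training diverged (non-finite loss) at epoch %d", ep + 1);
      ep_loss += loss * B;
      // backward
      fmat delta_l = dY;
      for (int i = static_cast<int>(ws.size()) - 1; i >= 0; --i) {
        const fmat& Ain = acts[i];
        fmat dW = Ain * delta_l.t();
        fvec db = arma::sum(delta_l, 1);
        if (i > 0) {
          fmat dA = ws[i] * delta_l;
          const fmat& Aout = acts[i];  // post-relu activation of layer i input
          for (arma::uword q = 0; q < dA.n_elem; ++q)
            if (Aout(q) <= 0.0f) dA(q) = 0.0f;
          delta_l = dA;
        }
        accW[i] += arma::square(dW);
        ws[i] -= lr * dW / (arma::sqrt(accW[i]) + 1e-7f);
        accB[i] += arma::square(db);
        bs[i] -= lr * db / (arma::sqrt(accB[i]) + 1e-7f);
      }
    }
    tr_hist.push_back(ep_loss / n);
    double vl = Xv.n_cols > 0 ? loss_of(recn_fwd(ws, bs, Xv), Tv, nullptr)
                              : ep_loss / n;
    val_hist.push_back(vl);
    if (vl < best_val) { best_val = vl; best_w = ws; best_b = bs; }
    Rcpp::checkUserInterrupt();
  }
  if (keep_best) { ws = best_w; bs = best_b; }
  List out(ws.size());
  for (size_t i = 0; i < ws.size(); ++i)
    out[i] = List::create(
      Named("W") = arma::conv_to<arma::mat>::from(ws[i]),
      Named("b") = arma::conv_to<arma::vec>::from(bs[i]));
  return List::create(Named("params") = out, Named("train_loss") = tr_hist,
                      Named("val_loss") = val_hist);
}
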