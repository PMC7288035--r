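// Minimal convolutional network used by the four-class topomap soft sensor.
// Layout conventions:
//   - an image is stored column-major with dim (H, W, C); a batch adds a 4th dim N
//   - im2col produces (H*W) x (C*K*K) so a convolution is one GEMM per image
//   - conv weights: (C*K*K) x F ; dense weights: (in) x (out)
// Double precision throughout; single-threaded and deterministic for a fixed seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static void im2col(const double* img, int H, int W, int C, int K, int pad,
                   mat& out /* (H*W) x (C*K*K) */) {
  for (int c = 0; c < C; ++c) {
    const double* ch = img + (size_t)c * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        int r = c * K * K + kw * K + kh;
        double* dst = out.colptr(r);
        for (int ow = 0; ow < W; ++ow) {
          int iw = ow + kw - pad;
          double* d = dst + (size_t)ow * H;
          if (iw < 0 || iw >= W) { std::fill(d, d + H, 0.0); continue; }
          const double* src = ch + (size_t)iw * H;
          int oh0 = std::max(0, pad - kh);
          int oh1 = std::min(H, H + pad - kh);
          if (oh0 > 0) std::fill(d, d + oh0, 0.0);
          if (oh1 < H) std::fill(d + oh1, d + H, 0.0);
          std::copy(src + oh0 + kh - pad, src + oh1 + kh - pad, d + oh0);
        }
      }
    }
  }
}

static void col2im(const mat& dcol, int H, int W, int C, int K, int pad, double* dimg) {
  std::fill(dimg, dimg + (size_t)H * W * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* ch = dimg + (size_t)c * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        int r = c * K * K + kw * K + kh;
        const double* s = dcol.colptr(r);
        for (int ow = 0; ow < W; ++ow) {
          int iw = ow + kw - pad;
          if (iw < 0 || iw >= W) continue;
          double* dst = ch + (size_t)iw * H;
          int oh0 = std::max(0, pad - kh);
          int oh1 = std::min(H, H + pad - kh);
          const double* ss = s + (size_t)ow * H;
          for (int oh = oh0; oh < oh1; ++oh) dst[oh + kh - pad] += ss[oh];
        }
      }
    }
  }
}

static void maxpool(const mat& in /* (H*W) x F */, int H, int W, int F, int P,
                    mat& out, umat& idx) {
  int H2 = H / P, W2 = W / P;
  for (int f = 0; f < F; ++f) {
    const double* ch = in.colptr(f);
    double* o = out.colptr(f);
    uword* ix = idx.colptr(f);
    for (int ow = 0; ow < W2; ++ow) {
      for (int oh = 0; oh < H2; ++oh) {
        double best = -datum::inf; uword bi = 0;
        for (int pw = 0; pw < P; ++pw) {
          for (int ph = 0; ph < P; ++ph) {
            uword j = (uword)(ow * P + pw) * H + (oh * P + ph);
            if (ch[j] > best) { best = ch[j]; bi = j; }
          }
        }
        o[(size_t)ow * H2 + oh] = best;
        ix[(size_t)ow * H2 + oh] = bi;
      }
    }
  }
}

struct NetDims {
  int K, P, C0, nblocks, dense, nclass;
  std::vector<int> F, Hs, Ws;  // Hs[i], Ws[i]: input size of block i; Hs[n]: final
  int flat;
};

static NetDims make_dims(int H, int W, int C, const IntegerVector& filters,
                         int K, int P, int dense, int nclass) {
  NetDims d;
  d.K = K; d.P = P; d.C0 = C; d.nblocks = filters.size();
  d.dense = dense; d.nclass = nclass;
  d.Hs.push_back(H); d.Ws.push_back(W);
  for (int i = 0; i < d.nblocks; ++i) {
    d.F.push_back(filters[i]);
    int h = d.Hs.back() / P, w = d.Ws.back() / P;
    if (h < 1 || w < 1) stop("image collapses to zero size at block %d", i + 1);
    d.Hs.push_back(h); d.Ws.push_back(w);
  }
  d.flat = d.Hs.back() * d.Ws.back() * d.F.back();
  return d;
}

// [[Rcpp::export]]
List cpp_cnn_init(int H, int W, int C, IntegerVector filters, int K, int P,
                  int dense, int nclass, int seed) {
  NetDims d = make_dims(H, W, C, filters, K, P, dense, nclass);
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  List Wc(d.nblocks), bc(d.nblocks);
  int cin = C;
  for (int i = 0; i < d.nblocks; ++i) {
    int fan_in = cin * K * K;
    mat w(fan_in, d.F[i]);
    double sd = std::sqrt(2.0 / fan_in);
    for (uword j = 0; j < w.n_elem; ++j) w(j) = sd * gauss(rng);
    Wc[i] = w;
    bc[i] = rowvec(d.F[i], fill::zeros);
    cin = d.F[i];
  }
  mat W1(d.flat, dense);
  double sd1 = std::sqrt(2.0 / d.flat);
  for (uword j = 0; j < W1.n_elem; ++j) W1(j) = sd1 * gauss(rng);
  mat W2(dense, nclass);
  double sd2 = std::sqrt(2.0 / dense);
  for (uword j = 0; j < W2.n_elem; ++j) W2(j) = sd2 * gauss(rng);
  return List::create(_["Wc"] = Wc, _["bc"] = bc,
                      _["W1"] = W1, _["b1"] = rowvec(dense, fill::zeros),
                      _["W2"] = W2, _["b2"] = rowvec(nclass, fill::zeros));
}

struct Net {
  NetDims d;
  std::vector<mat> Wc; std::vector<rowvec> bc;
  mat W1; rowvec b1; mat W2; rowvec b2;
  void load(const List& w, const NetDims& dims) {
    d = dims;
    List lw = w["Wc"], lb = w["bc"];
    Wc.clear(); bc.clear();
    for (int i = 0; i < d.nblocks; ++i) {
      Wc.push_back(as<mat>(lw[i]));
      bc.push_back(as<rowvec>(lb[i]));
    }
    W1 = as<mat>(w["W1"]); b1 = as<rowvec>(w["b1"]);
    W2 = as<mat>(w["W2"]); b2 = as<rowvec>(w["b2"]);
  }
  List dump() const {
    List lw(d.nblocks), lb(d.nblocks);
    for (int i = 0; i < d.nblocks; ++i) { lw[i] = Wc[i]; lb[i] = bc[i]; }
    return List::create(_["Wc"] = lw, _["bc"] = lb, _["W1"] = W1, _["b1"] = b1,
                        _["W2"] = W2, _["b2"] = b2);
  }
};

// per-image forward cache (training)
struct Cache {
  std::vector<mat> col;    // im2col input of each block
  std::vector<mat> act;    // relu output of each block (pre-pool)
  std::vector<mat> pooled; // pooled output of each block
  std::vector<umat> pidx;
  rowvec x, h_pre, h;      // flatten, dense pre-relu, dense post-dropout
  rowvec p;                // class probabilities
};

static void forward_one(const Net& net, const double* img, Cache& cc, bool train,
                        double dropout, std::mt19937_64* rng, rowvec* dropmask) {
  const NetDims& d = net.d;
  int nb = d.nblocks;
  cc.col.resize(nb); cc.act.resize(nb); cc.pooled.resize(nb); cc.pidx.resize(nb);
  int pad = (d.K - 1) / 2;
  const double* cur = img;
  int cin = d.C0;
  std::vector<double> buf;
  for (int i = 0; i < nb; ++i) {
    int H = d.Hs[i], W = d.Ws[i];
    cc.col[i].set_size((size_t)H * W, (size_t)cin * d.K * d.K);
    im2col(cur, H, W, cin, d.K, pad, cc.col[i]);
    cc.act[i] = cc.col[i] * net.Wc[i];
    cc.act[i].each_row() += net.bc[i];
    cc.act[i].transform([](double v) { return v > 0 ? v : 0.0; });
    int H2 = d.Hs[i + 1], W2 = d.Ws[i + 1];
    cc.pooled[i].set_size((size_t)H2 * W2, d.F[i]);
    cc.pidx[i].set_size((size_t)H2 * W2, d.F[i]);
    maxpool(cc.act[i], H, W, d.F[i], d.P, cc.pooled[i], cc.pidx[i]);
    cur = cc.pooled[i].memptr();
    cin = d.F[i];
  }
  cc.x = rowvec(cc.pooled[nb - 1].memptr(), d.flat);  // copy
  cc.h_pre = cc.x * net.W1 + net.b1;
  cc.h = cc.h_pre;
  cc.h.transform([](double v) { return v > 0 ? v : 0.0; });
  if (train && dropout > 0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    dropmask->set_size(d.dense);
    double keep = 1.0 - dropout;
    for (int j = 0; j < d.dense; ++j)
      (*dropmask)(j) = (unif(*rng) < keep) ? 1.0 / keep : 0.0;
    cc.h %= *dropmask;
  }
  rowvec z = cc.h * net.W2 + net.b2;
  z -= z.max();
  cc.p = exp(z);
  cc.p /= accu(cc.p);
}

struct Grads {
  std::vector<mat> Wc; std::vector<rowvec> bc;
  mat W1; rowvec b1; mat W2; rowvec b2;
  void zero_like(const Net& n) {
    Wc.clear(); bc.clear();
    for (int i = 0; i < n.d.nblocks; ++i) {
      Wc.push_back(mat(n.Wc[i].n_rows, n.Wc[i].n_cols, fill::zeros));
      bc.push_back(rowvec(n.bc[i].n_elem, fill::zeros));
    }
    W1 = mat(n.W1.n_rows, n.W1.n_cols, fill::zeros); b1 = rowvec(n.b1.n_elem, fill::zeros);
    W2 = mat(n.W2.n_rows, n.W2.n_cols, fill::zeros); b2 = rowvec(n.b2.n_elem, fill::zeros);
  }
};

static void backward_one(const Net& net, const Cache& cc, int y, double scale,
                         const rowvec& dropmask, bool use_drop, Grads& g) {
  const NetDims& d = net.d;
  int nb = d.nblocks, pad = (d.K - 1) / 2;
  rowvec dz = cc.p * scale;
  dz(y) -= scale;
  g.W2 += cc.h.t() * dz;
  g.b2 += dz;
  rowvec dh = dz * net.W2.t();
  if (use_drop) dh %= dropmask;
  for (uword j = 0; j < dh.n_elem; ++j) if (cc.h_pre(j) <= 0) dh(j) = 0;
  g.W1 += cc.x.t() * dh;
  g.b1 += dh;
  rowvec dx = dh * net.W1.t();
  // reshape flat gradient into pooled map of last block, then walk blocks backwards
  mat dpool(const_cast<double*>(dx.memptr()),
            (size_t)d.Hs[nb] * d.Ws[nb], d.F[nb - 1], true);
  for (int i = nb - 1; i >= 0; --i) {
    // unpool into relu-activation shape
    mat dact((size_t)d.Hs[i] * d.Ws[i], d.F[i], fill::zeros);
    for (int f = 0; f < d.F[i]; ++f) {
      const uword* ix = cc.pidx[i].colptr(f);
      const double* dp = dpool.colptr(f);
      double* da = dact.colptr(f);
      for (uword j = 0; j < dpool.n_rows; ++j) da[ix[j]] += dp[j];
    }
    // relu gate
    dact.elem(find(cc.act[i] == 0)).zeros();
    g.Wc[i] += cc.col[i].t() * dact;
    g.bc[i] += sum(dact, 0);
    if (i > 0) {
      mat dcol = dact * net.Wc[i].t();
      mat dimg((size_t)d.Hs[i] * d.Ws[i], d.F[i - 1], fill::none);
      col2im(dcol, d.Hs[i], d.Ws[i], d.F[i - 1], d.K, pad, dimg.memptr());
      dpool = dimg;
    }
  }
}

struct Adam {
  std::vector<mat> mWc, vWc; std::vector<rowvec> mbc, vbc;
  mat mW1, vW1, mW2, vW2; rowvec mb1, vb1, mb2, vb2;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Net& n) {
    for (int i = 0; i < n.d.nblocks; ++i) {
      mWc.push_back(mat(n.Wc[i].n_rows, n.Wc[i].n_cols, fill::zeros));
      vWc.push_back(mat(n.Wc[i].n_rows, n.Wc[i].n_cols, fill::zeros));
      mbc.push_back(rowvec(n.bc[i].n_elem, fill::zeros));
      vbc.push_back(rowvec(n.bc[i].n_elem, fill::zeros));
    }
    mW1 = vW1 = mat(n.W1.n_rows, n.W1.n_cols, fill::zeros);
    mW2 = vW2 = mat(n.W2.n_rows, n.W2.n_cols, fill::zeros);
    mb1 = vb1 = rowvec(n.b1.n_elem, fill::zeros);
    mb2 = vb2 = rowvec(n.b2.n_elem, fill::zeros);
  }
  template <class M>
  void upd(M& w, M& m, M& v, const M& g, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
  void step(Net& n, const Grads& g, double lr) {
    ++t;
    for (int i = 0; i < n.d.nblocks; ++i) {
      upd(n.Wc[i], mWc[i], vWc[i], g.Wc[i], lr);
      upd(n.bc[i], mbc[i], vbc[i], g.bc[i], lr);
    }
    upd(n.W1, mW1, vW1, g.W1, lr);
    upd(n.b1, mb1, vb1, g.b1, lr);
    upd(n.W2, mW2, vW2, g.W2, lr);
    upd(n.b2, mb2, vb2, g.b2, lr);
  }
};

static void eval_set(const Net& net, const double* X, const IntegerVector& y, int n,
                     size_t imsz, double& loss, double& acc) {
  Cache cc; rowvec dummy;
  double L = 0; int ok = 0;
  std::mt19937_64 norng;
  for (int i = 0; i < n; ++i) {
    forward_one(net, X + (size_t)i * imsz, cc, false, 0.0, &norng, &dummy);
    double py = std::max(cc.p(y[i]), 1e-12);
    L += -std::log(py);
    if ((int)cc.p.index_max() == y[i]) ++ok;
  }
  loss = L / n;
  acc = (double)ok / n;
}

// [[Rcpp::export]]
List cpp_cnn_train(NumericVector X, IntegerVector y,
                   NumericVector Xval, IntegerVector yval,
                   List weights, IntegerVector filters, int K, int P, int dense,
                   int nclass, int epochs, int batch, double lr, double dropout,
                   int patience, int seed, bool verbose) {
  IntegerVector dm = X.attr("dim");
  if (dm.size() != 4) stop("images must be a (H, W, C, N) array");
  int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  IntegerVector dmv = Xval.attr("dim");
  int Nv = dmv[3];
  NetDims d = make_dims(H, W, C, filters, K, P, dense, nclass);
  Net net; net.load(weights, d);
  Adam opt; opt.init(net);
  size_t imsz = (size_t)H * W * C;
  std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 13);
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  std::vector<double> trl, tra, vll, vla;
  double best_vl = datum::inf; int best_ep = -1, bad = 0;
  List best = net.dump();
  Cache cc; Grads g; rowvec dropmask;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(ord.begin(), ord.end(), rng);
    double L = 0; int ok = 0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      int bn = std::min(batch, N - b0);
      g.zero_like(net);
      for (int k = 0; k < bn; ++k) {
        int i = ord[b0 + k];
        forward_one(net, X.begin() + (size_t)i * imsz, cc, true, dropout, &rng, &dropmask);
        double py = std::max(cc.p(y[i]), 1e-12);
        L += -std::log(py);
        if ((int)cc.p.index_max() == y[i]) ++ok;
        backward_one(net, cc, y[i], 1.0 / bn, dropmask, dropout > 0, g);
      }
      opt.step(net, g, lr);
      if ((b0 / batch) % 16 == 0) Rcpp::checkUserInterrupt();
    }
    double vl, va;
    eval_set(net, Xval.begin(), yval, Nv, imsz, vl, va);
    trl.push_back(L / N); tra.push_back((double)ok / N);
    vll.push_back(vl); vla.push_back(va);
    if (verbose)
      Rprintf("epoch %d: loss %.4f acc %.4f | val loss %.4f acc %.4f\n",
              ep + 1, L / N, (double)ok / N, vl, va);
    if (vl < best_vl) { best_vl = vl; best_ep = ep; best = net.dump(); bad = 0; }
    else if (++bad >= patience) break;
  }
  return List::create(
      _["weights"] = best,
      _["history"] = DataFrame::create(_["epoch"] = seq_len(trl.size()),
                                       _["train_loss"] = trl, _["train_acc"] = tra,
                                       _["val_loss"] = vll, _["val_acc"] = vla),
      _["best_epoch"] = best_ep + 1);
}

// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(NumericVector X, List weights, IntegerVector filters,
                              int K, int P, int dense, int nclass) {
  IntegerVector dm = X.attr("dim");
  if (dm.size() != 4) stop("images must be a (H, W, C, N) array");
  int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  NetDims d = make_dims(H, W, C, filters, K, P, dense, nclass);
  Net net; net.load(weights, d);
  size_t imsz = (size_t)H * W * C;
  NumericMatrix out(N, nclass);
  Cache cc; rowvec dummy;
  std::mt19937_64 norng;
  for (int i = 0; i < N; ++i) {
    forward_one(net, X.begin() + (size_t)i * imsz, cc, false, 0.0, &norng, &dummy);
    for (int k = 0; k < nclass; ++k) out(i, k) = cc.p(k);
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
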