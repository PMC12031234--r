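// Deep Image Prior encoder-decoder with skip connections, fitted to a single
// noisy slice by Adam on the MSE objective  argmin_theta ||f_theta(z) - Y||^2
// with a fixed random input z. No deep-learning framework is available in
// the target environment, so convolutions (im2col + GEMM), nearest-neighbour
// upsampling and backpropagation are implemented directly here.
//
// Layout convention: a feature map is an arma::mat of size (channels, H*W)
// with spatial index p = i + j*H (column-major, matching R matrices).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline int reflc(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// One conv block: conv (im2col + GEMM) -> optional per-channel instance
// normalization with learnable scale/shift -> optional leaky ReLU.
// Normalization is what keeps a randomly initialized net trainable at
// DIP's customary step size; without it the sigmoid head saturates.
struct Conv {
  int Cin = 0, Cout = 0, k = 1, stride = 1;
  int Hin = 0, Win = 0, Hout = 0, Wout = 0;
  bool act = true;   // leaky ReLU (slope 0.1)
  bool norm = true;  // instance norm between conv and activation
  mat W; vec b, gamma, beta;
  mat col, pre, xhat;
  vec istd;
  mat gW; vec gb, ggamma, gbeta;
  mat mW, vW; vec mb, vb, mg, vg, mbt, vbt;
  std::vector<int> smap;  // (tap, outpix) -> input spatial index
  static constexpr double NEPS = 1e-5;

  void setup(int cin, int cout, int kk, int st, bool a, bool nrm,
             int hin, int win, const mat& W_, const vec& b_,
             const vec& g_ = vec(), const vec& bt_ = vec()) {
    Cin = cin; Cout = cout; k = kk; stride = st; act = a; norm = nrm;
    Hin = hin; Win = win; Hout = hin / st; Wout = win / st;
    W = W_; b = b_;
    if ((int)W.n_rows != Cout || (int)W.n_cols != Cin * k * k)
      stop("conv weight shape mismatch");
    mW.zeros(W.n_rows, W.n_cols); vW.zeros(W.n_rows, W.n_cols);
    mb.zeros(b.n_elem); vb.zeros(b.n_elem);
    if (norm) {
      gamma = g_; beta = bt_;
      if ((int)gamma.n_elem != Cout || (int)beta.n_elem != Cout)
        stop("norm parameter shape mismatch");
      mg.zeros(Cout); vg.zeros(Cout); mbt.zeros(Cout); vbt.zeros(Cout);
    }
    int r = k / 2, np = Hout * Wout;
    smap.resize(k * k * np);
    for (int t = 0, dj = -r; dj <= r; ++dj)
      for (int di = -r; di <= r; ++di, ++t)
        for (int jo = 0; jo < Wout; ++jo)
          for (int io = 0; io < Hout; ++io) {
            int p = io + jo * Hout;
            int ii = reflc(io * stride + di, Hin);
            int jj = reflc(jo * stride + dj, Win);
            smap[t * np + p] = ii + jj * Hin;
          }
  }

  mat forward(const mat& x) {
    int k2 = k * k, np = Hout * Wout;
    col.set_size(Cin * k2, np);
    for (int p = 0; p < np; ++p) {
      double* cp = col.colptr(p);
      for (int t = 0; t < k2; ++t) {
        const double* xp = x.colptr(smap[t * np + p]);
        for (int c = 0; c < Cin; ++c) cp[c * k2 + t] = xp[c];
      }
    }
    mat lin = W * col;
    lin.each_col() += b;
    if (norm) {
      vec mu = arma::mean(lin, 1);
      vec va = arma::var(lin, 1, 1);  // population variance per channel
      istd = 1.0 / arma::sqrt(va + NEPS);
      xhat = lin;
      xhat.each_col() -= mu;
      xhat.each_col() %= istd;
      pre = xhat;
      pre.each_col() %= gamma;
      pre.each_col() += beta;
    } else {
      pre = lin;
    }
    mat out = pre;
    if (act)
      for (double* v = out.memptr(); v != out.memptr() + out.n_elem; ++v)
        if (*v < 0) *v *= 0.1;
    return out;
  }

  mat backward(const mat& dy) {
    mat d = dy;
    if (act) {
      const double* pp = pre.memptr();
      for (double* v = d.memptr(); v != d.memptr() + d.n_elem; ++v, ++pp)
        if (*pp < 0) *v *= 0.1;
    }
    if (norm) {
      ggamma = arma::sum(d % xhat, 1);
      gbeta = arma::sum(d, 1);
      mat dxh = d;
      dxh.each_col() %= gamma;
      vec m1 = arma::mean(dxh, 1);
      vec m2 = arma::mean(dxh % xhat, 1);
      dxh.each_col() -= m1;
      dxh -= xhat.each_col() % m2;
      dxh.each_col() %= istd;
      d = dxh;
    }
    gW = d * col.t();
    gb = arma::sum(d, 1);
    mat dcol = W.t() * d;
    mat dx(Cin, Hin * Win, arma::fill::zeros);
    int k2 = k * k, np = Hout * Wout;
    for (int p = 0; p < np; ++p) {
      const double* cp = dcol.colptr(p);
      for (int t = 0; t < k2; ++t) {
        double* xp = dx.colptr(smap[t * np + p]);
        for (int c = 0; c < Cin; ++c) xp[c] += cp[c * k2 + t];
      }
    }
    return dx;
  }

  static void adam1(mat& w, mat& m, mat& v, const mat& g, double lr,
                    double b1, double b2, double eps, int t) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
  static void adam1v(vec& w, vec& m, vec& v, const vec& g, double lr,
                     double b1, double b2, double eps, int t) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }

  void adam(double lr, double b1, double b2, double eps, int t) {
    adam1(W, mW, vW, gW, lr, b1, b2, eps, t);
    adam1v(b, mb, vb, gb, lr, b1, b2, eps, t);
    if (norm) {
      adam1v(gamma, mg, vg, ggamma, lr, b1, b2, eps, t);
      adam1v(beta, mbt, vbt, gbeta, lr, b1, b2, eps, t);
    }
  }
};

static mat up2(const mat& x, int H, int Wd) {
  int Ho = 2 * H, Wo = 2 * Wd;
  mat out(x.n_rows, Ho * Wo);
  for (int j = 0; j < Wd; ++j)
    for (int i = 0; i < H; ++i) {
      int s = i + j * H;
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          out.col((2 * i + di) + (2 * j + dj) * Ho) = x.col(s);
    }
  return out;
}

static mat down2sum(const mat& g, int Ho, int Wo) {
  int H = Ho / 2, Wd = Wo / 2;
  mat out(g.n_rows, H * Wd, arma::fill::zeros);
  for (int j = 0; j < Wd; ++j)
    for (int i = 0; i < H; ++i) {
      int s = i + j * H;
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          out.col(s) += g.col((2 * i + di) + (2 * j + dj) * Ho);
    }
  return out;
}

struct Net {
  int D, C, S, Zc, H, W;
  std::vector<Conv> encA, encB, skp, decA, decB;
  Conv outc;
  std::vector<mat> e, s;  // encoder and skip activations
  mat yhat;

  Net(int depth, int base, int skip, int zc, int h, int w, List weights)
      : D(depth), C(base), S(skip), Zc(zc), H(h), W(w),
        encA(depth), encB(depth), skp(depth > 1 ? depth - 1 : 0),
        decA(depth), decB(depth), e(depth), s(depth) {
    int idx = 0;
    auto nextW = [&]() { return as<mat>(weights[idx++]); };
    auto nextb = [&]() { return as<vec>(weights[idx++]); };
    auto norm_conv = [&](Conv& cv, int cin, int cout, int kk, int st,
                         int hin, int win) {
      mat w = nextW(); vec bb = nextb();
      vec g = nextb(); vec bt = nextb();
      cv.setup(cin, cout, kk, st, true, true, hin, win, w, bb, g, bt);
    };
    for (int l = 0; l < D; ++l) {
      int hin = H >> l, win = W >> l;
      norm_conv(encA[l], (l == 0) ? Zc : C, C, 3, 2, hin, win);
      norm_conv(encB[l], C, C, 3, 1, hin / 2, win / 2);
      if (l < D - 1)  // the deepest level feeds the decoder directly
        norm_conv(skp[l], C, S, 1, 1, hin / 2, win / 2);
    }
    for (int j = 0; j < D; ++j) {
      int L = D - j - 1;  // resolution level produced by this step
      int hl = H >> L, wl = W >> L;
      norm_conv(decA[j], C + (L >= 1 ? S : 0), C, 3, 1, hl, wl);
      norm_conv(decB[j], C, C, 3, 1, hl, wl);
    }
    mat wo = nextW(); vec bo = nextb();
    outc.setup(C, 1, 1, 1, false, false, H, W, wo, bo);
  }

  const mat& forward(const mat& z) {
    mat x = z;
    for (int l = 0; l < D; ++l) {
      x = encB[l].forward(encA[l].forward(x));
      e[l] = x;
      if (l < D - 1) s[l] = skp[l].forward(x);
    }
    mat d = e[D - 1];
    for (int j = 0; j < D; ++j) {
      int L = D - j - 1;
      mat u = up2(d, H >> (L + 1), W >> (L + 1));
      mat xin = (L >= 1) ? arma::join_cols(s[L - 1], u) : u;
      d = decB[j].forward(decA[j].forward(xin));
    }
    mat o = outc.forward(d);
    yhat = 1.0 / (1.0 + arma::exp(-o));
    return yhat;
  }

  void backward(const mat& target) {
    int N = H * W;
    mat dpre = (2.0 / N) * (yhat - target) % yhat % (1.0 - yhat);
    mat dd = outc.backward(dpre);
    std::vector<mat> ge(D);
    for (int j = D - 1; j >= 0; --j) {
      int L = D - j - 1;
      mat dx = decA[j].backward(decB[j].backward(dd));
      mat du;
      if (L >= 1) {
        mat ds = dx.rows(0, S - 1);
        du = dx.rows(S, S + C - 1);
        mat gsk = skp[L - 1].backward(ds);
        if (ge[L - 1].n_elem) ge[L - 1] += gsk; else ge[L - 1] = gsk;
      } else du = dx;
      dd = down2sum(du, H >> L, W >> L);
    }
    if (ge[D - 1].n_elem) ge[D - 1] += dd; else ge[D - 1] = dd;
    for (int l = D - 1; l >= 0; --l) {
      mat g = encA[l].backward(encB[l].backward(ge[l]));
      if (l >= 1) {
        if (ge[l - 1].n_elem) ge[l - 1] += g; else ge[l - 1] = g;
      }
    }
  }

  void step(double lr, double b1, double b2, double eps, int t) {
    for (int l = 0; l < D; ++l) {
      encA[l].adam(lr, b1, b2, eps, t);
      encB[l].adam(lr, b1, b2, eps, t);
      if (l < D - 1) skp[l].adam(lr, b1, b2, eps, t);
      decA[l].adam(lr, b1, b2, eps, t);
      decB[l].adam(lr, b1, b2, eps, t);
    }
    outc.adam(lr, b1, b2, eps, t);
  }
};

// Forward pass of an untrained (or externally supplied) network.
// [[Rcpp::export]]
arma::rowvec dip_forward_cpp(const arma::mat& z, int H, int W, List weights,
                             List cfg) {
  Net net(as<int>(cfg["depth"]), as<int>(cfg["base_channels"]),
          as<int>(cfg["skip_channels"]), z.n_rows, H, W, weights);
  return net.forward(z).row(0);
}

// Full DIP optimization with smoothed-loss early stopping. The output kept
// is the one at the argmin of the moving-average loss, snapshotted online.
// [[Rcpp::export]]
List dip_fit_cpp(const arma::rowvec& target, int H, int W, const arma::mat& z,
                 List weights, List cfg) {
  Net net(as<int>(cfg["depth"]), as<int>(cfg["base_channels"]),
          as<int>(cfg["skip_channels"]), z.n_rows, H, W, weights);
  int iters = as<int>(cfg["iterations_max"]);
  double lr = as<double>(cfg["learning_rate"]);
  int window = as<int>(cfg["window"]);
  double min_delta = as<double>(cfg["min_delta"]);
  int patience = as<int>(cfg["patience"]);
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  mat tgt(1, H * W);
  tgt.row(0) = target;
  std::vector<double> trace; trace.reserve(iters);
  std::vector<double> smooth; smooth.reserve(iters);
  double runsum = 0, best = R_PosInf;
  int keep = 1, ran = 0, plateau = 0;
  bool stopped = false;
  arma::rowvec snapshot;

  for (int t = 1; t <= iters; ++t) {
    const mat& y = net.forward(z);
    double loss = arma::accu(arma::square(y - tgt)) / (H * W);
    if (!std::isfinite(loss))
      stop("DIP loss became non-finite at iteration %d", t);
    trace.push_back(loss);
    runsum += loss;
    if (t > window) runsum -= trace[t - window - 1];
    double sm = (t >= window) ? runsum / window : NA_REAL;
    smooth.push_back(sm);
    if (t >= window && sm < best) {
      best = sm;
      keep = t;
      snapshot = y.row(0);
    }
    ran = t;
    if (t >= 2 * window) {
      double impr = smooth[t - window - 1] - sm;
      plateau = (impr < min_delta) ? plateau + 1 : 0;
      if (plateau >= patience) { stopped = true; break; }
    }
    if (t < iters) {
      net.backward(tgt);
      net.step(lr, b1, b2, eps, t);
    }
  }
  if (!snapshot.n_elem) snapshot = net.yhat.row(0);  // iters < window
  return List::create(
      _["output"] = snapshot,
      _["loss_trace"] = trace,
      _["smoothed"] = smooth,
      _["keep_iteration"] = keep,
      _["stop_iteration"] = ran,
      _["stopped_early"] = stopped);
}
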