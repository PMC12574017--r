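// Convolutional-LSTM continuous decoder: feature-axis convolutions with
// batch normalization and ReLU, one LSTM layer over the window's time axis,
// fully connected layers, and a linear kinematic output. Trained with
// stochastic gradient descent (with momentum) on mean squared error, with
// patience-based early stopping on a validation set.
//
// Implemented from scratch (forward + analytic backprop); correctness of the
// gradients is asserted against numerical differentiation in the test suite.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

struct Cfg {
  int p, d, L;          // features, output DOFs, window length (frames)
  int F1, k1, s1;       // conv1 filters, kernel, stride (feature axis)
  int F2, k2, s2;       // conv2 filters, kernel, stride
  int h;                // LSTM hidden units
  std::vector<int> fc;  // fully connected layer sizes
  double lr, momentum, eps, bn_momentum;
  int batch;
  int P1, P2, m;        // derived: conv output positions, LSTM input size
};

static Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.p = as<int>(cfg["p"]); c.d = as<int>(cfg["d"]); c.L = as<int>(cfg["window_len"]);
  c.F1 = as<int>(cfg["conv1_filters"]); c.k1 = as<int>(cfg["conv1_kernel"]);
  c.s1 = as<int>(cfg["conv1_stride"]);
  c.F2 = as<int>(cfg["conv2_filters"]); c.k2 = as<int>(cfg["conv2_kernel"]);
  c.s2 = as<int>(cfg["conv2_stride"]);
  c.h = as<int>(cfg["lstm_hidden"]);
  c.fc = as<std::vector<int>>(cfg["fc_sizes"]);
  c.lr = as<double>(cfg["lr"]); c.momentum = as<double>(cfg["momentum"]);
  c.eps = as<double>(cfg["bn_eps"]); c.bn_momentum = as<double>(cfg["bn_momentum"]);
  c.batch = as<int>(cfg["batch_size"]);
  if (c.k1 > c.p) stop("conv1 kernel (%d) larger than the feature axis (%d)", c.k1, c.p);
  c.P1 = (c.p - c.k1) / c.s1 + 1;
  if (c.k2 > c.P1) stop("conv2 kernel (%d) larger than its input axis (%d)", c.k2, c.P1);
  c.P2 = (c.P1 - c.k2) / c.s2 + 1;
  c.m = c.P2 * c.F2;
  return c;
}

struct Net {
  mat W1; rowvec b1, g1, be1, rm1, rv1;
  mat W2; rowvec b2, g2, be2, rm2, rv2;
  mat Wx, Wh; rowvec bl;
  std::vector<mat> fcW; std::vector<rowvec> fcb;
  mat Wo; rowvec bo;
};

static Net net_from_list(const List& par) {
  Net n;
  n.W1 = as<mat>(par["W1"]); n.b1 = as<rowvec>(par["b1"]);
  n.g1 = as<rowvec>(par["g1"]); n.be1 = as<rowvec>(par["be1"]);
  n.rm1 = as<rowvec>(par["rm1"]); n.rv1 = as<rowvec>(par["rv1"]);
  n.W2 = as<mat>(par["W2"]); n.b2 = as<rowvec>(par["b2"]);
  n.g2 = as<rowvec>(par["g2"]); n.be2 = as<rowvec>(par["be2"]);
  n.rm2 = as<rowvec>(par["rm2"]); n.rv2 = as<rowvec>(par["rv2"]);
  n.Wx = as<mat>(par["Wx"]); n.Wh = as<mat>(par["Wh"]); n.bl = as<rowvec>(par["bl"]);
  List fw = par["fcW"], fb = par["fcb"];
  for (int i = 0; i < fw.size(); ++i) {
    n.fcW.push_back(as<mat>(fw[i]));
    n.fcb.push_back(as<rowvec>(fb[i]));
  }
  n.Wo = as<mat>(par["Wo"]); n.bo = as<rowvec>(par["bo"]);
  return n;
}

static List net_to_list(const Net& n) {
  List fw(n.fcW.size()), fb(n.fcb.size());
  for (size_t i = 0; i < n.fcW.size(); ++i) { fw[i] = n.fcW[i]; fb[i] = n.fcb[i]; }
  return List::create(
    _["W1"] = n.W1, _["b1"] = n.b1, _["g1"] = n.g1, _["be1"] = n.be1,
    _["rm1"] = n.rm1, _["rv1"] = n.rv1,
    _["W2"] = n.W2, _["b2"] = n.b2, _["g2"] = n.g2, _["be2"] = n.be2,
    _["rm2"] = n.rm2, _["rv2"] = n.rv2,
    _["Wx"] = n.Wx, _["Wh"] = n.Wh, _["bl"] = n.bl,
    _["fcW"] = fw, _["fcb"] = fb, _["Wo"] = n.Wo, _["bo"] = n.bo);
}

// [[Rcpp::export]]
List cpp_clstm_init(List cfg, int seed) {
  Cfg c = read_cfg(cfg);
  std::mt19937 rng((unsigned)seed);
  auto gauss = [&](int nr, int nc, double sd) {
    std::normal_distribution<double> N(0.0, sd);
    mat M(nr, nc);
    for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) M(i, j) = N(rng);
    return M;
  };
  Net n;
  n.W1 = gauss(c.k1, c.F1, std::sqrt(2.0 / c.k1));
  n.b1 = rowvec(c.F1, arma::fill::zeros);
  n.g1 = rowvec(c.F1, arma::fill::ones);  n.be1 = rowvec(c.F1, arma::fill::zeros);
  n.rm1 = rowvec(c.F1, arma::fill::zeros); n.rv1 = rowvec(c.F1, arma::fill::ones);
  n.W2 = gauss(c.k2 * c.F1, c.F2, std::sqrt(2.0 / (c.k2 * c.F1)));
  n.b2 = rowvec(c.F2, arma::fill::zeros);
  n.g2 = rowvec(c.F2, arma::fill::ones);  n.be2 = rowvec(c.F2, arma::fill::zeros);
  n.rm2 = rowvec(c.F2, arma::fill::zeros); n.rv2 = rowvec(c.F2, arma::fill::ones);
  n.Wx = gauss(4 * c.h, c.m, 1.0 / std::sqrt((double)c.m));
  n.Wh = gauss(4 * c.h, c.h, 1.0 / std::sqrt((double)c.h));
  n.bl = rowvec(4 * c.h, arma::fill::zeros);
  n.bl.subvec(c.h, 2 * c.h - 1).fill(1.0);  // forget-gate bias
  int prev = c.h;
  for (int s : c.fc) {
    n.fcW.push_back(gauss(s, prev, std::sqrt(2.0 / prev)));
    n.fcb.push_back(rowvec(s, arma::fill::zeros));
    prev = s;
  }
  n.Wo = gauss(c.d, prev, 1.0 / std::sqrt((double)prev));
  n.bo = rowvec(c.d, arma::fill::zeros);
  return net_to_list(n);
}

// Cached forward-pass intermediates for one batch.
struct Fwd {
  int B;
  mat C1, O1x, A1;            // im2col, BN1 x-hat, post-ReLU (N1 x F1)
  rowvec mu1, var1;
  mat C2, O2x, A2;            // (N2 x F2)
  rowvec mu2, var2;
  mat U;                      // (B*L x m), frame order l-major: fr = l*B + wi
  std::vector<mat> I, F, G, O, C, Hc, H; // per LSTM step, each B x h
  std::vector<mat> fcZ;       // FC activations, fcZ[0] = H_last
  std::vector<mat> fcMask;
  mat Out;
};

// Forward pass for windows ending at rows `ends` (0-based, inclusive) of Z.
// train = true uses batch statistics (and updates running stats when
// update_running = true); train = false uses running statistics.
static Fwd forward(Net& n, const Cfg& c, const mat& Z,
                   const std::vector<int>& ends, bool train,
                   bool update_running) {
  Fwd f;
  const int B = f.B = (int)ends.size();
  const int BL = B * c.L;

  // conv1 im2col: frame fr = l*B + wi is row ends[wi]-(L-1)+l of Z
  f.C1.set_size((arma::uword)BL * c.P1, c.k1);
  for (int l = 0; l < c.L; ++l) {
    for (int wi = 0; wi < B; ++wi) {
      const int zrow = ends[wi] - (c.L - 1) + l;
      const int fr = l * B + wi;
      for (int q = 0; q < c.P1; ++q) {
        const int base = q * c.s1;
        for (int kk = 0; kk < c.k1; ++kk)
          f.C1((arma::uword)fr * c.P1 + q, kk) = Z(zrow, base + kk);
      }
    }
  }
  mat O1 = f.C1 * n.W1; O1.each_row() += n.b1;

  auto bn_fwd = [&](mat& O, rowvec& mu, rowvec& var, mat& xhat,
                    const rowvec& g, const rowvec& be,
                    rowvec& rm, rowvec& rv) {
    if (train) {
      mu = arma::mean(O, 0);
      mat Oc = O; Oc.each_row() -= mu;
      var = arma::mean(arma::square(Oc), 0);
      if (update_running) {
        rm = (1.0 - c.bn_momentum) * rm + c.bn_momentum * mu;
        rv = (1.0 - c.bn_momentum) * rv + c.bn_momentum * var;
      }
      xhat = Oc; xhat.each_row() /= arma::sqrt(var + c.eps);
    } else {
      mu = rm; var = rv;
      xhat = O; xhat.each_row() -= mu;
      xhat.each_row() /= arma::sqrt(var + c.eps);
    }
    mat y = xhat; y.each_row() %= g; y.each_row() += be;
    return y;
  };

  mat y1 = bn_fwd(O1, f.mu1, f.var1, f.O1x, n.g1, n.be1, n.rm1, n.rv1);
  f.A1 = arma::clamp(y1, 0.0, arma::datum::inf);

  // conv2 im2col over (position, channel) of A1
  f.C2.set_size((arma::uword)BL * c.P2, c.k2 * c.F1);
  for (int fr = 0; fr < BL; ++fr) {
    for (int r = 0; r < c.P2; ++r) {
      const int base = r * c.s2;
      for (int ch = 0; ch < c.F1; ++ch)
        for (int kk = 0; kk < c.k2; ++kk)
          f.C2((arma::uword)fr * c.P2 + r, ch * c.k2 + kk) =
            f.A1((arma::uword)fr * c.P1 + base + kk, ch);
    }
  }
  mat O2 = f.C2 * n.W2; O2.each_row() += n.b2;
  mat y2 = bn_fwd(O2, f.mu2, f.var2, f.O2x, n.g2, n.be2, n.rm2, n.rv2);
  f.A2 = arma::clamp(y2, 0.0, arma::datum::inf);

  // flatten per frame: U(fr, ch*P2 + r) = A2(fr*P2 + r, ch)
  f.U.set_size(BL, c.m);
  for (int fr = 0; fr < BL; ++fr)
    for (int ch = 0; ch < c.F2; ++ch)
      for (int r = 0; r < c.P2; ++r)
        f.U(fr, ch * c.P2 + r) = f.A2((arma::uword)fr * c.P2 + r, ch);

  // LSTM over the L time steps
  f.I.resize(c.L); f.F.resize(c.L); f.G.resize(c.L); f.O.resize(c.L);
  f.C.resize(c.L); f.Hc.resize(c.L); f.H.resize(c.L);
  mat Hprev(B, c.h, arma::fill::zeros), Cprev(B, c.h, arma::fill::zeros);
  for (int l = 0; l < c.L; ++l) {
    mat Ul = f.U.rows((arma::uword)l * B, (arma::uword)l * B + B - 1);
    mat Gt = Ul * n.Wx.t() + Hprev * n.Wh.t();
    Gt.each_row() += n.bl;
    mat i = 1.0 / (1.0 + arma::exp(-Gt.cols(0, c.h - 1)));
    mat fg = 1.0 / (1.0 + arma::exp(-Gt.cols(c.h, 2 * c.h - 1)));
    mat g = arma::tanh(Gt.cols(2 * c.h, 3 * c.h - 1));
    mat o = 1.0 / (1.0 + arma::exp(-Gt.cols(3 * c.h, 4 * c.h - 1)));
    mat Cl = fg % Cprev + i % g;
    mat Hcl = arma::tanh(Cl);
    mat Hl = o % Hcl;
    f.I[l] = i; f.F[l] = fg; f.G[l] = g; f.O[l] = o;
    f.C[l] = Cl; f.Hc[l] = Hcl; f.H[l] = Hl;
    Hprev = Hl; Cprev = Cl;
  }

  // fully connected chain + linear output
  f.fcZ.clear(); f.fcMask.clear();
  f.fcZ.push_back(f.H[c.L - 1]);
  for (size_t i = 0; i < n.fcW.size(); ++i) {
    mat z = f.fcZ.back() * n.fcW[i].t();
    z.each_row() += n.fcb[i];
    mat mask = arma::conv_to<mat>::from(z > 0.0);
    f.fcMask.push_back(mask);
    f.fcZ.push_back(z % mask);
  }
  f.Out = f.fcZ.back() * n.Wo.t();
  f.Out.each_row() += n.bo;
  return f;
}

struct Grads {
  mat W1; rowvec b1, g1, be1;
  mat W2; rowvec b2, g2, be2;
  mat Wx, Wh; rowvec bl;
  std::vector<mat> fcW; std::vector<rowvec> fcb;
  mat Wo; rowvec bo;
};

static Grads backward(const Net& n, const Cfg& c, const Fwd& f, const mat& Y) {
  Grads g;
  const int B = f.B;
  const int BL = B * c.L;

  mat dOut = 2.0 * (f.Out - Y) / (double)(Y.n_rows * Y.n_cols);
  g.Wo = dOut.t() * f.fcZ.back();
  g.bo = arma::sum(dOut, 0);
  mat dZ = dOut * n.Wo;
  g.fcW.resize(n.fcW.size()); g.fcb.resize(n.fcb.size());
  for (int i = (int)n.fcW.size() - 1; i >= 0; --i) {
    dZ %= f.fcMask[i];
    g.fcW[i] = dZ.t() * f.fcZ[i];
    g.fcb[i] = arma::sum(dZ, 0);
    dZ = dZ * n.fcW[i];
  }

  // LSTM BPTT
  g.Wx.zeros(4 * c.h, c.m); g.Wh.zeros(4 * c.h, c.h); g.bl.zeros(4 * c.h);
  mat dU(BL, c.m, arma::fill::zeros);
  mat dH = dZ, dC(B, c.h, arma::fill::zeros);
  for (int l = c.L - 1; l >= 0; --l) {
    mat do_ = dH % f.Hc[l];
    dC += dH % f.O[l] % (1.0 - arma::square(f.Hc[l]));
    mat di = dC % f.G[l];
    mat dg = dC % f.I[l];
    mat Cprev = (l == 0) ? mat(B, c.h, arma::fill::zeros) : f.C[l - 1];
    mat df = dC % Cprev;
    mat dCprev = dC % f.F[l];
    mat dGt(B, 4 * c.h);
    dGt.cols(0, c.h - 1)            = di % f.I[l] % (1.0 - f.I[l]);
    dGt.cols(c.h, 2 * c.h - 1)      = df % f.F[l] % (1.0 - f.F[l]);
    dGt.cols(2 * c.h, 3 * c.h - 1)  = dg % (1.0 - arma::square(f.G[l]));
    dGt.cols(3 * c.h, 4 * c.h - 1)  = do_ % f.O[l] % (1.0 - f.O[l]);
    mat Ul = f.U.rows((arma::uword)l * B, (arma::uword)l * B + B - 1);
    mat Hprev = (l == 0) ? mat(B, c.h, arma::fill::zeros) : f.H[l - 1];
    g.Wx += dGt.t() * Ul;
    g.Wh += dGt.t() * Hprev;
    g.bl += arma::sum(dGt, 0);
    dU.rows((arma::uword)l * B, (arma::uword)l * B + B - 1) = dGt * n.Wx;
    dH = dGt * n.Wh;
    dC = dCprev;
  }

  // unflatten dU -> dA2
  mat dA2((arma::uword)BL * c.P2, c.F2, arma::fill::zeros);
  for (int fr = 0; fr < BL; ++fr)
    for (int ch = 0; ch < c.F2; ++ch)
      for (int r = 0; r < c.P2; ++r)
        dA2((arma::uword)fr * c.P2 + r, ch) = dU(fr, ch * c.P2 + r);

  auto bn_bwd = [&](mat& dy, const mat& xhat, const rowvec& var,
                    const rowvec& gam, rowvec& dgam, rowvec& dbe) {
    dgam = arma::sum(dy % xhat, 0);
    dbe = arma::sum(dy, 0);
    mat dxh = dy; dxh.each_row() %= gam;
    rowvec mdxh = arma::mean(dxh, 0);
    rowvec mdxx = arma::mean(dxh % xhat, 0);
    mat dx = dxh;
    dx.each_row() -= mdxh;
    dx -= xhat.each_row() % mdxx;
    dx.each_row() /= arma::sqrt(var + c.eps);
    return dx;
  };

  // ReLU + BN2 + conv2
  mat dy2 = dA2 % arma::conv_to<mat>::from(f.A2 > 0.0);
  mat dO2 = bn_bwd(dy2, f.O2x, f.var2, n.g2, g.g2, g.be2);
  g.W2 = f.C2.t() * dO2;
  g.b2 = arma::sum(dO2, 0);
  mat dC2 = dO2 * n.W2.t();

  // col2im back to dA1
  mat dA1((arma::uword)BL * c.P1, c.F1, arma::fill::zeros);
  for (int fr = 0; fr < BL; ++fr)
    for (int r = 0; r < c.P2; ++r) {
      const int base = r * c.s2;
      for (int ch = 0; ch < c.F1; ++ch)
        for (int kk = 0; kk < c.k2; ++kk)
          dA1((arma::uword)fr * c.P1 + base + kk, ch) +=
            dC2((arma::uword)fr * c.P2 + r, ch * c.k2 + kk);
    }

  mat dy1 = dA1 % arma::conv_to<mat>::from(f.A1 > 0.0);
  mat dO1 = bn_bwd(dy1, f.O1x, f.var1, n.g1, g.g1, g.be1);
  g.W1 = f.C1.t() * dO1;
  g.b1 = arma::sum(dO1, 0);
  return g;
}

// SGD-with-momentum velocity store mirroring the gradient layout.
struct Vel {
  Grads v;
  bool init = false;
};

static void sgd_update(Net& n, const Grads& g, Vel& vel, double lr, double mom) {
  if (!vel.init) {
    vel.v.W1.zeros(arma::size(g.W1)); vel.v.b1.zeros(arma::size(g.b1));
    vel.v.g1.zeros(arma::size(g.g1)); vel.v.be1.zeros(arma::size(g.be1));
    vel.v.W2.zeros(arma::size(g.W2)); vel.v.b2.zeros(arma::size(g.b2));
    vel.v.g2.zeros(arma::size(g.g2)); vel.v.be2.zeros(arma::size(g.be2));
    vel.v.Wx.zeros(arma::size(g.Wx)); vel.v.Wh.zeros(arma::size(g.Wh));
    vel.v.bl.zeros(arma::size(g.bl));
    vel.v.fcW.resize(g.fcW.size()); vel.v.fcb.resize(g.fcb.size());
    for (size_t i = 0; i < g.fcW.size(); ++i) {
      vel.v.fcW[i].zeros(arma::size(g.fcW[i]));
      vel.v.fcb[i].zeros(arma::size(g.fcb[i]));
    }
    vel.v.Wo.zeros(arma::size(g.Wo)); vel.v.bo.zeros(arma::size(g.bo));
    vel.init = true;
  }
  auto upd = [&](auto& w, auto& v, const auto& gr) { v = mom * v - lr * gr; w += v; };
  upd(n.W1, vel.v.W1, g.W1); upd(n.b1, vel.v.b1, g.b1);
  upd(n.g1, vel.v.g1, g.g1); upd(n.be1, vel.v.be1, g.be1);
  upd(n.W2, vel.v.W2, g.W2); upd(n.b2, vel.v.b2, g.b2);
  upd(n.g2, vel.v.g2, g.g2); upd(n.be2, vel.v.be2, g.be2);
  upd(n.Wx, vel.v.Wx, g.Wx); upd(n.Wh, vel.v.Wh, g.Wh); upd(n.bl, vel.v.bl, g.bl);
  for (size_t i = 0; i < g.fcW.size(); ++i) {
    upd(n.fcW[i], vel.v.fcW[i], g.fcW[i]);
    upd(n.fcb[i], vel.v.fcb[i], g.fcb[i]);
  }
  upd(n.Wo, vel.v.Wo, g.Wo); upd(n.bo, vel.v.bo, g.bo);
}

static double eval_loss(Net& n, const Cfg& c, const mat& Z, const mat& X,
                        const std::vector<int>& ends, int eval_batch = 256) {
  double se = 0.0; long cnt = 0;
  for (size_t s = 0; s < ends.size(); s += eval_batch) {
    size_t e = std::min(ends.size(), s + eval_batch);
    std::vector<int> sub(ends.begin() + s, ends.begin() + e);
    Fwd f = forward(n, c, Z, sub, false, false);
    mat Y(sub.size(), c.d);
    for (size_t i = 0; i < sub.size(); ++i) Y.row(i) = X.row(sub[i]);
    se += arma::accu(arma::square(f.Out - Y));
    cnt += (long)sub.size() * c.d;
  }
  return se / (double)cnt;
}

// [[Rcpp::export]]
List cpp_clstm_train(List params, const arma::mat& Z, const arma::mat& X,
                     IntegerVector train_ends, IntegerVector val_ends,
                     List cfg, int max_epochs, int patience, int seed) {
  Cfg c = read_cfg(cfg);
  Net n = net_from_list(params);
  std::vector<int> tr(train_ends.begin(), train_ends.end());
  std::vector<int> va(val_ends.begin(), val_ends.end());
  for (auto& i : tr) --i;  // to 0-based
  for (auto& i : va) --i;
  const bool use_val = !va.empty() && patience > 0;

  Vel vel;
  std::vector<double> tr_hist, va_hist;
  double best_val = arma::datum::inf;
  List best = net_to_list(n);
  int fails = 0, epochs_run = 0;
  bool stopped_early = false;
  std::mt19937 rng((unsigned)seed);

  for (int ep = 0; ep < max_epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double ep_loss = 0.0; int nb = 0;
    for (size_t s = 0; s < tr.size(); s += c.batch) {
      size_t e = std::min(tr.size(), s + c.batch);
      std::vector<int> sub(tr.begin() + s, tr.begin() + e);
      Fwd f = forward(n, c, Z, sub, true, true);
      mat Y(sub.size(), c.d);
      for (size_t i = 0; i < sub.size(); ++i) Y.row(i) = X.row(sub[i]);
      ep_loss += arma::accu(arma::square(f.Out - Y)) / (double)(Y.n_rows * Y.n_cols);
      ++nb;
      Grads g = backward(n, c, f, Y);
      sgd_update(n, g, vel, c.lr, c.momentum);
    }
    tr_hist.push_back(ep_loss / std::max(1, nb));
    ++epochs_run;

    if (use_val) {
      double vl = eval_loss(n, c, Z, X, va);
      va_hist.push_back(vl);
      if (vl < best_val) {
        best_val = vl; best = net_to_list(n); fails = 0;
      } else {
        ++fails;
        if (fails >= patience) { stopped_early = true; break; }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  if (!use_val) best = net_to_list(n);
  return List::create(
    _["params"] = best,
    _["train_loss"] = tr_hist, _["val_loss"] = va_hist,
    _["epochs"] = epochs_run, _["stopped_early"] = stopped_early,
    _["best_val_loss"] = use_val ? best_val : NA_REAL);
}

// [[Rcpp::export]]
arma::mat cpp_clstm_predict(List params, const arma::mat& Z, List cfg) {
  Cfg c = read_cfg(cfg);
  Net n = net_from_list(params);
  const int T = Z.n_rows;
  if (T < c.L) stop("need at least window_len (%d) frames, got %d", c.L, T);
  std::vector<int> ends;
  for (int t = c.L - 1; t < T; ++t) ends.push_back(t);
  mat out(ends.size(), c.d);
  const int eb = 256;
  for (size_t s = 0; s < ends.size(); s += eb) {
    size_t e = std::min(ends.size(), s + eb);
    std::vector<int> sub(ends.begin() + s, ends.begin() + e);
    Fwd f = forward(n, c, Z, sub, false, false);
    out.rows(s, e - 1) = f.Out;
  }
  return out;
}

// Training-mode loss and analytic gradients for one batch; used by the
// numerical gradient-check test.
// [[Rcpp::export]]
List cpp_clstm_grad(List params, const arma::mat& Z, const arma::mat& X,
                    IntegerVector ends, List cfg) {
  Cfg c = read_cfg(cfg);
  Net n = net_from_list(params);
  std::vector<int> sub(ends.begin(), ends.end());
  for (auto& i : sub) --i;
  Fwd f = forward(n, c, Z, sub, true, false);
  mat Y(sub.size(), c.d);
  for (size_t i = 0; i < sub.size(); ++i) Y.row(i) = X.row(sub[i]);
  double loss = arma::accu(arma::square(f.Out - Y)) / (double)(Y.n_rows * Y.n_cols);
  Grads g = backward(n, c, f, Y);
  List fw(g.fcW.size()), fb(g.fcb.size());
  for (size_t i = 0; i < g.fcW.size(); ++i) { fw[i] = g.fcW[i]; fb[i] = g.fcb[i]; }
  List gl = List::create(
    _["W1"] = g.W1, _["b1"] = g.b1, _["g1"] = g.g1, _["be1"] = g.be1,
    _["W2"] = g.W2, _["b2"] = g.b2, _["g2"] = g.g2, _["be2"] = g.be2,
    _["Wx"] = g.Wx, _["Wh"] = g.Wh, _["bl"] = g.bl,
    _["fcW"] = fw, _["fcb"] = fb, _["Wo"] = g.Wo, _["bo"] = g.bo);
  return List::create(_["loss"] = loss, _["grads"] = gl);
}

// [[Rcpp::export]]
double cpp_clstm_loss(List params, const arma::mat& Z, const arma::mat& X,
                      IntegerVector ends, List cfg) {
  Cfg c = read_cfg(cfg);
  Net n = net_from_list(params);
  std::vector<int> sub(ends.begin(), ends.end());
  for (auto& i : sub) --i;
  Fwd f = forward(n, c, Z, sub, true, false);
  mat Y(sub.size(), c.d);
  for (size_t i = 0; i < sub.size(); ++i) Y.row(i) = X.row(sub[i]);
  return arma::accu(arma::square(f.Out - Y)) / (double)(Y.n_rows * Y.n_cols);
}
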