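// Minimal 3D conv-net engine: shift-GEMM convolutions, 2x2x2 max pooling,
// batch norm, residual skips, dense taps, softmax cross-entropy.
// Stateless: every call rebuilds views onto the flat parameter vector, so the
// R side owns all weights, optimizer state and batch-norm running statistics.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::uvec;
using arma::uword;

namespace {

const double BN_EPS = 1e-5;

enum LayerKind {
  L_CONV = 1, L_RELU = 2, L_POOL = 3, L_BN = 4,
  L_GMAX = 5, L_DENSE = 6, L_RSAVE = 7, L_RADD = 8, L_SOFTMAX = 9
};

struct Layer {
  int kind, c_in, c_out;
  int din[3], dout[3];
  uword poff, pcnt;
  int aux; // res_add: 0-based index of the matching res_save layer
};

// Destination/source row maps for one kernel offset across the whole batch.
void offset_maps(int d, int h, int w, int n, int dz, int dy, int dx,
                 uvec &dst, uvec &src) {
  int z0 = std::max(0, -dz), z1 = d - 1 - std::max(0, dz);
  int y0 = std::max(0, -dy), y1 = h - 1 - std::max(0, dy);
  int x0 = std::max(0, -dx), x1 = w - 1 - std::max(0, dx);
  if (z1 < z0 || y1 < y0 || x1 < x0) { dst.reset(); src.reset(); return; }
  uword nvox = (uword)d * h * w;
  uword cnt = (uword)(z1 - z0 + 1) * (y1 - y0 + 1) * (x1 - x0 + 1) * n;
  dst.set_size(cnt); src.set_size(cnt);
  uword t = 0;
  for (int s = 0; s < n; ++s) {
    uword base = (uword)s * nvox;
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          dst[t] = base + (uword)z + (uword)d * y + (uword)d * h * x;
          src[t] = base + (uword)(z + dz) + (uword)d * (y + dy)
                   + (uword)d * h * (x + dx);
          ++t;
        }
  }
}

struct Net {
  std::vector<Layer> ls;
  arma::vec pv; // aliased parameter vector
  int n;        // batch size

  std::vector<mat> acts;            // acts[0] = input, acts[i+1] = out of layer i
  std::vector<arma::umat> pool_src; // argmax source row per (out_row, channel)
  std::vector<arma::rowvec> bn_mu, bn_sd;
  std::vector<mat> bn_xhat;

  Net(const List &layers, const arma::vec &params, int n_)
      : pv(params), n(n_) {
    int L = layers.size();
    ls.resize(L);
    for (int i = 0; i < L; ++i) {
      List li = layers[i];
      Layer &l = ls[i];
      l.kind = as<int>(li["kind"]);
      l.c_in = as<int>(li["c_in"]);
      l.c_out = as<int>(li["c_out"]);
      IntegerVector di = li["d_in"], dd = li["d_out"];
      for (int k = 0; k < 3; ++k) { l.din[k] = di[k]; l.dout[k] = dd[k]; }
      l.poff = (uword)as<double>(li["poff"]);
      l.pcnt = (uword)as<double>(li["pcnt"]);
      l.aux = li.containsElementNamed("aux") ? as<int>(li["aux"]) : -1;
    }
    acts.resize(L + 1);
    pool_src.resize(L);
    bn_mu.resize(L); bn_sd.resize(L); bn_xhat.resize(L);
  }

  mat Wview(uword off, uword r, uword c) const {
    return mat(const_cast<double *>(pv.memptr()) + off, r, c, false, true);
  }

  void conv_forward(const Layer &l, const mat &X, mat &Y) const {
    int d = l.din[0], h = l.din[1], w = l.din[2];
    arma::rowvec b(const_cast<double *>(pv.memptr()) + l.poff
                       + (uword)27 * l.c_in * l.c_out,
                   l.c_out, false, true);
    Y.set_size(X.n_rows, l.c_out);
    Y.each_row() = b;
    uword blk = (uword)l.c_in * l.c_out, o = 0;
    uvec dst, src;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz, ++o) {
          offset_maps(d, h, w, n, dz, dy, dx, dst, src);
          if (dst.n_elem == 0) continue;
          mat Wo = Wview(l.poff + o * blk, l.c_in, l.c_out);
          mat Xs = X.rows(src);
          Y.rows(dst) += Xs * Wo;
        }
  }

  void conv_backward(const Layer &l, const mat &X, const mat &dY, mat &dX,
                     arma::vec &g) const {
    int d = l.din[0], h = l.din[1], w = l.din[2];
    uword blk = (uword)l.c_in * l.c_out, o = 0;
    dX.zeros(X.n_rows, X.n_cols);
    arma::rowvec db = arma::sum(dY, 0);
    uword boff = l.poff + (uword)27 * blk;
    for (int c = 0; c < l.c_out; ++c) g[boff + c] += db[c];
    uvec dst, src;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz, ++o) {
          offset_maps(d, h, w, n, dz, dy, dx, dst, src);
          if (dst.n_elem == 0) continue;
          mat Wo = Wview(l.poff + o * blk, l.c_in, l.c_out);
          mat dYo = dY.rows(dst);
          mat Xs = X.rows(src);
          mat gW(g.memptr() + l.poff + o * blk, l.c_in, l.c_out, false, true);
          gW += Xs.t() * dYo;
          dX.rows(src) += dYo * Wo.t();
        }
  }

  // Forward through the first `upto` layers (1-based count).
  void forward(const mat &X, bool training, const List &bn_run, int upto) {
    acts[0] = X;
    int bn_i = 0;
    for (int i = 0; i < upto; ++i) {
      const Layer &l = ls[i];
      const mat &A = acts[i];
      mat &Y = acts[i + 1];
      switch (l.kind) {
      case L_CONV:
        conv_forward(l, A, Y);
        break;
      case L_RELU:
        Y = arma::clamp(A, 0.0, arma::datum::inf);
        break;
      case L_POOL: {
        int d = l.din[0], h = l.din[1], w = l.din[2];
        int od = l.dout[0], oh = l.dout[1], ow = l.dout[2];
        uword nvo = (uword)od * oh * ow, nvi = (uword)d * h * w;
        Y.set_size((uword)n * nvo, l.c_out);
        arma::umat &srcm = pool_src[i];
        srcm.set_size((uword)n * nvo, l.c_out);
        for (int s = 0; s < n; ++s) {
          uword obase = (uword)s * nvo, ibase = (uword)s * nvi;
          for (int x = 0; x < ow; ++x)
            for (int y = 0; y < oh; ++y)
              for (int z = 0; z < od; ++z) {
                uword orow = obase + (uword)z + (uword)od * y + (uword)od * oh * x;
                uword cand[8];
                int nc = 0;
                for (int l3 = 0; l3 < 2; ++l3)
                  for (int l2 = 0; l2 < 2; ++l2)
                    for (int l1 = 0; l1 < 2; ++l1) {
                      // dims too small to halve are passed through unchanged
                      int zz = (od == d) ? z : 2 * z + l1;
                      int yy = (oh == h) ? y : 2 * y + l2;
                      int xx = (ow == w) ? x : 2 * x + l3;
                      if (zz < d && yy < h && xx < w) {
                        uword r = ibase + (uword)zz + (uword)d * yy
                                  + (uword)d * h * xx;
                        bool dup = false;
                        for (int q = 0; q < nc; ++q)
                          if (cand[q] == r) dup = true;
                        if (!dup) cand[nc++] = r;
                      }
                    }
                for (int c = 0; c < l.c_out; ++c) {
                  double best = A(cand[0], c);
                  uword br = cand[0];
                  for (int q = 1; q < nc; ++q)
                    if (A(cand[q], c) > best) { best = A(cand[q], c); br = cand[q]; }
                  Y(orow, c) = best;
                  srcm(orow, c) = br;
                }
              }
        }
        break;
      }
      case L_BN: {
        arma::rowvec gamma(const_cast<double *>(pv.memptr()) + l.poff,
                           l.c_out, false, true);
        arma::rowvec beta(const_cast<double *>(pv.memptr()) + l.poff + l.c_out,
                          l.c_out, false, true);
        arma::rowvec mu, var;
        if (training) {
          mu = arma::mean(A, 0);
          mat C = A;
          C.each_row() -= mu;
          var = arma::mean(arma::square(C), 0);
        } else {
          List st = bn_run[bn_i];
          NumericVector m = st["mean"], v = st["var"];
          mu = arma::rowvec(m.begin(), m.size());
          var = arma::rowvec(v.begin(), v.size());
        }
        arma::rowvec sd = arma::sqrt(var + BN_EPS);
        bn_mu[i] = mu;
        bn_sd[i] = sd;
        mat xh = A;
        xh.each_row() -= mu;
        xh.each_row() /= sd;
        bn_xhat[i] = xh;
        Y = xh;
        Y.each_row() %= gamma;
        Y.each_row() += beta;
        ++bn_i;
        break;
      }
      case L_GMAX: {
        uword nvi = (uword)l.din[0] * l.din[1] * l.din[2];
        Y.set_size(n, l.c_out);
        arma::umat &srcm = pool_src[i];
        srcm.set_size(n, l.c_out);
        for (int s = 0; s < n; ++s) {
          uword ibase = (uword)s * nvi;
          for (int c = 0; c < l.c_out; ++c) {
            double best = A(ibase, c);
            uword br = ibase;
            for (uword r = 1; r < nvi; ++r)
              if (A(ibase + r, c) > best) { best = A(ibase + r, c); br = ibase + r; }
            Y(s, c) = best;
            srcm(s, c) = br;
          }
        }
        break;
      }
      case L_DENSE: {
        mat W = Wview(l.poff, l.c_in, l.c_out);
        arma::rowvec b(const_cast<double *>(pv.memptr()) + l.poff
                           + (uword)l.c_in * l.c_out,
                       l.c_out, false, true);
        Y = A * W;
        Y.each_row() += b;
        break;
      }
      case L_RSAVE:
        Y = A;
        break;
      case L_RADD: {
        const mat &S = acts[l.aux + 1];
        if (l.pcnt > 0) { // 1x1x1 projection when channel counts differ
          int c_save = (int)(l.pcnt / l.c_out);
          mat Wp = Wview(l.poff, c_save, l.c_out);
          Y = A + S * Wp;
        } else {
          Y = A + S;
        }
        break;
      }
      case L_SOFTMAX: {
        arma::vec mx = arma::max(A, 1);
        mat E = arma::exp(A.each_col() - mx);
        arma::vec den = arma::sum(E, 1);
        Y = E.each_col() / den;
        break;
      }
      default:
        stop("unknown layer kind");
      }
    }
  }

  // Backward from softmax cross-entropy. Requires last layer L_SOFTMAX.
  double backward(const arma::ivec &y, arma::vec &g) {
    int L = ls.size();
    if (ls[L - 1].kind != L_SOFTMAX) stop("last layer must be softmax");
    // dacts[i] = gradient wrt acts[i+1] (the output of layer i)
    std::vector<mat> dacts(L);
    const mat &P = acts[L];
    const mat &logits = acts[L - 1];
    int K = P.n_cols;
    double loss = 0.0;
    mat dlog(n, K);
    for (int s = 0; s < n; ++s) {
      // cross-entropy from logits via log-sum-exp (smooth, no clamping)
      double mx = logits.row(s).max();
      double lse = mx + std::log(arma::accu(arma::exp(logits.row(s) - mx)));
      loss += lse - logits(s, y[s]);
      for (int c = 0; c < K; ++c)
        dlog(s, c) = (P(s, c) - (c == y[s] ? 1.0 : 0.0)) / n;
    }
    loss /= n;
    dacts[L - 2] = dlog; // grad wrt logits = output of the layer below softmax
    for (int i = L - 2; i >= 0; --i) {
      mat &dY = dacts[i];
      if (dY.is_empty()) continue;
      const Layer &l = ls[i];
      const mat &X = acts[i];
      mat dX;
      switch (l.kind) {
      case L_CONV:
        conv_backward(l, X, dY, dX, g);
        break;
      case L_RELU: {
        dX = dY % arma::conv_to<mat>::from(X > 0);
        break;
      }
      case L_POOL:
      case L_GMAX: {
        dX.zeros(X.n_rows, X.n_cols);
        const arma::umat &srcm = pool_src[i];
        for (uword c = 0; c < dY.n_cols; ++c)
          for (uword r = 0; r < dY.n_rows; ++r)
            dX(srcm(r, c), c) += dY(r, c);
        break;
      }
      case L_BN: {
        arma::rowvec gamma(pv.memptr() + l.poff, l.c_out, false, true);
        const mat &xhat = bn_xhat[i];
        double m = (double)X.n_rows;
        arma::rowvec dgamma = arma::sum(dY % xhat, 0);
        arma::rowvec dbeta = arma::sum(dY, 0);
        for (int c = 0; c < l.c_out; ++c) {
          g[l.poff + c] += dgamma[c];
          g[l.poff + l.c_out + c] += dbeta[c];
        }
        mat dxh = dY;
        dxh.each_row() %= gamma;
        arma::rowvec s1 = arma::sum(dxh, 0);
        arma::rowvec s2 = arma::sum(dxh % xhat, 0);
        dX = dxh * m;
        dX.each_row() -= s1;
        dX -= xhat.each_row() % s2;
        dX.each_row() /= (m * bn_sd[i]);
        break;
      }
      case L_DENSE: {
        mat W = Wview(l.poff, l.c_in, l.c_out);
        mat gW(g.memptr() + l.poff, l.c_in, l.c_out, false, true);
        gW += X.t() * dY;
        arma::rowvec db = arma::sum(dY, 0);
        for (int c = 0; c < l.c_out; ++c)
          g[l.poff + (uword)l.c_in * l.c_out + c] += db[c];
        dX = dY * W.t();
        break;
      }
      case L_RSAVE:
        dX = dY;
        break;
      case L_RADD: {
        dX = dY; // main branch
        mat dS;
        if (l.pcnt > 0) {
          int c_save = (int)(l.pcnt / l.c_out);
          mat Wp = Wview(l.poff, c_save, l.c_out);
          const mat &S = acts[l.aux + 1];
          mat gW(g.memptr() + l.poff, c_save, l.c_out, false, true);
          gW += S.t() * dY;
          dS = dY * Wp.t();
        } else {
          dS = dY;
        }
        int j = l.aux;
        if (dacts[j].is_empty()) dacts[j] = dS;
        else dacts[j] += dS;
        break;
      }
      default:
        stop("backward: unknown layer kind");
      }
      if (i > 0) {
        if (dacts[i - 1].is_empty()) dacts[i - 1] = dX;
        else dacts[i - 1] += dX;
      }
      dY.reset();
    }
    return loss;
  }
};

} // namespace

// [[Rcpp::export(name = ".nn_batch_cpp")]]
List nn_batch_cpp(NumericVector params, List layers, NumericMatrix X, int n,
                  IntegerVector y, List bn_run, bool training, int mode,
                  int tap) {
  arma::vec pv(params.begin(), params.size(), false);
  mat Xm(X.begin(), X.nrow(), X.ncol(), false);
  Net net(layers, pv, n);
  int L = layers.size();

  if (mode == 2) { // tap activations
    net.forward(Xm, false, bn_run, tap);
    return List::create(_["act"] = wrap(net.acts[tap]));
  }
  if (mode == 1) { // predict class probabilities
    net.forward(Xm, false, bn_run, L);
    return List::create(_["probs"] = wrap(net.acts[L]));
  }
  // mode 0: training loss + gradient, batch BN statistics returned
  net.forward(Xm, true, bn_run, L);
  arma::vec g(params.size(), arma::fill::zeros);
  arma::ivec yy(y.size());
  for (int i = 0; i < y.size(); ++i) yy[i] = y[i];
  double loss = net.backward(yy, g);
  List bn_mean, bn_var;
  for (int i = 0; i < L; ++i)
    if (net.ls[i].kind == L_BN) {
      bn_mean.push_back(wrap(net.bn_mu[i]));
      arma::rowvec var = arma::square(net.bn_sd[i]) - BN_EPS;
      bn_var.push_back(wrap(var));
    }
  return List::create(_["loss"] = loss, _["grad"] = wrap(g),
                      _["probs"] = wrap(net.acts[L]), _["bn_mean"] = bn_mean,
                      _["bn_var"] = bn_var);
}
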