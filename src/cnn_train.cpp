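// Full-batch Adam training loop for the skip-connected 1D-CNN.
//
// Feature maps use the same flat (n * L, C) layout as the R reference
// engine (row i + (l-1)*n = sample i, position l); all gather indices
// (convolution taps, pooling windows, skip rows) are precomputed in R by
// cnn_plan() and passed in 1-based, so both engines perform literally the
// same arithmetic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

arma::uvec as_idx(SEXP v) {
  IntegerVector iv(v);
  arma::uvec out(iv.size());
  for (int i = 0; i < iv.size(); ++i) out[i] = iv[i] - 1;  // to 0-based
  return out;
}

std::vector<arma::uvec> as_idx_list(List l) {
  std::vector<arma::uvec> out;
  for (int i = 0; i < l.size(); ++i) out.push_back(as_idx(l[i]));
  return out;
}

std::vector<arma::mat> as_mat_list(List l) {
  std::vector<arma::mat> out;
  for (int i = 0; i < l.size(); ++i) out.push_back(as<arma::mat>(l[i]));
  return out;
}

arma::mat relu(const arma::mat& a) { return arma::clamp(a, 0.0, arma::datum::inf); }

// zero the entries of g where the activation was clipped (act <= 0)
void relu_mask(arma::mat& g, const arma::mat& act) {
  double* gp = g.memptr();
  const double* ap = act.memptr();
  for (arma::uword i = 0; i < g.n_elem; ++i)
    if (ap[i] <= 0.0) gp[i] = 0.0;
}

// With kernel size 1 and stride 1 (the default architecture) every tap is
// the identity permutation, so the gather can be skipped entirely.
bool is_identity(const arma::uvec& v, arma::uword n_rows) {
  if (v.n_elem != n_rows) return false;
  for (arma::uword i = 0; i < v.n_elem; ++i)
    if (v[i] != i) return false;
  return true;
}

// taps: k gather-index vectors; w: k matrices (cin x cout)
arma::mat conv_forward(const arma::mat& x, const std::vector<arma::uvec>& taps,
                       const std::vector<arma::mat>& w, const arma::rowvec& b,
                       bool identity) {
  arma::mat y;
  if (identity) {
    y = x * w[0];
  } else {
    y = x.rows(taps[0]) * w[0];
    for (size_t j = 1; j < w.size(); ++j) y += x.rows(taps[j]) * w[j];
  }
  y.each_row() += b;
  return y;
}

struct ConvGrad {
  std::vector<arma::mat> gw;
  arma::rowvec gb;
  arma::mat gx;
};

ConvGrad conv_backward(const arma::mat& x, const std::vector<arma::uvec>& taps,
                       const std::vector<arma::mat>& w, const arma::mat& gy,
                       bool identity) {
  ConvGrad g;
  if (identity) {
    g.gw.push_back(x.t() * gy);
    g.gx = gy * w[0].t();
  } else {
    g.gx.zeros(x.n_rows, x.n_cols);
    for (size_t j = 0; j < w.size(); ++j) {
      g.gw.push_back(x.rows(taps[j]).t() * gy);
      g.gx.rows(taps[j]) += gy * w[j].t();
    }
  }
  g.gb = arma::sum(gy, 0);
  return g;
}

struct PoolOut {
  arma::mat y;
  arma::umat arg;  // winning window per output cell (max pooling)
};

PoolOut pool_forward(const arma::mat& x, const std::vector<arma::uvec>& win,
                     bool average) {
  PoolOut out;
  out.y = x.rows(win[0]);
  if (average) {
    for (size_t w = 1; w < win.size(); ++w) out.y += x.rows(win[w]);
    out.y /= (double)win.size();
    return out;
  }
  out.arg.zeros(out.y.n_rows, out.y.n_cols);
  for (size_t w = 1; w < win.size(); ++w) {
    arma::mat cand = x.rows(win[w]);
    arma::uvec idx = arma::find(cand > out.y);
    out.y.elem(idx) = cand.elem(idx);
    out.arg.elem(idx).fill(w);
  }
  return out;
}

arma::mat pool_backward(const PoolOut& cache, const std::vector<arma::uvec>& win,
                        bool average, arma::uword in_rows, const arma::mat& gy) {
  arma::mat gx(in_rows, gy.n_cols, arma::fill::zeros);
  for (size_t w = 0; w < win.size(); ++w) {
    if (average) {
      gx.rows(win[w]) = gy / (double)win.size();
    } else {
      gx.rows(win[w]) = gy % arma::conv_to<arma::mat>::from(cache.arg == w);
    }
  }
  return gx;
}

struct Adam {
  std::vector<arma::mat> m, v;
  long t = 0;
  void init(const std::vector<arma::mat*>& ps) {
    for (auto* p : ps) {
      m.push_back(arma::mat(p->n_rows, p->n_cols, arma::fill::zeros));
      v.push_back(arma::mat(p->n_rows, p->n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<arma::mat*>& ps, const std::vector<arma::mat>& gs,
            double lr) {
    ++t;
    double bc1 = 1.0 - std::pow(0.9, (double)t);
    double bc2 = 1.0 - std::pow(0.999, (double)t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = 0.9 * m[i] + 0.1 * gs[i];
      v[i] = 0.999 * v[i] + 0.001 * (gs[i] % gs[i]);
      *ps[i] -= lr * (m[i] / bc1) / (arma::sqrt(v[i] / bc2) + 1e-8);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(const arma::mat& xm, const arma::vec& y,
                   List conv_w, List conv_b,
                   const arma::vec& dense_w0, double dense_b0,
                   List plan, int n, int flatten, int skip_ch1,
                   bool average_pool, double lr, int iterations,
                   double threshold) {
  // parameters
  std::vector<std::vector<arma::mat>> W;   // 4 conv layers, k taps each
  std::vector<arma::rowvec> B;
  for (int i = 0; i < 4; ++i) {
    W.push_back(as_mat_list(conv_w[i]));
    B.push_back(as<arma::rowvec>(conv_b[i]));
  }
  arma::mat dW = dense_w0;  // column vector as matrix
  arma::mat dB(1, 1); dB(0, 0) = dense_b0;

  // index plans
  std::vector<std::vector<arma::uvec>> taps;
  taps.push_back(as_idx_list(plan["conv1"]));
  taps.push_back(as_idx_list(plan["conv2"]));
  taps.push_back(as_idx_list(plan["conv3"]));
  taps.push_back(as_idx_list(plan["conv4"]));
  std::vector<arma::uvec> pool1 = as_idx_list(plan["pool1"]);
  std::vector<arma::uvec> pool2 = as_idx_list(plan["pool2"]);
  arma::uvec skip_rows = as_idx(plan["skip_rows"]);

  // identity-tap detection (kernel 1, stride 1 keeps sequence length)
  std::vector<arma::uword> conv_in_rows = {
      xm.n_rows, taps[0][0].n_elem, taps[1][0].n_elem, taps[3][0].n_elem};
  std::vector<bool> ident(4);
  for (int i = 0; i < 4; ++i)
    ident[i] = (taps[i].size() == 1) &&
               is_identity(taps[i][0], conv_in_rows[i]);

  // flatten parameter lists for Adam (biases as 1-row matrices)
  std::vector<arma::mat> Bm;
  for (int i = 0; i < 4; ++i) Bm.push_back(arma::mat(B[i]));
  std::vector<arma::mat*> ps;
  for (int i = 0; i < 4; ++i)
    for (auto& wj : W[i]) ps.push_back(&wj);
  for (int i = 0; i < 4; ++i) ps.push_back(&Bm[i]);
  ps.push_back(&dW); ps.push_back(&dB);
  Adam opt; opt.init(ps);

  arma::vec loss_hist(iterations), acc_hist(iterations);
  double nn = (double)n;

  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < 4; ++i) B[i] = Bm[i].row(0);
    arma::mat c1 = relu(conv_forward(xm, taps[0], W[0], B[0], ident[0]));
    arma::mat c2 = relu(conv_forward(c1, taps[1], W[1], B[1], ident[1]));
    arma::mat c3 = relu(conv_forward(c2, taps[2], W[2], B[2], ident[2]));
    bool skip_ident = is_identity(skip_rows, c1.n_rows) &&
                      c1.n_rows == c3.n_rows;
    arma::mat skip;
    if (skip_ident) skip = arma::join_rows(c1, c3);
    else skip = arma::join_rows(c1.rows(skip_rows), c3.rows(skip_rows));
    PoolOut p1 = pool_forward(skip, pool1, average_pool);
    arma::mat c4 = relu(conv_forward(p1.y, taps[3], W[3], B[3], ident[3]));
    PoolOut p2 = pool_forward(c4, pool2, average_pool);
    arma::mat flat(p2.y.memptr(), n, flatten);  // column-major reshape
    arma::vec logit = flat * dW + dB(0, 0);
    arma::vec prob = 1.0 / (1.0 + arma::exp(-logit));

    // stable BCE from logits: mean(softplus(logit) - y * logit)
    arma::vec sp = arma::clamp(logit, 0.0, arma::datum::inf) +
                   arma::log1p(arma::exp(-arma::abs(logit)));
    loss_hist[it] = arma::mean(sp - y % logit);
    double acc = 0;
    for (int i = 0; i < n; ++i)
      acc += ((prob[i] >= threshold) == (y[i] == 1.0)) ? 1.0 : 0.0;
    acc_hist[it] = acc / nn;

    // backward
    arma::mat glogit = (prob - y) / nn;  // n x 1
    arma::mat g_dW = flat.t() * glogit;
    arma::mat g_dB(1, 1); g_dB(0, 0) = arma::accu(glogit);
    arma::mat gflat = glogit * dW.t();  // n x flatten
    arma::mat gp2(gflat.memptr(), p2.y.n_rows, p2.y.n_cols);
    arma::mat gc4 = pool_backward(p2, pool2, average_pool, c4.n_rows, gp2);
    relu_mask(gc4, c4);
    ConvGrad b4 = conv_backward(p1.y, taps[3], W[3], gc4, ident[3]);
    arma::mat gskip = pool_backward(p1, pool1, average_pool, skip.n_rows,
                                    b4.gx);
    arma::mat gc1_skip = gskip.cols(0, skip_ch1 - 1);
    arma::mat gc3;
    if (skip_ident) {
      gc3 = gskip.cols(skip_ch1, gskip.n_cols - 1);
    } else {
      gc3.zeros(c3.n_rows, c3.n_cols);
      gc3.rows(skip_rows) = gskip.cols(skip_ch1, gskip.n_cols - 1);
    }
    relu_mask(gc3, c3);
    ConvGrad b3 = conv_backward(c2, taps[2], W[2], gc3, ident[2]);
    arma::mat gc2 = b3.gx;
    relu_mask(gc2, c2);
    ConvGrad b2 = conv_backward(c1, taps[1], W[1], gc2, ident[1]);
    arma::mat gc1 = b2.gx;
    if (skip_ident) gc1 += gc1_skip;
    else gc1.rows(skip_rows) += gc1_skip;
    relu_mask(gc1, c1);
    ConvGrad b1 = conv_backward(xm, taps[0], W[0], gc1, ident[0]);

    std::vector<arma::mat> gs;
    for (auto& g : b1.gw) gs.push_back(g);
    for (auto& g : b2.gw) gs.push_back(g);
    for (auto& g : b3.gw) gs.push_back(g);
    for (auto& g : b4.gw) gs.push_back(g);
    gs.push_back(arma::mat(b1.gb)); gs.push_back(arma::mat(b2.gb));
    gs.push_back(arma::mat(b3.gb)); gs.push_back(arma::mat(b4.gb));
    gs.push_back(g_dW); gs.push_back(g_dB);
    opt.step(ps, gs, lr);
  }

  List conv_w_out(4), conv_b_out(4);
  for (int i = 0; i < 4; ++i) {
    List wl(W[i].size());
    for (size_t j = 0; j < W[i].size(); ++j) wl[j] = W[i][j];
    conv_w_out[i] = wl;
    conv_b_out[i] = NumericVector(Bm[i].begin(), Bm[i].end());
  }
  return List::create(_["conv_w"] = conv_w_out, _["conv_b"] = conv_b_out,
                      _["dense_W"] = arma::vec(dW.col(0)),
                      _["dense_b"] = dB(0, 0),
                      _["loss"] = loss_hist, _["accuracy"] = acc_hist);
}
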