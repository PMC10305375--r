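// Full-batch Adam training loop for the variational autoencoder.
//
// Mirrors the pure-R reference engine step for step: same forward pass,
// same hand-derived gradients (decoder logits -> reparameterized latent
// draw -> encoder heads), same Adam updates, and the per-iteration latent
// noise is drawn from R's RNG (R::rnorm via Rcpp) in the same column-major
// order, so both engines produce identical histories under a fixed seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

arma::mat relu(const arma::mat& a) { return arma::clamp(a, 0.0, arma::datum::inf); }

void relu_mask(arma::mat& g, const arma::mat& act) {
  double* gp = g.memptr();
  const double* ap = act.memptr();
  for (arma::uword i = 0; i < g.n_elem; ++i)
    if (ap[i] <= 0.0) gp[i] = 0.0;
}

std::vector<arma::mat> as_mat_list(List l) {
  std::vector<arma::mat> out;
  for (int i = 0; i < l.size(); ++i) out.push_back(as<arma::mat>(l[i]));
  return out;
}

std::vector<arma::rowvec> as_rowvec_list(List l) {
  std::vector<arma::rowvec> out;
  for (int i = 0; i < l.size(); ++i) out.push_back(as<arma::rowvec>(l[i]));
  return out;
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

// [[Rcpp::export(name = ".vae_train_cpp")]]
List vae_train_cpp(const arma::mat& x,
                   List enc_W0, List enc_b0,
                   const arma::mat& mu_W0, const arma::rowvec& mu_b0,
                   const arma::mat& lv_W0, const arma::rowvec& lv_b0,
                   List dec_W0, List dec_b0,
                   double recon_weight, double lr, int iterations,
                   bool bce) {
  std::vector<arma::mat> enc_W = as_mat_list(enc_W0);
  std::vector<arma::mat> dec_W = as_mat_list(dec_W0);
  std::vector<arma::rowvec> enc_bv = as_rowvec_list(enc_b0);
  std::vector<arma::rowvec> dec_bv = as_rowvec_list(dec_b0);
  arma::mat mu_W = mu_W0, lv_W = lv_W0;
  arma::mat mu_B(mu_b0), lv_B(lv_b0);
  size_t n_enc = enc_W.size(), n_dec = dec_W.size();
  std::vector<arma::mat> enc_B, dec_B;
  for (auto& b : enc_bv) enc_B.push_back(arma::mat(b));
  for (auto& b : dec_bv) dec_B.push_back(arma::mat(b));

  int n = x.n_rows;
  int k = mu_W.n_cols;
  double nn = (double)n;

  std::vector<arma::mat*> ps;
  for (size_t i = 0; i < n_enc; ++i) { ps.push_back(&enc_W[i]); ps.push_back(&enc_B[i]); }
  ps.push_back(&mu_W); ps.push_back(&mu_B);
  ps.push_back(&lv_W); ps.push_back(&lv_B);
  for (size_t i = 0; i < n_dec; ++i) { ps.push_back(&dec_W[i]); ps.push_back(&dec_B[i]); }
  Adam opt; opt.init(ps);

  arma::vec h_total(iterations), h_recon(iterations), h_kl(iterations);

  for (int it = 0; it < iterations; ++it) {
    // encoder forward
    std::vector<arma::mat> eh(n_enc);
    arma::mat h = x;
    for (size_t i = 0; i < n_enc; ++i) {
      h = h * enc_W[i];
      h.each_row() += enc_B[i].row(0);
      h = relu(h);
      eh[i] = h;
    }
    arma::mat mu = h * mu_W;  mu.each_row() += mu_B.row(0);
    arma::mat lv = h * lv_W;  lv.each_row() += lv_B.row(0);

    // latent draw from R's RNG, column-major like matrix(rnorm(n*k), n, k)
    NumericVector rn = Rcpp::rnorm(n * k);
    arma::mat eps(rn.begin(), n, k);
    arma::mat s = arma::exp(lv / 2.0);
    arma::mat z = mu + s % eps;

    // decoder forward
    std::vector<arma::mat> dh(n_dec - 1);
    arma::mat d = z;
    for (size_t i = 0; i + 1 < n_dec; ++i) {
      d = d * dec_W[i];
      d.each_row() += dec_B[i].row(0);
      d = relu(d);
      dh[i] = d;
    }
    arma::mat a = d * dec_W[n_dec - 1];
    a.each_row() += dec_B[n_dec - 1].row(0);
    arma::mat xhat = 1.0 / (1.0 + arma::exp(-a));

    arma::vec recon;
    if (bce) {
      arma::mat sp = arma::clamp(a, 0.0, arma::datum::inf) +
                     arma::log1p(arma::exp(-arma::abs(a)));
      recon = arma::sum(sp - x % a, 1);
    } else {
      recon = arma::sum(arma::square(x - xhat), 1);
    }
    arma::vec kl = -0.5 * arma::sum(1.0 + lv - arma::square(mu) -
                                    arma::exp(lv), 1);
    h_total[it] = arma::mean(recon_weight * recon + kl);
    h_recon[it] = arma::mean(recon);
    h_kl[it] = arma::mean(kl);

    // backward (objective = mean over rows)
    arma::mat ga;
    if (bce) ga = recon_weight * (xhat - x) / nn;
    else ga = recon_weight * 2.0 * (xhat - x) % xhat % (1.0 - xhat) / nn;

    std::vector<arma::mat> g_dec_W(n_dec), g_dec_B(n_dec);
    arma::mat g = ga;
    for (int i = (int)n_dec - 1; i >= 0; --i) {
      const arma::mat& inp = (i == 0) ? z : dh[i - 1];
      g_dec_W[i] = inp.t() * g;
      g_dec_B[i] = arma::sum(g, 0);
      g = g * dec_W[i].t();
      if (i > 0) relu_mask(g, dh[i - 1]);
    }
    arma::mat gmu = g + mu / nn;
    arma::mat glv = g % eps % s * 0.5 + 0.5 * (arma::exp(lv) - 1.0) / nn;

    const arma::mat& top = eh[n_enc - 1];
    arma::mat g_mu_W = top.t() * gmu, g_mu_B = arma::sum(gmu, 0);
    arma::mat g_lv_W = top.t() * glv, g_lv_B = arma::sum(glv, 0);
    g = gmu * mu_W.t() + glv * lv_W.t();
    relu_mask(g, top);
    std::vector<arma::mat> g_enc_W(n_enc), g_enc_B(n_enc);
    for (int i = (int)n_enc - 1; i >= 0; --i) {
      const arma::mat& inp = (i == 0) ? x : eh[i - 1];
      g_enc_W[i] = inp.t() * g;
      g_enc_B[i] = arma::sum(g, 0);
      if (i > 0) {
        g = g * enc_W[i].t();
        relu_mask(g, eh[i - 1]);
      }
    }

    std::vector<arma::mat> gs;
    for (size_t i = 0; i < n_enc; ++i) { gs.push_back(g_enc_W[i]); gs.push_back(g_enc_B[i]); }
    gs.push_back(g_mu_W); gs.push_back(g_mu_B);
    gs.push_back(g_lv_W); gs.push_back(g_lv_B);
    for (size_t i = 0; i < n_dec; ++i) { gs.push_back(g_dec_W[i]); gs.push_back(g_dec_B[i]); }
    opt.step(ps, gs, lr);
  }

  List enc_W_out(n_enc), enc_b_out(n_enc), dec_W_out(n_dec), dec_b_out(n_dec);
  for (size_t i = 0; i < n_enc; ++i) {
    enc_W_out[i] = enc_W[i];
    enc_b_out[i] = NumericVector(enc_B[i].begin(), enc_B[i].end());
  }
  for (size_t i = 0; i < n_dec; ++i) {
    dec_W_out[i] = dec_W[i];
    dec_b_out[i] = NumericVector(dec_B[i].begin(), dec_B[i].end());
  }
  return List::create(_["enc_W"] = enc_W_out, _["enc_b"] = enc_b_out,
                      _["mu_W"] = mu_W,
                      _["mu_b"] = NumericVector(mu_B.begin(), mu_B.end()),
                      _["lv_W"] = lv_W,
                      _["lv_b"] = NumericVector(lv_B.begin(), lv_B.end()),
                      _["dec_W"] = dec_W_out, _["dec_b"] = dec_b_out,
                      _["total"] = h_total, _["recon"] = h_recon,
                      _["kl"] = h_kl);
}
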