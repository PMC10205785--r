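// Graph attention autoencoder trainer.
//
// Architecture (2-layer encoder / 2-layer decoder, mirrored dims):
//   enc L1 (attention): h1_u = ELU( sum_{v in N_u} a_uv W1 h0_v + b1 )
//   enc L2 (dense)    : h2_u = ELU( W2 h1_u + b2 )
//   dec L1 (dense)    : d1_u = ELU( V1 h2_u + c1 )
//   dec L2 (attention): d2_u = ELU( sum_{v in N_u} a'_uv V2 d1_v + c2 )
// Attention coefficients: softmax over N_u of sigmoid(a^T [W h_u (+) W h_v]).
// Loss: mean squared reconstruction error against the input features.
// Optimiser: Adam with L2 weight decay added to the gradients.
//
// All training arithmetic is single precision; matrices are held
// feature-major (features x spots) so BLAS sees contiguous columns.
// The run is fully deterministic given the initial parameters.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

inline fmat elu(const fmat& x) {
  fmat y = x;
  y.transform([](float v) { return v > 0.0f ? v : std::expm1(v); });
  return y;
}

// ELU'(pre) expressed through the activation: 1 where act > 0, act + 1
// otherwise (ELU is monotone, so act > 0 iff pre > 0). Avoids a second
// pass of exp calls.
inline fmat elu_deriv_from_act(const fmat& act) {
  fmat y = act;
  y.transform([](float v) { return v > 0.0f ? 1.0f : v + 1.0f; });
  return y;
}

struct AdamState {
  fmat m, v;
  explicit AdamState(const fmat& p) : m(size(p), fill::zeros),
                                      v(size(p), fill::zeros) {}
};

struct Adam {
  float lr, wd, b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  int t = 0;
  std::vector<fmat*> params;
  std::vector<AdamState> state;
  Adam(float lr_, float wd_) : lr(lr_), wd(wd_) {}
  void add(fmat& p) { params.push_back(&p); state.emplace_back(p); }
  void step(const std::vector<fmat>& grads) {
    ++t;
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < params.size(); ++i) {
      fmat g = grads[i] + wd * (*params[i]);
      AdamState& s = state[i];
      s.m = b1 * s.m + (1.0f - b1) * g;
      s.v = b2 * s.v + (1.0f - b2) * square(g);
      *params[i] -= lr * (s.m / c1) / (sqrt(s.v / c2) + eps);
    }
  }
};

// Per-edge attention coefficients for one layer.
// Z: features x spots projected input; ah/at: head/tail halves of the
// attention vector. Returns per-edge alpha (CSR order) and, optionally,
// the per-edge sigmoid scores for the backward pass.
void attention_forward(const fmat& Z, const fvec& ah, const fvec& at,
                       const ivec& ptr, const ivec& idx,
                       fvec& alpha, fvec& sig, double& max_dev) {
  const frowvec p = ah.t() * Z;
  const frowvec q = at.t() * Z;
  const uword n = Z.n_cols;
  for (uword u = 0; u < n; ++u) {
    double den = 0.0;
    for (int j = ptr[u]; j < ptr[u + 1]; ++j) {
      const float r = p[u] + q[idx[j]];
      const float e = 1.0f / (1.0f + std::exp(-r));
      sig[j] = e;
      alpha[j] = std::exp(e);
      den += alpha[j];
    }
    double chk = 0.0;
    for (int j = ptr[u]; j < ptr[u + 1]; ++j) {
      alpha[j] = (float)(alpha[j] / den);
      chk += alpha[j];
    }
    const double dev = std::abs(chk - 1.0);
    if (dev > max_dev) max_dev = dev;
  }
}

// S.col(u) = sum_j alpha_uj Z.col(v_j)
void aggregate(const fmat& Z, const fvec& alpha, const ivec& ptr,
               const ivec& idx, fmat& S) {
  S.zeros(Z.n_rows, Z.n_cols);
  for (uword u = 0; u < Z.n_cols; ++u)
    for (int j = ptr[u]; j < ptr[u + 1]; ++j)
      S.col(u) += alpha[j] * Z.col(idx[j]);
}

// Backward through aggregation + softmax + sigmoid + score.
// dS: gradient at the aggregated pre-bias output. On return dZ holds the
// full gradient w.r.t. Z (aggregation + attention paths) and dah/dat the
// attention-vector gradients.
void attention_backward(const fmat& Z, const fvec& alpha, const fvec& sig,
                        const fvec& ah, const fvec& at,
                        const ivec& ptr, const ivec& idx, const fmat& dS,
                        fmat& dZ, fvec& dah, fvec& dat) {
  const uword n = Z.n_cols;
  dZ.zeros(size(Z));
  fvec dalpha(alpha.n_elem);
  for (uword u = 0; u < n; ++u)
    for (int j = ptr[u]; j < ptr[u + 1]; ++j) {
      dZ.col(idx[j]) += alpha[j] * dS.col(u);
      dalpha[j] = dot(dS.col(u), Z.col(idx[j]));
    }
  fvec dp(n, fill::zeros), dq(n, fill::zeros);
  for (uword u = 0; u < n; ++u) {
    double s = 0.0;
    for (int j = ptr[u]; j < ptr[u + 1]; ++j) s += alpha[j] * dalpha[j];
    for (int j = ptr[u]; j < ptr[u + 1]; ++j) {
      const float de = alpha[j] * (dalpha[j] - (float)s);
      const float dr = de * sig[j] * (1.0f - sig[j]);
      dp[u] += dr;
      dq[idx[j]] += dr;
    }
  }
  dah = Z * dp;
  dat = Z * dq;
  dZ += ah * dp.t() + at * dq.t();
}

} // namespace

// [[Rcpp::export(name = ".adept_train_gae")]]
Rcpp::List adept_train_gae(const arma::mat& X, const arma::ivec& nbr_ptr,
                           const arma::ivec& nbr_idx, Rcpp::List par,
                           double lr, double weight_decay, int max_iter,
                           double tol, int tol_window,
                           bool check_attention) {
  const fmat Xt = conv_to<fmat>::from(X.t());   // genes x spots
  const uword g = Xt.n_rows, n = Xt.n_cols;
  const ivec& ptr = nbr_ptr;
  const ivec& idx = nbr_idx;
  const uword ne = idx.n_elem;

  fmat W1 = conv_to<fmat>::from(Rcpp::as<arma::mat>(par["W1"]));
  fmat a1 = conv_to<fmat>::from(Rcpp::as<arma::mat>(par["a1"]));
  fmat b1 = conv_to<fmat>::from(Rcpp::as<arma::mat>(par["b1"]));
  fmat W2 = conv_to<fmat>::from(Rcpp::as<arma::mat>(par["W2"]));
  fmat b2 = conv_to<fmat>::from(Rcpp::as<arma::mat>(par["b2"]));
  fmat V1 = conv_to<fmat>::from(Rcpp::as<arma::mat>(par["V1"]));
  fmat c1 = conv_to<fmat>::from(Rcpp::as<arma::mat>(par["c1"]));
  fmat V2 = conv_to<fmat>::from(Rcpp::as<arma::mat>(par["V2"]));
  fmat a2 = conv_to<fmat>::from(Rcpp::as<arma::mat>(par["a2"]));
  fmat c2 = conv_to<fmat>::from(Rcpp::as<arma::mat>(par["c2"]));
  const uword h = W1.n_rows, l = W2.n_rows;

  Adam opt((float)lr, (float)weight_decay);
  opt.add(W1); opt.add(a1); opt.add(b1); opt.add(W2); opt.add(b2);
  opt.add(V1); opt.add(c1); opt.add(V2); opt.add(a2); opt.add(c2);

  std::vector<double> loss_hist, att_dev;
  fvec alpha1(ne), sig1(ne), alpha2(ne), sig2(ne);
  fmat Z1, S1, H1, P2, H2, P3, D1, Z2, S2, D2;
  const float inv_ng = 1.0f / (float)(n * g);

  auto forward = [&](double& dev) {
    Z1 = W1 * Xt;
    attention_forward(Z1, a1.col(0).head(h), a1.col(0).tail(h), ptr, idx,
                      alpha1, sig1, dev);
    aggregate(Z1, alpha1, ptr, idx, S1);
    S1.each_col() += b1.col(0);
    H1 = elu(S1);
    P2 = W2 * H1;  P2.each_col() += b2.col(0);
    H2 = elu(P2);
    P3 = V1 * H2;  P3.each_col() += c1.col(0);
    D1 = elu(P3);
    Z2 = V2 * D1;
    attention_forward(Z2, a2.col(0).head(g), a2.col(0).tail(g), ptr, idx,
                      alpha2, sig2, dev);
    aggregate(Z2, alpha2, ptr, idx, S2);
    S2.each_col() += c2.col(0);
    D2 = elu(S2);
    return (double)accu(square(D2 - Xt)) * inv_ng;
  };

  int it = 0;
  for (; it < max_iter; ++it) {
    double dev = 0.0;
    const double loss = forward(dev);
    if (!std::isfinite(loss))
      Rcpp::stop("reconstruction loss became non-finite at iteration %d",
                 it + 1);
    loss_hist.push_back(loss);
    if (check_attention) att_dev.push_back(dev);

    // backward
    fmat G = 2.0f * inv_ng * (D2 - Xt);
    fmat dS2 = G % elu_deriv_from_act(D2);
    fmat dc2 = sum(dS2, 1);
    fmat dZ2;
    fvec da2h, da2t;
    attention_backward(Z2, alpha2, sig2, a2.col(0).head(g),
                       a2.col(0).tail(g), ptr, idx, dS2, dZ2, da2h, da2t);
    fmat dV2 = dZ2 * D1.t();
    fmat dD1 = V2.t() * dZ2;
    fmat dP3 = dD1 % elu_deriv_from_act(D1);
    fmat dc1 = sum(dP3, 1);
    fmat dV1 = dP3 * H2.t();
    fmat dH2 = V1.t() * dP3;
    fmat dP2 = dH2 % elu_deriv_from_act(H2);
    fmat db2 = sum(dP2, 1);
    fmat dW2 = dP2 * H1.t();
    fmat dH1 = W2.t() * dP2;
    fmat dS1 = dH1 % elu_deriv_from_act(H1);
    fmat db1 = sum(dS1, 1);
    fmat dZ1;
    fvec da1h, da1t;
    attention_backward(Z1, alpha1, sig1, a1.col(0).head(h),
                       a1.col(0).tail(h), ptr, idx, dS1, dZ1, da1h, da1t);
    fmat dW1 = dZ1 * Xt.t();
    fmat da1 = join_cols(fmat(da1h), fmat(da1t));
    fmat da2 = join_cols(fmat(da2h), fmat(da2t));

    opt.step({dW1, da1, db1, dW2, db2, dV1, dc1, dV2, da2, dc2});

    // convergence: relative improvement of the loss over a trailing window
    const int w = tol_window;
    if (tol > 0 && (int)loss_hist.size() > w) {
      const double prev = loss_hist[loss_hist.size() - 1 - w];
      if (prev - loss < tol * std::max(prev, 1e-12)) { ++it; break; }
    }
  }

  // final forward with the updated parameters so that the returned
  // embedding/reconstruction match the returned weights exactly
  double dev = 0.0;
  const double final_loss = forward(dev);
  loss_hist.push_back(final_loss);
  if (check_attention) att_dev.push_back(dev);

  return Rcpp::List::create(
    Rcpp::Named("params") = Rcpp::List::create(
      Rcpp::Named("W1") = conv_to<mat>::from(W1),
      Rcpp::Named("a1") = conv_to<mat>::from(a1),
      Rcpp::Named("b1") = conv_to<mat>::from(b1),
      Rcpp::Named("W2") = conv_to<mat>::from(W2),
      Rcpp::Named("b2") = conv_to<mat>::from(b2),
      Rcpp::Named("V1") = conv_to<mat>::from(V1),
      Rcpp::Named("c1") = conv_to<mat>::from(c1),
      Rcpp::Named("V2") = conv_to<mat>::from(V2),
      Rcpp::Named("a2") = conv_to<mat>::from(a2),
      Rcpp::Named("c2") = conv_to<mat>::from(c2)),
    Rcpp::Named("embedding") = conv_to<mat>::from(H2.t()),
    Rcpp::Named("reconstruction") = conv_to<mat>::from(D2.t()),
    Rcpp::Named("loss_history") = loss_hist,
    Rcpp::Named("attention_deviation") = att_dev,
    Rcpp::Named("iterations") = it);
}
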