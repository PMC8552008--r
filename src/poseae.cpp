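// Feed-forward pose autoencoder: full-batch forward/backward with batch
// normalization in the encoder. Mirrors the reference R implementation
// (pose_ae_forward / pose_ae_backward), which the test suite checks it
// against; this version exists because full-batch training over several
// thousand poses is gemm-bound and benefits from staying in compiled code.
//
// Parameter list layout (flat, named):
//   encW1..3, encG1..3 (gamma), encB1..3 (beta),
//   latW, latb, decW1..3, decb1..3, outW, outb

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-5;

static inline mat relu(const mat& x) {
  mat y = x;
  y.elem(find(x < 0)).zeros();
  return y;
}

// [[Rcpp::export]]
Rcpp::List poseae_loss_grad(const Rcpp::List& params, const arma::mat& X) {
  const int L = Rcpp::as<int>(params["n_hidden"]);
  std::vector<mat> encW(L), decW(L);
  std::vector<rowvec> encG(L), encB(L), decb(L);
  for (int l = 0; l < L; ++l) {
    std::string s = std::to_string(l + 1);
    encW[l] = Rcpp::as<mat>(params["encW" + s]);
    encG[l] = Rcpp::as<rowvec>(params["encG" + s]);
    encB[l] = Rcpp::as<rowvec>(params["encB" + s]);
    decW[l] = Rcpp::as<mat>(params["decW" + s]);
    decb[l] = Rcpp::as<rowvec>(params["decb" + s]);
  }
  mat latW = Rcpp::as<mat>(params["latW"]);
  rowvec latb = Rcpp::as<rowvec>(params["latb"]);
  mat outW = Rcpp::as<mat>(params["outW"]);
  rowvec outb = Rcpp::as<rowvec>(params["outb"]);

  const uword n = X.n_rows, d = X.n_cols;
  // ---- forward ----
  std::vector<mat> a_in(L), zhat(L), h(L);
  std::vector<rowvec> inv(L), bmean(L), bvar(L);
  std::vector<mat> bnout(L);
  mat a = X;
  for (int l = 0; l < L; ++l) {
    a_in[l] = a;
    mat z = a * encW[l];
    bmean[l] = mean(z, 0);
    bvar[l] = mean(square(z), 0) - square(bmean[l]);
    inv[l] = 1.0 / sqrt(bvar[l] + BN_EPS);
    mat zc = z.each_row() - bmean[l];
    zhat[l] = zc.each_row() % inv[l];
    mat bo = zhat[l].each_row() % encG[l];
    bo.each_row() += encB[l];
    bnout[l] = bo;
    h[l] = relu(bo);
    a = h[l];
  }
  mat lat_in = a;
  mat latent = a * latW;
  latent.each_row() += latb;
  a = latent;
  std::vector<mat> d_in(L), dz_pre(L);
  for (int l = 0; l < L; ++l) {
    d_in[l] = a;
    mat z = a * decW[l];
    z.each_row() += decb[l];
    dz_pre[l] = z;
    a = relu(z);
  }
  mat out_in = a;
  mat y = a * outW;
  y.each_row() += outb;

  mat resid = y - X;
  double loss = accu(square(resid)) / double(n * d);

  // ---- backward ----
  Rcpp::List grads;
  mat dy = 2.0 * resid / double(n * d);
  grads["outW"] = mat(out_in.t() * dy);
  grads["outb"] = vec(sum(dy, 0).t());
  mat da = dy * outW.t();
  for (int l = L - 1; l >= 0; --l) {
    mat dz = da;
    dz.elem(find(dz_pre[l] <= 0)).zeros();
    std::string s = std::to_string(l + 1);
    grads["decW" + s] = mat(d_in[l].t() * dz);
    grads["decb" + s] = vec(sum(dz, 0).t());
    da = dz * decW[l].t();
  }
  grads["latW"] = mat(lat_in.t() * da);
  grads["latb"] = vec(sum(da, 0).t());
  da = da * latW.t();
  for (int l = L - 1; l >= 0; --l) {
    mat dbn = da;
    dbn.elem(find(bnout[l] <= 0)).zeros();
    rowvec dgamma = sum(dbn % zhat[l], 0);
    rowvec dbeta = sum(dbn, 0);
    mat dzhat = dbn.each_row() % encG[l];
    // batchnorm backward with population batch statistics
    mat t1 = dzhat.each_row() - mean(dzhat, 0);
    mat t2 = zhat[l].each_row() % mean(dzhat % zhat[l], 0);
    mat dz = t1 - t2;
    dz.each_row() %= inv[l];
    std::string s = std::to_string(l + 1);
    grads["encW" + s] = mat(a_in[l].t() * dz);
    grads["encG" + s] = vec(dgamma.t());
    grads["encB" + s] = vec(dbeta.t());
    da = dz * encW[l].t();
  }

  Rcpp::List bstats;
  for (int l = 0; l < L; ++l) {
    std::string s = std::to_string(l + 1);
    bstats["m" + s] = vec(bmean[l].t());
    bstats["v" + s] = vec(bvar[l].t());
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads,
                            Rcpp::Named("bn") = bstats);
}

// Encoder in inference mode: frozen batch-norm statistics.
// [[Rcpp::export]]
arma::mat poseae_encode_cpp(const Rcpp::List& params, const arma::mat& X,
                            const Rcpp::List& bn_stats) {
  const int L = Rcpp::as<int>(params["n_hidden"]);
  mat a = X;
  for (int l = 0; l < L; ++l) {
    std::string s = std::to_string(l + 1);
    mat W = Rcpp::as<mat>(params["encW" + s]);
    rowvec g = Rcpp::as<rowvec>(params["encG" + s]);
    rowvec b = Rcpp::as<rowvec>(params["encB" + s]);
    Rcpp::List st = bn_stats[l];
    rowvec m = Rcpp::as<rowvec>(st["m"]);
    rowvec v = Rcpp::as<rowvec>(st["v"]);
    mat z = a * W;
    z.each_row() -= m;
    z.each_row() %= (1.0 / sqrt(v + BN_EPS));
    z.each_row() %= g;
    z.each_row() += b;
    a = relu(z);
  }
  mat latent = a * Rcpp::as<mat>(params["latW"]);
  latent.each_row() += Rcpp::as<rowvec>(params["latb"]);
  return latent;
}

// [[Rcpp::export]]
arma::mat poseae_decode_cpp(const Rcpp::List& params, const arma::mat& Z) {
  const int L = Rcpp::as<int>(params["n_hidden"]);
  mat a = Z;
  for (int l = 0; l < L; ++l) {
    std::string s = std::to_string(l + 1);
    mat z = a * Rcpp::as<mat>(params["decW" + s]);
    z.each_row() += Rcpp::as<rowvec>(params["decb" + s]);
    a = relu(z);
  }
  mat y = a * Rcpp::as<mat>(params["outW"]);
  y.each_row() += Rcpp::as<rowvec>(params["outb"]);
  return y;
}
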