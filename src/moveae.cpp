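// Bidirectional-LSTM sequence autoencoder: forward pass, backpropagation
// through time, and inference entry points. The training loop, optimizer
// and all random number generation live in R; this file is deterministic
// numerics only.
//
// Layout conventions: a batch of windows is an arma::cube with
// rows = batch, cols = channels/features, slices = timesteps.
// Gate order within the 4H-wide LSTM weight blocks: input, forget,
// cell candidate, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static inline mat relu(const mat& x) {
  mat y = x;
  y.elem(find(x < 0)).zeros();
  return y;
}

struct LstmCache {
  cube cat;    // B x (Din+H) x T : [x_t, h_{t-1}]
  cube gates;  // B x 4H x T     : activated i, f, g, o
  cube cst;    // B x H x T      : cell states
  cube tanhc;  // B x H x T      : tanh(cell states)
};

// One-direction LSTM over all timesteps. Returns hidden states B x H x T.
static cube lstm_forward(const cube& X, const mat& W, const rowvec& b,
                         LstmCache& cache) {
  const uword B = X.n_rows, Din = X.n_cols, T = X.n_slices;
  const uword H = W.n_cols / 4;
  cache.cat.set_size(B, Din + H, T);
  cache.gates.set_size(B, 4 * H, T);
  cache.cst.set_size(B, H, T);
  cache.tanhc.set_size(B, H, T);
  cube Hout(B, H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat cat(B, Din + H);
    cat.cols(0, Din - 1) = X.slice(t);
    cat.cols(Din, Din + H - 1) = h;
    mat z = cat * W;
    z.each_row() += b;
    mat i = sigmoid(z.cols(0, H - 1));
    mat f = sigmoid(z.cols(H, 2 * H - 1));
    mat g = tanh(z.cols(2 * H, 3 * H - 1));
    mat o = sigmoid(z.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    mat tc = tanh(c);
    h = o % tc;
    cache.cat.slice(t) = cat;
    cache.gates.slice(t).cols(0, H - 1) = i;
    cache.gates.slice(t).cols(H, 2 * H - 1) = f;
    cache.gates.slice(t).cols(2 * H, 3 * H - 1) = g;
    cache.gates.slice(t).cols(3 * H, 4 * H - 1) = o;
    cache.cst.slice(t) = c;
    cache.tanhc.slice(t) = tc;
    Hout.slice(t) = h;
  }
  return Hout;
}

// Backprop through one direction. dHout holds gradients flowing into each
// h_t from downstream consumers (not the recurrence). Returns dX.
static cube lstm_backward(const cube& dHout, const mat& W,
                          const LstmCache& cache, mat& dW, rowvec& db) {
  const uword B = dHout.n_rows, H = dHout.n_cols, T = dHout.n_slices;
  const uword Din = cache.cat.n_cols - H;
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(4 * H);
  cube dX(B, Din, T);
  mat dh_rec(B, H, fill::zeros), dc_rec(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    mat i = cache.gates.slice(tt).cols(0, H - 1);
    mat f = cache.gates.slice(tt).cols(H, 2 * H - 1);
    mat g = cache.gates.slice(tt).cols(2 * H, 3 * H - 1);
    mat o = cache.gates.slice(tt).cols(3 * H, 4 * H - 1);
    mat tc = cache.tanhc.slice(tt);
    mat c_prev = (tt == 0) ? mat(B, H, fill::zeros) : cache.cst.slice(tt - 1);
    mat dh = dHout.slice(tt) + dh_rec;
    mat dc = dc_rec + dh % o % (1.0 - tc % tc);
    mat dz(B, 4 * H);
    dz.cols(0, H - 1) = dc % g % i % (1.0 - i);
    dz.cols(H, 2 * H - 1) = dc % c_prev % f % (1.0 - f);
    dz.cols(2 * H, 3 * H - 1) = dc % i % (1.0 - g % g);
    dz.cols(3 * H, 4 * H - 1) = dh % tc % o % (1.0 - o);
    dW += cache.cat.slice(tt).t() * dz;
    db += sum(dz, 0);
    mat dcat = dz * W.t();
    dX.slice(tt) = dcat.cols(0, Din - 1);
    dh_rec = dcat.cols(Din, Din + H - 1);
    dc_rec = dc % f;
  }
  return dX;
}

static cube reverse_time(const cube& X) {
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t) Y.slice(t) = X.slice(X.n_slices - 1 - t);
  return Y;
}

struct BiCache {
  LstmCache fwd, bwd;
};

// Bidirectional layer: concatenated hidden states B x 2H x T.
static cube bilstm_forward(const cube& X, const mat& Wf, const rowvec& bf,
                           const mat& Wb, const rowvec& bb, BiCache& cache) {
  cube Hf = lstm_forward(X, Wf, bf, cache.fwd);
  cube Hb = reverse_time(lstm_forward(reverse_time(X), Wb, bb, cache.bwd));
  const uword H = Hf.n_cols;
  cube O(X.n_rows, 2 * H, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t) {
    O.slice(t).cols(0, H - 1) = Hf.slice(t);
    O.slice(t).cols(H, 2 * H - 1) = Hb.slice(t);
  }
  return O;
}

static cube bilstm_backward(const cube& dO, const mat& Wf, const mat& Wb,
                            const BiCache& cache, mat& dWf, rowvec& dbf,
                            mat& dWb, rowvec& dbb) {
  const uword H = dO.n_cols / 2, T = dO.n_slices, B = dO.n_rows;
  cube dHf(B, H, T), dHb(B, H, T);
  for (uword t = 0; t < T; ++t) {
    dHf.slice(t) = dO.slice(t).cols(0, H - 1);
    dHb.slice(t) = dO.slice(t).cols(H, 2 * H - 1);
  }
  cube dXf = lstm_backward(dHf, Wf, cache.fwd, dWf, dbf);
  cube dXb = reverse_time(lstm_backward(reverse_time(dHb), Wb, cache.bwd,
                                        dWb, dbb));
  return dXf + dXb;
}

// ---- parameter unpacking -------------------------------------------------

struct Params {
  mat W_in, e1f_W, e1b_W, e2f_W, e2b_W, W_mid, W_lat;
  mat d1f_W, d1b_W, d2f_W, d2b_W, W_td, W_out;
  rowvec b_in, e1f_b, e1b_b, e2f_b, e2b_b, b_mid, b_lat;
  rowvec d1f_b, d1b_b, d2f_b, d2b_b, b_td, b_out;
};

static Params unpack(const Rcpp::List& p) {
  Params q;
  q.W_in = Rcpp::as<mat>(p["W_in"]);     q.b_in = Rcpp::as<rowvec>(p["b_in"]);
  q.e1f_W = Rcpp::as<mat>(p["enc1f_W"]); q.e1f_b = Rcpp::as<rowvec>(p["enc1f_b"]);
  q.e1b_W = Rcpp::as<mat>(p["enc1b_W"]); q.e1b_b = Rcpp::as<rowvec>(p["enc1b_b"]);
  q.e2f_W = Rcpp::as<mat>(p["enc2f_W"]); q.e2f_b = Rcpp::as<rowvec>(p["enc2f_b"]);
  q.e2b_W = Rcpp::as<mat>(p["enc2b_W"]); q.e2b_b = Rcpp::as<rowvec>(p["enc2b_b"]);
  q.W_mid = Rcpp::as<mat>(p["W_mid"]);   q.b_mid = Rcpp::as<rowvec>(p["b_mid"]);
  q.W_lat = Rcpp::as<mat>(p["W_lat"]);   q.b_lat = Rcpp::as<rowvec>(p["b_lat"]);
  q.d1f_W = Rcpp::as<mat>(p["dec1f_W"]); q.d1f_b = Rcpp::as<rowvec>(p["dec1f_b"]);
  q.d1b_W = Rcpp::as<mat>(p["dec1b_W"]); q.d1b_b = Rcpp::as<rowvec>(p["dec1b_b"]);
  q.d2f_W = Rcpp::as<mat>(p["dec2f_W"]); q.d2f_b = Rcpp::as<rowvec>(p["dec2f_b"]);
  q.d2b_W = Rcpp::as<mat>(p["dec2b_W"]); q.d2b_b = Rcpp::as<rowvec>(p["dec2b_b"]);
  q.W_td = Rcpp::as<mat>(p["W_td"]);     q.b_td = Rcpp::as<rowvec>(p["b_td"]);
  q.W_out = Rcpp::as<mat>(p["W_out"]);   q.b_out = Rcpp::as<rowvec>(p["b_out"]);
  return q;
}

// Encoder forward to the latent codes. Caches are filled when `keep` is
// true (training); the per-timestep dense activations are returned via
// the out-parameters either way.
struct EncCache {
  cube A;        // B x D x T   relu'd time-distributed input dense
  cube X3;       // pre-relu of A
  cube O1, O2;   // bilstm outputs
  BiCache c1, c2;
  mat S, Mpre, M;  // summary, mid pre-activation, mid relu
};

static mat encoder_forward(const Params& q, const cube& X, EncCache& ec) {
  const uword B = X.n_rows, T = X.n_slices;
  const uword D = q.W_in.n_cols;
  ec.X3.set_size(B, D, T);
  ec.A.set_size(B, D, T);
  for (uword t = 0; t < T; ++t) {
    mat z = X.slice(t) * q.W_in;
    z.each_row() += q.b_in;
    ec.X3.slice(t) = z;
    ec.A.slice(t) = relu(z);
  }
  ec.O1 = bilstm_forward(ec.A, q.e1f_W, q.e1f_b, q.e1b_W, q.e1b_b, ec.c1);
  ec.O2 = bilstm_forward(ec.O1, q.e2f_W, q.e2f_b, q.e2b_W, q.e2b_b, ec.c2);
  const uword H = q.e2f_W.n_cols / 4;
  // summary: forward direction's last state, backward direction's state
  // at the first timestep (its own final state)
  ec.S.set_size(B, 2 * H);
  ec.S.cols(0, H - 1) = ec.O2.slice(T - 1).cols(0, H - 1);
  ec.S.cols(H, 2 * H - 1) = ec.O2.slice(0).cols(H, 2 * H - 1);
  ec.Mpre = ec.S * q.W_mid;
  ec.Mpre.each_row() += q.b_mid;
  ec.M = relu(ec.Mpre);
  mat Z = ec.M * q.W_lat;
  Z.each_row() += q.b_lat;
  return Z;
}

struct DecCache {
  cube Zrep;       // B x K x T
  cube O3, O4;     // bilstm outputs
  BiCache c3, c4;
  cube Gpre, G;    // time-distributed dense pre/post relu
};

static cube decoder_forward(const Params& q, const mat& Z, uword T,
                            DecCache& dc) {
  const uword B = Z.n_rows, K = Z.n_cols;
  dc.Zrep.set_size(B, K, T);
  for (uword t = 0; t < T; ++t) dc.Zrep.slice(t) = Z;
  dc.O3 = bilstm_forward(dc.Zrep, q.d1f_W, q.d1f_b, q.d1b_W, q.d1b_b, dc.c3);
  dc.O4 = bilstm_forward(dc.O3, q.d2f_W, q.d2f_b, q.d2b_W, q.d2b_b, dc.c4);
  const uword D = q.W_td.n_cols, C = q.W_out.n_cols;
  dc.Gpre.set_size(B, D, T);
  dc.G.set_size(B, D, T);
  cube Y(B, C, T);
  for (uword t = 0; t < T; ++t) {
    mat z = dc.O4.slice(t) * q.W_td;
    z.each_row() += q.b_td;
    dc.Gpre.slice(t) = z;
    dc.G.slice(t) = relu(z);
    mat y = dc.G.slice(t) * q.W_out;
    y.each_row() += q.b_out;
    Y.slice(t) = y;
  }
  return Y;
}

// ---- exported entry points ----------------------------------------------

// Mean-squared reconstruction loss and gradients for one mini-batch.
// X: cube with rows = batch, cols = channels, slices = timesteps.
// [[Rcpp::export]]
Rcpp::List moveae_loss_grad(const Rcpp::List& params, const arma::cube& X) {
  Params q = unpack(params);
  const uword B = X.n_rows, C = X.n_cols, T = X.n_slices;
  EncCache ec;
  DecCache dc;
  mat Z = encoder_forward(q, X, ec);
  cube Y = decoder_forward(q, Z, T, dc);
  const double denom = double(B) * double(C) * double(T);
  double loss = 0.0;
  cube dY(B, C, T);
  for (uword t = 0; t < T; ++t) {
    mat r = Y.slice(t) - X.slice(t);
    loss += accu(r % r);
    dY.slice(t) = 2.0 * r / denom;
  }
  loss /= denom;

  // ---- decoder backward ----
  const uword D = q.W_td.n_cols;
  const uword H2 = q.d2f_W.n_cols / 4;
  mat dW_out(size(q.W_out), fill::zeros), dW_td(size(q.W_td), fill::zeros);
  rowvec db_out(C, fill::zeros), db_td(D, fill::zeros);
  cube dO4(B, 2 * H2, T);
  for (uword t = 0; t < T; ++t) {
    dW_out += dc.G.slice(t).t() * dY.slice(t);
    db_out += sum(dY.slice(t), 0);
    mat dG = dY.slice(t) * q.W_out.t();
    dG.elem(find(dc.Gpre.slice(t) <= 0)).zeros();
    dW_td += dc.O4.slice(t).t() * dG;
    db_td += sum(dG, 0);
    dO4.slice(t) = dG * q.W_td.t();
  }
  mat dW_d2f, dW_d2b, dW_d1f, dW_d1b;
  rowvec db_d2f, db_d2b, db_d1f, db_d1b;
  cube dO3 = bilstm_backward(dO4, q.d2f_W, q.d2b_W, dc.c4,
                             dW_d2f, db_d2f, dW_d2b, db_d2b);
  cube dZrep = bilstm_backward(dO3, q.d1f_W, q.d1b_W, dc.c3,
                               dW_d1f, db_d1f, dW_d1b, db_d1b);
  mat dZ(B, Z.n_cols, fill::zeros);
  for (uword t = 0; t < T; ++t) dZ += dZrep.slice(t);

  // ---- encoder backward ----
  mat dM = dZ * q.W_lat.t();
  mat dW_lat = ec.M.t() * dZ;
  rowvec db_lat = sum(dZ, 0);
  dM.elem(find(ec.Mpre <= 0)).zeros();
  mat dS = dM * q.W_mid.t();
  mat dW_mid = ec.S.t() * dM;
  rowvec db_mid = sum(dM, 0);
  const uword H = q.e2f_W.n_cols / 4;
  cube dO2(B, 2 * H, T, fill::zeros);
  dO2.slice(T - 1).cols(0, H - 1) = dS.cols(0, H - 1);
  dO2.slice(0).cols(H, 2 * H - 1) = dS.cols(H, 2 * H - 1);
  mat dW_e2f, dW_e2b, dW_e1f, dW_e1b;
  rowvec db_e2f, db_e2b, db_e1f, db_e1b;
  cube dO1 = bilstm_backward(dO2, q.e2f_W, q.e2b_W, ec.c2,
                             dW_e2f, db_e2f, dW_e2b, db_e2b);
  cube dA = bilstm_backward(dO1, q.e1f_W, q.e1b_W, ec.c1,
                            dW_e1f, db_e1f, dW_e1b, db_e1b);
  mat dW_in(size(q.W_in), fill::zeros);
  rowvec db_in(q.W_in.n_cols, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat dAt = dA.slice(t);
    dAt.elem(find(ec.X3.slice(t) <= 0)).zeros();
    dW_in += X.slice(t).t() * dAt;
    db_in += sum(dAt, 0);
  }

  Rcpp::List grads = Rcpp::List::create(
    Rcpp::Named("W_in") = dW_in, Rcpp::Named("b_in") = vec(db_in.t()),
    Rcpp::Named("enc1f_W") = dW_e1f, Rcpp::Named("enc1f_b") = vec(db_e1f.t()),
    Rcpp::Named("enc1b_W") = dW_e1b, Rcpp::Named("enc1b_b") = vec(db_e1b.t()),
    Rcpp::Named("enc2f_W") = dW_e2f, Rcpp::Named("enc2f_b") = vec(db_e2f.t()),
    Rcpp::Named("enc2b_W") = dW_e2b, Rcpp::Named("enc2b_b") = vec(db_e2b.t()));
  grads["W_mid"] = dW_mid;  grads["b_mid"] = vec(db_mid.t());
  grads["W_lat"] = dW_lat;  grads["b_lat"] = vec(db_lat.t());
  grads["dec1f_W"] = dW_d1f; grads["dec1f_b"] = vec(db_d1f.t());
  grads["dec1b_W"] = dW_d1b; grads["dec1b_b"] = vec(db_d1b.t());
  grads["dec2f_W"] = dW_d2f; grads["dec2f_b"] = vec(db_d2f.t());
  grads["dec2b_W"] = dW_d2b; grads["dec2b_b"] = vec(db_d2b.t());
  grads["W_td"] = dW_td;     grads["b_td"] = vec(db_td.t());
  grads["W_out"] = dW_out;   grads["b_out"] = vec(db_out.t());

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}

// Latent codes for a batch of windows.
// [[Rcpp::export]]
arma::mat moveae_encode_cpp(const Rcpp::List& params, const arma::cube& X) {
  Params q = unpack(params);
  EncCache ec;
  return encoder_forward(q, X, ec);
}

// Reconstructions from latent codes; returns cube rows = batch,
// cols = channels, slices = timesteps.
// [[Rcpp::export]]
arma::cube moveae_decode_cpp(const Rcpp::List& params, const arma::mat& Z,
                             const int T) {
  Params q = unpack(params);
  DecCache dc;
  return decoder_forward(q, Z, (uword)T, dc);
}

// Reconstruction loss only (no gradients), for evaluation.
// [[Rcpp::export]]
double moveae_loss(const Rcpp::List& params, const arma::cube& X) {
  Params q = unpack(params);
  EncCache ec;
  DecCache dc;
  mat Z = encoder_forward(q, X, ec);
  cube Y = decoder_forward(q, Z, X.n_slices, dc);
  double loss = 0.0;
  for (uword t = 0; t < X.n_slices; ++t) {
    mat r = Y.slice(t) - X.slice(t);
    loss += accu(r % r);
  }
  return loss / (double(X.n_rows) * double(X.n_cols) * double(X.n_slices));
}
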