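// Fast path for the training loop: one epoch of minibatch forward/backward
// passes and Adam updates for GRU- and LSTM-family conversion models.
//
// This mirrors the reference implementation in R/train.R exactly: same
// equations, same batch-mean weighted cross-entropy gradient, same L2
// treatment (weight matrices only), same Adam.  All randomness (batch
// permutation, dropout masks) is drawn in R and passed in, so results are
// reproducible and the R and C++ paths can be compared directly in tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// A recurrent cell's parameters as parallel vectors of matrices and biases.
// GRU: W = {Wr, Ur, Wz, Uz, Wh, Uh}, b = {br, bz, bh}
// LSTM: W = {Wi, Ui, Wf, Uf, Wo, Uo, Wg, Ug}, b = {bi, bf, bo, bg}
struct CellP {
  bool gru;
  std::vector<mat> W;
  std::vector<vec> b;
};

static const char* GRU_W[] = {"Wr", "Ur", "Wz", "Uz", "Wh", "Uh"};
static const char* GRU_B[] = {"br", "bz", "bh"};
static const char* LSTM_W[] = {"Wi", "Ui", "Wf", "Uf", "Wo", "Uo", "Wg", "Ug"};
static const char* LSTM_B[] = {"bi", "bf", "bo", "bg"};

static CellP cell_from_list(const List& l, bool gru) {
  CellP c; c.gru = gru;
  int nw = gru ? 6 : 8, nb = gru ? 3 : 4;
  const char** wn = gru ? GRU_W : LSTM_W;
  const char** bn = gru ? GRU_B : LSTM_B;
  for (int i = 0; i < nw; ++i) c.W.push_back(Rcpp::as<mat>(l[wn[i]]));
  for (int i = 0; i < nb; ++i) c.b.push_back(Rcpp::as<vec>(l[bn[i]]));
  return c;
}

static List cell_to_list(const CellP& c) {
  List l;
  int nw = c.gru ? 6 : 8, nb = c.gru ? 3 : 4;
  const char** wn = c.gru ? GRU_W : LSTM_W;
  const char** bn = c.gru ? GRU_B : LSTM_B;
  for (int i = 0; i < nw; ++i) l[wn[i]] = c.W[(size_t)i];
  for (int i = 0; i < nb; ++i) l[bn[i]] = c.b[(size_t)i];
  return l;
}

static CellP zeros_like(const CellP& c) {
  CellP z; z.gru = c.gru;
  for (const mat& w : c.W) z.W.push_back(zeros<mat>(w.n_rows, w.n_cols));
  for (const vec& v : c.b) z.b.push_back(zeros<vec>(v.n_elem));
  return z;
}

// Per-step cache of a recurrent forward pass over a batch.
struct StepCache {
  mat x, h_prev;          // shared
  mat r, z, hc, rh;       // GRU
  mat i, f, o, g, tc, c_prev; // LSTM
};

struct CellRun {
  std::vector<StepCache> cache;
  mat h;  // final hidden state
};

static mat addb(mat a, const vec& b) { a.each_row() += b.t(); return a; }

static CellRun cell_forward(const CellP& p, const std::vector<mat>& X,
                            const mat* h0) {
  CellRun run;
  arma::uword N = X[0].n_rows, H = p.b[0].n_elem;
  mat h = h0 ? *h0 : zeros<mat>(N, H);
  mat cs = zeros<mat>(N, H); // LSTM cell state (decoder starts at zero)
  for (const mat& Xt : X) {
    StepCache sc;
    sc.x = Xt; sc.h_prev = h;
    if (p.gru) {
      sc.r = sigm(addb(Xt * p.W[0].t() + h * p.W[1].t(), p.b[0]));
      sc.z = sigm(addb(Xt * p.W[2].t() + h * p.W[3].t(), p.b[1]));
      sc.rh = sc.r % h;
      sc.hc = tanh(addb(Xt * p.W[4].t() + sc.rh * p.W[5].t(), p.b[2]));
      h = (1.0 - sc.z) % h + sc.z % sc.hc;
    } else {
      sc.c_prev = cs;
      sc.i = sigm(addb(Xt * p.W[0].t() + h * p.W[1].t(), p.b[0]));
      sc.f = sigm(addb(Xt * p.W[2].t() + h * p.W[3].t(), p.b[1]));
      sc.o = sigm(addb(Xt * p.W[4].t() + h * p.W[5].t(), p.b[2]));
      sc.g = tanh(addb(Xt * p.W[6].t() + h * p.W[7].t(), p.b[3]));
      cs = sc.f % cs + sc.i % sc.g;
      sc.tc = tanh(cs);
      h = sc.o % sc.tc;
    }
    run.cache.push_back(std::move(sc));
  }
  run.h = h;
  return run;
}

// Backpropagation through time; gradient enters at the final hidden state.
// Returns the gradient with respect to the initial hidden state.
static mat cell_backward(const CellP& p, const CellRun& run, mat dh,
                         CellP& g) {
  mat dc;
  if (!p.gru) dc = zeros<mat>(dh.n_rows, dh.n_cols);
  for (int t = (int)run.cache.size() - 1; t >= 0; --t) {
    const StepCache& sc = run.cache[(size_t)t];
    if (p.gru) {
      mat dz = dh % (sc.hc - sc.h_prev);
      mat dhc = dh % sc.z;
      mat dh_prev = dh % (1.0 - sc.z);
      mat da_h = dhc % (1.0 - sc.hc % sc.hc);
      g.W[4] += da_h.t() * sc.x;
      g.W[5] += da_h.t() * sc.rh;
      g.b[2] += sum(da_h, 0).t();
      mat drh = da_h * p.W[5];
      mat dr = drh % sc.h_prev;
      dh_prev += drh % sc.r;
      mat da_r = dr % sc.r % (1.0 - sc.r);
      g.W[0] += da_r.t() * sc.x;
      g.W[1] += da_r.t() * sc.h_prev;
      g.b[0] += sum(da_r, 0).t();
      dh_prev += da_r * p.W[1];
      mat da_z = dz % sc.z % (1.0 - sc.z);
      g.W[2] += da_z.t() * sc.x;
      g.W[3] += da_z.t() * sc.h_prev;
      g.b[1] += sum(da_z, 0).t();
      dh_prev += da_z * p.W[3];
      dh = dh_prev;
    } else {
      mat do_ = dh % sc.tc;
      mat dct = dc + dh % sc.o % (1.0 - sc.tc % sc.tc);
      mat di = dct % sc.g;
      mat df = dct % sc.c_prev;
      mat dg = dct % sc.i;
      dc = dct % sc.f;
      mat da_i = di % sc.i % (1.0 - sc.i);
      mat da_f = df % sc.f % (1.0 - sc.f);
      mat da_o = do_ % sc.o % (1.0 - sc.o);
      mat da_g = dg % (1.0 - sc.g % sc.g);
      g.W[0] += da_i.t() * sc.x; g.W[1] += da_i.t() * sc.h_prev;
      g.b[0] += sum(da_i, 0).t();
      g.W[2] += da_f.t() * sc.x; g.W[3] += da_f.t() * sc.h_prev;
      g.b[1] += sum(da_f, 0).t();
      g.W[4] += da_o.t() * sc.x; g.W[5] += da_o.t() * sc.h_prev;
      g.b[2] += sum(da_o, 0).t();
      g.W[6] += da_g.t() * sc.x; g.W[7] += da_g.t() * sc.h_prev;
      g.b[3] += sum(da_g, 0).t();
      dh = da_i * p.W[1] + da_f * p.W[3] + da_o * p.W[5] + da_g * p.W[7];
    }
  }
  return dh;
}

// [[Rcpp::export(rng = true)]]
List fit_loop_cpp(List enc_fwd, Rcpp::Nullable<List> enc_bwd,
                  Rcpp::Nullable<List> decoder, List head,
                  const arma::cube& X, const arma::mat& D,
                  const arma::vec& y,
                  const arma::imat& perms, int batch_size, double dropout,
                  bool gru, bool seq2seq, int horizon,
                  double lr, double alpha, double l2) {
  CellP ef = cell_from_list(enc_fwd, gru);
  bool bidir = enc_bwd.isNotNull();
  CellP eb; if (bidir) eb = cell_from_list(enc_bwd.get(), gru);
  CellP dec; if (seq2seq) dec = cell_from_list(decoder.get(), gru);
  mat W2 = head["W2"]; vec b2 = head["b2"];
  mat W1 = head["W1"]; vec b1v = head["b1"];

  CellP m_ef = zeros_like(ef), v_ef = zeros_like(ef);
  CellP m_eb, v_eb, m_dec, v_dec;
  if (bidir) { m_eb = zeros_like(eb); v_eb = zeros_like(eb); }
  if (seq2seq) { m_dec = zeros_like(dec); v_dec = zeros_like(dec); }
  mat mW2 = zeros<mat>(size(W2)), vW2 = zeros<mat>(size(W2));
  mat mW1 = zeros<mat>(size(W1)), vW1 = zeros<mat>(size(W1));
  vec mb2 = zeros<vec>(b2.n_elem), vb2 = zeros<vec>(b2.n_elem);
  vec mb1 = zeros<vec>(1), vb1 = zeros<vec>(1);

  arma::uword N = X.n_rows, T = X.n_cols, Fn = X.n_slices;
  arma::uword H = ef.b[0].n_elem;
  arma::uword latent = bidir ? 2 * H : H;
  bool use_drop = dropout > 0;

  const double b1a = 0.9, b2a = 0.999, eps = 1e-8;
  int step_t = 0;
  arma::uword nb = (N + batch_size - 1) / batch_size;
  int epochs = perms.n_cols;
  vec trace(static_cast<arma::uword>(epochs));

  for (int epoch = 0; epoch < epochs; ++epoch) {
  double ep_loss = 0.0;
  for (arma::uword bi = 0; bi < nb; ++bi) {
    arma::uword lo = bi * batch_size;
    arma::uword hi = std::min<arma::uword>(lo + batch_size, N) - 1;
    arma::uword n = hi - lo + 1;
    uvec idx(n);
    for (arma::uword k = 0; k < n; ++k)
      idx[k] = (arma::uword)perms(lo + k, epoch) - 1;

    std::vector<mat> Xs(T);
    for (arma::uword t = 0; t < T; ++t) {
      mat Xt(n, Fn);
      for (arma::uword f = 0; f < Fn; ++f) {
        for (arma::uword k = 0; k < n; ++k) Xt(k, f) = X(idx[k], t, f);
      }
      Xs[t] = std::move(Xt);
    }
    mat Db = D.n_cols ? D.rows(idx) : mat(n, 0);
    vec yb = y.elem(idx);

    // forward
    CellRun rf = cell_forward(ef, Xs, nullptr);
    CellRun rb;
    mat lat;
    if (bidir) {
      std::vector<mat> Xr(Xs.rbegin(), Xs.rend());
      rb = cell_forward(eb, Xr, nullptr);
      lat = join_rows(rf.h, rb.h);
    } else {
      lat = rf.h;
    }
    CellRun rd;
    if (seq2seq) {
      std::vector<mat> Z(static_cast<size_t>(horizon), zeros<mat>(n, 1));
      rd = cell_forward(dec, Z, &lat);
      lat = rd.h;
    }
    mat mask;
    if (use_drop) {
      // column-major draw order matches matrix(runif(n * latent), n, latent)
      mask.set_size(n, latent);
      for (arma::uword c = 0; c < latent; ++c)
        for (arma::uword k = 0; k < n; ++k)
          mask(k, c) = (unif_rand() >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
      lat = lat % mask;
    }
    mat inp = Db.n_cols ? join_rows(lat, Db) : lat;
    mat z2 = addb(inp * W2.t(), b2);
    mat r2 = z2; r2.elem(find(r2 < 0)).zeros();
    vec logits = r2 * W1.t() + b1v(0);
    vec p = 1.0 / (1.0 + exp(-logits));
    vec pc = clamp(p, 1e-7, 1.0 - 1e-7);
    ep_loss += -accu(alpha * yb % log(pc) +
                     (1.0 - alpha) * (1.0 - yb) % log(1.0 - pc));

    // backward
    vec dlogit = (-alpha * yb % (1.0 - pc) +
                  (1.0 - alpha) * (1.0 - yb) % pc) / (double)n;
    mat gW1 = dlogit.t() * r2;
    double gb1 = accu(dlogit);
    mat dr2 = dlogit * W1;
    mat dz2 = dr2 % conv_to<mat>::from(z2 > 0);
    mat gW2 = dz2.t() * inp;
    vec gb2 = sum(dz2, 0).t();
    mat dinp = dz2 * W2;
    mat dlat = dinp.cols(0, latent - 1);
    if (use_drop) dlat = dlat % mask;

    CellP g_ef = zeros_like(ef), g_eb, g_dec;
    if (bidir) g_eb = zeros_like(eb);
    if (seq2seq) {
      g_dec = zeros_like(dec);
      dlat = cell_backward(dec, rd, dlat, g_dec);
    }
    if (bidir) {
      cell_backward(ef, rf, dlat.cols(0, H - 1), g_ef);
      cell_backward(eb, rb, dlat.cols(H, 2 * H - 1), g_eb);
    } else {
      cell_backward(ef, rf, dlat, g_ef);
    }

    // L2 on weight matrices (not biases), matching the reference path
    if (l2 > 0) {
      for (size_t i = 0; i < ef.W.size(); ++i) g_ef.W[i] += 2.0 * l2 * ef.W[i];
      if (bidir)
        for (size_t i = 0; i < eb.W.size(); ++i)
          g_eb.W[i] += 2.0 * l2 * eb.W[i];
      if (seq2seq)
        for (size_t i = 0; i < dec.W.size(); ++i)
          g_dec.W[i] += 2.0 * l2 * dec.W[i];
      gW2 += 2.0 * l2 * W2;
      gW1 += 2.0 * l2 * W1;
    }

    // Adam
    step_t += 1;
    double c1 = 1.0 - std::pow(b1a, step_t), c2 = 1.0 - std::pow(b2a, step_t);
    auto upd = [&](mat& P, const mat& G, mat& M, mat& V) {
      M = b1a * M + (1.0 - b1a) * G;
      V = b2a * V + (1.0 - b2a) * (G % G);
      P -= lr * (M / c1) / (sqrt(V / c2) + eps);
    };
    auto updv = [&](vec& P, const vec& G, vec& M, vec& V) {
      M = b1a * M + (1.0 - b1a) * G;
      V = b2a * V + (1.0 - b2a) * (G % G);
      P -= lr * (M / c1) / (sqrt(V / c2) + eps);
    };
    auto upd_cell = [&](CellP& P, const CellP& G, CellP& M, CellP& V) {
      for (size_t i = 0; i < P.W.size(); ++i) upd(P.W[i], G.W[i], M.W[i], V.W[i]);
      for (size_t i = 0; i < P.b.size(); ++i) updv(P.b[i], G.b[i], M.b[i], V.b[i]);
    };
    upd_cell(ef, g_ef, m_ef, v_ef);
    if (bidir) upd_cell(eb, g_eb, m_eb, v_eb);
    if (seq2seq) upd_cell(dec, g_dec, m_dec, v_dec);
    upd(W2, gW2, mW2, vW2);
    updv(b2, gb2, mb2, vb2);
    upd(W1, gW1, mW1, vW1);
    vec gb1v(1); gb1v(0) = gb1;
    updv(b1v, gb1v, mb1, vb1);
  }
  trace(static_cast<arma::uword>(epoch)) = ep_loss;
  }

  List head_out = List::create(Named("W2") = W2, Named("b2") = b2,
                               Named("W1") = W1, Named("b1") = b1v);
  return List::create(
    Named("enc_fwd") = cell_to_list(ef),
    Named("enc_bwd") = bidir ? (SEXP)cell_to_list(eb) : R_NilValue,
    Named("decoder") = seq2seq ? (SEXP)cell_to_list(dec) : R_NilValue,
    Named("head") = head_out,
    Named("trace") = trace);
}
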