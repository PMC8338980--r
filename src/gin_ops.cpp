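// Fused GIN compute kernel.
//
// One call runs the whole network for a minibatch of subjects sharing a
// single weighted adjacency: one-hot expansion, K rounds of
// aggregate/combine (affine -> batch norm -> ReLU -> dropout -> affine
// -> batch norm), per-layer sum-pooling, concatenated linear readout,
// and (optionally) the full backward pass for parameter gradients
// and/or the gradient with respect to the one-hot input.  Keeping the
// layer caches inside the call avoids shuttling large activation
// matrices across the R boundary, which would otherwise dominate
// training time.
//
// Activations are (V*B) x C matrices with node index fastest within
// subject, so the aggregation is a single (V x V) * (V x B*C) product
// through a reshape view, and cost stays linear in the number of edges.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct BnCache {
  arma::mat xhat;
  arma::rowvec invsd, rm, rv;
};

static arma::mat bn_fwd(const arma::mat& X, const arma::rowvec& g,
                        const arma::rowvec& be, const arma::rowvec& rm,
                        const arma::rowvec& rv, bool training,
                        double momentum, double eps, BnCache& cache) {
  arma::rowvec mu, va;
  if (training) {
    mu = arma::mean(X, 0);
    va = arma::mean(arma::square(X), 0) - arma::square(mu);
    cache.rm = (1.0 - momentum) * rm + momentum * mu;
    cache.rv = (1.0 - momentum) * rv + momentum * va;
  } else {
    mu = rm;
    va = rv;
  }
  cache.invsd = 1.0 / arma::sqrt(va + eps);
  cache.xhat = X.each_row() - mu;
  cache.xhat.each_row() %= cache.invsd;
  arma::mat out = cache.xhat.each_row() % g;
  out.each_row() += be;
  return out;
}

static arma::mat bn_bwd(const arma::mat& dout, const BnCache& cache,
                        const arma::rowvec& g, bool training,
                        arma::rowvec& dg, arma::rowvec& dbe) {
  dg = arma::sum(dout % cache.xhat, 0);
  dbe = arma::sum(dout, 0);
  arma::mat dxhat = dout.each_row() % g;
  if (training) {
    double N = (double) dout.n_rows;
    arma::rowvec s1 = arma::sum(dxhat, 0) / N;
    arma::rowvec s2 = arma::sum(dxhat % cache.xhat, 0) / N;
    dxhat.each_row() -= s1;
    dxhat -= cache.xhat.each_row() % s2;
  }
  dxhat.each_row() %= cache.invsd;
  return dxhat;
}

// aggregation (A + (1+eps) I) applied to a flat (V*B x C) activation
static arma::mat aggregate(const arma::mat& M, const arma::mat& H,
                           int V, int B) {
  arma::mat Hv(const_cast<double*>(H.memptr()), V, B * H.n_cols, false);
  arma::mat R = M * Hv;
  return arma::mat(R.memptr(), V * B, H.n_cols);
}

// [[Rcpp::export]]
List cpp_gin_run(const IntegerMatrix& slots, const arma::mat& A,
                 const List& layers, const arma::vec& w, double b,
                 bool identity_mlp, bool batch_norm, bool training,
                 double momentum, double bn_eps,
                 const Nullable<List>& dropout_masks,
                 const Nullable<NumericVector>& labels,
                 bool want_grads, bool want_input_grad) {
  const int B = slots.nrow(), V = slots.ncol();
  const int K = layers.size();
  const bool backward = want_grads || want_input_grad;

  // one-hot input, (V*B) x 6
  arma::mat H0(V * B, 6, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int v = 0; v < V; ++v)
      H0(s * V + v, slots(s, v) - 1) = 1.0;

  std::vector<arma::mat> Ms(K), Hs(K + 1), Xs(K), P1s(K), Rs(K);
  std::vector<BnCache> bn1(K), bn2(K);
  std::vector<double> epses(K);
  Hs[0] = H0;

  List masks;
  bool use_mask = dropout_masks.isNotNull();
  if (use_mask) masks = dropout_masks.get();

  arma::uvec layer_dims(K);
  arma::mat G;  // B x sum C_k
  std::vector<arma::mat> Gk(K);
  for (int k = 0; k < K; ++k) {
    List ly = layers[k];
    double eps_k = as<double>(ly["eps"]);
    epses[k] = eps_k;
    Ms[k] = A + (1.0 + eps_k) * arma::eye(V, V);
    arma::mat X = aggregate(Ms[k], Hs[k], V, B);
    arma::mat Hn;
    if (identity_mlp) {
      Hn = X;
    } else {
      arma::mat W1 = as<arma::mat>(ly["W1"]);
      arma::rowvec b1 = as<arma::rowvec>(ly["b1"]);
      arma::mat W2 = as<arma::mat>(ly["W2"]);
      arma::rowvec b2 = as<arma::rowvec>(ly["b2"]);
      arma::mat Z1 = X * W1;
      Z1.each_row() += b1;
      arma::mat P1;
      if (batch_norm) {
        P1 = bn_fwd(Z1, as<arma::rowvec>(ly["g1"]), as<arma::rowvec>(ly["be1"]),
                    as<arma::rowvec>(ly["rm1"]), as<arma::rowvec>(ly["rv1"]),
                    training, momentum, bn_eps, bn1[k]);
      } else {
        P1 = Z1;
      }
      arma::mat R = arma::clamp(P1, 0.0, arma::datum::inf);
      if (use_mask) R %= as<arma::mat>(masks[k]);
      Hn = R * W2;
      Hn.each_row() += b2;
      if (batch_norm)
        Hn = bn_fwd(Hn, as<arma::rowvec>(ly["g2"]), as<arma::rowvec>(ly["be2"]),
                    as<arma::rowvec>(ly["rm2"]), as<arma::rowvec>(ly["rv2"]),
                    training, momentum, bn_eps, bn2[k]);
      if (backward) { Xs[k] = X; P1s[k] = P1; Rs[k] = R; }
    }
    if (backward && identity_mlp) Xs[k] = X;
    // per-subject sum-pooling
    arma::cube Hc(Hn.memptr(), V, B, Hn.n_cols, false);
    arma::mat g(B, Hn.n_cols);
    for (arma::uword c = 0; c < Hn.n_cols; ++c)
      g.col(c) = arma::sum(Hc.slice(c), 0).t();
    Gk[k] = g;
    layer_dims(k) = Hn.n_cols;
    Hs[k + 1] = Hn;
  }
  G = Gk[0];
  for (int k = 1; k < K; ++k) G = arma::join_rows(G, Gk[k]);
  arma::vec y = G * w + b;
  arma::vec p = 1.0 / (1.0 + arma::exp(-y));

  List out;
  out["y"] = NumericVector(y.begin(), y.end());
  out["p"] = NumericVector(p.begin(), p.end());
  out["G"] = G;
  out["layer_dims"] = IntegerVector(layer_dims.begin(), layer_dims.end());
  if (batch_norm && training) {
    List bn_new(K);
    for (int k = 0; k < K; ++k)
      bn_new[k] = List::create(_["rm1"] = bn1[k].rm, _["rv1"] = bn1[k].rv,
                               _["rm2"] = bn2[k].rm, _["rv2"] = bn2[k].rv);
    out["bn_new"] = bn_new;
  }
  if (!backward) return out;

  arma::vec dy;
  if (labels.isNotNull()) {
    // gradient of the mean binary cross-entropy at the sigmoid output
    NumericVector l(labels.get());
    dy = (p - arma::vec(l.begin(), l.size())) / (double) B;
  } else {
    dy = arma::vec(B, arma::fill::ones);   // gradient of the raw output
  }

  List layer_grads(K);
  arma::mat dG = dy * w.t();               // B x sum C_k
  arma::mat dH_next;
  int off_end = arma::accu(layer_dims);
  for (int k = K - 1; k >= 0; --k) {
    int Ck = layer_dims(k);
    int off = off_end - Ck;
    off_end = off;
    // readout contribution: every node of subject s receives dG[s, block k]
    arma::mat dHk = arma::repelem(dG.cols(off, off + Ck - 1), V, 1);
    if (dH_next.n_elem > 0) dHk += dH_next;
    List ly = layers[k];
    arma::mat dAgg;
    List lg;
    if (identity_mlp) {
      dAgg = dHk;
      lg = List::create(_["eps"] = arma::accu(dAgg % Hs[k]));
    } else {
      arma::mat W1 = as<arma::mat>(ly["W1"]);
      arma::mat W2 = as<arma::mat>(ly["W2"]);
      arma::mat dZ2;
      arma::rowvec dg1, dbe1, dg2, dbe2;
      if (batch_norm) {
        dZ2 = bn_bwd(dHk, bn2[k], as<arma::rowvec>(ly["g2"]), training,
                     dg2, dbe2);
      } else {
        dZ2 = dHk;
      }
      arma::mat dW2 = Rs[k].t() * dZ2;
      arma::rowvec db2 = arma::sum(dZ2, 0);
      arma::mat dR = dZ2 * W2.t();
      if (use_mask) dR %= as<arma::mat>(masks[k]);
      arma::mat dP1 = dR % (P1s[k] > 0);
      arma::mat dZ1;
      if (batch_norm) {
        dZ1 = bn_bwd(dP1, bn1[k], as<arma::rowvec>(ly["g1"]), training,
                     dg1, dbe1);
      } else {
        dZ1 = dP1;
      }
      arma::mat dW1 = Xs[k].t() * dZ1;
      arma::rowvec db1 = arma::sum(dZ1, 0);
      dAgg = dZ1 * W1.t();
      lg = List::create(_["eps"] = arma::accu(dAgg % Hs[k]),
                        _["W1"] = dW1, _["b1"] = arma::vec(db1.t()),
                        _["W2"] = dW2, _["b2"] = arma::vec(db2.t()));
      if (batch_norm) {
        lg["g1"] = arma::vec(dg1.t()); lg["be1"] = arma::vec(dbe1.t());
        lg["g2"] = arma::vec(dg2.t()); lg["be2"] = arma::vec(dbe2.t());
      }
    }
    layer_grads[k] = lg;
    if (k > 0 || want_input_grad)
      dH_next = aggregate(Ms[k].t(), dAgg, V, B);
  }
  if (want_grads) {
    out["grads"] = List::create(
      _["layers"] = layer_grads,
      _["w"] = arma::vec(G.t() * dy), _["b"] = arma::accu(dy));
  }
  if (want_input_grad) out["input"] = dH_next;
  return out;
}
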