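// One transformer encoder layer (post-norm, GELU feed-forward), forward and
// backward, batched.  Layout: the hidden-state matrix X is (B*T) x d with
// sequence b in rows [b*T, (b+1)*T); heads are column blocks of width dk.
// Caches returned by the forward pass (needCache) are consumed by the
// backward pass; inference-only forwards skip them.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double gelu1(double x) {
  return 0.5 * x * (1.0 + std::erf(x * M_SQRT1_2));
}
static inline double geluGrad1(double x) {
  const double phi = std::exp(-0.5 * x * x) * 0.3989422804014327;
  return 0.5 * (1.0 + std::erf(x * M_SQRT1_2)) + x * phi;
}

// LayerNorm over rows; returns out, caches xhat and inv (1/sd per row).
static void lnForward(const arma::mat& M, const arma::rowvec& g,
                      const arma::rowvec& b, arma::mat& out, arma::mat& xhat,
                      arma::vec& inv) {
  const double eps = 1e-12;
  arma::vec mu = arma::mean(M, 1);
  xhat = M.each_col() - mu;
  arma::vec v = arma::mean(arma::square(xhat), 1);
  inv = 1.0 / arma::sqrt(v + eps);
  xhat.each_col() %= inv;
  out = xhat.each_row() % g;
  out.each_row() += b;
}

// Backward: dOut -> dX; accumulates dg, db.
static arma::mat lnBackward(const arma::mat& dOut, const arma::mat& xhat,
                            const arma::vec& inv, const arma::rowvec& g,
                            arma::rowvec& dg, arma::rowvec& db) {
  dg = arma::sum(dOut % xhat, 0);
  db = arma::sum(dOut, 0);
  arma::mat dxhat = dOut.each_row() % g;
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % xhat, 1);
  arma::mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv;
  return dX;
}

// Multi-head attention forward on projected Q, K, V; fills ctx and attn.
static void attnForward(const arma::mat& Q, const arma::mat& K,
                        const arma::mat& V, int B, int T, int h, int dk,
                        const arma::mat& mask, arma::mat& ctx,
                        arma::cube& attn) {
  const double scale = 1.0 / std::sqrt((double)dk);
  for (int b = 0; b < B; ++b) {
    const arma::uvec keep = arma::find(mask.row(b) > 0.5);
    const bool full = (int)keep.n_elem == T;
    const int r0 = b * T, r1 = b * T + T - 1;
    for (int i = 0; i < h; ++i) {
      const int c0 = i * dk, c1 = (i + 1) * dk - 1;
      arma::mat& A = attn.slice(b * h + i);
      A = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * scale;
      if (full) {
        arma::vec mx = arma::max(A, 1);
        A = arma::exp(A.each_col() - mx);
        A.each_col() /= arma::sum(A, 1);
      } else {
        for (int r = 0; r < T; ++r) {
          double m = -arma::datum::inf;
          for (arma::uword j = 0; j < keep.n_elem; ++j)
            m = std::max(m, A(r, keep(j)));
          double z = 0.0;
          arma::rowvec soft(T, arma::fill::zeros);
          for (arma::uword j = 0; j < keep.n_elem; ++j) {
            double e = std::exp(A(r, keep(j)) - m);
            soft(keep(j)) = e;
            z += e;
          }
          A.row(r) = soft / z;
        }
      }
      ctx.submat(r0, c0, r1, c1) = A * V.submat(r0, c0, r1, c1);
    }
  }
}

// [[Rcpp::export(name = ".encLayerForwardCpp")]]
List encLayerForwardCpp(const arma::mat& X, const List& ly, int B, int T,
                        int h, int dk, const arma::mat& mask,
                        Nullable<NumericMatrix> drop1 = R_NilValue,
                        Nullable<NumericMatrix> drop2 = R_NilValue,
                        bool needCache = true, bool keepAttn = false) {
  const arma::mat Wq = ly["Wq"], Wk = ly["Wk"], Wv = ly["Wv"], Wo = ly["Wo"];
  const arma::mat W1 = ly["W1"], W2 = ly["W2"];
  const arma::rowvec bq = as<arma::rowvec>(ly["bq"]),
      bk = as<arma::rowvec>(ly["bk"]), bv = as<arma::rowvec>(ly["bv"]),
      bo = as<arma::rowvec>(ly["bo"]), bf1 = as<arma::rowvec>(ly["bf1"]),
      bf2 = as<arma::rowvec>(ly["bf2"]), g1 = as<arma::rowvec>(ly["g1"]),
      b1 = as<arma::rowvec>(ly["b1"]), g2 = as<arma::rowvec>(ly["g2"]),
      b2 = as<arma::rowvec>(ly["b2"]);

  arma::mat Q = X * Wq; Q.each_row() += bq;
  arma::mat K = X * Wk; K.each_row() += bk;
  arma::mat V = X * Wv; V.each_row() += bv;
  arma::mat ctx(B * T, h * dk);
  arma::cube attn(T, T, B * h);
  attnForward(Q, K, V, B, T, h, dk, mask, ctx, attn);
  arma::mat O = ctx * Wo; O.each_row() += bo;
  if (drop1.isNotNull()) O %= as<arma::mat>(drop1);
  arma::mat X1, xhat1; arma::vec inv1;
  lnForward(X + O, g1, b1, X1, xhat1, inv1);
  arma::mat Z1 = X1 * W1; Z1.each_row() += bf1;
  arma::mat H = Z1;
  H.transform([](double x) { return gelu1(x); });
  arma::mat F2 = H * W2; F2.each_row() += bf2;
  if (drop2.isNotNull()) F2 %= as<arma::mat>(drop2);
  arma::mat X2, xhat2; arma::vec inv2;
  lnForward(X1 + F2, g2, b2, X2, xhat2, inv2);

  if (!needCache) {
    if (keepAttn) return List::create(_["X2"] = X2, _["attn"] = attn);
    return List::create(_["X2"] = X2);
  }
  return List::create(
      _["X2"] = X2, _["Q"] = Q, _["K"] = K, _["V"] = V, _["ctx"] = ctx,
      _["attn"] = attn, _["xhat1"] = xhat1, _["inv1"] = inv1, _["X1"] = X1,
      _["Z1"] = Z1, _["H"] = H, _["xhat2"] = xhat2, _["inv2"] = inv2);
}

// [[Rcpp::export(name = ".encLayerBackwardCpp")]]
List encLayerBackwardCpp(const arma::mat& dX2, const arma::mat& Xin,
                         const List& ly, const List& cache, int B, int T,
                         int h, int dk,
                         Nullable<NumericMatrix> drop1 = R_NilValue,
                         Nullable<NumericMatrix> drop2 = R_NilValue) {
  const arma::mat Wq = ly["Wq"], Wk = ly["Wk"], Wv = ly["Wv"], Wo = ly["Wo"];
  const arma::mat W1 = ly["W1"], W2 = ly["W2"];
  const arma::rowvec g1 = as<arma::rowvec>(ly["g1"]),
      g2 = as<arma::rowvec>(ly["g2"]);
  const arma::mat Q = cache["Q"], K = cache["K"], V = cache["V"],
      ctx = cache["ctx"], X1 = cache["X1"], Z1 = cache["Z1"], H = cache["H"],
      xhat1 = cache["xhat1"], xhat2 = cache["xhat2"];
  const arma::vec inv1 = cache["inv1"], inv2 = cache["inv2"];
  const arma::cube attn = cache["attn"];
  const double scale = 1.0 / std::sqrt((double)dk);

  arma::rowvec dg2, db2;
  arma::mat dR2 = lnBackward(dX2, xhat2, inv2, g2, dg2, db2);
  arma::mat dF2 = dR2;
  if (drop2.isNotNull()) dF2 %= as<arma::mat>(drop2);
  arma::mat dH = dF2 * W2.t();
  arma::mat dW2 = H.t() * dF2;
  arma::rowvec dbf2 = arma::sum(dF2, 0);
  arma::mat dZ1 = Z1;
  dZ1.transform([](double x) { return geluGrad1(x); });
  dZ1 %= dH;
  arma::mat dX1 = dR2 + dZ1 * W1.t();
  arma::mat dW1 = X1.t() * dZ1;
  arma::rowvec dbf1 = arma::sum(dZ1, 0);

  arma::rowvec dg1, db1;
  arma::mat dR1 = lnBackward(dX1, xhat1, inv1, g1, dg1, db1);
  arma::mat dO = dR1;
  if (drop1.isNotNull()) dO %= as<arma::mat>(drop1);
  arma::mat dCtx = dO * Wo.t();
  arma::mat dWo = ctx.t() * dO;
  arma::rowvec dbo = arma::sum(dO, 0);

  arma::mat dQ(B * T, h * dk), dK(B * T, h * dk), dV(B * T, h * dk);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T, r1 = b * T + T - 1;
    for (int i = 0; i < h; ++i) {
      const int c0 = i * dk, c1 = (i + 1) * dk - 1;
      const arma::mat& A = attn.slice(b * h + i);
      arma::mat dA = dCtx.submat(r0, c0, r1, c1) *
                     V.submat(r0, c0, r1, c1).t();
      arma::vec rs = arma::sum(dA % A, 1);
      arma::mat dS = A % (dA.each_col() - rs);
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1) * scale;
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1) * scale;
      dV.submat(r0, c0, r1, c1) = A.t() * dCtx.submat(r0, c0, r1, c1);
    }
  }
  arma::mat dXin = dR1 + dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  return List::create(
      _["dXin"] = dXin,
      _["Wq"] = Xin.t() * dQ, _["bq"] = arma::sum(dQ, 0),
      _["Wk"] = Xin.t() * dK, _["bk"] = arma::sum(dK, 0),
      _["Wv"] = Xin.t() * dV, _["bv"] = arma::sum(dV, 0),
      _["Wo"] = dWo, _["bo"] = dbo,
      _["g1"] = dg1, _["b1"] = db1,
      _["W1"] = dW1, _["bf1"] = dbf1, _["W2"] = dW2, _["bf2"] = dbf2,
      _["g2"] = dg2, _["b2"] = db2);
}
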