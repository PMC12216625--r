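// Gated-recurrent-unit chemical language model: teacher-forced
// log-likelihoods with full backpropagation through time, batch
// multinomial sampling, and sequence log-likelihood evaluation.
//
// Parameters are an R list:
//   E  : V x d embedding
//   W  : list of L matrices, 3h x in_dim   (gate row order: z, r, n)
//   U  : list of L matrices, 3h x h
//   bx : list of L vectors, 3h             (input bias)
//   bh : list of L vectors, 3h             (hidden bias; the n-gate hidden
//                                           term is r .* (U_n h + bh_n))
//   Wo : V x h output projection, bo : V
//
// Token indices are 1-based (R convention) in all interfaces.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::uword;

namespace {

struct GruParams {
  mat E;
  std::vector<mat> W, U;
  std::vector<vec> bx, bh;
  mat Wo;
  vec bo;
  int L, V, d, h;
};

GruParams unpack(const List& params) {
  GruParams p;
  p.E  = as<mat>(params["E"]);
  p.Wo = as<mat>(params["Wo"]);
  p.bo = as<vec>(params["bo"]);
  List W = params["W"], U = params["U"], bx = params["bx"], bh = params["bh"];
  p.L = W.size();
  for (int l = 0; l < p.L; ++l) {
    p.W.push_back(as<mat>(W[l]));
    p.U.push_back(as<mat>(U[l]));
    p.bx.push_back(as<vec>(bx[l]));
    p.bh.push_back(as<vec>(bh[l]));
  }
  p.V = p.E.n_rows;
  p.d = p.E.n_cols;
  p.h = p.U[0].n_cols;
  return p;
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// one GRU cell step for a whole batch; columns are batch members
// xin: in_dim x B, hprev: h x B; outputs gates for backprop
void gru_step(const GruParams& p, int l, const mat& xin, const mat& hprev,
              mat& z, mat& r, mat& n, mat& uhn, mat& hnew) {
  const int h = p.h;
  mat gx = p.W[l] * xin;           // 3h x B
  gx.each_col() += p.bx[l];
  mat gh = p.U[l] * hprev;         // 3h x B
  gh.each_col() += p.bh[l];
  z   = sigmoid(gx.rows(0, h - 1)     + gh.rows(0, h - 1));
  r   = sigmoid(gx.rows(h, 2 * h - 1) + gh.rows(h, 2 * h - 1));
  uhn = gh.rows(2 * h, 3 * h - 1);
  n   = arma::tanh(gx.rows(2 * h, 3 * h - 1) + r % uhn);
  hnew = (1.0 - z) % n + z % hprev;
}

// column-wise log-softmax
mat log_softmax(mat logits) {
  arma::rowvec m = arma::max(logits, 0);
  logits.each_row() -= m;
  arma::rowvec lse = arma::log(arma::sum(arma::exp(logits), 0));
  logits.each_row() -= lse;
  return logits;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_clm_grad")]]
List cpp_clm_grad(List params, IntegerMatrix X, IntegerVector lengths,
                  NumericVector weights, bool need_grad) {
  GruParams p = unpack(params);
  const int B = X.nrow(), T = X.ncol();
  const int h = p.h, L = p.L;
  if (B != lengths.size())
    stop("lengths must have one entry per sequence");

  // stored activations per layer: h x B x (T-1) steps
  std::vector<cube> Hs(L), Zs(L), Rs(L), Ns(L), UHNs(L), Xin(L);
  if (T < 2) stop("sequences must contain at least GO and one token");
  const int S = T - 1;  // number of prediction steps
  for (int l = 0; l < L; ++l) {
    int in_dim = (l == 0) ? p.d : h;
    Hs[l].zeros(h, B, S); Zs[l].zeros(h, B, S); Rs[l].zeros(h, B, S);
    Ns[l].zeros(h, B, S); UHNs[l].zeros(h, B, S);
    if (need_grad) Xin[l].zeros(in_dim, B, S);
  }

  vec loglik(B, arma::fill::zeros);
  mat hprev[8]; // supports up to 8 layers
  if (L > 8) stop("at most 8 recurrent layers supported");
  for (int l = 0; l < L; ++l) hprev[l].zeros(h, B);

  // forward
  std::vector<mat> dlogits_store;   // V x B per step (only if need_grad)
  long n_tokens = 0;
  for (int t = 0; t < S; ++t) {
    // embed input tokens X[, t]
    mat xin(p.d, B);
    for (int b = 0; b < B; ++b) {
      int tok = X(b, t) - 1;
      if (tok < 0 || tok >= p.V) stop("token index out of range");
      xin.col(b) = p.E.row(tok).t();
    }
    mat cur = xin;
    for (int l = 0; l < L; ++l) {
      if (need_grad) Xin[l].slice(t) = cur;
      mat z, r, n, uhn, hnew;
      gru_step(p, l, cur, hprev[l], z, r, n, uhn, hnew);
      Zs[l].slice(t) = z; Rs[l].slice(t) = r; Ns[l].slice(t) = n;
      UHNs[l].slice(t) = uhn; Hs[l].slice(t) = hnew;
      hprev[l] = hnew;
      cur = hnew;
    }
    mat logits = p.Wo * cur;  // V x B
    logits.each_col() += p.bo;
    mat lp = log_softmax(logits);
    mat dlg;
    if (need_grad) dlg.zeros(p.V, B);
    for (int b = 0; b < B; ++b) {
      if (t + 1 < lengths[b]) {   // target exists at position t+1
        int tgt = X(b, t + 1) - 1;
        loglik[b] += lp(tgt, b);
        ++n_tokens;
        if (need_grad) {
          vec pr = arma::exp(lp.col(b));
          dlg.col(b) = -weights[b] * pr;   // grad of  w_b * loglik_b
          dlg(tgt, b) += weights[b];
        }
      }
    }
    if (need_grad) dlogits_store.push_back(dlg);
  }

  List out = List::create(_["loglik"] = loglik, _["n_tokens"] = (double)n_tokens);
  if (!need_grad) return out;

  // backward: gradient of G = sum_b w_b * loglik_b
  mat gE(p.V, p.d, arma::fill::zeros);
  mat gWo(p.V, h, arma::fill::zeros);
  vec gbo(p.V, arma::fill::zeros);
  std::vector<mat> gW(L), gU(L);
  std::vector<vec> gbx(L), gbh(L);
  for (int l = 0; l < L; ++l) {
    gW[l].zeros(p.W[l].n_rows, p.W[l].n_cols);
    gU[l].zeros(p.U[l].n_rows, p.U[l].n_cols);
    gbx[l].zeros(3 * h); gbh[l].zeros(3 * h);
  }
  std::vector<mat> dh(L, mat(h, B, arma::fill::zeros));

  for (int t = S - 1; t >= 0; --t) {
    // output layer
    const mat& dlg = dlogits_store[t];
    gWo += dlg * Hs[L - 1].slice(t).t();
    gbo += arma::sum(dlg, 1);
    dh[L - 1] += p.Wo.t() * dlg;

    // through layers top-down
    mat dx_lower;
    for (int l = L - 1; l >= 0; --l) {
      mat z = Zs[l].slice(t), r = Rs[l].slice(t), n = Ns[l].slice(t);
      mat uhn = UHNs[l].slice(t);
      mat hm1 = (t == 0) ? mat(h, B, arma::fill::zeros) : Hs[l].slice(t - 1);
      mat d = dh[l];
      if (l < L - 1) d += dx_lower;  // gradient from layer above's input

      mat dz = d % (hm1 - n) % z % (1.0 - z);
      mat dn = d % (1.0 - z) % (1.0 - n % n);
      mat dr = dn % uhn % r % (1.0 - r);
      mat dnr = dn % r;              // grad wrt (U_n h + bh_n)

      mat dgx(3 * h, B);
      dgx.rows(0, h - 1)         = dz;
      dgx.rows(h, 2 * h - 1)     = dr;
      dgx.rows(2 * h, 3 * h - 1) = dn;

      const mat& xin = Xin[l].slice(t);
      gW[l]  += dgx * xin.t();
      gbx[l] += arma::sum(dgx, 1);

      mat dgh(3 * h, B);
      dgh.rows(0, h - 1)         = dz;
      dgh.rows(h, 2 * h - 1)     = dr;
      dgh.rows(2 * h, 3 * h - 1) = dnr;
      gU[l]  += dgh * hm1.t();
      gbh[l] += arma::sum(dgh, 1);

      // propagate
      mat dhprev = d % z + p.U[l].t() * dgh;
      mat dx = p.W[l].t() * dgx;
      dh[l] = dhprev;
      dx_lower = dx;
    }
    // embedding gradient
    for (int b = 0; b < B; ++b) {
      int tok = X(b, t) - 1;
      gE.row(tok) += dx_lower.col(b).t();
    }
  }

  List gWl(L), gUl(L), gbxl(L), gbhl(L);
  for (int l = 0; l < L; ++l) {
    gWl[l] = gW[l]; gUl[l] = gU[l]; gbxl[l] = gbx[l]; gbhl[l] = gbh[l];
  }
  out["grad"] = List::create(_["E"] = gE, _["W"] = gWl, _["U"] = gUl,
                             _["bx"] = gbxl, _["bh"] = gbhl,
                             _["Wo"] = gWo, _["bo"] = gbo);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_clm_sample")]]
List cpp_clm_sample(List params, int n, int max_len, int seed,
                    int go_idx, int eos_idx) {
  GruParams p = unpack(params);
  const int h = p.h, L = p.L;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<mat> hs(L, mat(h, n, arma::fill::zeros));
  IntegerMatrix tokens(n, max_len);  // emitted tokens (after GO), 0 = unused
  NumericVector loglik(n);
  IntegerVector lengths(n);          // emitted count (incl. EOS if reached)
  LogicalVector truncated(n);
  std::vector<bool> done(n, false);

  std::vector<int> cur(n, go_idx - 1);
  for (int t = 0; t < max_len; ++t) {
    mat xin(p.d, n);
    for (int b = 0; b < n; ++b) xin.col(b) = p.E.row(cur[b]).t();
    mat curm = xin;
    for (int l = 0; l < L; ++l) {
      mat z, r, nn, uhn, hnew;
      gru_step(p, l, curm, hs[l], z, r, nn, uhn, hnew);
      // frozen state for finished sequences
      for (int b = 0; b < n; ++b) if (done[b]) hnew.col(b) = hs[l].col(b);
      hs[l] = hnew;
      curm = hnew;
    }
    mat logits = p.Wo * curm;
    logits.each_col() += p.bo;
    mat lp = log_softmax(logits);
    for (int b = 0; b < n; ++b) {
      if (done[b]) continue;
      vec pr = arma::exp(lp.col(b));
      double u = unif(rng), acc = 0.0;
      int pick = p.V - 1;
      for (int v = 0; v < p.V; ++v) { acc += pr[v]; if (u <= acc) { pick = v; break; } }
      tokens(b, t) = pick + 1;
      loglik[b] += lp(pick, b);
      lengths[b] = t + 1;
      cur[b] = pick;
      if (pick + 1 == eos_idx) done[b] = true;
    }
    bool all_done = true;
    for (int b = 0; b < n; ++b) if (!done[b]) { all_done = false; break; }
    if (all_done) break;
  }
  for (int b = 0; b < n; ++b) truncated[b] = !done[b];
  return List::create(_["tokens"] = tokens, _["lengths"] = lengths,
                      _["loglik"] = loglik, _["truncated"] = truncated);
}
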