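// Numerical core: scalar Kalman recursion and the multi-resolution LSTM
// forecaster (forward pass and full backpropagation-through-time gradient).
// The network is small (4 LSTM branches -> concat -> FC -> log-softmax), so
// a direct Armadillo implementation is both fast enough and fully
// deterministic given the parameter vector.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Strictly causal scalar Kalman filter (random-walk state model).
// State:       x_t = G x_{t-1} + w_t,  w_t ~ N(0, q)
// Observation: y_t = F x_t + v_t,      v_t ~ N(0, r)
// [[Rcpp::export]]
Rcpp::NumericVector kalman_filter_cpp(Rcpp::NumericVector y, double G,
                                      double F, double q, double r,
                                      double x0, double P0) {
  const int n = y.size();
  Rcpp::NumericVector out(n);
  double x = x0, P = P0;
  for (int t = 0; t < n; ++t) {
    // predict
    double xp = G * x;
    double Pp = G * P * G + q;
    // update
    double S = F * Pp * F + r;
    double K = Pp * F / S;
    x = xp + K * (y[t] - F * xp);
    P = (1.0 - K * F) * Pp;
    out[t] = x;
  }
  return out;
}

namespace {

struct Dims {
  int I;   // inputs per time step (number of synergies)
  int H;   // hidden units per LSTM branch
  int F1;  // units in the first fully connected layer
  int C;   // number of classes
  int B;   // branches
  int W;   // time steps per branch
  int lstm_per_branch() const { return 4 * H * (I + H + 1); }
  int cat() const { return B * H; }
  int total() const {
    return B * lstm_per_branch() + cat() * F1 + F1 + F1 * C + C;
  }
};

struct Params {
  std::vector<mat> Wx, Wh;
  std::vector<rowvec> bg;
  mat W1, W2;
  rowvec b1, b2;
};

Params unpack(const vec& p, const Dims& d) {
  Params P;
  int off = 0;
  for (int b = 0; b < d.B; ++b) {
    P.Wx.push_back(reshape(p.subvec(off, off + d.I * 4 * d.H - 1), d.I, 4 * d.H));
    off += d.I * 4 * d.H;
    P.Wh.push_back(reshape(p.subvec(off, off + d.H * 4 * d.H - 1), d.H, 4 * d.H));
    off += d.H * 4 * d.H;
    P.bg.push_back(p.subvec(off, off + 4 * d.H - 1).t());
    off += 4 * d.H;
  }
  P.W1 = reshape(p.subvec(off, off + d.cat() * d.F1 - 1), d.cat(), d.F1);
  off += d.cat() * d.F1;
  P.b1 = p.subvec(off, off + d.F1 - 1).t();
  off += d.F1;
  P.W2 = reshape(p.subvec(off, off + d.F1 * d.C - 1), d.F1, d.C);
  off += d.F1 * d.C;
  P.b2 = p.subvec(off, off + d.C - 1).t();
  return P;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct BranchCache {
  cube ig, fg, gg, og, cs, hs;  // gate activations, cell and hidden states
};

// Forward for one branch; returns final hidden state, optionally caching.
mat branch_forward(const cube& X, const mat& Wx, const mat& Wh,
                   const rowvec& bg, const Dims& d, BranchCache* cache) {
  const int N = X.n_rows;
  const int W = X.n_slices;  // branches may differ in sequence length
  mat h(N, d.H, fill::zeros), c(N, d.H, fill::zeros);
  if (cache) {
    cache->ig.set_size(N, d.H, W);
    cache->fg.set_size(N, d.H, W);
    cache->gg.set_size(N, d.H, W);
    cache->og.set_size(N, d.H, W);
    cache->cs.set_size(N, d.H, W);
    cache->hs.set_size(N, d.H, W);
  }
  for (int t = 0; t < W; ++t) {
    mat G = X.slice(t) * Wx + h * Wh;
    G.each_row() += bg;
    mat i = sigm(G.cols(0, d.H - 1));
    mat f = sigm(G.cols(d.H, 2 * d.H - 1));
    mat g = tanh(G.cols(2 * d.H, 3 * d.H - 1));
    mat o = sigm(G.cols(3 * d.H, 4 * d.H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    if (cache) {
      cache->ig.slice(t) = i;
      cache->fg.slice(t) = f;
      cache->gg.slice(t) = g;
      cache->og.slice(t) = o;
      cache->cs.slice(t) = c;
      cache->hs.slice(t) = h;
    }
  }
  return h;
}

mat log_softmax(mat logits) {
  vec m = max(logits, 1);
  logits.each_col() -= m;
  vec lse = log(sum(exp(logits), 1));
  logits.each_col() -= lse;
  return logits;
}

}  // namespace

// Forward pass of the full network. X is a list of B arrays with
// dimensions (N, I, W). Returns the N x C matrix of log-probabilities.
// [[Rcpp::export]]
arma::mat forecaster_forward_cpp(const arma::vec& params, Rcpp::List X,
                                 int I, int H, int F1, int C) {
  Dims d;
  d.I = I; d.H = H; d.F1 = F1; d.C = C; d.B = X.size();
  cube X0 = Rcpp::as<cube>(X[0]);
  Params P = unpack(params, d);
  const int N = X0.n_rows;
  mat cat(N, d.cat());
  for (int b = 0; b < d.B; ++b) {
    cube Xb = Rcpp::as<cube>(X[b]);
    cat.cols(b * H, (b + 1) * H - 1) =
        branch_forward(Xb, P.Wx[b], P.Wh[b], P.bg[b], d, nullptr);
  }
  mat z1 = cat * P.W1;
  z1.each_row() += P.b1;
  mat a1 = clamp(z1, 0.0, datum::inf);  // ReLU
  mat logits = a1 * P.W2;
  logits.each_row() += P.b2;
  return log_softmax(logits);
}

// Weighted negative log-likelihood loss and gradient wrt all parameters.
// y is 0-based class index; w_class has length C (per-class loss weights).
// Loss = -sum_i w[y_i] logp(i, y_i) / sum_i w[y_i].
// [[Rcpp::export]]
Rcpp::List forecaster_grad_cpp(const arma::vec& params, Rcpp::List X,
                               const arma::ivec& y, const arma::vec& w_class,
                               int I, int H, int F1, int C) {
  Dims d;
  d.I = I; d.H = H; d.F1 = F1; d.C = C; d.B = X.size();
  std::vector<cube> Xs;
  for (int b = 0; b < d.B; ++b) Xs.push_back(Rcpp::as<cube>(X[b]));
  const int N = Xs[0].n_rows;
  Params P = unpack(params, d);

  std::vector<BranchCache> caches(d.B);
  mat cat(N, d.cat());
  for (int b = 0; b < d.B; ++b) {
    cat.cols(b * H, (b + 1) * H - 1) =
        branch_forward(Xs[b], P.Wx[b], P.Wh[b], P.bg[b], d, &caches[b]);
  }
  mat z1 = cat * P.W1;
  z1.each_row() += P.b1;
  mat a1 = clamp(z1, 0.0, datum::inf);
  mat logits = a1 * P.W2;
  logits.each_row() += P.b2;
  mat logp = log_softmax(logits);

  vec wi(N);
  for (int i = 0; i < N; ++i) wi[i] = w_class[y[i]];
  const double wsum = accu(wi);
  double loss = 0.0;
  for (int i = 0; i < N; ++i) loss -= wi[i] * logp(i, y[i]);
  loss /= wsum;

  // backward through the softmax/NLL head
  mat dlogits = exp(logp);  // softmax probabilities
  for (int i = 0; i < N; ++i) dlogits(i, y[i]) -= 1.0;
  dlogits.each_col() %= wi / wsum;

  mat gW2 = a1.t() * dlogits;
  rowvec gb2 = sum(dlogits, 0);
  mat da1 = dlogits * P.W2.t();
  mat dz1 = da1 % (z1 > 0);
  mat gW1 = cat.t() * dz1;
  rowvec gb1 = sum(dz1, 0);
  mat dcat = dz1 * P.W1.t();

  vec grad(d.total(), fill::zeros);
  int off = 0;
  for (int b = 0; b < d.B; ++b) {
    const BranchCache& cc = caches[b];
    mat dh = dcat.cols(b * H, (b + 1) * H - 1);
    mat dc(N, d.H, fill::zeros);
    mat gWx(d.I, 4 * d.H, fill::zeros), gWh(d.H, 4 * d.H, fill::zeros);
    rowvec gbg(4 * d.H, fill::zeros);
    const int Wb = Xs[b].n_slices;
    for (int t = Wb - 1; t >= 0; --t) {
      const mat& i = cc.ig.slice(t);
      const mat& f = cc.fg.slice(t);
      const mat& g = cc.gg.slice(t);
      const mat& o = cc.og.slice(t);
      const mat& c = cc.cs.slice(t);
      mat tc = tanh(c);
      mat do_ = dh % tc;
      mat dct = dc + dh % o % (1.0 - tc % tc);
      mat cprev = (t == 0) ? mat(N, d.H, fill::zeros) : mat(cc.cs.slice(t - 1));
      mat di = dct % g;
      mat df = dct % cprev;
      mat dg = dct % i;
      dc = dct % f;
      mat dG(N, 4 * d.H);
      dG.cols(0, d.H - 1) = di % i % (1.0 - i);
      dG.cols(d.H, 2 * d.H - 1) = df % f % (1.0 - f);
      dG.cols(2 * d.H, 3 * d.H - 1) = dg % (1.0 - g % g);
      dG.cols(3 * d.H, 4 * d.H - 1) = do_ % o % (1.0 - o);
      mat hprev = (t == 0) ? mat(N, d.H, fill::zeros) : mat(cc.hs.slice(t - 1));
      gWx += Xs[b].slice(t).t() * dG;
      gWh += hprev.t() * dG;
      gbg += sum(dG, 0);
      dh = dG * P.Wh[b].t();
    }
    grad.subvec(off, off + d.I * 4 * d.H - 1) = vectorise(gWx);
    off += d.I * 4 * d.H;
    grad.subvec(off, off + d.H * 4 * d.H - 1) = vectorise(gWh);
    off += d.H * 4 * d.H;
    grad.subvec(off, off + 4 * d.H - 1) = gbg.t();
    off += 4 * d.H;
  }
  grad.subvec(off, off + d.cat() * d.F1 - 1) = vectorise(gW1);
  off += d.cat() * d.F1;
  grad.subvec(off, off + d.F1 - 1) = gb1.t();
  off += d.F1;
  grad.subvec(off, off + d.F1 * d.C - 1) = vectorise(gW2);
  off += d.F1 * d.C;
  grad.subvec(off, off + d.C - 1) = gb2.t();

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}
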