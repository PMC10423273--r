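// Single-hidden-layer GRU trained by backpropagation through time.
// Deterministic under R's RNG (weight init, batch shuffling): callers seed
// with set.seed(). Single-threaded by design; networks are small (tens of
// units, chunks of 8 time steps x 6 features).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;

namespace {

// Parameter layout (indices into the parameter vector):
// 0 Wz (K x U)  1 Wr  2 Wh  3 Uz (U x U)  4 Ur  5 Uh
// 6 bz (1 x U)  7 br  8 bh  9 Wo (U x C) 10 bo (1 x C)
const int N_PAR = 11;

struct Cache {
  std::vector<mat> Z, R, C, H; // per time step, batch x U
};

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Slice the (N, T, K) data cube into T matrices of (batch x K) for a batch.
std::vector<mat> slice_batch(const arma::cube& X, const arma::uvec& idx) {
  const int T = X.n_cols, K = X.n_slices;
  std::vector<mat> out(T);
  for (int t = 0; t < T; ++t) {
    mat m(idx.n_elem, K);
    for (int k = 0; k < K; ++k) {
      arma::vec col = X.slice(k).col(t);
      m.col(k) = col.elem(idx);
    }
    out[t] = m;
  }
  return out;
}

// Forward pass; returns final hidden state, optionally filling the cache.
mat forward(const std::vector<mat>& Xt, const std::vector<mat>& P,
            Cache* cache) {
  const int T = Xt.size();
  const int n = Xt[0].n_rows;
  const int U = P[3].n_rows;
  mat H = arma::zeros<mat>(n, U);
  for (int t = 0; t < T; ++t) {
    mat Z = sigmoid(Xt[t] * P[0] + H * P[3] + arma::repmat(P[6], n, 1));
    mat R = sigmoid(Xt[t] * P[1] + H * P[4] + arma::repmat(P[7], n, 1));
    mat C = arma::tanh(Xt[t] * P[2] + (R % H) * P[5] + arma::repmat(P[8], n, 1));
    mat Hn = (1.0 - Z) % H + Z % C;
    if (cache) {
      cache->Z.push_back(Z); cache->R.push_back(R);
      cache->C.push_back(C); cache->H.push_back(Hn);
    }
    H = Hn;
  }
  return H;
}

mat output_layer(const mat& H, const std::vector<mat>& P) {
  return H * P[9] + arma::repmat(P[10], H.n_rows, 1);
}

mat softmax_rows(const mat& logits) {
  mat z = logits.each_col() - arma::max(logits, 1);
  mat e = arma::exp(z);
  return e.each_col() / arma::sum(e, 1);
}

// Mean loss on a set; classification: categorical cross-entropy on one-hot Y,
// regression: mean squared error over all outputs.
double loss_value(const mat& out, const mat& Y, bool classify) {
  if (classify) {
    mat p = softmax_rows(out);
    double ll = arma::accu(Y % arma::log(p + 1e-12));
    return -ll / out.n_rows;
  }
  mat d = out - Y;
  return arma::accu(d % d) / d.n_elem;
}

// BPTT for one batch: fills grads (same layout as P), returns batch loss.
double backward(const std::vector<mat>& Xt, const mat& Y, bool classify,
                const std::vector<mat>& P, std::vector<mat>& G) {
  Cache cache;
  mat Hlast = forward(Xt, P, &cache);
  mat out = output_layer(Hlast, P);
  double loss = loss_value(out, Y, classify);

  const int T = Xt.size();
  const int n = Xt[0].n_rows;
  const int U = P[3].n_rows;
  for (int i = 0; i < N_PAR; ++i) G[i].zeros(arma::size(P[i]));

  mat dout;
  if (classify) dout = (softmax_rows(out) - Y) / (double)n;
  else          dout = 2.0 * (out - Y) / (double)(n * Y.n_cols);

  G[9] = Hlast.t() * dout;
  G[10] = arma::sum(dout, 0);
  mat dH = dout * P[9].t();

  for (int t = T - 1; t >= 0; --t) {
    const mat& Z = cache.Z[t];
    const mat& R = cache.R[t];
    const mat& C = cache.C[t];
    mat Hprev = (t == 0) ? arma::zeros<mat>(n, U) : cache.H[t - 1];

    mat dz = dH % (C - Hprev) % Z % (1.0 - Z);
    mat dc = dH % Z % (1.0 - C % C);
    mat dHprev = dH % (1.0 - Z);

    // candidate: C = tanh(X Wh + (R % Hprev) Uh + bh)
    G[2] += Xt[t].t() * dc;
    mat drh = dc * P[5].t();
    G[5] += (R % Hprev).t() * dc;
    G[8] += arma::sum(dc, 0);
    mat dr = drh % Hprev % R % (1.0 - R);
    dHprev += drh % R;

    G[0] += Xt[t].t() * dz;
    G[3] += Hprev.t() * dz;
    G[6] += arma::sum(dz, 0);
    dHprev += dz * P[3].t();

    G[1] += Xt[t].t() * dr;
    G[4] += Hprev.t() * dr;
    G[7] += arma::sum(dr, 0);
    dHprev += dr * P[4].t();

    dH = dHprev;
  }
  return loss;
}

// Glorot-uniform init via R's RNG.
mat glorot(int nr, int nc) {
  double lim = std::sqrt(6.0 / (nr + nc));
  mat m(nr, nc);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = R::runif(-lim, lim);
  return m;
}

// Orthogonal init for recurrent kernels (QR of a Gaussian matrix).
mat orthogonal(int n) {
  mat A(n, n);
  for (arma::uword j = 0; j < A.n_cols; ++j)
    for (arma::uword i = 0; i < A.n_rows; ++i)
      A(i, j) = R::norm_rand();
  mat Q, Rm;
  arma::qr(Q, Rm, A);
  // sign correction so the factorization is unique
  for (int j = 0; j < n; ++j) if (Rm(j, j) < 0) Q.col(j) *= -1.0;
  return Q;
}

arma::cube as_cube(const NumericVector& x) {
  IntegerVector dim = x.attr("dim");
  arma::cube X(dim[0], dim[1], dim[2]);
  std::copy(x.begin(), x.end(), X.memptr());
  return X;
}

mat eval_output(const arma::cube& X, const arma::uvec& idx,
                const std::vector<mat>& P) {
  std::vector<mat> Xt = slice_batch(X, idx);
  return output_layer(forward(Xt, P, nullptr), P);
}

} // namespace

// [[Rcpp::export]]
List cpp_gru_train(NumericVector x_train, NumericMatrix y_train,
                   NumericVector x_val, NumericMatrix y_val,
                   bool classify, int units, double lr, int batch_size,
                   int max_epochs, int patience) {
  RNGScope rng;
  arma::cube X = as_cube(x_train);
  const int N = X.n_rows, K = X.n_slices;
  const int C = y_train.ncol();
  mat Y(y_train.begin(), N, C);

  bool has_val = x_val.size() > 0;
  arma::cube Xv;
  mat Yv;
  if (has_val) {
    Xv = as_cube(x_val);
    Yv = mat(y_val.begin(), Xv.n_rows, C);
  }

  std::vector<mat> P(N_PAR), G(N_PAR), M(N_PAR), V(N_PAR);
  P[0] = glorot(K, units); P[1] = glorot(K, units); P[2] = glorot(K, units);
  P[3] = orthogonal(units); P[4] = orthogonal(units); P[5] = orthogonal(units);
  P[6] = arma::zeros<rowvec>(units); P[7] = P[6]; P[8] = P[6];
  P[9] = glorot(units, C); P[10] = arma::zeros<rowvec>(C);
  for (int i = 0; i < N_PAR; ++i) {
    M[i] = arma::zeros<mat>(arma::size(P[i]));
    V[i] = M[i];
    G[i] = M[i];
  }

  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long step = 0;
  double best = R_PosInf;
  int wait = 0, best_epoch = 0;
  std::vector<mat> Pbest = P;
  std::vector<double> tr_hist, val_hist;

  arma::uvec all_val;
  if (has_val) all_val = arma::regspace<arma::uvec>(0, Xv.n_rows - 1);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // seeded shuffle through R's RNG
    IntegerVector ord = sample(N, N, false);
    double epoch_loss = 0.0;
    int nb = 0;
    for (int start = 0; start < N; start += batch_size) {
      int end = std::min(start + batch_size, N);
      arma::uvec idx(end - start);
      for (int i = start; i < end; ++i) idx[i - start] = ord[i] - 1;
      std::vector<mat> Xt = slice_batch(X, idx);
      mat Yb(idx.n_elem, C);
      for (arma::uword i = 0; i < idx.n_elem; ++i) Yb.row(i) = Y.row(idx[i]);
      epoch_loss += backward(Xt, Yb, classify, P, G);
      ++nb;
      ++step;
      double lr_t = lr * std::sqrt(1.0 - std::pow(b2, (double)step)) /
                    (1.0 - std::pow(b1, (double)step));
      for (int i = 0; i < N_PAR; ++i) {
        M[i] = b1 * M[i] + (1.0 - b1) * G[i];
        V[i] = b2 * V[i] + (1.0 - b2) * (G[i] % G[i]);
        P[i] -= lr_t * M[i] / (arma::sqrt(V[i]) + eps);
      }
    }
    epoch_loss /= nb;
    tr_hist.push_back(epoch_loss);

    double monitor = epoch_loss;
    if (has_val) {
      mat outv = eval_output(Xv, all_val, P);
      monitor = loss_value(outv, Yv, classify);
      val_hist.push_back(monitor);
    }
    if (monitor < best) {
      best = monitor;
      best_epoch = epoch + 1;
      wait = 0;
      Pbest = P;
    } else if (++wait >= patience) break;
  }

  List weights(N_PAR);
  for (int i = 0; i < N_PAR; ++i) weights[i] = wrap(Pbest[i]);
  return List::create(_["weights"] = weights,
                      _["train_loss"] = tr_hist,
                      _["val_loss"] = val_hist,
                      _["best_epoch"] = best_epoch,
                      _["best_loss"] = best);
}

// [[Rcpp::export]]
NumericMatrix cpp_gru_predict(NumericVector x, List weights, bool classify) {
  arma::cube X = as_cube(x);
  std::vector<mat> P(N_PAR);
  for (int i = 0; i < N_PAR; ++i) P[i] = as<mat>(weights[i]);
  arma::uvec idx = arma::regspace<arma::uvec>(0, X.n_rows - 1);
  mat out = eval_output(X, idx, P);
  if (classify) out = softmax_rows(out);
  return wrap(out);
}
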