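// Multi-layer perceptron regressor trained with minibatch Adam
// (batch <= 200, shuffled each epoch).
// ReLU hidden activations, identity output, squared loss with an L2
// penalty (alpha/2n)*||W||^2 on the weights. Training stops
// when the loss has failed to improve by at least `tol` for 10 consecutive
// epochs, or at `max_iter`. All randomness (Glorot init) derives from
// `seed`.
#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat glorot(int fan_in, int fan_out, std::mt19937 &rng) {
  double bound = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> unif(-bound, bound);
  arma::mat w(fan_in, fan_out);
  for (arma::uword j = 0; j < w.n_cols; ++j)
    for (arma::uword i = 0; i < w.n_rows; ++i)
      w(i, j) = unif(rng);
  return w;
}

// [[Rcpp::export(name = ".mlp_fit_cpp")]]
List mlp_fit_cpp(const arma::mat &X, const arma::vec &y,
                 const arma::ivec &hidden, int max_iter, double tol,
                 double lr_init, int seed, double alpha) {
  const int L = hidden.n_elem + 1;  // number of weight layers
  std::vector<int> sizes;
  sizes.push_back(X.n_cols);
  for (arma::uword i = 0; i < hidden.n_elem; ++i) sizes.push_back(hidden(i));
  sizes.push_back(1);

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = glorot(sizes[l], sizes[l + 1], rng);
    b[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
    mW[l] = arma::mat(sizes[l], sizes[l + 1], arma::fill::zeros);
    vW[l] = arma::mat(sizes[l], sizes[l + 1], arma::fill::zeros);
    mb[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
    vb[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
  }

  const double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  const int n = X.n_rows;
  const int batch = std::min(200, n);
  double lr = lr_init;
  double best_loss = arma::datum::inf;
  int bad_epochs = 0, it = 0;
  double loss = arma::datum::inf;
  long tstep = 0;  // adam step counter (per batch update)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<arma::mat> act(L + 1);
  for (it = 1; it <= max_iter; ++it) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    for (int start = 0; start < n; start += batch) {
      const int m = std::min(batch, n - start);
      arma::uvec idx(m);
      for (int i = 0; i < m; ++i) idx[i] = order[start + i];
      // forward
      act[0] = X.rows(idx);
      for (int l = 0; l < L; ++l) {
        act[l + 1] = act[l] * W[l];
        act[l + 1].each_row() += b[l];
        if (l < L - 1)
          act[l + 1].transform([](double v) { return v > 0 ? v : 0.0; });
      }
      arma::vec resid = act[L].col(0) - y.elem(idx);
      double pen = 0.0;
      for (int l = 0; l < L; ++l) pen += arma::accu(arma::square(W[l]));
      double bloss = 0.5 * arma::dot(resid, resid) / m +
                     0.5 * alpha * pen / m;
      epoch_loss += bloss * m;

      // backward
      arma::mat delta = resid / m;  // m x 1
      ++tstep;
      double b1t = 1.0 - std::pow(beta1, (double)tstep);
      double b2t = 1.0 - std::pow(beta2, (double)tstep);
      for (int l = L - 1; l >= 0; --l) {
        arma::mat gW = act[l].t() * delta + (alpha / m) * W[l];
        arma::rowvec gb = arma::sum(delta, 0);
        arma::mat delta_prev;
        if (l > 0) {
          delta_prev = delta * W[l].t();
          delta_prev.elem(arma::find(act[l] <= 0)).zeros();  // ReLU gate
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(gW);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(gb);
        W[l] -= lr * (mW[l] / b1t) / (arma::sqrt(vW[l] / b2t) + adam_eps);
        b[l] -= lr * (mb[l] / b1t) / (arma::sqrt(vb[l] / b2t) + adam_eps);
        if (l > 0) delta = delta_prev;
      }
    }
    loss = epoch_loss / n;

    if (loss < best_loss - tol) {
      bad_epochs = 0;
    } else if (++bad_epochs >= 10) {
      best_loss = std::min(best_loss, loss);
      break;
    }
    best_loss = std::min(best_loss, loss);
  }

  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = b[l];
  }
  return List::create(_["weights"] = Wout, _["biases"] = bout,
                      _["n_iter"] = std::min(it, max_iter), _["loss"] = loss);
}

// [[Rcpp::export(name = ".mlp_predict_cpp")]]
arma::vec mlp_predict_cpp(List fit, const arma::mat &X) {
  List Wl = fit["weights"], bl = fit["biases"];
  const int L = Wl.size();
  arma::mat a = X;
  for (int l = 0; l < L; ++l) {
    arma::mat W = as<arma::mat>(Wl[l]);
    arma::rowvec b = as<arma::rowvec>(bl[l]);
    a = a * W;
    a.each_row() += b;
    if (l < L - 1) a.transform([](double v) { return v > 0 ? v : 0.0; });
  }
  return a.col(0);
}
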