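// Minibatch trainer for the fully connected classifier (ReLU hidden layers,
// sigmoid output, binary cross-entropy, Adam). Written in C++ because the
// cross-validation / ablation grid trains dozens of networks; the forward
// and backward passes are plain dense algebra.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat relu(const arma::mat& z) { return arma::clamp(z, 0.0, arma::datum::inf); }

// Fisher-Yates with an explicit mt19937 so shuffling is identical across
// platforms for a given seed.
static arma::uvec shuffled_indices(std::size_t n, std::mt19937& rng) {
  arma::uvec idx = arma::regspace<arma::uvec>(0, n - 1);
  for (std::size_t i = n - 1; i > 0; --i) {
    std::size_t j = rng() % (i + 1);
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

// [[Rcpp::export]]
List fcn_train_cpp(const arma::mat& X, const arma::vec& y,
                   List W0, List b0,
                   int epochs, int batch_size, double lr,
                   int seed) {
  const int L = W0.size();  // number of weight layers (hidden + output)
  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W0[l]);
    b[l] = as<arma::rowvec>(b0[l]);
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }

  const std::size_t n = X.n_rows;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  long step = 0;
  arma::vec epoch_loss(epochs, arma::fill::zeros);

  for (int e = 0; e < epochs; ++e) {
    arma::uvec ord = shuffled_indices(n, rng);
    double loss_sum = 0.0;
    std::size_t n_batches = 0;
    for (std::size_t s = 0; s < n; s += batch_size) {
      std::size_t hi = std::min(n - 1, s + batch_size - 1);
      arma::uvec rows = ord.subvec(s, hi);
      arma::mat A = X.rows(rows);
      arma::vec yb = y.elem(rows);
      const double m = static_cast<double>(rows.n_elem);

      // forward
      std::vector<arma::mat> acts(L + 1), zs(L);
      acts[0] = A;
      for (int l = 0; l < L; ++l) {
        zs[l] = acts[l] * W[l];
        zs[l].each_row() += b[l];
        acts[l + 1] = (l < L - 1) ? relu(zs[l])
                                  : 1.0 / (1.0 + arma::exp(-zs[l]));
      }
      arma::vec p = arma::clamp(acts[L].col(0), 1e-12, 1.0 - 1e-12);
      loss_sum += -arma::mean(yb % arma::log(p) +
                              (1.0 - yb) % arma::log(1.0 - p));
      ++n_batches;

      // backward (sigmoid + cross-entropy collapses to p - y)
      arma::mat delta = (acts[L] - arma::mat(yb)) / m;
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, (double)step);
      const double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (int l = L - 1; l >= 0; --l) {
        arma::mat dW = acts[l].t() * delta;
        arma::rowvec db = arma::sum(delta, 0);
        if (l > 0) {
          delta = (delta * W[l].t()) % arma::conv_to<arma::mat>::from(zs[l - 1] > 0.0);
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * dW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(dW);
        mb[l] = beta1 * mb[l] + (1 - beta1) * db;
        vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(db);
        W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
        b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
      }
    }
    epoch_loss[e] = loss_sum / std::max<std::size_t>(1, n_batches);
  }

  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = b[l];
  }
  return List::create(_["weights"] = Wout, _["biases"] = bout,
                      _["loss"] = epoch_loss);
}

// [[Rcpp::export]]
arma::vec fcn_predict_cpp(const arma::mat& X, List W0, List b0) {
  const int L = W0.size();
  arma::mat A = X;
  for (int l = 0; l < L; ++l) {
    arma::mat Z = A * as<arma::mat>(W0[l]);
    Z.each_row() += as<arma::rowvec>(b0[l]);
    A = (l < L - 1) ? relu(Z) : 1.0 / (1.0 + arma::exp(-Z));
  }
  return A.col(0);
}
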