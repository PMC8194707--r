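// Cost/gradient kernels for sparse-autoencoder training. These are the
// inner loops of full-batch L-BFGS optimization; parameters travel as one
// flat vector in the same layout the R code uses (column-major weight
// matrices, then biases).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double RHO_CLIP = 1e-6;

static inline arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// Composite autoencoder cost (pixel-summed reconstruction MSE averaged
// over examples + L2 + KL sparsity) and its gradient.
// par: [W1 (dH x dI), b1, W2 (dI x dH), b2]; X: dI x N.
// [[Rcpp::export(rng = false)]]
List aeCostGradCpp(const arma::vec& par, const arma::mat& X,
                   double lambda, double beta, double rho, int dH) {
  const int dI = X.n_rows;
  const int N = X.n_cols;
  const double* p = par.memptr();
  const arma::mat W1(const_cast<double*>(p), dH, dI, false, true);
  const arma::vec b1(const_cast<double*>(p + dH * dI), dH, false, true);
  const arma::mat W2(const_cast<double*>(p + dH * dI + dH), dI, dH,
                     false, true);
  const arma::vec b2(const_cast<double*>(p + 2 * dH * dI + dH), dI,
                     false, true);

  arma::mat Z = sigmoid(W1 * X + arma::repmat(b1, 1, N));
  arma::mat Xh = sigmoid(W2 * Z + arma::repmat(b2, 1, N));
  arma::vec rhoHat = arma::clamp(arma::mean(Z, 1), RHO_CLIP, 1.0 - RHO_CLIP);

  arma::mat R = Xh - X;
  double mse = arma::accu(arma::square(R)) / N;
  double kl = arma::accu(rho * arma::log(rho / rhoHat) +
                         (1.0 - rho) * arma::log((1.0 - rho) /
                                                 (1.0 - rhoHat)));
  double cost = mse + 0.5 * lambda * (arma::accu(arma::square(W1)) +
                                      arma::accu(arma::square(W2))) +
                beta * kl;
  if (!std::isfinite(cost))
    stop("autoencoder cost is non-finite; check input scaling and hyperparameters");

  arma::mat D2 = (2.0 / N) * R % Xh % (1.0 - Xh);
  arma::vec sparseGrad = (beta / N) * (-rho / rhoHat +
                                       (1.0 - rho) / (1.0 - rhoHat));
  arma::mat D1 = (W2.t() * D2 + arma::repmat(sparseGrad, 1, N)) %
                 Z % (1.0 - Z);

  arma::vec grad(par.n_elem);
  double* g = grad.memptr();
  arma::mat gW1(g, dH, dI, false, true);
  arma::vec gb1(g + dH * dI, dH, false, true);
  arma::mat gW2(g + dH * dI + dH, dI, dH, false, true);
  arma::vec gb2(g + 2 * dH * dI + dH, dI, false, true);
  gW1 = D1 * X.t() + lambda * W1;
  gb1 = arma::sum(D1, 1);
  gW2 = D2 * Z.t() + lambda * W2;
  gb2 = arma::sum(D2, 1);

  return List::create(_["cost"] = cost, _["mse"] = mse, _["kl"] = kl,
                      _["grad"] = grad);
}

// Cross-entropy of the two-encoder + softmax stack with optional L2
// weight decay on the encoder weight matrices, and its gradient.
// par: [W1a (n1 x d), b1a, W1b (n2 x n1), b1b, Ws (2 x n2), bs(2)];
// X: d x N; Y: 2 x N one-hot.
// [[Rcpp::export(rng = false)]]
List stackCostGradCpp(const arma::vec& par, const arma::mat& X,
                      const arma::mat& Y, int n1, int n2, double decay,
                      bool wantGrad) {
  const int d = X.n_rows;
  const int N = X.n_cols;
  const double* p = par.memptr();
  size_t off = 0;
  const arma::mat W1a(const_cast<double*>(p + off), n1, d, false, true);
  off += (size_t)n1 * d;
  const arma::vec b1a(const_cast<double*>(p + off), n1, false, true);
  off += n1;
  const arma::mat W1b(const_cast<double*>(p + off), n2, n1, false, true);
  off += (size_t)n2 * n1;
  const arma::vec b1b(const_cast<double*>(p + off), n2, false, true);
  off += n2;
  const arma::mat Ws(const_cast<double*>(p + off), 2, n2, false, true);
  off += 2 * n2;
  const arma::vec bs(const_cast<double*>(p + off), 2, false, true);

  arma::mat Z1 = sigmoid(W1a * X + arma::repmat(b1a, 1, N));
  arma::mat Z2 = sigmoid(W1b * Z1 + arma::repmat(b1b, 1, N));
  arma::mat S = Ws * Z2 + arma::repmat(bs, 1, N);
  S.each_row() -= arma::max(S, 0);
  arma::mat P = arma::exp(S);
  P.each_row() /= arma::sum(P, 0);

  double cost = -arma::accu(Y % arma::log(P + 1e-12)) / N +
                0.5 * decay * (arma::accu(arma::square(W1a)) +
                               arma::accu(arma::square(W1b)));
  if (!wantGrad) return List::create(_["cost"] = cost);

  arma::mat Ds = (P - Y) / N;
  arma::mat D2 = (Ws.t() * Ds) % Z2 % (1.0 - Z2);
  arma::mat D1 = (W1b.t() * D2) % Z1 % (1.0 - Z1);

  arma::vec grad(par.n_elem);
  double* g = grad.memptr();
  off = 0;
  arma::mat gW1a(g + off, n1, d, false, true); off += (size_t)n1 * d;
  arma::vec gb1a(g + off, n1, false, true); off += n1;
  arma::mat gW1b(g + off, n2, n1, false, true); off += (size_t)n2 * n1;
  arma::vec gb1b(g + off, n2, false, true); off += n2;
  arma::mat gWs(g + off, 2, n2, false, true); off += 2 * n2;
  arma::vec gbs(g + off, 2, false, true);
  gW1a = D1 * X.t() + decay * W1a;
  gb1a = arma::sum(D1, 1);
  gW1b = D2 * Z1.t() + decay * W1b;
  gb1b = arma::sum(D2, 1);
  gWs = Ds * Z2.t();
  gbs = arma::sum(Ds, 1);

  return List::create(_["cost"] = cost, _["grad"] = grad);
}
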