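// Forward-backward, Viterbi and transition accumulators for the
// time-delay-embedded HMM. Works on one contiguous segment at a time;
// segments separated by bad samples are handled by the R caller so that
// no transitions are counted across gaps.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Scaled forward-backward on a single segment.
// loglik: T x K matrix of per-state observation log-likelihoods.
// trans:  K x K row-stochastic transition matrix.
// init:   length-K initial distribution.
// Returns gamma (T x K), xi (K x K summed over t), and the segment
// log-likelihood.
// [[Rcpp::export(name = ".fb_segment")]]
List fb_segment(const arma::mat& loglik, const arma::mat& trans,
                const arma::vec& init) {
  const arma::uword T = loglik.n_rows, K = loglik.n_cols;
  // likelihoods rescaled per time point to avoid under/overflow
  arma::vec mx = arma::max(loglik, 1);
  arma::mat b = arma::exp(loglik.each_col() - mx);  // T x K

  arma::mat alpha(T, K), beta(T, K);
  arma::vec c(T);  // scaling constants

  arma::rowvec a = init.t() % b.row(0);
  c(0) = arma::accu(a);
  alpha.row(0) = a / c(0);
  for (arma::uword t = 1; t < T; ++t) {
    a = (alpha.row(t - 1) * trans) % b.row(t);
    c(t) = arma::accu(a);
    if (c(t) <= 0 || !std::isfinite(c(t))) stop("forward pass underflow");
    alpha.row(t) = a / c(t);
  }

  beta.row(T - 1).ones();
  for (arma::uword t = T - 1; t > 0; --t) {
    arma::rowvec bb = (beta.row(t) % b.row(t)) * trans.t();
    beta.row(t - 1) = bb / c(t);
  }

  arma::mat gamma = alpha % beta;
  gamma.each_col() /= arma::sum(gamma, 1);

  arma::mat xi(K, K, arma::fill::zeros);
  for (arma::uword t = 0; t + 1 < T; ++t) {
    arma::mat m = (alpha.row(t).t() * (beta.row(t + 1) % b.row(t + 1))) %
                  trans / c(t + 1);
    xi += m;
  }

  double ll = arma::accu(arma::log(c)) + arma::accu(mx);
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// Max-product Viterbi path (1-based states) for one segment.
// [[Rcpp::export(name = ".viterbi_segment")]]
IntegerVector viterbi_segment(const arma::mat& loglik, const arma::mat& trans,
                              const arma::vec& init) {
  const arma::uword T = loglik.n_rows, K = loglik.n_cols;
  arma::mat lt = arma::log(trans);
  arma::mat delta(T, K);
  arma::umat psi(T, K, arma::fill::zeros);

  delta.row(0) = arma::log(init.t()) + loglik.row(0);
  for (arma::uword t = 1; t < T; ++t) {
    for (arma::uword k = 0; k < K; ++k) {
      arma::vec cand = delta.row(t - 1).t() + lt.col(k);
      arma::uword best = cand.index_max();
      psi(t, k) = best;
      delta(t, k) = cand(best) + loglik(t, k);
    }
  }
  IntegerVector path(T);
  arma::uword s = delta.row(T - 1).index_max();
  path[T - 1] = (int)s + 1;
  for (arma::uword t = T - 1; t > 0; --t) {
    s = psi(t, s);
    path[t - 1] = (int)s + 1;
  }
  return path;
}

// Markov-chain path sampler: start is 1-based; u is a vector of T-1
// uniforms (drawn in R so R-level seeding governs reproducibility).
// [[Rcpp::export(name = ".markov_path")]]
IntegerVector markov_path(const arma::mat& cumtrans, int start,
                          const NumericVector& u) {
  const int T = u.size() + 1;
  const arma::uword K = cumtrans.n_rows;
  IntegerVector path(T);
  int s = start - 1;
  path[0] = start;
  for (int t = 1; t < T; ++t) {
    double x = u[t - 1];
    arma::uword k = 0;
    while (k + 1 < K && x > cumtrans(s, k)) ++k;
    s = (int)k;
    path[t] = s + 1;
  }
  return path;
}

// Weighted zero-mean scatter matrices: for each state k,
// S_k = X diag(w_k) X' and n_k = sum(w_k), with X of size D x T.
// [[Rcpp::export(name = ".weighted_scatter")]]
List weighted_scatter(const arma::mat& X, const arma::mat& gamma) {
  const arma::uword K = gamma.n_cols, D = X.n_rows;
  arma::cube S(D, D, K);
  arma::vec n(K);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat Xw = X.each_row() % gamma.col(k).t();
    S.slice(k) = Xw * X.t();
    n(k) = arma::accu(gamma.col(k));
  }
  return List::create(_["scatter"] = S, _["n"] = n);
}
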