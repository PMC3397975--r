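#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Core update loop of the stochastic resource-allocation dynamics.
//
// Per step, every reaction i samples a direction m_i in {-1,+1} with
// P(m_i = +1) = (1 + tanh y_i)/2, then the accumulators are updated by
// y <- y - eta * rescale * (J m + h). The mean-field variant replaces the
// sampled m by its conditional expectation tanh(y) and is deterministic.
//
// Uses R's RNG (unif_rand), so trajectories are reproducible bit-for-bit
// under set.seed() on the R side.
//
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(const arma::mat& J,
              const arma::vec& h,
              const arma::vec& y0,
              const int steps,
              const int burnin,
              const double eta,
              const double rescale,
              const IntegerVector& checkpoints,
              const bool stochastic,
              const double clip) {
  const arma::uword N = J.n_rows;
  arma::vec y = y0;
  arma::vec m(N), msum_all(N, arma::fill::zeros), msum_post(N, arma::fill::zeros);

  const int K = checkpoints.size();
  arma::mat y_ck(N, K), mmean_ck(N, K);
  int next_ck = 0;
  long clipped = 0;

  RNGScope scope;
  for (int t = 1; t <= steps; ++t) {
    if (stochastic) {
      for (arma::uword i = 0; i < N; ++i) {
        const double p = 0.5 * (1.0 + std::tanh(y(i)));
        m(i) = (unif_rand() < p) ? 1.0 : -1.0;
      }
    } else {
      m = arma::tanh(y);
    }
    msum_all += m;
    if (t > burnin) msum_post += m;

    y -= (eta * rescale) * (J * m + h);
    for (arma::uword i = 0; i < N; ++i) {
      if (y(i) > clip)  { y(i) = clip;  ++clipped; }
      if (y(i) < -clip) { y(i) = -clip; ++clipped; }
    }

    while (next_ck < K && checkpoints[next_ck] == t) {
      y_ck.col(next_ck) = y;
      mmean_ck.col(next_ck) = msum_all / static_cast<double>(t);
      ++next_ck;
    }
  }

  return List::create(
    _["y"] = y_ck,
    _["m_mean"] = mmean_ck,
    _["msum_post"] = msum_post,
    _["y_final"] = y,
    _["clipped"] = clipped);
}
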