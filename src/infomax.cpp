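// Extended-infomax ICA core: natural-gradient updates with a sub/super-
// Gaussian switch, annealed learning rate, and restart on divergence.
// Operates on pre-whitened data; whitening and bookkeeping live in R.
//
// Randomness (block permutations, kurtosis subsampling) comes from an
// internal xorshift generator seeded from the caller, so results are
// reproducible independently of R's RNG state.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  arma::uword below(arma::uword n) { return (arma::uword)(next() % n); }
};

void fisher_yates(arma::uvec& idx, XorShift64& rng) {
  for (arma::uword i = idx.n_elem - 1; i > 0; --i) {
    arma::uword j = rng.below(i + 1);
    std::swap(idx[i], idx[j]);
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List infomax_core(const arma::mat& X, int block, double lrate,
                        int max_iter, double tol, bool extended,
                        int ext_interval, double seed) {
  const arma::uword n = X.n_rows, N = X.n_cols;
  const arma::uword B = std::min((arma::uword)block, N);
  XorShift64 rng((uint64_t)seed);

  arma::mat W = arma::eye(n, n);
  arma::mat BI = (double)B * arma::eye(n, n);
  arma::vec signs = arma::ones(n);          // +1 super-Gaussian, -1 sub-Gaussian
  const arma::uword kurt_n = std::min<arma::uword>(6000, N);
  const double anneal_deg = 60.0, anneal_step = extended ? 0.98 : 0.90;
  const double blowup = 1e8, lrate_floor = 1e-12;

  arma::mat oldW = W;
  arma::vec old_delta(n * n, arma::fill::zeros);
  double old_change = 0.0;
  bool converged = false;
  int iter = 0, blockno = 0;

  arma::uvec perm = arma::regspace<arma::uvec>(0, N - 1);

  arma::mat Xp(n, N);
  for (iter = 1; iter <= max_iter; ++iter) {
    fisher_yates(perm, rng);
    Xp = X.cols(perm);          // one gather per pass; blocks stay contiguous
    bool blew_up = false;
    for (arma::uword t0 = 0; t0 + B <= N; t0 += B) {
      auto Xb = Xp.cols(t0, t0 + B - 1);
      arma::mat U = W * Xb;
      arma::mat Y = arma::tanh(U);
      if (extended) {
        W += lrate * (BI - arma::diagmat(signs) * (Y * U.t()) - U * U.t()) * W;
        if (++blockno % ext_interval == 0) {
          // re-estimate source kurtosis signs on a random subsample
          arma::uvec sub(kurt_n);
          for (arma::uword i = 0; i < kurt_n; ++i) sub[i] = rng.below(N);
          arma::mat Us = W * X.cols(sub);
          arma::vec m2 = arma::mean(arma::square(Us), 1);
          arma::vec m4 = arma::mean(arma::square(arma::square(Us)), 1);
          arma::vec kurt = m4 / arma::square(m2) - 3.0;
          signs = arma::sign(kurt + 0.02);  // small bias toward super-Gaussian
          signs.replace(0.0, 1.0);
        }
      } else {
        W += lrate * (BI - U * U.t()) * W;  // plain infomax (logistic, super-G)
      }
      if (!W.is_finite() || arma::abs(W).max() > blowup) { blew_up = true; break; }
    }
    if (blew_up) {
      lrate *= 0.5;
      if (lrate < lrate_floor)
        Rcpp::stop("infomax diverged: learning rate annealed below %g", lrate_floor);
      W = arma::eye(n, n); oldW = W;
      old_delta.zeros(); old_change = 0.0;
      continue;
    }
    arma::vec delta = arma::vectorise(W - oldW);
    double change = arma::dot(delta, delta);
    if (iter > 2 && old_change > 0) {
      double cosang = arma::dot(delta, old_delta) /
                      std::sqrt(change * old_change);
      cosang = std::max(-1.0, std::min(1.0, cosang));
      if (std::acos(cosang) * 180.0 / M_PI > anneal_deg) lrate *= anneal_step;
    }
    oldW = W; old_delta = delta; old_change = change;
    if (change < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("iterations") = std::min(iter, max_iter),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("lrate") = lrate,
      Rcpp::Named("signs") = signs);
}
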