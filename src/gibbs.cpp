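#include <Rcpp.h>
using namespace Rcpp;

// Cholesky factor (lower) of a small SPD matrix, in place on a copy.
static void chol_lower(const NumericMatrix& a, std::vector<double>& L, int p) {
  for (int i = 0; i < p * p; ++i) L[i] = 0.0;
  for (int j = 0; j < p; ++j) {
    double d = a(j, j);
    for (int k = 0; k < j; ++k) d -= L[j + k * p] * L[j + k * p];
    if (d <= 0.0) stop("posterior precision matrix not positive definite");
    L[j + j * p] = std::sqrt(d);
    for (int i = j + 1; i < p; ++i) {
      double s = a(i, j);
      for (int k = 0; k < j; ++k) s -= L[i + k * p] * L[j + k * p];
      L[i + j * p] = s / L[j + j * p];
    }
  }
}

// Gibbs sampler for the normal linear model with independent normal priors
// on the coefficients and a uniform prior on the residual SD.
//
// Inputs are the sufficient statistics (D'D, D'y, y'y, n), prior mean and
// precision vectors, the uniform upper bound on sigma, chain settings,
// initial coefficient values per chain, and optionally a fixed sigma^2
// (sigma2_fixed > 0 disables the variance update; the exact conjugate case).
//
// Full conditionals:
//   beta | sigma^2 ~ N(A^{-1} b, A^{-1}),  A = D'D/sigma^2 + T,
//                                          b = D'y/sigma^2 + T mu0
//   sigma^2 | beta ~ InvGamma((n-1)/2, SSR/2) truncated at sigma_upper^2
// (the shape (n-1)/2 carries the Jacobian of the uniform-on-sigma prior).
// Uses R's RNG so set.seed() in R fixes the trajectory.
// [[Rcpp::export]]
List gibbs_sampler_cpp(NumericMatrix DtD, NumericVector Dty, double yty,
                       int n, NumericVector mu0, NumericVector tau,
                       double sigma_upper,
                       int n_chains, int n_iter, int n_burn,
                       NumericMatrix inits, NumericVector sigma2_init,
                       double sigma2_fixed) {
  const int p = DtD.nrow();
  const int keep = n_iter - n_burn;
  const bool fixed_sigma = sigma2_fixed > 0.0;
  const double sigma2_cap = sigma_upper * sigma_upper;
  const double shape = 0.5 * (n - 1);

  NumericVector draws(Dimension(keep, p + 1, n_chains));
  std::vector<double> beta(p), L(p * p), zvec(p), tmp(p);
  NumericMatrix A(p, p);

  RNGScope scope;
  for (int ch = 0; ch < n_chains; ++ch) {
    for (int j = 0; j < p; ++j) beta[j] = inits(j, ch);
    double sigma2 = fixed_sigma ? sigma2_fixed : sigma2_init[ch];

    for (int it = 0; it < n_iter; ++it) {
      // coefficient block: joint conjugate normal draw
      const double inv_s2 = 1.0 / sigma2;
      for (int i = 0; i < p; ++i) {
        for (int j = 0; j < p; ++j) A(i, j) = DtD(i, j) * inv_s2;
        A(i, i) += tau[i];
        tmp[i] = Dty[i] * inv_s2 + tau[i] * mu0[i];
      }
      chol_lower(A, L, p);
      // mean: solve A m = tmp via L L' m = tmp
      for (int i = 0; i < p; ++i) {
        double s = tmp[i];
        for (int k = 0; k < i; ++k) s -= L[i + k * p] * zvec[k];
        zvec[i] = s / L[i + i * p];
      }
      for (int i = p - 1; i >= 0; --i) {
        double s = zvec[i];
        for (int k = i + 1; k < p; ++k) s -= L[k + i * p] * beta[k];
        beta[i] = s / L[i + i * p];
      }
      // add noise: beta += L'^{-1} z, z ~ N(0, I)
      for (int i = 0; i < p; ++i) zvec[i] = norm_rand();
      for (int i = p - 1; i >= 0; --i) {
        double s = zvec[i];
        for (int k = i + 1; k < p; ++k) s -= L[k + i * p] * zvec[k];
        zvec[i] = s / L[i + i * p];
      }
      for (int i = 0; i < p; ++i) beta[i] += zvec[i];

      if (!fixed_sigma) {
        // SSR = y'y - 2 b'D'y + b'D'D b
        double ssr = yty;
        for (int i = 0; i < p; ++i) {
          ssr -= 2.0 * beta[i] * Dty[i];
          for (int j = 0; j < p; ++j) ssr += beta[i] * DtD(i, j) * beta[j];
        }
        if (ssr < 1e-300) ssr = 1e-300;
        // truncated inverse gamma by rejection; bound essentially never binds
        double s2new;
        int tries = 0;
        do {
          s2new = ssr / (2.0 * R::rgamma(shape, 1.0));
          if (++tries > 1000)
            stop("sigma^2 rejection sampler exceeded 1000 tries "
                 "(sigma_upper too small for these data)");
        } while (s2new > sigma2_cap);
        sigma2 = s2new;
      }

      if (it >= n_burn) {
        const int row = it - n_burn;
        for (int j = 0; j < p; ++j)
          draws[row + j * keep + ch * keep * (p + 1)] = beta[j];
        draws[row + p * keep + ch * keep * (p + 1)] = std::sqrt(sigma2);
      }
    }
  }
  return List::create(Named("draws") = draws);
}
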