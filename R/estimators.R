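#' Prior specification for the Bayesian adjusted model
#'
#' Independent priors for the linear model of Y on X and Z: a vague normal
#' on the exposure coefficient, an informative normal on the measured
#' confounder-outcome coefficient, and a uniform prior on the residual
#' standard deviation. All normal priors are parameterized by precision
#' (tau = 1/variance), never by a standard deviation.
#'
#' @param mu_yz Prior mean for the Z-Y coefficient (typically external
#'   knowledge of the confounder-outcome relation).
#' @param tau_yz Prior precision for the Z-Y coefficient; the informative
#'   part. The simulation study scales it with the sample size
#'   (n, n/10, n/100).
#' @param tau_yx Prior precision for the X-Y coefficient (default 0.001,
#'   effectively flat).
#' @param sigma_upper Upper bound of the uniform prior on the residual SD
#'   (default 100).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu_yz, tau_yz, tau_yx = 0.001, sigma_upper = 100) {
  stopifnot(is.finite(mu_yz), is.finite(tau_yz), is.finite(tau_yx),
            is.finite(sigma_upper))
  if (tau_yz <= 0 || tau_yx <= 0 || sigma_upper <= 0)
    stop("tau_yz, tau_yx and sigma_upper must be strictly positive",
         call. = FALSE)
  structure(list(mu_yz = mu_yz, tau_yz = tau_yz, tau_yx = tau_yx,
                 sigma_upper = sigma_upper),
            class = "prior_spec")
}

#' Markov chain Monte Carlo settings
#'
#' @param n_chains Number of parallel chains (default 4).
#' @param n_iter Iterations per chain (default 2000).
#' @param n_burn Burn-in iterations discarded per chain (default 1000);
#'   must be smaller than `n_iter`.
#' @param seed Integer seed governing initialization and all draws.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 2000L, n_burn = 1000L,
                        seed = 1L) {
  n_chains <- as.integer(n_chains)
  n_iter <- as.integer(n_iter)
  n_burn <- as.integer(n_burn)
  if (n_chains < 1L) stop("n_chains must be >= 1", call. = FALSE)
  if (n_burn >= n_iter) stop("n_burn must be < n_iter", call. = FALSE)
  if (n_burn < 0L) stop("n_burn must be >= 0", call. = FALSE)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Ordinary least-squares fit of the outcome model
#'
#' Fits Y on a chosen covariate set by OLS. The structural model is
#' zero-mean, so no intercept is included by default; set
#' `intercept = TRUE` for real (non-centred) data.
#'
#' @param data Data frame with column `y` and the requested covariates.
#' @param covariates Character vector of covariate column names, e.g.
#'   `"x"` (unadjusted) or `c("x", "z")` (adjusted for the measured
#'   confounder).
#' @param intercept Include an intercept term? Default `FALSE`.
#' @return An object of class `fit_result`: method label, named coefficient
#'   vector `estimate`, standard errors, and residual-SD estimate `sigma`.
#' @examples
#' d <- generate_dataset(scenario_params(beta_xz = 1, beta_yz = 1), seed = 1)
#' ols_fit(d, c("x", "z"))
#' @export
ols_fit <- function(data, covariates = c("x", "z"), intercept = FALSE) {
  validate_dataset(data, c("y", covariates))
  fml <- stats::reformulate(covariates, response = "y",
                            intercept = intercept)
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: covariates are collinear", call. = FALSE)
  sm <- summary(fit)
  est <- stats::coef(fit)
  se <- stats::setNames(sm$coefficients[, "Std. Error"],
                        rownames(sm$coefficients))
  structure(list(method = paste0("ols[", paste(covariates, collapse = ","),
                                 if (intercept) ",1" else "", "]"),
                 estimate = est, se = se, sigma = sm$sigma,
                 covariates = covariates),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("OLS fit (", x$method, ")\n", sep = "")
  tab <- cbind(estimate = x$estimate, se = x$se)
  print(round(tab, 4))
  cat(sprintf("residual SD: %.4f\n", x$sigma))
  invisible(x)
}

#' Exact conjugate posterior mean of the coefficients at fixed variance
#'
#' With the residual variance held fixed, the normal likelihood and
#' independent normal priors are conjugate, and the posterior of the
#' coefficient vector is normal with mean
#' \deqn{(D'D/\sigma^2 + T)^{-1}(D'y/\sigma^2 + T\mu_0)}
#' where D is the (x, z) design, T = diag(tau_yx, tau_yz) and
#' mu_0 = (0, mu_yz). Used as the exact oracle for the Gibbs sampler's
#' coefficient block.
#'
#' @param data Data frame with columns `y`, `x`, `z`.
#' @param prior A [prior_spec()].
#' @param sigma2 Fixed residual variance, > 0.
#' @return Named vector `c(x = ..., z = ...)` of posterior means.
#' @export
conjugate_posterior_mean <- function(data, prior, sigma2) {
  validate_dataset(data, c("y", "x", "z"))
  stopifnot(inherits(prior, "prior_spec"), sigma2 > 0)
  D <- cbind(x = data$x, z = data$z)
  Tm <- diag(c(prior$tau_yx, prior$tau_yz))
  mu0 <- c(0, prior$mu_yz)
  A <- crossprod(D) / sigma2 + Tm
  if (!is.finite(rcond(A)) || rcond(A) < 1e-15)
    stop("singular posterior precision matrix", call. = FALSE)
  b <- crossprod(D, data$y) / sigma2 + Tm %*% mu0
  drop(stats::setNames(solve(A, b), c("x", "z")))
}

#' Gibbs sampler for the informative-prior outcome model
#'
#' Samples the joint posterior of (beta_yx, beta_yz, sigma) for the linear
#' model of Y on X and Z under independent priors
#' beta_yx ~ N(0, precision tau_yx), beta_yz ~ N(mu_yz, precision tau_yz)
#' and sigma ~ U(0, sigma_upper). The sampler alternates (i) an exact joint
#' bivariate-normal draw of the coefficients given sigma^2 (conjugate
#' update) and (ii) an inverse-gamma draw of sigma^2 whose shape carries
#' the Jacobian of the uniform-on-sigma prior, truncated at sigma_upper^2
#' by rejection. Chains start at the OLS estimates jittered by +-2 OLS
#' standard errors so that the potential scale reduction diagnostic is
#' meaningful.
#'
#' @param data Data frame with columns `y`, `x`, `z`.
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()]; its seed fixes the whole trajectory.
#' @param intercept Include an intercept with an effectively flat normal
#'   prior (precision 1e-6)? Default `FALSE` (zero-mean model).
#' @param sigma2_fixed If a positive number, the residual variance is held
#'   fixed at this value and only the coefficient block is sampled (exact
#'   conjugate setting, used for validation).
#' @return An object of class `posterior_summary`: posterior `mean`, `sd`
#'   and potential scale reduction `rhat` per parameter, the retained draw
#'   count, and the draws themselves (`draws`, an iterations x parameters x
#'   chains array).
#' @examples
#' d <- generate_dataset(scenario_params(beta_xz = 1, beta_yz = 1, n = 200), seed = 1)
#' fit <- gibbs_fit(d, prior_spec(mu_yz = 1, tau_yz = 200),
#'                  mcmc_config(n_iter = 500, n_burn = 250, seed = 1))
#' fit$mean
#' @export
gibbs_fit <- function(data, prior, mcmc = mcmc_config(), intercept = FALSE,
                      sigma2_fixed = NA_real_) {
  validate_dataset(data, c("y", "x", "z"))
  stopifnot(inherits(prior, "prior_spec"), inherits(mcmc, "mcmc_config"))

  D <- cbind(x = data$x, z = data$z)
  mu0 <- c(0, prior$mu_yz)
  tau <- c(prior$tau_yx, prior$tau_yz)
  if (intercept) {
    D <- cbind(`(Intercept)` = 1, D)
    mu0 <- c(0, mu0)
    tau <- c(1e-6, tau)
  }
  pnames <- colnames(D)

  set.seed(mcmc$seed)
  ols <- stats::lm.fit(D, data$y)
  if (ols$rank < ncol(D))
    stop("rank-deficient design: cannot initialize chains", call. = FALSE)
  rss <- sum(ols$residuals^2)
  s2 <- rss / (nrow(D) - ncol(D))
  se <- sqrt(diag(chol2inv(chol(crossprod(D)))) * s2)
  inits <- vapply(seq_len(mcmc$n_chains), function(ch) {
    ols$coefficients + stats::runif(ncol(D), -2, 2) * se
  }, numeric(ncol(D)))
  sigma2_init <- s2 * stats::runif(mcmc$n_chains, 0.5, 2)

  res <- gibbs_sampler_cpp(
    crossprod(D), crossprod(D, data$y), sum(data$y^2), nrow(D),
    mu0, tau, prior$sigma_upper,
    mcmc$n_chains, mcmc$n_iter, mcmc$n_burn,
    inits, sigma2_init,
    if (is.na(sigma2_fixed)) -1 else sigma2_fixed)

  draws <- res$draws  # retained x (p + 1) x chains
  dimnames(draws) <- list(NULL, c(pnames, "sigma"), NULL)
  if (!all(is.finite(draws)))
    stop("non-finite draws in Gibbs sampler; chain state: ",
         paste(utils::capture.output(str(res)), collapse = " "),
         call. = FALSE)

  flat <- apply(draws, 2, c)
  post_mean <- colMeans(flat)
  post_sd <- apply(flat, 2, stats::sd)
  rhat <- apply(draws, 2, gelman_rhat)
  if (any(rhat > 1.1, na.rm = TRUE))
    warning("potential scale reduction > 1.1 for: ",
            paste(names(rhat)[which(rhat > 1.1)], collapse = ", "),
            call. = FALSE)

  structure(list(mean = post_mean, sd = post_sd, rhat = rhat,
                 n_retained = dim(draws)[1] * dim(draws)[3],
                 draws = draws, prior = prior, mcmc = mcmc),
            class = "posterior_summary")
}

# Gelman-Rubin potential scale reduction from a retained-draws matrix
# (iterations x chains); plain (unsplit) version on retained draws.
gelman_rhat <- function(x) {
  x <- as.matrix(x)
  m <- ncol(x)
  if (m < 2L) return(NA_real_)
  n <- nrow(x)
  w <- mean(apply(x, 2, stats::var))
  b <- n * stats::var(colMeans(x))
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (", x$n_retained, " retained draws, ",
      dim(x$draws)[3], " chains)\n", sep = "")
  tab <- cbind(mean = x$mean, sd = x$sd, rhat = x$rhat)
  print(round(tab, 4))
  invisible(x)
}
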