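#' Large-sample bias of the unadjusted exposure-outcome estimator
#'
#' Closed-form asymptotic bias of the ordinary least-squares coefficient of
#' X in a regression of Y on X alone, when both confounders Z and U are
#' omitted:
#' \deqn{bias(\beta_{yx}) = \beta_{yz}\left(\beta_{xz}\frac{Var(Z)}{Var(X)} +
#'   \beta_{zu}\beta_{xu}\frac{Var(U)}{Var(X)}\right) +
#'   \beta_{yu}\frac{Var(U)}{Var(X)}(\beta_{xu} + \beta_{zu}\beta_{xz})}
#' Each term corresponds to an open backdoor path from X to Y; the bias does
#' not depend on the true effect `beta_yx`.
#'
#' @param params A [scenario_params()] object.
#' @return The scalar asymptotic bias.
#' @examples
#' bias_unadjusted(scenario_params(beta_yz = 1, beta_xz = 1))  # 0.5
#' @export
bias_unadjusted <- function(params) {
  m <- implied_moments(params)
  p <- params
  p$beta_yz * (p$beta_xz * m$var_z / m$var_x +
                 p$beta_zu * p$beta_xu * m$var_u / m$var_x) +
    p$beta_yu * (m$var_u / m$var_x) * (p$beta_xu + p$beta_zu * p$beta_xz)
}

#' Large-sample bias of the Z-adjusted exposure-outcome estimator
#'
#' Closed-form asymptotic bias of the OLS coefficient of X in a regression
#' of Y on X and the measured confounder Z, when U remains omitted:
#' \deqn{bias(\beta_{yx|z}) = \beta_{xu}\beta_{yu}
#'   \frac{Var(U)(1-\rho_{uz}^2)}{Var(X)(1-\rho_{xz}^2)}}
#' The numerator is the residual confounding carried by U after conditioning
#' on Z; the denominator Var(X|Z) shrinks as Z predicts X more strongly,
#' which amplifies the residual bias (near-instrument behaviour).
#'
#' @param params A [scenario_params()] object with `rho_xz^2 < 1`.
#' @return The scalar asymptotic bias.
#' @examples
#' bias_adjusted_z(scenario_params(beta_xz = 1, beta_yz = 1,
#'                                 beta_xu = 1, beta_yu = 1))  # 0.5
#' @export
bias_adjusted_z <- function(params) {
  m <- implied_moments(params)
  if (1 - m$rho_xz^2 <= .Machine$double.eps * 100)
    stop("degenerate scenario: Z is a perfect linear proxy of X (rho_xz^2 = 1)",
         call. = FALSE)
  params$beta_xu * params$beta_yu * m$var_u * (1 - m$rho_uz^2) /
    (m$var_x * (1 - m$rho_xz^2))
}

#' Standardized correlations for the confounder-outcome bias formula
#'
#' Container for the pairwise correlations among standardized Z, X, U and
#' the direct effect of standardized U on standardized Y, the inputs of
#' [bias_zy_conditional()].
#'
#' @param rho_zu,rho_xz,rho_xu Pairwise correlations, each in `[-1, 1]`;
#'   jointly they must form a positive semidefinite 3x3 correlation matrix
#'   over (Z, X, U).
#' @param beta_yu_std Direct effect of U on Y with both standardized.
#' @return An object of class `standardized_correlations`.
#' @export
standardized_correlations <- function(rho_zu, rho_xz, rho_xu, beta_yu_std) {
  vals <- c(rho_zu = rho_zu, rho_xz = rho_xz, rho_xu = rho_xu)
  if (any(abs(vals) > 1))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  R <- matrix(c(1, rho_xz, rho_zu,
                rho_xz, 1, rho_xu,
                rho_zu, rho_xu, 1), 3, 3,
              dimnames = list(c("z", "x", "u"), c("z", "x", "u")))
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("correlations do not form a positive semidefinite matrix",
         call. = FALSE)
  structure(list(rho_zu = rho_zu, rho_xz = rho_xz, rho_xu = rho_xu,
                 beta_yu_std = beta_yu_std),
            class = "standardized_correlations")
}

#' Convert a scenario to standardized correlations
#'
#' Standardizes the implied joint distribution of a scenario so that the
#' confounder-outcome bias formula (which assumes a multivariate standard
#' normal) can be applied: correlations come from the implied covariance and
#' the direct U effect is rescaled by sd(U)/sd(Y).
#'
#' @param params A [scenario_params()] object.
#' @return A [standardized_correlations()] object.
#' @export
standardize_scenario <- function(params) {
  m <- implied_moments(params)
  standardized_correlations(
    rho_zu = m$rho_uz, rho_xz = m$rho_xz, rho_xu = m$rho_xu,
    beta_yu_std = params$beta_yu * sqrt(m$var_u / m$var_y))
}

#' Bias of the measured confounder-outcome coefficient
#'
#' Asymptotic bias of the Z coefficient in a regression of Y on X and Z when
#' U is omitted, with all variables standardized:
#' \deqn{bias(\beta_{yz|x}) = \beta'_{yu}
#'   \frac{\rho_{zu} - \rho_{xz}\rho_{xu}}{1 - \rho_{xz}^2}}
#' Even when Z and U are marginally independent (`rho_zu = 0`) the Z-Y
#' relation is biased, because conditioning on the collider X opens a path
#' from Z to Y through U. This distortion is what an informative prior on
#' the Z-Y coefficient can push back against.
#'
#' @param corr A [standardized_correlations()] object with `rho_xz^2 < 1`.
#' @return The scalar asymptotic bias on the standardized scale.
#' @examples
#' bias_zy_conditional(standardized_correlations(0.5, 0, 0.5, 1))  # 0.5
#' @export
bias_zy_conditional <- function(corr) {
  stopifnot(inherits(corr, "standardized_correlations"))
  if (1 - corr$rho_xz^2 <= .Machine$double.eps * 100)
    stop("degenerate: rho_xz^2 = 1", call. = FALSE)
  corr$beta_yu_std * (corr$rho_zu - corr$rho_xz * corr$rho_xu) /
    (1 - corr$rho_xz^2)
}

#' Population (large-sample) regression coefficients from a covariance matrix
#'
#' Solves the normal equations at the population level: for covariance
#' matrix Sigma, the large-n OLS coefficients of the outcome on a covariate
#' set are `solve(Sigma[cc], Sigma[c, y])`. Serves as the exact oracle for
#' every closed-form bias expression: the bias of an estimator is its
#' population coefficient minus the structural truth.
#'
#' @param cov Covariance matrix (PSD) with optional dimnames.
#' @param outcome Index or name of the outcome variable.
#' @param covariates Indices or names of the covariates.
#' @return Named vector of population regression coefficients.
#' @examples
#' m <- implied_moments(scenario_params(beta_zu = 1, beta_xz = 1,
#'                                      beta_yz = 1, beta_yu = 1))
#' population_regression(m$sigma, "y", c("x", "z"))  # (0, 1.5)
#' @export
population_regression <- function(cov, outcome, covariates) {
  cov <- as.matrix(cov)
  scc <- cov[covariates, covariates, drop = FALSE]
  scy <- cov[covariates, outcome]
  rc <- rcond(scc)
  if (!is.finite(rc) || rc < 1e-12)
    stop("covariate block of the covariance matrix is (near-)singular",
         call. = FALSE)
  b <- solve(scc, scy)
  names(b) <- if (is.character(covariates)) covariates else
    colnames(cov)[covariates]
  b
}
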