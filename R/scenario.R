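#' Scenario parameters for the structural confounding model
#'
#' Bundles the path coefficients and residual variances of the linear
#' structural model with one exposure (X), one outcome (Y), a measured
#' confounder (Z) and an unmeasured confounder (U):
#' \deqn{z_i = \beta_{zu} u_i + \xi_i}
#' \deqn{x_i = \beta_{xz} z_i + \beta_{xu} u_i + \zeta_i}
#' \deqn{y_i = \beta_{yx} x_i + \beta_{yz} z_i + \beta_{yu} u_i + \varepsilon_i}
#' with independent zero-mean normal errors. Intercepts are omitted: the
#' model is zero-mean throughout.
#'
#' @param beta_yx Effect of exposure X on outcome Y (the estimand).
#' @param beta_yz,beta_yu Effects of the confounders Z and U on Y.
#' @param beta_xz,beta_xu Effects of the confounders Z and U on X.
#' @param beta_zu Effect of U on Z (confounder-confounder path).
#' @param var_u,var_z_resid,var_x_resid,var_y_resid Variance of U and the
#'   residual variances of the Z, X and Y equations. All strictly positive.
#' @param n Sample size for generated datasets; at least 3.
#' @return An object of class `scenario_params` (a named list).
#' @seealso [implied_moments()], [generate_dataset()], [build_grid()]
#' @examples
#' p <- scenario_params(beta_yz = 1, beta_xz = 1)
#' implied_moments(p)
#' @export
scenario_params <- function(beta_yx = 0, beta_yz = 0, beta_yu = 0,
                            beta_xz = 0, beta_xu = 0, beta_zu = 0,
                            var_u = 1, var_z_resid = 1,
                            var_x_resid = 1, var_y_resid = 1,
                            n = 1000L) {
  p <- list(beta_yx = beta_yx, beta_yz = beta_yz, beta_yu = beta_yu,
            beta_xz = beta_xz, beta_xu = beta_xu, beta_zu = beta_zu,
            var_u = var_u, var_z_resid = var_z_resid,
            var_x_resid = var_x_resid, var_y_resid = var_y_resid,
            n = as.integer(n))
  validate_scenario_params(p)
  class(p) <- "scenario_params"
  p
}

validate_scenario_params <- function(p) {
  coefs <- c("beta_yx", "beta_yz", "beta_yu", "beta_xz", "beta_xu", "beta_zu")
  for (nm in coefs) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("scenario_params: '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  vars <- c("var_u", "var_z_resid", "var_x_resid", "var_y_resid")
  for (nm in vars) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("scenario_params: variance '", nm, "' must be strictly positive",
           call. = FALSE)
  }
  if (is.na(p$n) || p$n < 3L)
    stop("scenario_params: 'n' must be an integer >= 3", call. = FALSE)
  invisible(p)
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Structural scenario (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  Y <- %.3g X + %.3g Z + %.3g U   (resid var %.3g)\n",
              x$beta_yx, x$beta_yz, x$beta_yu, x$var_y_resid))
  cat(sprintf("  X <- %.3g Z + %.3g U            (resid var %.3g)\n",
              x$beta_xz, x$beta_xu, x$var_x_resid))
  cat(sprintf("  Z <- %.3g U                     (resid var %.3g)\n",
              x$beta_zu, x$var_z_resid))
  cat(sprintf("  Var(U) = %.3g\n", x$var_u))
  invisible(x)
}

#' Exact second moments implied by a scenario
#'
#' Propagates the structural coefficients through the model to the marginal
#' variances, covariances, correlations, and the conditional variances
#' Var(U|Z) and Var(X|Z) that enter the omitted-confounder bias formulas.
#' All moments are exact population quantities, not simulation estimates.
#'
#' @param params A [scenario_params()] object.
#' @return An object of class `implied_moments`: a named list with elements
#'   `var_u`, `var_z`, `var_x`, `var_y`, `cov_zu`, `cov_xu`, `cov_xz`,
#'   `cov_yu`, `cov_yz`, `cov_yx`, `rho_uz`, `rho_xz`, `rho_xu`,
#'   `var_u_given_z`, `var_x_given_z`, and `sigma` (the full 4x4 covariance
#'   matrix over U, Z, X, Y).
#' @examples
#' m <- implied_moments(scenario_params(beta_xz = 1, beta_yz = 1))
#' m$var_x  # beta_xz^2 * Var(Z) + resid = 2
#' @export
implied_moments <- function(params) {
  validate_scenario_params(params)
  p <- params
  var_u <- p$var_u
  var_z <- p$beta_zu^2 * var_u + p$var_z_resid
  cov_zu <- p$beta_zu * var_u
  cov_xu <- p$beta_xz * p$beta_zu * var_u + p$beta_xu * var_u
  cov_xz <- p$beta_xz * var_z + p$beta_xu * cov_zu
  var_x <- p$beta_xz^2 * var_z + p$beta_xu^2 * var_u +
    2 * p$beta_xz * p$beta_xu * cov_zu + p$var_x_resid
  cov_yu <- p$beta_yx * cov_xu + p$beta_yz * cov_zu + p$beta_yu * var_u
  cov_yz <- p$beta_yx * cov_xz + p$beta_yz * var_z + p$beta_yu * cov_zu
  cov_yx <- p$beta_yx * var_x + p$beta_yz * cov_xz + p$beta_yu * cov_xu
  var_y <- p$beta_yx * cov_yx + p$beta_yz * cov_yz + p$beta_yu * cov_yu +
    p$var_y_resid

  rho_uz <- cov_zu / sqrt(var_u * var_z)
  rho_xz <- cov_xz / sqrt(var_x * var_z)
  rho_xu <- cov_xu / sqrt(var_x * var_u)

  sigma <- matrix(c(var_u,  cov_zu, cov_xu, cov_yu,
                    cov_zu, var_z,  cov_xz, cov_yz,
                    cov_xu, cov_xz, var_x,  cov_yx,
                    cov_yu, cov_yz, cov_yx, var_y),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(c("u", "z", "x", "y"),
                                  c("u", "z", "x", "y")))

  m <- list(var_u = var_u, var_z = var_z, var_x = var_x, var_y = var_y,
            cov_zu = cov_zu, cov_xu = cov_xu, cov_xz = cov_xz,
            cov_yu = cov_yu, cov_yz = cov_yz, cov_yx = cov_yx,
            rho_uz = rho_uz, rho_xz = rho_xz, rho_xu = rho_xu,
            var_u_given_z = var_u * (1 - rho_uz^2),
            var_x_given_z = var_x * (1 - rho_xz^2),
            sigma = sigma)
  class(m) <- "implied_moments"
  m
}

#' @export
print.implied_moments <- function(x, ...) {
  cat("Implied second moments over (U, Z, X, Y):\n")
  print(round(x$sigma, 6))
  cat(sprintf("rho_uz = %.4f, rho_xz = %.4f, rho_xu = %.4f\n",
              x$rho_uz, x$rho_xz, x$rho_xu))
  invisible(x)
}
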