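#' Generate a synthetic dataset from a structural scenario
#'
#' Samples one dataset from the structural model: U first from
#' N(0, var_u), then Z from U, X from Z and U, and finally Y from X, Z, U,
#' each with independent normal residuals. The unmeasured confounder U is
#' retained as a column so that a "full model" reference fit is possible;
#' analysis functions only use it when explicitly requested.
#'
#' @param params A [scenario_params()] object.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `data.frame` with `params$n` rows and columns `y`, `x`, `z`, `u`.
#' @examples
#' d <- generate_dataset(scenario_params(beta_xz = 1, beta_yz = 1, n = 500), seed = 1)
#' head(d)
#' @export
generate_dataset <- function(params, seed) {
  validate_scenario_params(params)
  stopifnot(length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  p <- params
  n <- p$n
  u <- stats::rnorm(n, 0, sqrt(p$var_u))
  z <- p$beta_zu * u + stats::rnorm(n, 0, sqrt(p$var_z_resid))
  x <- p$beta_xz * z + p$beta_xu * u + stats::rnorm(n, 0, sqrt(p$var_x_resid))
  y <- p$beta_yx * x + p$beta_yz * z + p$beta_yu * u +
    stats::rnorm(n, 0, sqrt(p$var_y_resid))
  data.frame(y = y, x = x, z = z, u = u)
}

#' Generate multivariate-normal data from a covariance matrix
#'
#' Draws `n` rows from a multivariate normal with the given mean vector and
#' covariance matrix. Used to emulate cohort data where only summary moments
#' are available; column roles record which variable plays outcome, exposure,
#' measured confounder and (optionally) unmeasured confounder downstream.
#'
#' @param mean Mean vector.
#' @param cov Symmetric positive semidefinite covariance matrix.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param roles Character vector naming the columns, by default
#'   `c("u","z","x","y")` when `cov` is 4x4 and unnamed.
#' @return A `data.frame` with `n` rows; its `"roles"` attribute records the
#'   column roles.
#' @examples
#' m <- implied_moments(scenario_params(beta_xz = 1, beta_yz = 1))
#' d <- generate_from_covariance(rep(0, 4), m$sigma, n = 100, seed = 1)
#' @export
generate_from_covariance <- function(mean, cov, n, seed, roles = NULL) {
  cov <- as.matrix(cov)
  k <- nrow(cov)
  if (ncol(cov) != k) stop("'cov' must be square", call. = FALSE)
  if (length(mean) != k)
    stop("'mean' length must match the dimension of 'cov'", call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("'cov' must be symmetric", call. = FALSE)
  cov <- (cov + t(cov)) / 2
  eig <- eigen(cov, symmetric = TRUE)
  tol <- -1e-8 * max(abs(eig$values), 1)
  if (any(eig$values < tol))
    stop(sprintf("'cov' is not positive semidefinite: smallest eigenvalue %.6g",
                 min(eig$values)), call. = FALSE)
  if (is.null(roles)) {
    roles <- colnames(cov)
    if (is.null(roles)) {
      if (k == 4L) roles <- c("u", "z", "x", "y")
      else roles <- paste0("v", seq_len(k))
    }
  }
  set.seed(as.integer(seed))
  lam <- pmax(eig$values, 0)
  zmat <- matrix(stats::rnorm(n * k), nrow = n)
  out <- zmat %*% (t(eig$vectors) * sqrt(lam))
  out <- sweep(out, 2, mean, "+")
  out <- as.data.frame(out)
  names(out) <- roles
  attr(out, "roles") <- roles
  out
}

validate_dataset <- function(data, cols) {
  if (!is.data.frame(data)) stop("'data' must be a data.frame", call. = FALSE)
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop("dataset lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (cl in cols) {
    v <- data[[cl]]
    if (!is.numeric(v) || anyNA(v))
      stop("column '", cl, "' must be numeric with no missing values",
           call. = FALSE)
  }
  invisible(data)
}
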