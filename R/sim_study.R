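#' Build the full factorial scenario grid
#'
#' The 72 simulation scenarios: beta_zu in {0, 1} x beta_yz in {1, 2} x
#' beta_xz in {1, 2} x beta_yu in {0, 1, 2} x beta_xu in {0, 1, 2}, with
#' beta_yx = 0, all variances 1 and n = 1000. Ordering is deterministic:
#' beta_zu varies slowest, then beta_yz, beta_xz, beta_yu, beta_xu.
#'
#' @param n Sample size per dataset (default 1000).
#' @return A list of [scenario_params()] of length 72, with a `grid_id`
#'   attribute on each element.
#' @export
build_grid <- function(n = 1000L) {
  design <- expand.grid(beta_xu = c(0, 1, 2), beta_yu = c(0, 1, 2),
                        beta_xz = c(1, 2), beta_yz = c(1, 2),
                        beta_zu = c(0, 1))
  # expand.grid varies the first column fastest; reorder columns for clarity
  design <- design[, c("beta_zu", "beta_yz", "beta_xz", "beta_yu", "beta_xu")]
  grid <- lapply(seq_len(nrow(design)), function(i) {
    p <- scenario_params(beta_yx = 0,
                         beta_yz = design$beta_yz[i],
                         beta_xz = design$beta_xz[i],
                         beta_yu = design$beta_yu[i],
                         beta_xu = design$beta_xu[i],
                         beta_zu = design$beta_zu[i],
                         n = n)
    attr(p, "grid_id") <- i
    p
  })
  grid
}

#' Scenarios printed in the headline results table
#'
#' The 18 grid members with beta_xz = beta_yz = 1, numbered in the printed
#' row order: beta_yu slowest (0, 1, 2), then beta_xu (0, 1, 2), then
#' beta_zu (0, 1).
#'
#' @param n Sample size per dataset (default 1000).
#' @return Named list of 18 [scenario_params()] ("row1" ... "row18").
#' @export
table1_scenarios <- function(n = 1000L) {
  rows <- expand.grid(beta_zu = c(0, 1), beta_xu = c(0, 1, 2),
                      beta_yu = c(0, 1, 2))
  out <- lapply(seq_len(nrow(rows)), function(i) {
    scenario_params(beta_yx = 0, beta_yz = 1, beta_xz = 1,
                    beta_yu = rows$beta_yu[i], beta_xu = rows$beta_xu[i],
                    beta_zu = rows$beta_zu[i], n = n)
  })
  names(out) <- paste0("row", seq_along(out))
  out
}

#' Summarize Monte-Carlo estimates against the truth
#'
#' @param estimates Numeric vector of at least two finite estimates.
#' @param truth The true parameter value.
#' @return Named vector `c(bias, sd, mse)`: mean estimate minus truth,
#'   sample standard deviation (denominator n-1), and mean squared
#'   deviation from the truth.
#' @examples
#' summarize_estimates(c(0, 2), truth = 0)  # bias 1, sd sqrt(2), mse 2
#' @export
summarize_estimates <- function(estimates, truth) {
  if (length(estimates) < 2L)
    stop("need at least 2 estimates", call. = FALSE)
  if (!all(is.finite(estimates)))
    stop("non-finite estimates", call. = FALSE)
  c(bias = mean(estimates) - truth,
    sd = stats::sd(estimates),
    mse = mean((estimates - truth)^2))
}

#' Run one simulation scenario under all five estimators
#'
#' For each replicate r a dataset is generated with seed
#' `master_seed + r`, then analysed five ways: OLS of Y on X (unadjusted),
#' OLS of Y on X and Z (adjusted), and the Gibbs sampler with each supplied
#' prior. The X-coefficient estimates (posterior means for the Bayesian
#' fits) are summarized against the structural truth `beta_yx`.
#'
#' @param params A [scenario_params()] object.
#' @param priors Named list of [prior_spec()] objects; defaults to the
#'   three informative priors centred on the true `beta_yz` with precision
#'   n, n/10 and n/100 (see [default_priors()]).
#' @param reps Number of Monte-Carlo replicates (>= 2, default 100).
#' @param master_seed Base seed; replicate r uses `master_seed + r`.
#' @param mcmc An [mcmc_config()] template; its seed is overridden per
#'   replicate.
#' @return An object of class `scenario_metrics`: a list with the
#'   parameters, a `metrics` data.frame (one row per method with bias, sd,
#'   mse), `reps` and `master_seed`.
#' @export
run_scenario <- function(params, priors = NULL, reps = 100L,
                         master_seed = 1L, mcmc = mcmc_config()) {
  validate_scenario_params(params)
  reps <- as.integer(reps)
  if (reps < 2L) stop("reps must be >= 2", call. = FALSE)
  if (is.null(priors)) priors <- default_priors(params)
  stopifnot(length(priors) >= 1L, all(vapply(priors, inherits, TRUE,
                                             "prior_spec")))
  if (is.null(names(priors)))
    names(priors) <- paste0("bayes", seq_along(priors))

  methods <- c("unadjusted", "adjusted", names(priors))
  est <- matrix(NA_real_, nrow = reps, ncol = length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    seed_r <- master_seed + r
    d <- tryCatch({
      dat <- generate_dataset(params, seed = seed_r)
      est[r, "unadjusted"] <- ols_fit(dat, "x")$estimate[["x"]]
      est[r, "adjusted"] <- ols_fit(dat, c("x", "z"))$estimate[["x"]]
      for (nm in names(priors)) {
        cfg <- mcmc_config(mcmc$n_chains, mcmc$n_iter, mcmc$n_burn,
                           seed = seed_r)
        fit <- suppressWarnings(gibbs_fit(dat, priors[[nm]], cfg))
        est[r, nm] <- fit$mean[["x"]]
      }
      NULL
    }, error = function(e) e)
    if (!is.null(d))
      stop("replicate with seed ", seed_r, " failed: ", conditionMessage(d),
           call. = FALSE)
  }
  metrics <- as.data.frame(t(apply(est, 2, summarize_estimates,
                                   truth = params$beta_yx)))
  metrics <- cbind(method = rownames(metrics), metrics)
  rownames(metrics) <- NULL
  structure(list(params = params, metrics = metrics, estimates = est,
                 reps = reps, master_seed = master_seed),
            class = "scenario_metrics")
}

#' Default informative priors for a scenario
#'
#' The three priors of the simulation study: normal on the Z-Y coefficient
#' with the true `beta_yz` as mean and precision n, n/10 and n/100.
#'
#' @param params A [scenario_params()] object.
#' @return Named list of three [prior_spec()] objects
#'   (`tau_n`, `tau_n10`, `tau_n100`).
#' @export
default_priors <- function(params) {
  n <- params$n
  list(tau_n = prior_spec(mu_yz = params$beta_yz, tau_yz = n),
       tau_n10 = prior_spec(mu_yz = params$beta_yz, tau_yz = n / 10),
       tau_n100 = prior_spec(mu_yz = params$beta_yz, tau_yz = n / 100))
}

#' @export
print.scenario_metrics <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Scenario (beta_zu=%g, beta_yz=%g, beta_xz=%g, beta_yu=%g, beta_xu=%g), %d reps\n",
    p$beta_zu, p$beta_yz, p$beta_xz, p$beta_yu, p$beta_xu, x$reps))
  m <- x$metrics
  m[, -1] <- round(m[, -1], 4)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Reproduce a results table over a set of scenarios
#'
#' Runs [run_scenario()] for each scenario and assembles one row per
#' scenario with the (bias, sd, mse) triple for every method. Column order
#' follows the printed table: unadjusted, adjusted, then the Bayesian
#' models from the most to the least precise prior (the n/10 column is
#' included; published tables omit it for clarity).
#'
#' @param scenarios List of [scenario_params()] (e.g. [table1_scenarios()]
#'   or a subset of [build_grid()]). May be empty.
#' @param reps Replicates per scenario (default 100).
#' @param master_seed Base seed; scenario i uses `master_seed + 10000 * i`.
#' @param mcmc An [mcmc_config()] template.
#' @param verbose Print a progress line per scenario?
#' @return A data.frame with one row per scenario: the scenario parameters
#'   followed by `<method>_bias`, `<method>_sd`, `<method>_mse` columns.
#' @export
reproduce_table <- function(scenarios, reps = 100L, master_seed = 1L,
                            mcmc = mcmc_config(), verbose = FALSE) {
  method_cols <- c("unadjusted", "adjusted", "tau_n", "tau_n10", "tau_n100")
  par_cols <- c("beta_zu", "beta_yz", "beta_xz", "beta_yu", "beta_xu")
  header <- c("scenario", par_cols,
              as.vector(t(outer(method_cols, c("bias", "sd", "mse"),
                                paste, sep = "_"))))
  if (length(scenarios) == 0L) {
    out <- as.data.frame(matrix(numeric(0), ncol = length(header),
                                dimnames = list(NULL, header)))
    out$scenario <- character(0)
    return(out[, header])
  }
  ids <- names(scenarios)
  if (is.null(ids)) ids <- as.character(seq_along(scenarios))
  rows <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    t0 <- proc.time()[["elapsed"]]
    sm <- run_scenario(scenarios[[i]], reps = reps,
                       master_seed = master_seed + 10000L * i, mcmc = mcmc)
    p <- sm$params
    row <- c(list(scenario = ids[i]),
             stats::setNames(lapply(par_cols, function(cl) p[[cl]]), par_cols))
    for (mth in sm$metrics$method) {
      mm <- sm$metrics[sm$metrics$method == mth, ]
      row[[paste0(mth, "_bias")]] <- mm$bias
      row[[paste0(mth, "_sd")]] <- mm$sd
      row[[paste0(mth, "_mse")]] <- mm$mse
    }
    rows[[i]] <- as.data.frame(row, check.names = FALSE)
    if (verbose)
      message(sprintf("scenario %s done in %.1fs", ids[i],
                      proc.time()[["elapsed"]] - t0))
  }
  out <- do.call(rbind, rows)
  out[, intersect(header, names(out))]
}
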