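test_that("unadjusted bias matches the published closed-form values", {
  tb <- table1_scenarios()
  expect_equal(bias_unadjusted(tb$row1), 0.50, tolerance = 1e-12)
  expect_equal(bias_unadjusted(tb$row8), 1.00, tolerance = 1e-12)
  # no confounder-outcome paths: no bias
  expect_equal(bias_unadjusted(scenario_params(beta_xz = 1, beta_xu = 1,
                                               beta_zu = 1)), 0)
})

test_that("Z-adjusted bias matches the published closed-form values", {
  tb <- table1_scenarios()
  expect_equal(bias_adjusted_z(tb$row9), 0.50, tolerance = 1e-12)
  expect_equal(bias_adjusted_z(tb$row10), 1 / 3, tolerance = 1e-12)
  expect_equal(bias_adjusted_z(tb$row16), 2 / 3, tolerance = 1e-12)
  # U with no path to X cannot confound X-Y given Z
  expect_equal(bias_adjusted_z(scenario_params(beta_zu = 1, beta_xz = 1,
                                               beta_yz = 1, beta_yu = 1)), 0)
})

test_that("closed forms equal the population-regression oracle on all 72 scenarios", {
  for (p in build_grid()) {
    m <- implied_moments(p)
    o_unadj <- population_regression(m$sigma, "y", "x")[["x"]] - p$beta_yx
    o_adj <- population_regression(m$sigma, "y", c("x", "z"))[["x"]] - p$beta_yx
    expect_equal(bias_unadjusted(p), o_unadj, tolerance = 1e-10)
    expect_equal(bias_adjusted_z(p), o_adj, tolerance = 1e-10)
  }
})

test_that("population regression reproduces known coefficient values", {
  p8 <- scenario_params(beta_zu = 1, beta_xz = 1, beta_yz = 1, beta_yu = 1)
  b <- population_regression(implied_moments(p8)$sigma, "y", c("x", "z"))
  expect_equal(unname(b), c(0, 1.5), tolerance = 1e-12)
  expect_gt(b[["z"]], 1)  # Z-Y coefficient biased above the structural 1

  p16 <- scenario_params(beta_zu = 1, beta_xz = 1, beta_yz = 1, beta_yu = 2,
                         beta_xu = 1)
  b16 <- population_regression(implied_moments(p16)$sigma, "y", c("x", "z"))
  expect_equal(b16[["x"]], 2 / 3, tolerance = 1e-12)

  # identity covariance: coefficients are the raw covariances with y
  S <- diag(3); dimnames(S) <- list(c("x", "z", "y"), c("x", "z", "y"))
  S["x", "y"] <- S["y", "x"] <- 0.3
  expect_equal(population_regression(S, "y", c("x", "z")),
               c(x = 0.3, z = 0))

  expect_error(population_regression(matrix(1, 3, 3), 3, 1:2), "singular")
})

test_that("confounder-outcome bias formula behaves as derived", {
  # no direct U effect: no bias
  expect_equal(bias_zy_conditional(standardized_correlations(0.4, 0.3, 0.2, 0)),
               0)
  # marginally independent Z and U, but conditioning on the collider X
  # opens Z -> Y via U
  b <- bias_zy_conditional(standardized_correlations(0, 0.5, 0.5, 1))
  expect_equal(b, -1 * 0.5 * 0.5 / (1 - 0.25), tolerance = 1e-12)
  expect_true(b != 0)
  # direct substitution
  expect_equal(bias_zy_conditional(standardized_correlations(0.5, 0, 0.5, 1)),
               0.5)
  # degenerate: Z a perfect proxy of X
  expect_error(bias_zy_conditional(standardized_correlations(0, 1, 0, 1)),
               "rho_xz")
  expect_error(standardized_correlations(0.9, -0.9, 0.9, 1),
               "positive semidefinite")
})

test_that("standardized conversion agrees with the standardized-scale oracle", {
  for (p in list(scenario_params(beta_zu = 1, beta_xz = 1, beta_yz = 1,
                                 beta_yu = 1),
                 scenario_params(beta_xz = 2, beta_yz = 1, beta_xu = 1,
                                 beta_yu = 2),
                 scenario_params(beta_zu = 1, beta_xz = 1, beta_yz = 2,
                                 beta_xu = 2, beta_yu = 1))) {
    m <- implied_moments(p)
    R <- stats::cov2cor(m$sigma)
    bz_pop <- population_regression(R, "y", c("x", "z"))[["z"]]
    bz_true_std <- p$beta_yz * sqrt(m$var_z / m$var_y)
    expect_equal(bias_zy_conditional(standardize_scenario(p)),
                 bz_pop - bz_true_std, tolerance = 1e-10)
  }
})

test_that("confounder-outcome bias verified by simulation", {
  corr <- standardized_correlations(0.5, 0, 0.5, 1)
  # joint standardized model: Z, X, U with those correlations and
  # Y = 0.3 X + 0.2 Z + 1 U + e; regress Y on X, Z and inspect the Z bias
  R <- matrix(c(1, 0, 0.5,
                0, 1, 0.5,
                0.5, 0.5, 1), 3, 3,
              dimnames = list(c("z", "x", "u"), c("z", "x", "u")))
  set.seed(99)
  n <- 2e5
  L <- chol(R)
  zxu <- matrix(rnorm(3 * n), ncol = 3) %*% L
  colnames(zxu) <- c("z", "x", "u")
  y <- 0.3 * zxu[, "x"] + 0.2 * zxu[, "z"] + zxu[, "u"] + rnorm(n)
  bz <- coef(lm(y ~ 0 + zxu[, "x"] + zxu[, "z"]))[[2]]
  expect_equal(bz - 0.2, bias_zy_conditional(corr), tolerance = 0.02)
})

test_that("adjusted bias is monotone in its drivers", {
  base <- function(beta_xu, beta_yu, beta_zu)
    scenario_params(beta_zu = beta_zu, beta_xz = 1, beta_yz = 1,
                    beta_xu = beta_xu, beta_yu = beta_yu)
  # nondecreasing in |beta_yu| (which leaves the X, Z, U moments untouched)
  b_yu <- sapply(c(0, 0.5, 1, 2), function(v) abs(bias_adjusted_z(base(1, v, 0))))
  expect_true(all(diff(b_yu) >= 0))
  # decreasing as the confounders become more correlated
  b_zu <- sapply(c(0, 0.5, 1, 2), function(v) abs(bias_adjusted_z(base(1, 1, v))))
  expect_true(all(diff(b_zu) < 0))
  # in the formula itself (moments held fixed), the bias scales linearly
  # with beta_xu * beta_yu; at the structural level raising beta_xu also
  # inflates Var(X), so monotonicity is a formula-level statement
  m <- implied_moments(base(1, 1, 0))
  fixed_moment_bias <- function(bxu, byu)
    bxu * byu * m$var_u * (1 - m$rho_uz^2) / (m$var_x * (1 - m$rho_xz^2))
  vals <- sapply(c(0, 0.5, 1, 2), fixed_moment_bias, byu = 1)
  expect_true(all(diff(vals) > 0))
})

test_that("near-instrument adjustment amplifies residual bias", {
  # with Z unrelated to U, the residual confounding carried by U is scaled
  # by Var(X)/Var(X|Z) = 1/(1 - rho_xz^2) once Z is adjusted for; the
  # amplification factor grows with the Z-X relation
  amp_factor <- function(beta_xz) {
    p <- scenario_params(beta_zu = 0, beta_xz = beta_xz, beta_yz = 1,
                         beta_xu = 1, beta_yu = 1)
    m <- implied_moments(p)
    u_term_unadjusted <- p$beta_yu * m$var_u * p$beta_xu / m$var_x
    abs(bias_adjusted_z(p)) / abs(u_term_unadjusted)
  }
  vals <- sapply(c(0, 1, 2, 3), amp_factor)
  expect_equal(vals[1], 1)  # no Z-X relation: adjustment changes nothing
  expect_true(all(diff(vals) > 0))

  # a near-instrument (strong Z-X, no Z-Y path) makes adjustment worse
  # than no adjustment at all
  near_iv <- scenario_params(beta_zu = 0, beta_xz = 2, beta_yz = 0,
                             beta_xu = 1, beta_yu = 1)
  expect_gt(abs(bias_adjusted_z(near_iv)), abs(bias_unadjusted(near_iv)))
})

test_that("both bias formulas are invariant to the true exposure effect", {
  for (byx in c(-2, 0, 0.5, 3)) {
    p <- scenario_params(beta_yx = byx, beta_zu = 1, beta_xz = 1,
                         beta_yz = 1, beta_xu = 1, beta_yu = 2)
    p0 <- scenario_params(beta_yx = 0, beta_zu = 1, beta_xz = 1,
                          beta_yz = 1, beta_xu = 1, beta_yu = 2)
    expect_equal(bias_unadjusted(p), bias_unadjusted(p0))
    expect_equal(bias_adjusted_z(p), bias_adjusted_z(p0))
  }
})
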