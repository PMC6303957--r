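# priorconf

Sensitivity analysis of unmeasured confounding for linear exposure–outcome
models, via an informative prior on the *measured* confounder–outcome
relation.

## The problem

Observational estimates of a continuous exposure effect are biased when a
common cause of exposure and outcome is not adjusted for. Classical Bayesian
sensitivity analyses put priors on the parameters of the *unmeasured*
confounder — quantities that are, almost by definition, hard to elicit.
`priorconf` implements the complementary idea: unmeasured confounding also
distorts the coefficient of the *measured* confounder, so constraining that
coefficient with an informative prior (its plausible value is often known
from large studies or meta-analyses) can indirectly pull bias out of the
exposure coefficient.

## The model

Structural equations for outcome *Y*, exposure *X*, measured confounder *Z*
and unmeasured confounder *U* (all continuous, zero mean, linear,
independent normal errors):

```
z_i = β_zu u_i + ξ_i
x_i = β_xz z_i + β_xu u_i + ζ_i
y_i = β_yx x_i + β_yz z_i + β_yu u_i + ε_i
```

The package provides, for this model:

- **Closed-form asymptotic biases.** Omitting both confounders:
  `bias(β_yx) = β_yz(β_xz·Var(Z) + β_zu·β_xu·Var(U))/Var(X) +
  β_yu·Var(U)(β_xu + β_zu·β_xz)/Var(X)`. Omitting only *U* while adjusting
  for *Z*: `bias(β_yx|z) = β_xu·β_yu·Var(U)(1−ρ_uz²) / (Var(X)(1−ρ_xz²))`.
  A third expression gives the induced bias in the *Z–Y* coefficient
  (collider distortion through conditioning on *X*), the signal the prior
  exploits. All three are verified against a population-regression oracle
  (`population_regression()`).
- **A Gibbs sampler** (`gibbs_fit()`, C++ core) for the Bayesian linear
  model of *Y* on *X* and *Z* with priors `β_yx ~ N(0, τ = 0.001)`,
  `β_yz ~ N(μ, τ)` (the informative part, τ a precision) and
  `σ ~ U(0, 100)`; 4 chains × 2000 iterations with 1000 burn-in by default,
  potential-scale-reduction diagnostics, posterior mean as point estimate.
- **A Monte-Carlo harness** (`run_scenario()`, `reproduce_table()`) that
  compares unadjusted OLS, Z-adjusted OLS and three Bayesian fits
  (prior precision n, n/10, n/100) by bias, empirical SD and MSE over a
  72-scenario factorial grid (`build_grid()`).

## Worked example

A scenario where *U* genuinely confounds the *X–Y* relation
(β_xu = β_yu = 1) alongside an independent measured confounder *Z*:

```r
library(priorconf)
scen <- scenario_params(beta_yx = 0, beta_yz = 1, beta_xz = 1,
                        beta_yu = 1, beta_xu = 1, beta_zu = 0, n = 1000)
bias_unadjusted(scen)   # 0.667  — Y ~ X alone
bias_adjusted_z(scen)   # 0.500  — Y ~ X + Z, U still omitted

d <- generate_dataset(scen, seed = 42)
ols_fit(d, c("x", "z"))
#>   estimate     se
#> x   0.4838 0.0276     <- biased: truth is 0
#> z   0.5906 0.0483     <- also biased: truth is 1

gibbs_fit(d, prior_spec(mu_yz = 1, tau_yz = 1000), mcmc_config(seed = 42))
#>         mean     sd   rhat
#> x     0.3897 0.0253 0.9999   <- bias pulled from 0.48 toward 0
#> z     0.8810 0.0272 0.9998   <- prior pulls Z-Y back toward 1
#> sigma 1.2642 0.0292 1.0001
```

The OLS fit of *Z* lands at 0.59 when its structural value is 1 — an
"unexpected" confounder–outcome estimate that flags unmeasured confounding.
Anchoring it with a precise prior centred at 1 moves the exposure
coefficient from 0.48 to 0.39. Averaged over 100 replicates:

```r
run_scenario(scen, reps = 100, master_seed = 42)
#>      method   bias     sd    mse
#>  unadjusted 0.6685 0.0233 0.4475
#>    adjusted 0.5021 0.0284 0.2530
#>       tau_n 0.3847 0.0237 0.1485   <- precision 1000: least bias and MSE
#>     tau_n10 0.4713 0.0266 0.2228
#>    tau_n100 0.4985 0.0282 0.2493
```

The gain is not universal: when *U* confounds *Z–Y* but not *X–Y*, the same
prior *induces* exposure bias, and when the biased *Z* coefficient already
equals the prior mean, nothing changes. The methods vignette
(`vignettes/informative-prior-confounding.Rmd`) works through these regimes.

A thin command-line front end is included:

```sh
Rscript inst/scripts/priorconf-cli.R grid --scenarios table1 --reps 100 --seed 1 --out table1.csv
Rscript inst/scripts/priorconf-cli.R fit --data mydata.csv --prior-mean 0.32 --prior-precision 1000 --seed 1 --out fit.json
```

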