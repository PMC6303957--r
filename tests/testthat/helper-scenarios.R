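# Shared Monte-Carlo runs: scenario results are cached so that the several
# tests reading different cells of the same replication table trigger one
# simulation per scenario, not one per assertion.
.scenario_cache <- new.env(parent = emptyenv())

table1_run <- function(i, reps = 100L) {
  key <- sprintf("row%d_%d", i, reps)
  if (is.null(.scenario_cache[[key]])) {
    p <- table1_scenarios()[[i]]
    .scenario_cache[[key]] <- run_scenario(p, reps = reps,
                                           master_seed = 100000L + 1000L * i)
  }
  .scenario_cache[[key]]
}

metric_of <- function(sm, method, what) {
  sm$metrics[sm$metrics$method == method, what]
}

# delta-method tolerance for a sample covariance under normality
cov_tol <- function(sii, sjj, sij, n, z = 4) z * sqrt((sii * sjj + sij^2) / n)
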