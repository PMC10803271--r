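# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_genome <- function() {
  if (is.null(.fixture_env$genome)) .fixture_env$genome <- toy_genome()
  .fixture_env$genome
}

# a small simulated cohort reused by several test files
fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_cohort(simulation_config(n_cases = 30L, seed = 101L))
  }
  .fixture_env$sim
}

fixture_report <- function() {
  if (is.null(.fixture_env$report)) {
    sim <- fixture_sim()
    .fixture_env$report <- interpret_cohort(sim$cases, sim$call_sets, sim$bundle)
  }
  .fixture_env$report
}

passing_qc <- function(...) {
  m <- tibble::tibble(
    normal_yield_gb = 100, tumor_yield_gb = 250,
    normal_autosome_cov15_frac = 0.97, normal_contamination = 0.01,
    tumor_contamination = 0.01, pair_concordant = TRUE
  )
  overrides <- list(...)
  m[names(overrides)] <- overrides
  m
}
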