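# Shared fixtures, all built in code.

# life table with no mortality until the cap (forced to 1 at the cap age)
flat_life_table <- function(max_age = 200, p = 0) {
  tibble::tibble(
    age = 0:max_age,
    p_annual = c(rep(p, max_age), 1)
  )
}

# a single-matrix schedule: the same clinical matrix in force forever
constant_schedule <- function(m, name = "const") {
  transition_schedule(name, list(
    year1 = m, year2 = m, year3 = m, natural_history = m
  ))
}

# random row-stochastic clinical matrix (dense; for conservation properties)
random_clinical_matrix <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m / rowSums(m)
}

# a compact scenario for pipeline-level tests: default study conditions but
# a short horizon so full runs stay fast
small_scenario <- function(horizon_years = 5, seed = 42, ...) {
  dme_scenario(horizon_years = horizon_years, seed = seed, ...)
}
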