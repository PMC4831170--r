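test_that("discounting starts only beyond the first year", {
  s <- discount_settings(0.035)
  expect_equal(discount_factor(0.5, s), 1)
  expect_equal(discount_factor(1, s), 1)
  # frozen: 1.035^-2 evaluated independently
  expect_equal(discount_factor(2, s), 0.933510700366403, tolerance = 1e-12)
  expect_equal(discount_factor(c(0, 3), discount_settings(0)), c(1, 1))
  expect_error(discount_factor(-1, s), "non-negative")
  # alternative convention: time measured from the cutoff
  s2 <- discount_settings(0.035, from_time_zero = FALSE)
  expect_equal(discount_factor(2, s2), 1.035^-1, tolerance = 1e-12)
})

test_that("constant utility, no deaths, no discounting gives QALYs = u * T", {
  u <- 0.731
  T_years <- 7
  sched <- constant_schedule(diag(2))
  mort <- mortality_model(flat_life_table(), rr_combined = 2.45)
  tr <- run_cohort(c(1, 0), sched, mort, horizon_cycles = T_years * 4)
  q <- accumulate_trace(tr, c(u, u, 0), discount_settings(0))
  expect_equal(q, u * T_years, tolerance = 1e-9)
})

test_that("a single cycle accumulates half-cycle-corrected payoff", {
  sched <- constant_schedule(diag(1) + 0)
  mort <- mortality_model(flat_life_table(), rr_combined = 1)
  tr <- run_cohort(1, sched, mort, horizon_cycles = 1)
  u_b <- 0.8
  got <- accumulate_trace(tr, c(u_b, 0), discount_settings(0.035))
  # occupancy constant: 0.5*(1+1) * u_b * 0.25 * df(0.125), df = 1 inside year 1
  expect_equal(got, u_b * 0.25)
})

test_that("time without visual impairment saturates at the horizon", {
  sc <- small_scenario(horizon_years = 4)
  sc$discount$annual_rate <- 0
  sc$life_table <- flat_life_table()
  res <- run_cea(sc)
  # no deaths, cohort starts above the threshold and treatment-year matrices
  # keep everyone alive: years without VI cannot exceed the horizon
  expect_true(all(res$strategies$years_no_vi <= 4 + 1e-9))
  expect_equal(res$strategies$life_years, rep(4, 3), tolerance = 1e-12)
})

test_that("trapezoidal totals lie between start- and end-of-cycle totals", {
  set.seed(21)
  mort <- mortality_model(generate_life_table())
  for (i in 1:10) {
    n <- sample(2:5, 1)
    sched <- constant_schedule(random_clinical_matrix(n))
    init <- as.numeric(random_clinical_matrix(n)[1, ])
    tr <- run_cohort(init, sched, mort, horizon_cycles = 20)
    payoff <- c(sort(stats::runif(n)), 0)
    s <- discount_settings(0.035)
    tot <- vapply(c("start", "trapezoid", "end"), function(w) {
      accumulate_trace(tr, payoff, s, timing = w)
    }, numeric(1))
    expect_gte(tot[["trapezoid"]], min(tot[["start"]], tot[["end"]]) - 1e-12)
    expect_lte(tot[["trapezoid"]], max(tot[["start"]], tot[["end"]]) + 1e-12)
    # trapezoid is exactly the mean of the two endpoint accumulations
    expect_equal(tot[["trapezoid"]], (tot[["start"]] + tot[["end"]]) / 2,
                 tolerance = 1e-12)
  }
})

test_that("higher discount rates never increase non-negative totals", {
  sc <- small_scenario(horizon_years = 6)
  totals <- vapply(c(0, 0.035, 0.07), function(r) {
    sc$discount$annual_rate <- r
    run_cea(sc, keep_traces = FALSE)$strategies$qalys[1]
  }, numeric(1))
  expect_true(totals[3] <= totals[2] && totals[2] <= totals[1])
})

test_that("comparisons flag dominance and honour the NMB identity", {
  a <- list(strategy = "ran", cost = 12180, qalys = 8.59, years_no_vi = 4.352)
  b <- list(strategy = "afl", cost = 15004, qalys = 8.54, years_no_vi = 4.321)
  cmp <- compare_strategies(a, b, wtp = 25000)
  expect_equal(cmp$delta_cost, -2824)
  expect_equal(cmp$dominance, "dominant")
  expect_equal(cmp$icer, "dominant")
  expect_equal(cmp$nmb, 0.05 * 25000 + 2824, tolerance = 1e-9)
  expect_identical(cmp$nmb, cmp$delta_qalys * cmp$wtp - cmp$delta_cost)

  cmp2 <- compare_strategies(
    list(strategy = "a", cost = 1000, qalys = 0.1, years_no_vi = 0),
    list(strategy = "b", cost = 0, qalys = 0, years_no_vi = 0), wtp = 25000
  )
  expect_equal(cmp2$icer_value, 10000)
  expect_equal(cmp2$nmb, 1500)
  expect_equal(cmp2$dominance, "none")

  # break-even: NMB exactly zero
  cmp3 <- compare_strategies(
    list(strategy = "a", cost = 2500, qalys = 0.1, years_no_vi = 0),
    list(strategy = "b", cost = 0, qalys = 0, years_no_vi = 0), wtp = 25000
  )
  expect_equal(cmp3$nmb, 0)

  # zero QALY difference: ICER undefined, NMB still computed
  cmp4 <- compare_strategies(
    list(strategy = "a", cost = 100, qalys = 1, years_no_vi = 1),
    list(strategy = "b", cost = 0, qalys = 1, years_no_vi = 1), wtp = 25000
  )
  expect_match(cmp4$icer, "undefined")
  expect_equal(cmp4$nmb, -100)
})

test_that("scaling every unit cost scales totals and deltas linearly", {
  sc <- small_scenario(horizon_years = 4)
  res1 <- run_cea(sc, keep_traces = FALSE)
  k <- 3
  sc2 <- sc
  for (f in c("admin_cost", "monitoring_cost", "laser_cost", "vi_cost_year1",
              "vi_cost_year2plus", "blindness_allowance")) {
    sc2$costs[[f]] <- sc2$costs[[f]] * k
  }
  for (nm in names(sc2$strategies)) {
    sc2$strategies[[nm]]$price <- sc2$strategies[[nm]]$price * k
  }
  res2 <- run_cea(sc2, keep_traces = FALSE)
  expect_equal(res2$strategies$cost, k * res1$strategies$cost,
               tolerance = 1e-12)
  expect_equal(res2$comparisons$delta_cost, k * res1$comparisons$delta_cost,
               tolerance = 1e-12)
  expect_equal(res2$strategies$qalys, res1$strategies$qalys)
})
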