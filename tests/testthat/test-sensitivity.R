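sc_small <- small_scenario(horizon_years = 4, seed = 42)

test_that("a degenerate range produces zero swing", {
  r <- tibble::tibble(
    parameter = "Administration cost",
    path = list(c("costs", "admin_cost")),
    base = 66.4, low = 66.4, high = 66.4, variation = "none"
  )
  ow <- run_owsa(sc_small, r)
  expect_equal(ow$swing, rep(0, nrow(ow)))
  expect_equal(ow$nmb_low, ow$nmb_base, tolerance = 1e-12)
})

test_that("raising the comparator's price raises the intervention's NMB", {
  r <- tibble::tibble(
    parameter = "Price of aflibercept",
    path = list(c("strategies", "aflibercept_2q8", "price")),
    base = 613.36, low = 460.02, high = 766.70, variation = "+/-25%"
  )
  ow <- run_owsa(sc_small, r)
  expect_true(all(ow$nmb_high > ow$nmb_low))
})

test_that("a linear cost parameter produces a symmetric swing", {
  r <- tibble::tibble(
    parameter = "Administration cost",
    path = list(c("costs", "admin_cost")),
    base = 66.4, low = 66.4 * 0.75, high = 66.4 * 1.25, variation = "+/-25%"
  )
  ow <- run_owsa(sc_small, r)
  expect_equal(ow$nmb_high - ow$nmb_base, ow$nmb_base - ow$nmb_low,
               tolerance = 1e-9)
})

test_that("tornado rows are sorted by swing and cover the input table", {
  ranges <- default_owsa_ranges(sc_small)
  expect_true(all(ranges$low <= ranges$base & ranges$base <= ranges$high))
  expect_setequal(
    ranges$parameter,
    c("Time horizon (years)", "Discount rate", "Baseline age",
      "Utility multiplier - BSE", "Utility multiplier - WSE",
      "Relative risk mortality with DME",
      "OR ranibizumab PRN vs aflibercept month 0-3",
      "OR ranibizumab T&E vs aflibercept month 0-3",
      "Price of ranibizumab", "Price of aflibercept",
      "Administration cost", "Monitoring visit cost",
      "VI state cost year 1", "VI state cost year 2+")
  )
  ow <- run_owsa(sc_small, ranges[1:4, ])
  for (cmp in unique(ow$comparison)) {
    expect_false(is.unsorted(rev(ow$swing[ow$comparison == cmp])))
  }
  bad <- ranges[1, ]
  bad$low <- bad$base + 1
  expect_error(run_owsa(sc_small, bad), "low <= base <= high")
  expect_error(run_owsa(sc_small, tibble::tibble(
    parameter = "x", path = list(c("no", "where")),
    base = 1, low = 0, high = 2, variation = ""
  )), "no\\$where")
})

test_that("identical seeds give bit-identical PSA draw sequences", {
  p1 <- run_psa(sc_small, n_sims = 15, seed = 101)
  p2 <- run_psa(sc_small, n_sims = 15, seed = 101)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(sc_small, n_sims = 15, seed = 102)
  expect_false(identical(p3$draws, p1$draws))
})

test_that("zero-variance distributions reproduce the base case", {
  sc <- sc_small
  sc$psa$zero_variance <- TRUE
  base <- run_cea(sc, keep_traces = FALSE)$comparisons
  psa <- run_psa(sc, n_sims = 20, seed = 8)
  for (i in unique(psa$draws$sim)) {
    d <- psa$draws[psa$draws$sim == i, ]
    expect_equal(d$delta_cost, base$delta_cost)
    expect_equal(d$delta_qalys, base$delta_qalys)
    expect_equal(d$nmb, base$nmb)
  }
})

test_that("gamma draws match their specified moments", {
  set.seed(99)
  base <- 66.4; low <- 49.8; high <- 83
  draws <- replicate(10000, dmecea:::draw_gamma(base, low, high, FALSE))
  sd_target <- (high - low) / (2 * qnorm(0.975))
  se <- sd_target / sqrt(10000)
  expect_lt(abs(mean(draws) - base), 2 * se)
  expect_true(all(draws > 0))
})

test_that("beta and Dirichlet draws respect their supports", {
  set.seed(4)
  u <- dmecea:::draw_beta_vec(rep(0.7, 500), 100, FALSE)
  expect_true(all(u > 0 & u < 1))
  row <- c(0.2, 0.5, 0.3, 0)
  d <- dmecea:::draw_dirichlet_row(100 * row, FALSE)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(d[4], 0)  # structural zeros stay zero
  expect_equal(dmecea:::draw_dirichlet_row(100 * row, TRUE), row)
})

test_that("drawn scenarios are complete and valid", {
  set.seed(31)
  resolved <- resolve_scenario(sc_small)
  for (i in 1:10) {
    s2 <- draw_psa_scenario(sc_small, resolved)
    expect_silent(validate_scenario(s2))
    for (m in s2$transitions$matrices) validate_transition_matrix(m)
    expect_true(all(diff(s2$utilities$bse) >= 0))
  }
})

test_that("the acceptability curve has the right limits and monotonicity", {
  draws <- tibble::tibble(
    comparison = "a",
    delta_cost = c(-100, -50, 20, 40, -10),
    delta_qalys = c(0.01, 0.02, 0.005, 0.001, 0.03)
  )
  ceac <- build_ceac(draws, wtp_grid = seq(0, 50000, by = 5000))
  # at zero WTP the probability is the fraction of cost-saving draws
  expect_equal(ceac$prob_cost_effective[ceac$wtp == 0],
               mean(draws$delta_cost < 0))
  # all gains positive: the curve is non-decreasing in WTP
  expect_false(is.unsorted(ceac$prob_cost_effective))
  # at high WTP it converges to P(QALY gain > 0) = 1 here
  expect_equal(ceac$prob_cost_effective[ceac$wtp == 50000], 1)

  dominant <- tibble::tibble(comparison = "a", delta_cost = c(-1, -2),
                             delta_qalys = c(0.1, 0.2))
  c2 <- build_ceac(dominant, wtp_grid = c(0, 25000))
  expect_equal(c2$prob_cost_effective, c(1, 1))
  expect_error(build_ceac(dominant, wtp_grid = numeric(0)), "non-empty")
})

test_that("NMB is strictly decreasing in a strategy's own price", {
  prices <- c(300, 656.16, 1200)
  nmbs <- vapply(prices, function(p) {
    s <- set_scenario_parameter(
      sc_small, c("strategies", "ranibizumab_prn", "price"), p)
    cmp <- run_cea(s, keep_traces = FALSE)$comparisons
    cmp$nmb[cmp$strategy == "ranibizumab_prn"]
  }, numeric(1))
  expect_true(all(diff(nmbs) < 0))
})

test_that("break-even price search is self-consistent and bracket-stable", {
  th <- find_price_threshold(sc_small, "ranibizumab_prn",
                             bounds = c(100, 4000), tol = 0.01)
  expect_lt(abs(attr(th, "nmb")), 1)  # one cent of price moves NMB < 1 EUR
  th2 <- find_price_threshold(sc_small, "ranibizumab_prn",
                              bounds = c(0, 8000), tol = 0.01)
  expect_lt(abs(as.numeric(th) - as.numeric(th2)), 0.02)
  expect_error(
    find_price_threshold(sc_small, "ranibizumab_prn", bounds = c(1, 2)),
    "does not change sign"
  )
  expect_error(find_price_threshold(sc_small, "nope"), "unknown strategy")
})
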