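test_that("net price deducts the rebate", {
  expect_equal(net_price(100, 0), 100)
  expect_equal(net_price(100, 0.08), 92)
  expect_error(net_price(-5, 0.1), "non-negative")
  expect_error(net_price(100, 1), "\\[0, 1\\)")
  # homogeneous of degree 1 in list price, decreasing in rebate
  expect_equal(net_price(2 * 781.52, 0.08), 2 * net_price(781.52, 0.08))
  expect_lt(net_price(100, 0.2), net_price(100, 0.1))
})

test_that("weighted unit costs reproduce the published tariffs", {
  # hospital/outpatient laser mix
  laser <- weighted_unit_cost(c(177, 20.15), c(0.625, 0.375))
  expect_equal(laser, 118.18125)
  expect_equal(round(laser), 118)
  # single component is returned as-is; monthly allowance sums to the year
  expect_equal(weighted_unit_cost(42.42, 1), 42.42)
  expect_equal(weighted_unit_cost(362, 12), 4344)
  expect_error(weighted_unit_cost(numeric(0), numeric(0)), "non-empty")
  expect_error(weighted_unit_cost(c(1, 2), 1), "same length")
  expect_error(weighted_unit_cost(c(1, 2), c(0.5, -0.5)), "non-negative")
})

test_that("state utilities mix eye classes and fold in bilateral patients", {
  um <- utility_model(bse = c(0.5, 0.8), wse = c(0.5, 0.8))
  # identical vectors: the mixture is the common vector
  expect_equal(state_utilities(um, include_death = FALSE), c(0.5, 0.8))
  # pure better-seeing-eye class
  um_b <- utility_model(bse = c(0.6, 0.9), wse = c(0.2, 0.3),
                        prop_bse = 0.998, prop_wse = 0, prop_bilateral = 1)
  expect_equal(state_utilities(um_b, include_death = FALSE), c(0.6, 0.9))
  # hand-mixed value at a 50/50 effective split
  um_h <- utility_model(bse = c(0.1, 0.80), wse = c(0.1, 0.70),
                        prop_bse = 0.5, prop_wse = 0.5, prop_bilateral = 0)
  expect_equal(state_utility(2, um_h), 0.75)
  # death utility is zero, not an error
  expect_equal(state_utility(3, um_h), 0)
  expect_error(state_utility(9, um_h), "out of range")
})

test_that("the mixture lies between the two eye-class utilities", {
  set.seed(3)
  for (i in 1:20) {
    b <- sort(stats::runif(4))
    w <- sort(stats::runif(4))
    um <- utility_model(b, w, prop_bilateral = stats::runif(1))
    u <- state_utilities(um, include_death = FALSE)
    expect_true(all(u >= pmin(b, w) - 1e-12 & u <= pmax(b, w) + 1e-12))
  }
})

test_that("bilateral folding matches its closed form", {
  um <- utility_model(c(0.5, 0.8), c(0.6, 0.7))
  expect_equal(prop_bse_effective(um),
               0.22 + 0.78 * 0.402 / (0.402 + 0.596))
})

test_that("utility vectors must be monotone and in range", {
  expect_error(utility_model(c(0.8, 0.5), c(0.5, 0.6)), "non-decreasing")
  expect_error(utility_model(c(0.5, 1.2), c(0.5, 0.6)), "\\[-0.1, 1\\]")
  expect_error(utility_model(c(0.5, 0.8), c(0.5, 0.6), prop_bse = 0.7,
                             prop_wse = 0.7), "within 0.01")
})

test_that("cycle costs decompose by component and vanish after treatment", {
  ss <- build_state_space()
  st <- strategy("x", list_price = 100, rebate = 0, price = 100,
                 injections = list(year1 = 4, year2 = 4, year3 = 4),
                 monitoring = list(year1 = 4, year2 = 4, year3 = 4))
  cm <- cost_model(admin_cost = 10, monitoring_cost = 5, laser_cost = 0,
                   laser_sessions = list(year1 = 0, year2 = 0, year3 = 0))
  # death costs nothing in any cycle
  expect_equal(cycle_cost(ss$death_index, c(0, 5, 40), st, cm, ss),
               c(0, 0, 0))
  # treated, non-impaired band: drug + admin + monitoring only
  expect_equal(cycle_cost(5, 0, st, cm, ss), (100 + 10) * 1 + 5 * 1)
  # post-treatment, non-impaired: nothing
  expect_equal(cycle_cost(5, 12, st, cm, ss), 0)
  # post-treatment, impaired: year-2+ state cost per cycle
  expect_equal(cycle_cost(1, 12, st, cm, ss), 4866.49 / 4)
  # first-year impaired state cost
  expect_equal(cycle_cost(2, 0, st, cm, ss), (100 + 10) + 5 + 5248.49 / 4)
})

test_that("untreated visually impaired cycles cost a quarter of the annual rate", {
  ss <- build_state_space()
  st <- strategy("none", list_price = 0, price = 0,
                 injections = list(year1 = 0, year2 = 0, year3 = 0),
                 monitoring = list(year1 = 0, year2 = 0, year3 = 0))
  cm <- cost_model(laser_sessions = list(year1 = 0, year2 = 0, year3 = 0))
  expect_equal(cycle_cost(1, 4, st, cm, ss), 1216.6225)
})

test_that("the blindness allowance switch adds to the worst band only", {
  ss <- build_state_space()
  st <- strategy("none", list_price = 0, price = 0,
                 injections = list(year1 = 0, year2 = 0, year3 = 0),
                 monitoring = list(year1 = 0, year2 = 0, year3 = 0))
  base <- cost_model(laser_sessions = list(year1 = 0, year2 = 0, year3 = 0))
  extra <- cost_model(laser_sessions = list(year1 = 0, year2 = 0, year3 = 0),
                      add_blindness_allowance = TRUE)
  expect_equal(cycle_cost(1, 8, st, extra, ss) - cycle_cost(1, 8, st, base, ss),
               4344 / 4)
  expect_equal(cycle_cost(2, 8, st, extra, ss), cycle_cost(2, 8, st, base, ss))
})

test_that("the vectorised cost matrix agrees with per-state cycle costs", {
  sc <- dme_scenario()
  res <- resolve_scenario(sc)
  ss <- res$state_space
  st <- sc$strategies$aflibercept_2q8
  cm <- cost_matrix(16, st, res$costs, ss)
  for (b in 1:ss$n_states) {
    expect_equal(cm[, b], cycle_cost(rep(b, 16), 0:15, st, res$costs, ss))
  }
})

test_that("strategy schedules accept annual counts or per-cycle counts", {
  st <- strategy("x", list_price = 10, price = 10,
                 injections = list(year1 = c(3, 2, 1.5, 1.5), year2 = 6,
                                   year3 = 4),
                 monitoring = list(year1 = 8, year2 = 8, year3 = 8))
  expect_equal(st$injections$year1, c(3, 2, 1.5, 1.5))
  expect_equal(st$injections$year2, rep(1.5, 4))
  expect_error(
    strategy("x", list_price = 10, price = 10,
             injections = list(year1 = c(1, 2), year2 = 1, year3 = 1),
             monitoring = list(year1 = 1, year2 = 1, year3 = 1)),
    "per-cycle"
  )
})
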