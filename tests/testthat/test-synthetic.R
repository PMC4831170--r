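test_that("zero bias and zero jitter give symmetric random-walk rows", {
  m <- generate_transition_matrix(8, bias = 0, jitter_sd = 0)
  for (i in 3:6) {
    expect_equal(m[i, i - 1], m[i, i + 1], tolerance = 1e-12)
    expect_equal(m[i, i - 2], m[i, i + 2], tolerance = 1e-12)
  }
  validate_transition_matrix(m)
})

test_that("moves are banded: at most two bands per cycle", {
  m <- generate_transition_matrix(8, bias = 0.3, jitter_sd = 0.05)
  for (i in 1:8) {
    reach <- abs(seq_len(8) - i) <= 2
    expect_equal(sum(m[i, !reach]), 0)
  }
})

test_that("positive improvement bias raises the expected band move", {
  up <- generate_transition_matrix(8, bias = 0.25, jitter_sd = 0)
  down <- generate_transition_matrix(8, bias = -0.10, jitter_sd = 0)
  for (i in 3:6) {
    drift_up <- sum((seq_len(8) - i) * up[i, ])
    drift_down <- sum((seq_len(8) - i) * down[i, ])
    expect_gt(drift_up, 0)
    expect_lt(drift_down, 0)
  }
  expect_error(generate_transition_matrix(8, bias = 1), "below 1")
})

test_that("identical seeds give identical schedules", {
  sc <- dme_scenario(seed = 77)
  s1 <- generate_schedules(sc)
  s2 <- generate_schedules(sc)
  expect_identical(s1, s2)
  s3 <- generate_schedules(dme_scenario(seed = 78))
  expect_false(identical(s1, s3))
})

test_that("comparator arms are derived through the odds-ratio chain", {
  sc <- dme_scenario(seed = 5)
  scheds <- generate_schedules(sc)
  prn_y1 <- scheds$ranibizumab_prn$matrices$year1
  # aflibercept's first cycle = observed arm pushed through the inverse OR
  afl_adj <- scheds$aflibercept_2q8$matrices$year1_adjusted
  expect_equal(afl_adj, apply_odds_ratio_matrix(prn_y1, 1.5949, inverse = TRUE),
               tolerance = 1e-12)
  # T&E's first cycle = aflibercept's pushed forward through its own OR
  te_adj <- scheds$ranibizumab_te$matrices$year1_adjusted
  expect_equal(te_adj, apply_odds_ratio_matrix(afl_adj, 1.65),
               tolerance = 1e-12)
  # the observed arm itself carries no adjusted matrix
  expect_null(scheds$ranibizumab_prn$matrices$year1_adjusted)
  # later cycles share the observed arm's matrices
  expect_equal(scheds$aflibercept_2q8$matrices$year2,
               scheds$ranibizumab_prn$matrices$year2)
})

test_that("generated scenarios pass engine validation across seeds", {
  n_checked <- 0L
  for (s in 1:100) {
    sc <- dme_scenario(seed = s)
    scheds <- generate_schedules(sc)
    for (sched in scheds) {
      for (m in sched$matrices) {
        validate_transition_matrix(m, tol = 1e-9)
        n_checked <- n_checked + 1L
      }
    }
  }
  # 100 seeds x 3 strategies x (4 period matrices + adjusted for 2 arms)
  expect_equal(n_checked, 100L * (3L * 4L + 2L))
})

test_that("synthetic utilities are monotone with a wider BSE range", {
  u <- generate_utilities(8)
  expect_true(all(diff(u$bse) > 0))
  expect_true(all(diff(u$wse) > 0))
  expect_gt(diff(range(u$bse)), diff(range(u$wse)))
})

test_that("the baseline concentrates on bands overlapping the trial window", {
  ss <- build_state_space()
  b <- baseline_distribution(ss)
  expect_equal(sum(b), 1)
  # no baseline mass at or below 35 letters, none in the top band
  expect_equal(b[1:2], c(0, 0))
  expect_equal(b[8], 0)
  expect_true(all(b[4:6] > b[7]))
  expect_error(baseline_distribution(ss, window = c(101, 102)), "overlaps")
})

test_that("a cheaper, more effective strategy is always flagged dominant", {
  # constructed: one arm pays less per vial and improves more
  for (s in 1:5) {
    sc <- dme_scenario(seed = s, horizon_years = 6)
    sc$strategies$ranibizumab_prn$price <- 100
    sc$strategies$aflibercept_2q8$price <- 900
    sc$strategies$ranibizumab_prn$or_vs_reference <- 2.5
    sc$strategies$ranibizumab_te <- NULL
    res <- run_cea(sc, keep_traces = FALSE)
    expect_equal(res$comparisons$dominance, "dominant")
  }
})

test_that("treatment-biased schedules beat natural history on time without VI", {
  sc <- dme_scenario(seed = 9)
  res <- resolve_scenario(sc)
  mort <- res$mortality
  treated <- res$schedules$ranibizumab_prn
  nat <- constant_schedule(treated$matrices$natural_history)
  tr_t <- run_cohort(res$baseline, treated, mort, horizon_cycles = 40)
  tr_n <- run_cohort(res$baseline, nat, mort, horizon_cycles = 40)
  no_vi <- as.numeric(!is_vi_state(res$state_space))
  no_vi[res$state_space$death_index] <- 0
  s <- discount_settings(0)
  expect_gt(accumulate_trace(tr_t, no_vi, s), accumulate_trace(tr_n, no_vi, s))
})
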