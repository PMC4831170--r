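#' Discounting settings
#'
#' Outcomes and costs occurring beyond the first year are discounted at an
#' annual rate (default 3.5%).  Time inside the first year carries factor 1.
#'
#' @param annual_rate Annual discount rate (default 0.035).
#' @param enabled_after_year Discounting starts beyond this time, years
#'   (default 1).
#' @param from_time_zero When `TRUE` (default) the factor beyond the cutoff
#'   is `(1 + r)^(-t)` with `t` measured from model entry; when `FALSE`, from
#'   the cutoff itself.
#' @return An object of class `dme_discount`.
#' @export
discount_settings <- function(annual_rate = 0.035,
                              enabled_after_year = 1,
                              from_time_zero = TRUE) {
  if (annual_rate < 0) abort("`annual_rate` must be non-negative.")
  structure(
    list(annual_rate = annual_rate,
         enabled_after_year = enabled_after_year,
         from_time_zero = from_time_zero),
    class = "dme_discount"
  )
}

#' Discount factor at a time point
#'
#' @param t Time in years from model entry (non-negative).
#' @param settings A `dme_discount`.
#' @return Discount factor in (0, 1\].
#' @examples
#' discount_factor(2, discount_settings())
#' @export
discount_factor <- function(t, settings = discount_settings()) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  r <- settings$annual_rate
  cutoff <- settings$enabled_after_year
  t_eff <- if (settings$from_time_zero) t else t - cutoff
  ifelse(t <= cutoff, 1, (1 + r)^(-t_eff))
}

#' Accumulate a discounted payoff over a cohort trace
#'
#' Applies the trapezoidal half-cycle correction: the payoff mass for cycle
#' `t` is carried by the average of the state occupancies at the start and
#' end of the cycle, valued at the cycle midpoint's discount factor.
#' Per-year payoffs (utilities, time indicators) are multiplied by the cycle
#' length; per-cycle payoffs (costs already expressed per cycle) are not.
#'
#' @param trace A `dme_trace`.
#' @param payoff Either a vector (one value per state, constant over cycles)
#'   or a `horizon_cycles x n_states` matrix (row `t` for zero-based cycle
#'   `t - 1`).
#' @param settings A `dme_discount`.
#' @param per_cycle Is `payoff` already a per-cycle amount (`TRUE` for
#'   costs) rather than an annual rate (`FALSE`, default, for utilities)?
#' @param timing `"trapezoid"` (default, half-cycle corrected), `"start"` or
#'   `"end"` (occupancy at the cycle's start or end; used for bracketing
#'   checks).
#' @return Discounted total.
#' @examples
#' ss <- build_state_space(c(50))
#' sched <- transition_schedule("demo", list(
#'   year1 = diag(2), year2 = diag(2), year3 = diag(2),
#'   natural_history = diag(2)))
#' lt <- tibble::tibble(age = 63:100, p_annual = c(rep(0, 37), 1))
#' tr <- run_cohort(c(1, 0), sched, mortality_model(lt), horizon_cycles = 8)
#' accumulate_trace(tr, c(0.8, 0.6, 0), discount_settings(0))  # 2 years at 0.8
#' @export
accumulate_trace <- function(trace, payoff, settings = discount_settings(),
                             per_cycle = FALSE,
                             timing = c("trapezoid", "start", "end")) {
  timing <- match.arg(timing)
  occ <- trace$occupancy
  h <- trace$horizon_cycles
  n <- ncol(occ)
  if (is.matrix(payoff)) {
    if (nrow(payoff) != h || ncol(payoff) != n) {
      abort(sprintf("payoff matrix must be %d x %d.", h, n))
    }
  } else {
    if (length(payoff) != n) {
      abort(sprintf("payoff vector must have %d entries (one per state).", n))
    }
    payoff <- matrix(payoff, nrow = h, ncol = n, byrow = TRUE)
  }
  w <- switch(timing,
    trapezoid = 0.5 * (occ[seq_len(h), , drop = FALSE] +
                       occ[seq_len(h) + 1, , drop = FALSE]),
    start = occ[seq_len(h), , drop = FALSE],
    end = occ[seq_len(h) + 1, , drop = FALSE]
  )
  midpoints <- (seq_len(h) - 0.5) * trace$cycle_years
  df <- discount_factor(midpoints, settings)
  scale <- if (per_cycle) 1 else trace$cycle_years
  sum(rowSums(w * payoff) * df) * scale
}

#' Compare two strategies' accumulated results
#'
#' Computes incremental cost, QALYs and years without visual impairment of
#' `a` over `b`, the ICER or a dominance label, the net monetary benefit at
#' the willingness-to-pay threshold, and cost per year without visual
#' impairment.
#'
#' The ICER is reported as a number only when the increments point the same
#' way; when `a` is cheaper and more effective it is `"dominant"`, costlier
#' and less effective `"dominated"`.  The raw ratio is always kept in
#' `icer_value` for audit.
#'
#' @param a,b Named lists or one-row data frames with `strategy`, `cost`,
#'   `qalys`, `years_no_vi` (both computed on identical settings).
#' @param wtp Willingness to pay, EUR per QALY (default 25000).
#' @return One-row tibble with the deltas, `icer` (character), `icer_value`,
#'   `dominance`, `nmb`, `cost_per_year_no_vi`.
#' @examples
#' compare_strategies(
#'   list(strategy = "a", cost = 12180, qalys = 8.59, years_no_vi = 4.352),
#'   list(strategy = "b", cost = 15004, qalys = 8.54, years_no_vi = 4.321)
#' )
#' @export
compare_strategies <- function(a, b, wtp = 25000) {
  d_cost <- a$cost - b$cost
  d_qaly <- a$qalys - b$qalys
  d_vi <- a$years_no_vi - b$years_no_vi
  icer_value <- if (d_qaly != 0) d_cost / d_qaly else NA_real_
  dominance <- if (d_cost < 0 && d_qaly > 0) {
    "dominant"
  } else if (d_cost > 0 && d_qaly < 0) {
    "dominated"
  } else {
    "none"
  }
  icer <- if (dominance != "none") {
    dominance
  } else if (d_qaly == 0) {
    "undefined (zero QALY difference)"
  } else {
    formatC(icer_value, format = "f", digits = 2)
  }
  tibble(
    comparison = paste(a$strategy, "vs", b$strategy),
    strategy = a$strategy,
    reference = b$strategy,
    delta_cost = d_cost,
    delta_qalys = d_qaly,
    delta_years_no_vi = d_vi,
    icer = icer,
    icer_value = icer_value,
    dominance = dominance,
    nmb = d_qaly * wtp - d_cost,
    cost_per_year_no_vi = if (d_vi != 0) d_cost / d_vi else NA_real_,
    wtp = wtp
  )
}
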