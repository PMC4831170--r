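#' Net reimbursed price after rebate
#'
#' @param list_price Published acquisition price, EUR per vial.
#' @param rebate Payer rebate as a fraction in \[0, 1).
#' @return `list_price * (1 - rebate)`.
#' @examples
#' net_price(781.52, 0.08)
#' @export
net_price <- function(list_price, rebate) {
  if (any(list_price < 0)) abort("`list_price` must be non-negative.")
  if (any(rebate < 0 | rebate >= 1)) abort("`rebate` must lie in [0, 1).")
  list_price * (1 - rebate)
}

#' Weighted sum of cost components
#'
#' Tariffs that differ by care setting are combined as `sum(cost * weight)`.
#' Weights are used exactly as given — they are published shares and are not
#' renormalised.
#'
#' @param costs Numeric vector of component costs (EUR).
#' @param weights Numeric vector of non-negative weights, same length.
#' @return Weighted unit cost, EUR.
#' @examples
#' # hospital vs outpatient laser tariff
#' weighted_unit_cost(c(177, 20.15), c(0.625, 0.375))
#' @export
weighted_unit_cost <- function(costs, weights) {
  if (length(costs) == 0) abort("`costs` must be non-empty.")
  if (length(costs) != length(weights)) {
    abort("`costs` and `weights` must have the same length.")
  }
  if (any(weights < 0)) abort("`weights` must be non-negative.")
  sum(costs * weights)
}

per_cycle_counts <- function(x, cycles_per_year, what) {
  lapply(x, function(v) {
    if (length(v) == 1) v <- rep(v / cycles_per_year, cycles_per_year)
    if (length(v) != cycles_per_year) {
      abort(sprintf("%s: supply 1 annual count or %d per-cycle counts.",
                    what, cycles_per_year))
    }
    if (any(v < 0)) abort(sprintf("%s counts must be non-negative.", what))
    v
  })
}

#' Define a treatment strategy
#'
#' A strategy bundles the drug's pricing, its injection and monitoring
#' schedule over the treatment years, and its relative efficacy versus the
#' comparator arm as an odds ratio on improvement.
#'
#' @param name Strategy identifier, e.g. `"ranibizumab_prn"`.
#' @param list_price Published acquisition price, EUR per vial.
#' @param rebate Payer rebate fraction (default 0).
#' @param price Resolved reimbursed price used by the model; defaults to
#'   `net_price(list_price, rebate)`.  Supply explicitly when the reimbursed
#'   price is published directly.
#' @param injections Per-year injection counts over the treatment years:
#'   named list `year1`..`yearN`, each either one annual count (spread evenly
#'   over cycles) or one count per cycle.
#' @param monitoring Per-year monitoring-visit counts, same shape.
#' @param or_vs_reference Odds ratio on improvement versus the reference arm
#'   (> 0); `NA` for the reference arm itself.
#' @param n_treatment_years Years on treatment (default 3).
#' @return An object of class `dme_strategy`.
#' @examples
#' strategy("aflibercept_2q8", list_price = 718.83, rebate = 0.065,
#'          injections = list(year1 = c(3, 2, 1.5, 1.5), year2 = 6, year3 = 4),
#'          monitoring = list(year1 = 6, year2 = 6, year3 = 4))
#' @export
strategy <- function(name, list_price, rebate = 0,
                     price = net_price(list_price, rebate),
                     injections, monitoring,
                     or_vs_reference = NA_real_,
                     n_treatment_years = 3) {
  if (price < 0) abort("`price` must be non-negative.")
  if (!is.na(or_vs_reference) && or_vs_reference <= 0) {
    abort("`or_vs_reference` must be positive.")
  }
  cycles_per_year <- 4L
  structure(
    list(
      name = name,
      list_price = list_price,
      rebate = rebate,
      price = price,
      injections = per_cycle_counts(injections, cycles_per_year,
                                    paste0(name, " injections")),
      monitoring = per_cycle_counts(monitoring, cycles_per_year,
                                    paste0(name, " monitoring")),
      or_vs_reference = or_vs_reference,
      n_treatment_years = n_treatment_years,
      cycles_per_year = cycles_per_year
    ),
    class = "dme_strategy"
  )
}

#' Non-drug unit costs and state costs
#'
#' @param admin_cost EUR per injection administered (default 66.40, a
#'   weighted tariff across administration settings).
#' @param monitoring_cost EUR per monitoring visit (default 10.00).
#' @param laser_cost EUR per laser session (default 118, weighted across
#'   hospital and outpatient settings).
#' @param laser_sessions Per-year laser session counts during treatment
#'   years (same shape as a strategy's `injections`).
#' @param vi_cost_year1 Annual cost attached to states with BCVA at or below
#'   the visual-impairment threshold during year 1 (default 5248.49 EUR).
#' @param vi_cost_year2plus The same from year 2 onward (default 4866.49 EUR).
#' @param blindness_allowance Annual social allowance for blindness (default
#'   4344 EUR = 362/month).
#' @param add_blindness_allowance The visual-impairment state cost is treated
#'   as all-in by default (`FALSE`); set `TRUE` to add the allowance on top
#'   for the worst band.
#' @return An object of class `dme_costs`.
#' @export
cost_model <- function(admin_cost = 66.40,
                       monitoring_cost = 10.00,
                       laser_cost = 118,
                       laser_sessions = list(year1 = 1, year2 = 0.5, year3 = 0.5),
                       vi_cost_year1 = 5248.49,
                       vi_cost_year2plus = 4866.49,
                       blindness_allowance = 4344,
                       add_blindness_allowance = FALSE) {
  vals <- c(admin_cost, monitoring_cost, laser_cost,
            vi_cost_year1, vi_cost_year2plus, blindness_allowance)
  if (any(vals < 0)) abort("all costs must be non-negative.")
  structure(
    list(
      admin_cost = admin_cost,
      monitoring_cost = monitoring_cost,
      laser_cost = laser_cost,
      laser_sessions = per_cycle_counts(laser_sessions, 4L, "laser_sessions"),
      vi_cost_year1 = vi_cost_year1,
      vi_cost_year2plus = vi_cost_year2plus,
      blindness_allowance = blindness_allowance,
      add_blindness_allowance = add_blindness_allowance
    ),
    class = "dme_costs"
  )
}

#' Per-band utilities mixed over treated-eye classes
#'
#' Utilities differ by whether the treated eye is the better-seeing (BSE) or
#' worse-seeing (WSE) eye; patients with bilateral disease take the BSE
#' values.  The effective BSE weight folds the bilateral share into the BSE
#' class and splits the remainder by the published unilateral shares.
#'
#' @param bse,wse Per-band utility vectors, ordered worst to best band,
#'   monotone non-decreasing, each value in \[-0.1, 1\].
#' @param prop_bse,prop_wse Shares treated for the better-/worse-seeing eye
#'   (defaults 0.402 and 0.596; they may sum to slightly under 1 as
#'   published).
#' @param prop_bilateral Share with bilateral disease (default 0.22).
#' @param multiplier_bse,multiplier_wse Sensitivity-analysis multipliers
#'   applied to the whole vector (default 1); products are capped at 1.
#' @return An object of class `dme_utilities`.
#' @export
utility_model <- function(bse, wse,
                          prop_bse = 0.402, prop_wse = 0.596,
                          prop_bilateral = 0.22,
                          multiplier_bse = 1, multiplier_wse = 1) {
  if (length(bse) != length(wse)) abort("`bse` and `wse` must have equal length.")
  for (v in list(bse = bse, wse = wse)) {
    if (any(v < -0.1 | v > 1)) abort("utilities must lie in [-0.1, 1].")
    if (any(diff(v) < 0)) abort("utilities must be non-decreasing in band.")
  }
  if (abs(prop_bse + prop_wse - 1) > 0.01) {
    abort("`prop_bse` + `prop_wse` must be within 0.01 of 1.")
  }
  structure(
    list(
      bse = bse, wse = wse,
      prop_bse = prop_bse, prop_wse = prop_wse,
      prop_bilateral = prop_bilateral,
      multiplier_bse = multiplier_bse, multiplier_wse = multiplier_wse
    ),
    class = "dme_utilities"
  )
}

#' Effective better-seeing-eye weight
#'
#' @param model A `dme_utilities`.
#' @return Fraction of the cohort taking BSE utilities after folding in
#'   bilateral patients.
#' @export
prop_bse_effective <- function(model) {
  model$prop_bilateral +
    (1 - model$prop_bilateral) * model$prop_bse / (model$prop_bse + model$prop_wse)
}

#' Per-state utility vector
#'
#' Mixture of BSE and WSE utilities by the effective BSE weight; death has
#' utility 0.
#'
#' @param model A `dme_utilities`.
#' @param include_death Append the death-state 0 (default `TRUE`).
#' @return Numeric utility vector over states.
#' @export
state_utilities <- function(model, include_death = TRUE) {
  w <- prop_bse_effective(model)
  bse <- pmin(model$bse * model$multiplier_bse, 1)
  wse <- pmin(model$wse * model$multiplier_wse, 1)
  u <- w * bse + (1 - w) * wse
  if (include_death) u <- c(u, 0) else u
}

#' Utility of a single state
#'
#' @param band State index (live band, or the death index).
#' @param model A `dme_utilities`.
#' @return Utility value; the death state returns 0.
#' @export
state_utility <- function(band, model) {
  u <- state_utilities(model, include_death = TRUE)
  if (any(band < 1 | band > length(u))) abort("`band` out of range.")
  u[band]
}

#' Cost incurred during one cycle in one state
#'
#' Sums, for a cohort member occupying `band` during zero-based `cycle`:
#' drug acquisition (`price` x injections this cycle), administration,
#' monitoring, laser, and — for visually impaired bands — a quarter of the
#' year-dependent annual state cost.  Treatment components stop after the
#' treatment years; the death state costs nothing.
#'
#' @param band State index (1 = worst band; `n_bands + 1` = death).
#' @param cycle Zero-based cycle index.
#' @param strategy A `dme_strategy`.
#' @param costs A `dme_costs`.
#' @param state_space A `dme_state_space`.
#' @return EUR for the cycle.
#' @export
cycle_cost <- function(band, cycle, strategy, costs, state_space) {
  mapply(function(b, t) cycle_cost_one(b, t, strategy, costs, state_space),
         band, cycle)
}

cycle_cost_one <- function(band, cycle, strategy, costs, state_space) {
  if (band == state_space$death_index) return(0)
  cpy <- strategy$cycles_per_year
  year <- cycle %/% cpy + 1
  pos <- cycle %% cpy + 1
  total <- 0
  if (year <= strategy$n_treatment_years) {
    inj <- strategy$injections[[paste0("year", year)]][pos]
    vis <- strategy$monitoring[[paste0("year", year)]][pos]
    las <- costs$laser_sessions[[paste0("year", year)]]
    las <- if (is.null(las)) 0 else las[pos]
    total <- total + strategy$price * inj + costs$admin_cost * inj +
      costs$monitoring_cost * vis + costs$laser_cost * las
  }
  if (is_vi_state(state_space)[band]) {
    annual <- if (year == 1) costs$vi_cost_year1 else costs$vi_cost_year2plus
    total <- total + annual / cpy
    if (costs$add_blindness_allowance && band == 1) {
      total <- total + costs$blindness_allowance / cpy
    }
  }
  total
}

#' Per-cycle, per-state cost matrix
#'
#' @param horizon_cycles Number of cycles.
#' @param strategy A `dme_strategy`.
#' @param costs A `dme_costs`.
#' @param state_space A `dme_state_space`.
#' @return `horizon_cycles x n_states` matrix of EUR per cycle; row `t`
#'   covers zero-based cycle `t - 1`.
#' @export
cost_matrix <- function(horizon_cycles, strategy, costs, state_space) {
  n <- state_space$n_states
  cpy <- strategy$cycles_per_year
  cycles <- seq_len(horizon_cycles) - 1L
  year <- cycles %/% cpy + 1L
  pos <- cycles %% cpy + 1L

  # treatment components are the same for every live band
  treat <- numeric(horizon_cycles)
  on_treat <- year <= strategy$n_treatment_years
  if (any(on_treat)) {
    ykey <- paste0("year", year[on_treat])
    inj <- mapply(function(y, p) strategy$injections[[y]][p],
                  ykey, pos[on_treat])
    vis <- mapply(function(y, p) strategy$monitoring[[y]][p],
                  ykey, pos[on_treat])
    las <- mapply(function(y, p) {
      v <- costs$laser_sessions[[y]]
      if (is.null(v)) 0 else v[p]
    }, ykey, pos[on_treat])
    treat[on_treat] <- (strategy$price + costs$admin_cost) * inj +
      costs$monitoring_cost * vis + costs$laser_cost * las
  }

  vi_annual <- ifelse(year == 1, costs$vi_cost_year1, costs$vi_cost_year2plus)
  vi <- is_vi_state(state_space)

  out <- matrix(0, horizon_cycles, n)
  live <- seq_len(state_space$n_bands)
  out[, live] <- treat
  out[, vi] <- out[, vi] + vi_annual / cpy
  if (costs$add_blindness_allowance) {
    out[, 1] <- out[, 1] + costs$blindness_allowance / cpy
  }
  out[, state_space$death_index] <- 0
  out
}
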