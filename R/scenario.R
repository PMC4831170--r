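#' Define a model scenario
#'
#' A scenario gathers every input of the cost-utility model: the state
#' space, cohort settings, discounting, mortality, utilities, unit costs,
#' the treatment strategies with their prices and schedules, the transition
#' settings (published odds ratios plus either explicit period matrices or
#' the synthetic-generator settings), the baseline distribution, one-way
#' sensitivity ranges and probabilistic-sensitivity settings.
#'
#' The defaults encode the base case of a payer-perspective comparison of
#' ranibizumab 0.5 mg PRN, ranibizumab 0.5 mg treat-and-extend, and
#' aflibercept 2 mg 2q8 in diabetic macular edema (year-2014 Greek tariffs):
#' start age 63, 22% bilateral disease, 3.5% annual discounting beyond year
#' 1, WTP 25,000 EUR/QALY, combined mortality relative risk 1.27 x 1.93,
#' reimbursed prices 656.16 / 613.36 EUR, odds ratios 1.5949 (PRN vs
#' aflibercept, months 0--3) and 1.65 (T&E vs aflibercept, months 0--3).
#' Inputs the sources do not print — per-period transition matrices,
#' per-band utilities, the life table, injection counts — default to
#' clearly-flagged synthetic stand-ins (see `synthetic`).
#'
#' @param name Scenario label.
#' @param seed Seed driving every synthetic component.
#' @param band_edges,vi_threshold State-space settings (see
#'   [build_state_space()]).
#' @param start_age,max_age,cycle_years Cohort settings; the lifetime
#'   horizon runs until `max_age`.
#' @param horizon_years Horizon override in years; `NULL` (default) means
#'   lifetime.
#' @param discount List with `annual_rate`, `enabled_after_year`,
#'   `from_time_zero` (see [discount_settings()]).
#' @param wtp Willingness to pay, EUR per QALY.
#' @param mortality List with `rr_diabetes`, `rr_dme`, optional
#'   `rr_combined` override.
#' @param life_table Tibble `age`/`p_annual`, or `NULL` for the synthetic
#'   Gompertz table.
#' @param utilities List: per-band `bse`/`wse` vectors (or `NULL` for
#'   synthetic), shares `prop_bse`, `prop_wse`, `prop_bilateral`, and the
#'   sensitivity multipliers.
#' @param costs List of [cost_model()] arguments.
#' @param strategies Named list of [strategy()] objects.
#' @param reference_strategy Comparator for incremental results.
#' @param transitions List: `observed_arm` (whose matrices are taken as
#'   observed), `or_cycles` (zero-based cycles the odds ratios modify),
#'   optional explicit `matrices` (named `year1`..`year3`,
#'   `natural_history`) for the observed arm.
#' @param synthetic Generator settings: random-walk weights, per-year
#'   improvement biases, natural-history decline bias, jitter, utility
#'   anchors, recruitment window.
#' @param baseline Baseline distribution over live bands, or `NULL` to
#'   derive it from the recruitment window.
#' @param n_treatment_years Years on anti-VEGF treatment (default 3).
#' @param psa List: `n_sims`, `seed`, `dirichlet_ess`, `utility_ess`,
#'   `zero_variance`.
#' @return An object of class `dme_scenario` (a named list).
#' @examples
#' sc <- dme_scenario()
#' sc$wtp
#' @export
dme_scenario <- function(
    name = "dme-anti-vegf-base-case",
    seed = 42,
    band_edges = c(25, 35, 45, 55, 65, 75, 85),
    vi_threshold = 35,
    start_age = 63,
    max_age = 100,
    cycle_years = 0.25,
    horizon_years = NULL,
    discount = list(annual_rate = 0.035, enabled_after_year = 1,
                    from_time_zero = TRUE),
    wtp = 25000,
    mortality = list(rr_diabetes = 1.27, rr_dme = 1.93, rr_combined = NULL),
    life_table = NULL,
    utilities = list(bse = NULL, wse = NULL,
                     prop_bse = 0.402, prop_wse = 0.596,
                     prop_bilateral = 0.22,
                     multiplier_bse = 1, multiplier_wse = 1),
    costs = list(admin_cost = 66.40, monitoring_cost = 10.00,
                 laser_cost = 118,
                 laser_sessions = list(year1 = 1, year2 = 0.5, year3 = 0.5),
                 vi_cost_year1 = 5248.49, vi_cost_year2plus = 4866.49,
                 blindness_allowance = 4344,
                 add_blindness_allowance = FALSE),
    strategies = NULL,
    reference_strategy = "aflibercept_2q8",
    transitions = list(observed_arm = "ranibizumab_prn", or_cycles = 0L,
                       matrices = NULL),
    synthetic = list(stay_weight = 0.55, step1_weight = 0.18,
                     step2_weight = 0.045,
                     improvement_bias = c(0.25, 0.10, 0.10),
                     decline_bias = 0.10,
                     jitter_sd = 0.02,
                     bse_anchors = c(0.50, 0.85),
                     wse_anchors = c(0.70, 0.80),
                     recruitment_window = c(39, 78)),
    baseline = NULL,
    n_treatment_years = 3,
    psa = list(n_sims = 1000, seed = 20140801, dirichlet_ess = 100,
               utility_ess = 100, zero_variance = FALSE)) {
  strategies <- strategies %||% default_strategies()
  sc <- structure(
    list(
      name = name, seed = seed,
      band_edges = band_edges, vi_threshold = vi_threshold,
      start_age = start_age, max_age = max_age, cycle_years = cycle_years,
      horizon_years = horizon_years,
      discount = discount, wtp = wtp,
      mortality = mortality, life_table = life_table,
      utilities = utilities, costs = costs,
      strategies = strategies,
      reference_strategy = reference_strategy,
      transitions = transitions,
      synthetic = synthetic,
      baseline = baseline,
      n_treatment_years = n_treatment_years,
      psa = psa
    ),
    class = "dme_scenario"
  )
  validate_scenario(sc)
  sc
}

# Published prices and odds ratios; injection/monitoring counts are synthetic
# placeholders (the sources describe the regimens but print no counts).
default_strategies <- function() {
  list(
    ranibizumab_prn = strategy(
      "ranibizumab_prn",
      list_price = 781.52, rebate = 0.08, price = 656.16,
      injections = list(year1 = c(2.5, 2, 1.5, 1), year2 = 3, year3 = 2),
      monitoring = list(year1 = 12, year2 = 12, year3 = 12),
      or_vs_reference = 1.5949
    ),
    ranibizumab_te = strategy(
      "ranibizumab_te",
      list_price = 781.52, rebate = 0.08, price = 656.16,
      injections = list(year1 = c(3, 2, 1.5, 1.5), year2 = 4, year3 = 2.5),
      monitoring = list(year1 = 8, year2 = 8, year3 = 8),
      or_vs_reference = 1.65
    ),
    aflibercept_2q8 = strategy(
      "aflibercept_2q8",
      list_price = 718.83, rebate = 0.065, price = 613.36,
      injections = list(year1 = c(3, 2, 1.5, 1.5), year2 = 6, year3 = 4),
      monitoring = list(year1 = 8, year2 = 8, year3 = 8),
      or_vs_reference = NA_real_
    )
  )
}

#' Validate a scenario
#'
#' Structural and range checks over every block; errors name the failing
#' field.
#'
#' @param scenario A `dme_scenario`.
#' @return `scenario`, invisibly.
#' @export
validate_scenario <- function(scenario) {
  check <- function(ok, field, msg) {
    if (!ok) abort(sprintf("scenario$%s: %s", field, msg))
  }
  sc <- scenario
  check(length(sc$band_edges) >= 1 && all(diff(sc$band_edges) > 0),
        "band_edges", "must be strictly increasing with >= 1 edge.")
  check(sc$start_age < sc$max_age, "start_age", "must be below max_age.")
  check(sc$cycle_years > 0, "cycle_years", "must be positive.")
  check(sc$discount$annual_rate >= 0, "discount$annual_rate",
        "must be non-negative.")
  check(sc$wtp >= 0, "wtp", "must be non-negative.")
  check(is.null(sc$horizon_years) || sc$horizon_years > 0, "horizon_years",
        "must be positive when set.")
  check(sc$mortality$rr_diabetes > 0 && sc$mortality$rr_dme > 0,
        "mortality", "relative risks must be positive.")
  check(length(sc$strategies) >= 1, "strategies", "need at least one.")
  check(sc$reference_strategy %in% names(sc$strategies),
        "reference_strategy", "must name a strategy.")
  check(sc$transitions$observed_arm %in% names(sc$strategies),
        "transitions$observed_arm", "must name a strategy.")
  for (nm in names(sc$strategies)) {
    st <- sc$strategies[[nm]]
    check(st$price >= 0, paste0("strategies$", nm, "$price"),
          "must be non-negative.")
    check(is.na(st$or_vs_reference) || st$or_vs_reference > 0,
          paste0("strategies$", nm, "$or_vs_reference"), "must be positive.")
  }
  with(sc$utilities, {
    check(abs(prop_bse + prop_wse - 1) <= 0.01, "utilities",
          "prop_bse + prop_wse must be within 0.01 of 1.")
    check(prop_bilateral >= 0 && prop_bilateral <= 1,
          "utilities$prop_bilateral", "must lie in [0, 1].")
  })
  check(all(abs(c(sc$synthetic$improvement_bias, sc$synthetic$decline_bias)) < 1),
        "synthetic", "bias magnitudes must be below 1.")
  if (!is.null(sc$baseline)) {
    check(abs(sum(sc$baseline) - 1) <= 1e-9 && all(sc$baseline >= 0),
          "baseline", "must be a probability vector over live bands.")
  }
  invisible(scenario)
}

#' Resolve a scenario into model-ready components
#'
#' Materialises the state space, mortality model, utility model, cost
#' model, per-strategy transition schedules, baseline distribution and
#' horizon, substituting seeded synthetic stand-ins wherever the scenario
#' leaves a component `NULL`.
#'
#' @param scenario A `dme_scenario`.
#' @return A list of resolved components (class `dme_resolved`).
#' @export
resolve_scenario <- function(scenario) {
  ss <- build_state_space(scenario$band_edges, scenario$vi_threshold)
  lt <- scenario$life_table %||%
    generate_life_table(min_age = 0, max_age = scenario$max_age)
  mort <- mortality_model(lt,
                          rr_diabetes = scenario$mortality$rr_diabetes,
                          rr_dme = scenario$mortality$rr_dme,
                          rr_combined = scenario$mortality$rr_combined)
  uvec <- if (is.null(scenario$utilities$bse) || is.null(scenario$utilities$wse)) {
    generate_utilities(ss$n_bands,
                       bse_anchors = scenario$synthetic$bse_anchors,
                       wse_anchors = scenario$synthetic$wse_anchors)
  } else {
    list(bse = scenario$utilities$bse, wse = scenario$utilities$wse)
  }
  util <- utility_model(
    bse = uvec$bse, wse = uvec$wse,
    prop_bse = scenario$utilities$prop_bse,
    prop_wse = scenario$utilities$prop_wse,
    prop_bilateral = scenario$utilities$prop_bilateral,
    multiplier_bse = scenario$utilities$multiplier_bse,
    multiplier_wse = scenario$utilities$multiplier_wse
  )
  costs <- do.call(cost_model, scenario$costs)
  schedules <- generate_schedules(scenario, ss)
  baseline <- scenario$baseline %||%
    baseline_distribution(ss, scenario$synthetic$recruitment_window)
  horizon_years <- scenario$horizon_years %||%
    (scenario$max_age - scenario$start_age)
  horizon_cycles <- ceiling(horizon_years / scenario$cycle_years)
  structure(
    list(
      state_space = ss, mortality = mort, utilities = util, costs = costs,
      schedules = schedules, baseline = baseline,
      horizon_cycles = horizon_cycles,
      discount = do.call(discount_settings, scenario$discount)
    ),
    class = "dme_resolved"
  )
}

#' Set a scenario parameter by path
#'
#' Paths address scenario fields the way [purrr::pluck()] does, e.g.
#' `c("costs", "admin_cost")` or
#' `c("strategies", "ranibizumab_prn", "price")`.  Used by the sensitivity
#' analyses; errors name the unresolvable path.
#'
#' @param scenario A `dme_scenario`.
#' @param path Character vector of nested names (or a list of such vectors,
#'   all set to the same value — e.g. a drug price shared by two arms).
#' @param value Replacement value.
#' @return Modified scenario.
#' @export
set_scenario_parameter <- function(scenario, path, value) {
  paths <- if (is.list(path)) path else list(path)
  for (p in paths) {
    p <- as.character(p)
    parent <- if (length(p) == 1) {
      scenario
    } else {
      do.call(purrr::pluck, c(list(scenario), as.list(p[-length(p)])))
    }
    if (!is.list(parent) || !(p[length(p)] %in% names(parent))) {
      abort(sprintf("parameter path '%s' not found in scenario.",
                    paste(p, collapse = "$")))
    }
    scenario <- purrr::assign_in(scenario, as.list(p), value)
  }
  scenario
}

#' @export
print.dme_scenario <- function(x, ...) {
  cat(sprintf("<dme_scenario> '%s'\n", x$name))
  cat(sprintf("  strategies: %s (reference: %s)\n",
              paste(names(x$strategies), collapse = ", "),
              x$reference_strategy))
  cat(sprintf("  cohort: start age %g, cycle %g y, horizon %s\n",
              x$start_age, x$cycle_years,
              if (is.null(x$horizon_years)) {
                sprintf("lifetime (to age %g)", x$max_age)
              } else {
                sprintf("%g years", x$horizon_years)
              }))
  cat(sprintf("  discount %g%%/y beyond year %g; WTP %g EUR/QALY; seed %d\n",
              100 * x$discount$annual_rate, x$discount$enabled_after_year,
              x$wtp, x$seed))
  invisible(x)
}
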