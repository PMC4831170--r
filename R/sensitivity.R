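#' Default one-way sensitivity ranges
#'
#' One row per varied input, mirroring the published sensitivity table:
#' time horizon, discount rate, baseline age, utility multipliers, the
#' combined mortality relative risk (base 1.27 x 1.93, varied 1.00--4.90),
#' both months-0--3 odds ratios, both reimbursed drug prices (+/-25%),
#' administration and monitoring costs, and both visual-impairment state
#' costs.  The `path` column addresses the scenario field(s) each row
#' varies (the ranibizumab price is shared by the PRN and T&E arms).
#'
#' @param scenario A `dme_scenario` (used for base values).
#' @return Tibble: `parameter`, `path` (list-column), `base`, `low`, `high`,
#'   `variation`.
#' @export
default_owsa_ranges <- function(scenario = dme_scenario()) {
  rr_base <- scenario$mortality$rr_combined %||%
    (scenario$mortality$rr_diabetes * scenario$mortality$rr_dme)
  lifetime <- scenario$horizon_years %||% (scenario$max_age - scenario$start_age)
  tibble(
    parameter = c(
      "Time horizon (years)", "Discount rate", "Baseline age",
      "Utility multiplier - BSE", "Utility multiplier - WSE",
      "Relative risk mortality with DME",
      "OR ranibizumab PRN vs aflibercept month 0-3",
      "OR ranibizumab T&E vs aflibercept month 0-3",
      "Price of ranibizumab", "Price of aflibercept",
      "Administration cost", "Monitoring visit cost",
      "VI state cost year 1", "VI state cost year 2+"
    ),
    path = list(
      "horizon_years",
      c("discount", "annual_rate"),
      "start_age",
      c("utilities", "multiplier_bse"),
      c("utilities", "multiplier_wse"),
      c("mortality", "rr_combined"),
      c("strategies", "ranibizumab_prn", "or_vs_reference"),
      c("strategies", "ranibizumab_te", "or_vs_reference"),
      list(c("strategies", "ranibizumab_prn", "price"),
           c("strategies", "ranibizumab_te", "price")),
      c("strategies", "aflibercept_2q8", "price"),
      c("costs", "admin_cost"),
      c("costs", "monitoring_cost"),
      c("costs", "vi_cost_year1"),
      c("costs", "vi_cost_year2plus")
    ),
    base = c(lifetime, scenario$discount$annual_rate, scenario$start_age,
             1, 1, rr_base, 1.5949, 1.65, 656.16, 613.36,
             66.40, 10.00, 5248.49, 4866.49),
    low = c(3, 0, scenario$start_age - 10, 0.80, 0.80, 1.00,
            0.61, 0.43, 492.12, 460.02, 49.80, 7.50, 3936.37, 3649.87),
    high = c(lifetime, 0.07, scenario$start_age + 10, 1.20, 1.20, 4.90,
             5.37, 6.08, 820.20, 766.70, 83.00, 12.50, 6560.61, 6083.11),
    variation = c("scenario horizons", "0-7%", "+/-10 years", "+/-20%",
                  "+/-20%", "+/-100%", "standard error", "standard error",
                  "+/-25%", "+/-25%", "+/-25%", "+/-25%", "+/-25%", "+/-25%")
  )
}

#' One-way sensitivity analysis (tornado)
#'
#' Reruns the full pipeline once at each range's low and high value,
#' holding everything else at base, and records the net monetary benefit of
#' each comparison.  Rows are sorted by swing (|NMB_high - NMB_low|)
#' descending, the tornado order.
#'
#' @param scenario A `dme_scenario`.
#' @param ranges Tibble as from [default_owsa_ranges()]; rows must satisfy
#'   `low <= base <= high`.
#' @param outcome Currently `"nmb"` only.
#' @return An object of class `dme_owsa`: tibble with `parameter`,
#'   `comparison`, `low`, `high`, `nmb_low`, `nmb_high`, `nmb_base`,
#'   `swing`; base NMBs as attribute.
#' @export
run_owsa <- function(scenario, ranges = default_owsa_ranges(scenario),
                     outcome = "nmb") {
  stopifnot(identical(outcome, "nmb"))
  if (any(ranges$low > ranges$base | ranges$base > ranges$high)) {
    abort("every OWSA range must satisfy low <= base <= high.")
  }
  base_cmp <- run_cea(scenario, keep_traces = FALSE)$comparisons
  nmb_at <- function(sc) {
    run_cea(sc, keep_traces = FALSE)$comparisons |>
      select("strategy", "nmb")
  }
  rows <- purrr::pmap(ranges, function(parameter, path, base, low, high, ...) {
    lo <- nmb_at(set_scenario_parameter(scenario, path, low)) |>
      rename(nmb_low = "nmb")
    hi <- nmb_at(set_scenario_parameter(scenario, path, high)) |>
      rename(nmb_high = "nmb")
    dplyr::inner_join(lo, hi, by = "strategy") |>
      mutate(parameter = parameter, low = low, high = high, .before = 1)
  })
  out <- bind_rows(rows) |>
    dplyr::left_join(base_cmp |> select("strategy", nmb_base = "nmb"),
                     by = "strategy") |>
    mutate(swing = abs(.data$nmb_high - .data$nmb_low)) |>
    rename(comparison = "strategy") |>
    arrange(.data$comparison, desc(.data$swing))
  structure(out, class = c("dme_owsa", class(out)),
            reference = scenario$reference_strategy)
}

#' Tornado diagram
#'
#' @param owsa A `dme_owsa` (from [run_owsa()]).
#' @param comparison Strategy to plot; default the first.
#' @return A ggplot: horizontal NMB bars from low to high per parameter,
#'   widest swing on top.
#' @export
plot_tornado <- function(owsa, comparison = NULL) {
  comparison <- comparison %||% owsa$comparison[1]
  d <- owsa |>
    filter(.data$comparison == !!comparison) |>
    arrange(.data$swing) |>
    mutate(parameter = factor(.data$parameter, levels = .data$parameter))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$nmb_low, xend = .data$nmb_high,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 5, colour = "steelblue"
    ) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$nmb_base),
                        linetype = "dashed") +
    ggplot2::labs(x = "Net monetary benefit (EUR)", y = NULL,
                  title = sprintf("Tornado: %s vs %s", comparison,
                                  attr(owsa, "reference"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dme_owsa <- function(object, ...) plot_tornado(object, ...)

# --- probabilistic sensitivity -------------------------------------------

draw_gamma <- function(base, low, high, zero_variance) {
  if (zero_variance || base == 0) return(base)
  sd <- (high - low) / (2 * qnorm(0.975))
  if (sd <= 0) return(base)
  shape <- (base / sd)^2
  rgamma(1, shape = shape, rate = shape / base)
}

draw_lognormal <- function(base, low, high, zero_variance) {
  if (zero_variance) return(base)
  sdlog <- (log(high) - log(low)) / (2 * qnorm(0.975))
  if (sdlog <= 0) return(base)
  rlnorm(1, meanlog = log(base), sdlog = sdlog)
}

draw_beta_vec <- function(means, ess, zero_variance) {
  if (zero_variance) return(means)
  means <- pmin(pmax(means, 1e-6), 1 - 1e-6)
  rbeta(length(means), shape1 = means * ess, shape2 = (1 - means) * ess)
}

draw_dirichlet_row <- function(alpha, zero_variance) {
  if (zero_variance) return(alpha / sum(alpha))
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- rgamma(sum(pos), shape = alpha[pos])
  g / sum(g)
}

#' Draw one probabilistic parameter set
#'
#' Second-order Monte Carlo draw: costs and prices from gamma
#' distributions (mean at base, the one-way range as a 95% interval), odds
#' ratios and the mortality relative risk from lognormals (the one-way
#' range as a 95% interval), per-band utilities from betas at a fixed
#' effective sample size, and the observed arm's transition-matrix rows
#' jointly from Dirichlet distributions (concentration = effective sample
#' size x base row), preserving row-stochasticity.  Comparator matrices are
#' re-derived from the drawn matrices and drawn odds ratios.  With
#' `scenario$psa$zero_variance` every draw reproduces the base value
#' exactly.
#'
#' @param scenario A `dme_scenario`.
#' @param resolved Optional pre-resolved base components (for speed inside
#'   [run_psa()]).
#' @return A complete, valid `dme_scenario` with drawn values substituted.
#'   Uses the current RNG stream; seed management is the caller's job.
#' @export
draw_psa_scenario <- function(scenario, resolved = NULL) {
  resolved <- resolved %||% resolve_scenario(scenario)
  zv <- isTRUE(scenario$psa$zero_variance)
  s2 <- scenario

  observed <- scenario$transitions$observed_arm
  base_mats <- resolved$schedules[[observed]]$matrices
  base_mats$year1_adjusted <- NULL
  ess <- scenario$psa$dirichlet_ess
  s2$transitions$matrices <- lapply(base_mats, function(m) {
    t(apply(m, 1, function(row) draw_dirichlet_row(ess * row, zv)))
  })

  u_ess <- scenario$psa$utility_ess
  bse <- draw_beta_vec(resolved$utilities$bse, u_ess, zv)
  wse <- draw_beta_vec(resolved$utilities$wse, u_ess, zv)
  # beta draws are exchangeable across bands; restore band monotonicity
  s2$utilities$bse <- sort(bse)
  s2$utilities$wse <- sort(wse)

  ranges <- default_owsa_ranges(scenario)
  get_range <- function(param) ranges[ranges$parameter == param, ]

  r <- get_range("Relative risk mortality with DME")
  s2$mortality$rr_combined <- draw_lognormal(r$base, r$low, r$high, zv)
  for (spec in list(
    list("OR ranibizumab PRN vs aflibercept month 0-3",
         c("strategies", "ranibizumab_prn", "or_vs_reference"), "lognormal"),
    list("OR ranibizumab T&E vs aflibercept month 0-3",
         c("strategies", "ranibizumab_te", "or_vs_reference"), "lognormal"),
    list("Price of ranibizumab",
         list(c("strategies", "ranibizumab_prn", "price"),
              c("strategies", "ranibizumab_te", "price")), "gamma"),
    list("Price of aflibercept",
         c("strategies", "aflibercept_2q8", "price"), "gamma"),
    list("Administration cost", c("costs", "admin_cost"), "gamma"),
    list("Monitoring visit cost", c("costs", "monitoring_cost"), "gamma"),
    list("VI state cost year 1", c("costs", "vi_cost_year1"), "gamma"),
    list("VI state cost year 2+", c("costs", "vi_cost_year2plus"), "gamma")
  )) {
    r <- get_range(spec[[1]])
    if (nrow(r) == 0) next
    val <- if (spec[[3]] == "gamma") {
      draw_gamma(r$base, r$low, r$high, zv)
    } else {
      draw_lognormal(r$base, r$low, r$high, zv)
    }
    s2 <- set_scenario_parameter(s2, spec[[2]], val)
  }
  s2
}

#' Probabilistic sensitivity analysis
#'
#' Runs the full pipeline on `n_sims` independently drawn parameter sets
#' (see [draw_psa_scenario()]) and collects incremental results per
#' comparison.  Identical seeds give bit-identical draw sequences.
#'
#' @param scenario A `dme_scenario`.
#' @param n_sims Number of draws (default from `scenario$psa`).
#' @param seed RNG seed (default from `scenario$psa`).
#' @return An object of class `dme_psa`: list with `draws` (tibble: `sim`,
#'   `comparison`, `delta_cost`, `delta_qalys`, `delta_years_no_vi`,
#'   `nmb`), `n_sims`, `seed`, `wtp`, `scenario`.
#' @export
run_psa <- function(scenario, n_sims = scenario$psa$n_sims,
                    seed = scenario$psa$seed) {
  resolved <- resolve_scenario(scenario)
  draws <- with_preserved_seed(seed, {
    purrr::map(seq_len(n_sims), function(i) {
      s2 <- draw_psa_scenario(scenario, resolved)
      run_cea(s2, keep_traces = FALSE)$comparisons |>
        mutate(sim = i, .before = 1) |>
        select("sim", comparison = "strategy", "delta_cost", "delta_qalys",
               "delta_years_no_vi", "nmb")
    }) |> bind_rows()
  })
  structure(
    list(draws = draws, n_sims = n_sims, seed = seed,
         wtp = scenario$wtp, scenario = scenario),
    class = "dme_psa"
  )
}

#' @export
print.dme_psa <- function(x, ...) {
  cat(sprintf("<dme_psa> %d draws (seed %d)\n", x$n_sims, x$seed))
  print(
    x$draws |>
      group_by(.data$comparison) |>
      summarise(
        mean_delta_cost = mean(.data$delta_cost),
        mean_delta_qalys = mean(.data$delta_qalys),
        p_cost_effective = mean(.data$delta_qalys * x$wtp - .data$delta_cost > 0)
      )
  )
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value the probability of being
#' cost-effective is the fraction of draws with positive net monetary
#' benefit at that threshold.
#'
#' @param psa A `dme_psa`, or a tibble of draws with `comparison`,
#'   `delta_cost`, `delta_qalys`.
#' @param wtp_grid Thresholds, EUR per QALY.
#' @return An object of class `dme_ceac`: tibble with `wtp`, `comparison`,
#'   `prob_cost_effective`.
#' @export
build_ceac <- function(psa, wtp_grid = seq(0, 100000, by = 2500)) {
  if (length(wtp_grid) == 0) abort("`wtp_grid` must be non-empty.")
  draws <- if (inherits(psa, "dme_psa")) psa$draws else as_tibble(psa)
  if (nrow(draws) == 0) abort("need at least one PSA draw.")
  out <- tidyr::expand_grid(wtp = wtp_grid,
                            comparison = unique(draws$comparison)) |>
    purrr::pmap(function(wtp, comparison) {
      d <- draws[draws$comparison == comparison, ]
      tibble(wtp = wtp, comparison = comparison,
             prob_cost_effective =
               mean(d$delta_qalys * wtp - d$delta_cost > 0))
    }) |>
    bind_rows()
  structure(out, class = c("dme_ceac", class(out)))
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac A `dme_ceac`.
#' @return A ggplot of P(cost-effective) against willingness to pay.
#' @export
plot_ceac <- function(ceac) {
  ggplot2::ggplot(ceac, ggplot2::aes(x = .data$wtp,
                                     y = .data$prob_cost_effective,
                                     colour = .data$comparison)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability cost-effective", colour = "Comparison",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dme_ceac <- function(object, ...) plot_ceac(object)

#' Break-even price search
#'
#' Bisects on a strategy's reimbursed drug price until the net monetary
#' benefit of that strategy versus the reference crosses zero: the price at
#' which the strategy ceases to be cost-effective at the scenario's
#' willingness-to-pay threshold.  NMB is strictly decreasing in the
#' strategy's own price, so the root is unique.
#'
#' @param scenario A `dme_scenario`.
#' @param strategy_name Strategy whose price is varied.
#' @param bounds Price bracket, EUR; NMB must change sign over it.
#' @param tol Bracket width at which to stop, EUR (default 0.01).
#' @return The break-even price, EUR, with attributes `nmb` (NMB evaluated
#'   at the returned price) and `iterations`.
#' @export
find_price_threshold <- function(scenario, strategy_name,
                                 bounds = c(0, 5000), tol = 0.01) {
  if (!strategy_name %in% names(scenario$strategies)) {
    abort(sprintf("unknown strategy '%s'.", strategy_name))
  }
  nmb_at <- function(price) {
    sc <- set_scenario_parameter(
      scenario, c("strategies", strategy_name, "price"), price)
    cmp <- run_cea(sc, keep_traces = FALSE)$comparisons
    cmp$nmb[cmp$strategy == strategy_name]
  }
  lo <- bounds[1]; hi <- bounds[2]
  f_lo <- nmb_at(lo); f_hi <- nmb_at(hi)
  if (sign(f_lo) == sign(f_hi)) {
    abort(sprintf(
      "NMB does not change sign over [%g, %g]: NMB(%g) = %.2f, NMB(%g) = %.2f.",
      lo, hi, lo, f_lo, hi, f_hi))
  }
  iter <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- nmb_at(mid)
    if (f_mid == 0) { lo <- mid; hi <- mid; break }
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
    iter <- iter + 1L
  }
  root <- (lo + hi) / 2
  structure(root, nmb = nmb_at(root), iterations = iter)
}
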