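#' Run the cost-utility analysis
#'
#' Resolves the scenario, advances one cohort per strategy, accumulates
#' discounted costs, QALYs and years without visual impairment with the
#' trapezoidal half-cycle correction, and computes incremental economics of
#' every strategy against the reference.
#'
#' @param scenario A `dme_scenario`.
#' @param keep_traces Keep the per-strategy cohort traces on the result
#'   (default `TRUE`).
#' @return An object of class `dme_cea`: list with `strategies` (tibble:
#'   `strategy`, `cost`, `qalys`, `years_no_vi`, `life_years`),
#'   `comparisons` (tibble, see [compare_strategies()]), `traces`,
#'   `scenario`, `resolved`.
#' @examples
#' \donttest{
#' res <- run_cea(dme_scenario(horizon_years = 5))
#' res$strategies
#' tidy(res)
#' }
#' @export
run_cea <- function(scenario, keep_traces = TRUE) {
  res <- resolve_scenario(scenario)
  ss <- res$state_space
  u <- state_utilities(res$utilities)
  no_vi <- as.numeric(!is_vi_state(ss))
  no_vi[ss$death_index] <- 0
  alive <- c(rep(1, ss$n_bands), 0)

  rows <- list()
  traces <- list()
  for (nm in names(res$schedules)) {
    tr <- run_cohort(res$baseline, res$schedules[[nm]], res$mortality,
                     horizon_cycles = res$horizon_cycles,
                     start_age = scenario$start_age,
                     cycle_years = scenario$cycle_years)
    cm <- cost_matrix(res$horizon_cycles, scenario$strategies[[nm]],
                      res$costs, ss)
    rows[[nm]] <- tibble(
      strategy = nm,
      cost = accumulate_trace(tr, cm, res$discount, per_cycle = TRUE),
      qalys = accumulate_trace(tr, u, res$discount),
      years_no_vi = accumulate_trace(tr, no_vi, res$discount),
      life_years = accumulate_trace(tr, alive, res$discount)
    )
    if (keep_traces) traces[[nm]] <- tr
  }
  strategies <- bind_rows(rows)

  ref_row <- as.list(strategies[strategies$strategy == scenario$reference_strategy, ])
  comparisons <- bind_rows(lapply(
    setdiff(strategies$strategy, scenario$reference_strategy),
    function(nm) {
      compare_strategies(as.list(strategies[strategies$strategy == nm, ]),
                         ref_row, wtp = scenario$wtp)
    }
  ))

  structure(
    list(strategies = strategies, comparisons = comparisons,
         traces = traces, scenario = scenario, resolved = res),
    class = "dme_cea"
  )
}

#' @export
print.dme_cea <- function(x, ...) {
  cat(sprintf("<dme_cea> '%s' — %d strategies, horizon %d cycles\n",
              x$scenario$name, nrow(x$strategies), x$resolved$horizon_cycles))
  print(
    x$strategies |>
      mutate(dplyr::across(c("cost"), ~ round(.x, 0)),
             dplyr::across(c("qalys", "years_no_vi", "life_years"),
                           ~ round(.x, 3)))
  )
  if (nrow(x$comparisons) > 0) {
    cat(sprintf("\nIncremental vs %s (WTP %s EUR/QALY):\n",
                x$scenario$reference_strategy,
                format(x$scenario$wtp, big.mark = ",")))
    print(
      x$comparisons |>
        select("strategy", "delta_cost", "delta_qalys", "icer", "nmb") |>
        mutate(delta_cost = round(.data$delta_cost, 0),
               delta_qalys = round(.data$delta_qalys, 3),
               nmb = round(.data$nmb, 0))
    )
  }
  invisible(x)
}

#' Tidy incremental results
#'
#' @param x A `dme_cea`.
#' @param ... Unused.
#' @return The comparisons tibble (one row per strategy vs reference).
#' @export
tidy.dme_cea <- function(x, ...) {
  x$comparisons
}

#' One-row model summary
#'
#' @param x A `dme_cea`.
#' @param ... Unused.
#' @return One-row tibble: strategy count, horizon, discount rate, WTP, and
#'   whether any strategy dominates the reference.
#' @export
glance.dme_cea <- function(x, ...) {
  tibble(
    n_strategies = nrow(x$strategies),
    horizon_cycles = x$resolved$horizon_cycles,
    start_age = x$scenario$start_age,
    discount_rate = x$scenario$discount$annual_rate,
    wtp = x$scenario$wtp,
    reference = x$scenario$reference_strategy,
    any_dominant = any(x$comparisons$dominance == "dominant")
  )
}

#' Cost-effectiveness plane of the base-case comparisons
#'
#' @param object A `dme_cea`.
#' @param ... Unused.
#' @return A ggplot of incremental QALYs vs incremental cost with the WTP
#'   line.
#' @export
autoplot.dme_cea <- function(object, ...) {
  ggplot2::ggplot(object$comparisons,
                  ggplot2::aes(x = .data$delta_qalys, y = .data$delta_cost,
                               colour = .data$strategy)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(slope = object$scenario$wtp, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (EUR)",
                  colour = "Strategy",
                  title = "Cost-effectiveness plane vs reference") +
    ggplot2::theme_minimal()
}
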