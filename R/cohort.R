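#' Advance a cohort through the model
#'
#' Runs the cohort recursion `occupancy[t+1] = occupancy[t] %*% M_t`, where
#' `M_t` composes the clinical matrix in force during cycle `t` with the
#' age-specific per-cycle death probability.  The cohort ages by the cycle
#' length each cycle; the annual life-table probability is looked up at the
#' floored age and scaled by the disease relative risk on the hazard scale.
#'
#' @param initial Baseline distribution over live bands (sums to 1; death
#'   mass 0 at entry).
#' @param schedule A `dme_schedule`.
#' @param mortality A `dme_mortality`.
#' @param horizon_cycles Number of cycles to run.  Default `NULL` means a
#'   lifetime horizon: cycles until the cohort reaches the life-table cap.
#' @param start_age Cohort age at model entry, years (default 63).
#' @param cycle_years Cycle length in years (default 0.25).
#' @return An object of class `dme_trace`: a list with `occupancy`
#'   (`(horizon+1) x n_states` matrix, row `t+1` = distribution after `t`
#'   cycles), `labels`, `start_age`, `cycle_years`.
#' @examples
#' ss <- build_state_space(c(50))
#' sched <- transition_schedule("demo", list(
#'   year1 = diag(2), year2 = diag(2), year3 = diag(2),
#'   natural_history = diag(2)))
#' tr <- run_cohort(c(0.5, 0.5), sched, mortality_model(generate_life_table()),
#'                  horizon_cycles = 8)
#' head(as_tibble(tr))
#' @export
run_cohort <- function(initial, schedule, mortality,
                       horizon_cycles = NULL,
                       start_age = 63, cycle_years = 0.25) {
  if (abs(sum(initial) - 1) > 1e-9) abort("`initial` must sum to 1.")
  if (any(initial < 0)) abort("`initial` must be non-negative.")
  n_live <- length(initial)
  if (is.null(horizon_cycles)) {
    horizon_cycles <- ceiling((mortality$max_age - start_age) / cycle_years)
  }
  if (horizon_cycles < 1) abort("`horizon_cycles` must be >= 1.")

  n_states <- n_live + 1L
  occ <- matrix(0, horizon_cycles + 1, n_states)
  occ[1, seq_len(n_live)] <- initial

  ages <- start_age + (seq_len(horizon_cycles) - 1) * cycle_years
  p_death <- dme_cycle_death_prob(mortality, ages, cycle_years)

  v <- occ[1, ]
  for (t in seq_len(horizon_cycles)) {
    clin <- schedule_matrix(schedule, t - 1L)
    if (nrow(clin) != n_live) {
      abort(sprintf("clinical matrix at cycle %d has %d states; expected %d.",
                    t - 1L, nrow(clin), n_live))
    }
    live <- v[seq_len(n_live)]
    nxt <- as.numeric(live %*% clin) * (1 - p_death[t])
    v <- c(nxt, v[n_states] + sum(live) * p_death[t])
    occ[t + 1, ] <- v
  }

  labels <- c(paste0("state", seq_len(n_live)), "death")
  if (!is.null(colnames(schedule$matrices[[1]]))) {
    labels <- c(colnames(schedule$matrices[[1]]), "death")
  }
  colnames(occ) <- labels
  structure(
    list(
      occupancy = occ,
      labels = labels,
      n_live = n_live,
      horizon_cycles = horizon_cycles,
      start_age = start_age,
      cycle_years = cycle_years,
      strategy_name = schedule$strategy_name
    ),
    class = "dme_trace"
  )
}

#' @export
print.dme_trace <- function(x, ...) {
  cat(sprintf(
    "<dme_trace> '%s': %d cycles of %g years, %d live states + death\n",
    x$strategy_name, x$horizon_cycles, x$cycle_years, x$n_live
  ))
  cat(sprintf("  final death occupancy: %.4f\n",
              x$occupancy[nrow(x$occupancy), x$n_live + 1]))
  invisible(x)
}

#' Cohort trace as a tibble
#'
#' @param x A `dme_trace`.
#' @param ... Unused.
#' @return Wide tibble: `cycle`, `age`, one column per state (occupancy).
#'   Cycle 0 is the baseline distribution.
#' @export
as_tibble.dme_trace <- function(x, ...) {
  cycles <- 0:x$horizon_cycles
  out <- tibble(
    cycle = cycles,
    age = x$start_age + cycles * x$cycle_years
  )
  occ <- as_tibble(as.data.frame(x$occupancy))
  dplyr::bind_cols(out, occ)
}

#' @describeIn as_tibble.dme_trace Long-format tidy trace (`cycle`, `age`,
#'   `state`, `occupancy`).
#' @export
tidy.dme_trace <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(-c("cycle", "age"),
                        names_to = "state", values_to = "occupancy") |>
    mutate(state = factor(.data$state, levels = x$labels))
}

#' Plot a cohort trace
#'
#' State occupancy over time as a stacked area chart.
#'
#' @param object A `dme_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dme_trace <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$age, y = .data$occupancy,
                                 fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(
      x = "Cohort age (years)", y = "State occupancy",
      fill = "State",
      title = sprintf("Cohort trace: %s", object$strategy_name)
    ) +
    ggplot2::theme_minimal()
}
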