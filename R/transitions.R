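#' Validate a per-cycle transition matrix
#'
#' Checks row-stochasticity (rows sum to 1 within `tol`), entries in
#' \[0, 1\], and — when the matrix includes the death state — that the death
#' row is the absorbing unit vector.
#'
#' @param m Square numeric matrix.
#' @param includes_death Does the last row/column represent the absorbing
#'   death state?
#' @param tol Row-sum tolerance (default `1e-9`).
#' @return `m`, invisibly, after validation.
#' @export
validate_transition_matrix <- function(m, includes_death = FALSE, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("transition matrix must be square.")
  }
  if (any(m < -tol | m > 1 + tol)) {
    abort("transition probabilities must lie in [0, 1].")
  }
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0) {
    abort(sprintf("row %d sums to %.12f, not 1 (tolerance %g).",
                  off[1], rs[off[1]], tol))
  }
  if (includes_death) {
    d <- nrow(m)
    unit <- numeric(d); unit[d] <- 1
    if (any(abs(m[d, ] - unit) > tol)) {
      abort("death row must be absorbing (unit vector on death).")
    }
  }
  invisible(m)
}

#' Adjust a transition row by an odds ratio on improvement
#'
#' Relative efficacy from a network meta-analysis is expressed as an odds
#' ratio on *improving*, i.e. moving to any better visual-acuity band.  The
#' aggregate improvement probability `p` of the row is transformed on the
#' odds scale, `p' = OR p / (1 - p + OR p)`, then mass inside the improvement
#' set is rescaled by `p'/p` and mass outside by `(1-p')/(1-p)`, preserving
#' the relative composition on each side and row-stochasticity.
#'
#' Applying the inverse odds ratio (`inverse = TRUE`, equivalent to using
#' `1/or_value`) converts a reference arm's row into a comparator arm's row.
#'
#' @param row Numeric probability row summing to 1.
#' @param or_value Odds ratio (> 0).
#' @param improvement_set Integer indices of the states counted as
#'   improvement (states better than the current one).
#' @param inverse Apply `1/or_value` instead of `or_value`.
#' @return Adjusted row of the same length, summing to 1.
#' @examples
#' row <- c(0.3, 0.4, 0.3)
#' apply_odds_ratio(row, 1.5949, improvement_set = 3)
#' @export
apply_odds_ratio <- function(row, or_value, improvement_set, inverse = FALSE) {
  if (or_value <= 0) abort("`or_value` must be positive.")
  if (abs(sum(row) - 1) > 1e-9) abort("`row` must sum to 1.")
  or <- if (inverse) 1 / or_value else or_value
  if (or == 1) return(row)
  p <- sum(row[improvement_set])
  if (p == 0) return(row)
  if (p >= 1) {
    warn("entire row mass lies in the improvement set; odds ratio has no effect.")
    return(row)
  }
  odds_new <- or * p / (1 - p)
  p_new <- odds_new / (1 + odds_new)
  out <- row
  out[improvement_set] <- row[improvement_set] * (p_new / p)
  out[-improvement_set] <- row[-improvement_set] * ((1 - p_new) / (1 - p))
  out
}

#' Adjust every row of a clinical matrix by an odds ratio
#'
#' For each live state the improvement set is all strictly better bands
#' (higher indices, bands being ordered worst to best).  The top band has no
#' better band and is left unchanged.
#'
#' @param clinical Square matrix over live bands only (no death).
#' @param or_value Odds ratio.
#' @param inverse Apply the inverse odds ratio.
#' @return Adjusted clinical matrix.
#' @export
apply_odds_ratio_matrix <- function(clinical, or_value, inverse = FALSE) {
  n <- nrow(clinical)
  out <- clinical
  for (i in seq_len(n - 1)) {
    out[i, ] <- apply_odds_ratio(clinical[i, ], or_value,
                                 improvement_set = (i + 1):n,
                                 inverse = inverse)
  }
  out
}

#' Compose a clinical matrix with a per-cycle death probability
#'
#' Death competes multiplicatively with clinical movement: each clinical
#' probability is scaled by the survival probability `1 - p_death` and the
#' remainder goes to the appended death column.  The death row is absorbing.
#'
#' @param clinical Square row-stochastic matrix over live bands.
#' @param p_death Per-cycle death probability (scalar or one value per live
#'   band).
#' @return `(n+1) x (n+1)` matrix including the death state.
#' @examples
#' compose_with_death(matrix(c(0.6, 0.4, 0.2, 0.8), 2, byrow = TRUE), 0.01)
#' @export
compose_with_death <- function(clinical, p_death) {
  if (any(p_death < 0 | p_death > 1)) abort("`p_death` must lie in [0, 1].")
  n <- nrow(clinical)
  out <- matrix(0, n + 1, n + 1)
  out[seq_len(n), seq_len(n)] <- clinical * (1 - p_death)
  out[seq_len(n), n + 1] <- p_death
  out[n + 1, n + 1] <- 1
  dimnames(out) <- NULL
  out
}

#' Assemble a per-strategy transition schedule
#'
#' A schedule maps each model cycle to the clinical (live-state) transition
#' matrix in force during that cycle: treatment-period matrices for the
#' treatment years (default 3, one matrix per year), then a natural-history
#' matrix for every later cycle.  Matrices adjusted by a relative-efficacy
#' odds ratio can be restricted to specific cycles (the published odds
#' ratios cover months 0--3, i.e. the first cycle).
#'
#' @param strategy_name Label for the strategy.
#' @param matrices Named list with elements `year1`, `year2`, `year3` (as
#'   many as `n_treatment_years`) and `natural_history`; optionally
#'   `year1_adjusted`, used in the cycles listed in `adjusted_cycles`.
#' @param n_treatment_years Years on treatment (default 3).
#' @param cycles_per_year Cycles per model year (default 4).
#' @param adjusted_cycles Zero-based cycle indices using `year1_adjusted`
#'   (default `0`, the months 0--3 cycle), ignored when no adjusted matrix is
#'   supplied.
#' @return An object of class `dme_schedule`.
#' @export
transition_schedule <- function(strategy_name, matrices,
                                n_treatment_years = 3,
                                cycles_per_year = 4,
                                adjusted_cycles = 0L) {
  needed <- c(paste0("year", seq_len(n_treatment_years)), "natural_history")
  missing <- setdiff(needed, names(matrices))
  if (length(missing) > 0) {
    abort(sprintf("schedule for '%s' is missing matrices: %s.",
                  strategy_name, paste(missing, collapse = ", ")))
  }
  for (nm in names(matrices)) validate_transition_matrix(matrices[[nm]])
  structure(
    list(
      strategy_name = strategy_name,
      matrices = matrices,
      n_treatment_years = n_treatment_years,
      cycles_per_year = cycles_per_year,
      adjusted_cycles = as.integer(adjusted_cycles)
    ),
    class = "dme_schedule"
  )
}

#' Period label in force during a cycle
#'
#' @param schedule A `dme_schedule`.
#' @param cycle Zero-based cycle index (the transition out of cycle `t`).
#' @return Character label, e.g. `"year1"` or `"natural_history"`.
#' @export
schedule_period <- function(schedule, cycle) {
  year <- cycle %/% schedule$cycles_per_year + 1
  ifelse(year <= schedule$n_treatment_years,
         paste0("year", year), "natural_history")
}

#' Clinical matrix in force during a cycle
#'
#' @inheritParams schedule_period
#' @return Clinical transition matrix over live bands.
#' @export
schedule_matrix <- function(schedule, cycle) {
  if (cycle %in% schedule$adjusted_cycles &&
      !is.null(schedule$matrices$year1_adjusted)) {
    return(schedule$matrices$year1_adjusted)
  }
  period <- schedule_period(schedule, cycle)
  m <- schedule$matrices[[period]]
  if (is.null(m)) {
    abort(sprintf("schedule for '%s' has no matrix for cycle %d (period %s).",
                  schedule$strategy_name, cycle, period))
  }
  m
}
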