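#' Background mortality with a disease-related relative risk
#'
#' Bundles an annual all-cause life table with the relative risks applied to
#' it: one for diabetes mellitus and one for diabetic macular edema on top of
#' diabetes.  The combined relative risk is their product (1.27 x 1.93 =
#' 2.4511, quoted as 2.45 at two decimals); it multiplies the all-cause
#' mortality *hazard*, not the probability, so scaled probabilities can never
#' exceed 1.
#'
#' @param life_table Tibble/data frame with columns `age` (integer years) and
#'   `p_annual` (annual all-cause death probability).  Must cover every age
#'   the cohort can reach and carry probability 1 at the cap age.
#' @param rr_diabetes Relative risk of death associated with diabetes
#'   (default 1.27).
#' @param rr_dme Additional relative risk associated with DME (default 1.93).
#' @param rr_combined Optional override for the combined relative risk; when
#'   `NULL` (default) it is `rr_diabetes * rr_dme`.  Sensitivity analyses vary
#'   this field directly.
#' @return An object of class `dme_mortality`.
#' @examples
#' lt <- generate_life_table()
#' m <- mortality_model(lt)
#' round(m$rr_combined, 2)
#' @export
mortality_model <- function(life_table,
                            rr_diabetes = 1.27,
                            rr_dme = 1.93,
                            rr_combined = NULL) {
  life_table <- as_tibble(life_table)
  if (!all(c("age", "p_annual") %in% names(life_table))) {
    abort("`life_table` needs columns `age` and `p_annual`.")
  }
  if (any(life_table$p_annual < 0 | life_table$p_annual > 1)) {
    abort("life-table probabilities must lie in [0, 1].")
  }
  if (any(diff(life_table$age) != 1)) {
    abort("`life_table` must cover consecutive integer ages.")
  }
  rr <- rr_combined %||% (rr_diabetes * rr_dme)
  if (rr <= 0) abort("combined relative risk must be positive.")
  structure(
    list(
      life_table = life_table,
      rr_diabetes = rr_diabetes,
      rr_dme = rr_dme,
      rr_combined = rr,
      max_age = max(life_table$age)
    ),
    class = "dme_mortality"
  )
}

#' Convert an annual probability to a shorter cycle
#'
#' Assumes a constant hazard within the year: `1 - (1 - p)^t` for a cycle of
#' `t` years.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param cycle_years Cycle length in years (default 0.25, a 3-month cycle).
#' @return Per-cycle probability.
#' @examples
#' annual_prob_to_cycle(0.04, 0.25)
#' @export
annual_prob_to_cycle <- function(p_annual, cycle_years = 0.25) {
  if (any(p_annual < 0 | p_annual > 1)) {
    abort("`p_annual` must lie in [0, 1].")
  }
  if (any(cycle_years <= 0)) abort("`cycle_years` must be positive.")
  1 - (1 - p_annual)^cycle_years
}

#' Per-cycle death probability under the disease relative risk
#'
#' The annual probability at `floor(age)` is converted to a hazard
#' \eqn{-\log(1 - p)}, scaled by the combined relative risk, and converted
#' back over the cycle: \eqn{1 - e^{-rr \cdot (-\log(1-p)) \cdot t}}.  An
#' annual probability of 1 yields 1 (the hazard is infinite).
#'
#' @param mortality A `dme_mortality`.
#' @param age Cohort age in years (may be fractional; looked up at
#'   `floor(age)`).
#' @param cycle_years Cycle length in years.
#' @return Per-cycle death probability, capped at 1.
#' @examples
#' m <- mortality_model(generate_life_table())
#' dme_cycle_death_prob(m, 63)
#' @export
dme_cycle_death_prob <- function(mortality, age, cycle_years = 0.25) {
  age_i <- pmin(floor(age), mortality$max_age)
  idx <- match(age_i, mortality$life_table$age)
  if (anyNA(idx)) {
    abort(sprintf("age %s outside life-table coverage (%d-%d).",
                  paste(age[is.na(idx)], collapse = ", "),
                  min(mortality$life_table$age), mortality$max_age))
  }
  p <- mortality$life_table$p_annual[idx]
  out <- ifelse(
    p >= 1, 1,
    1 - exp(-mortality$rr_combined * (-log(1 - p)) * cycle_years)
  )
  pmin(out, 1)
}

#' Synthetic Gompertz life table
#'
#' Annual death probability `p(age) = 1 - exp(-a * exp(b * age))`, monotone
#' non-decreasing in age and forced to 1 at the cap age so the cohort cannot
#' outlive the table.  Stands in for a national all-cause life table.
#'
#' @param min_age,max_age Age coverage (defaults 0 and 100).
#' @param a,b Gompertz level and shape (defaults `5e-5`, `0.09`).
#' @return Tibble with columns `age`, `p_annual`.
#' @examples
#' lt <- generate_life_table()
#' lt[lt$age == 63, ]
#' @export
generate_life_table <- function(min_age = 0, max_age = 100,
                                a = 5e-5, b = 0.09) {
  if (a <= 0 || b <= 0) abort("Gompertz parameters `a` and `b` must be positive.")
  age <- seq(min_age, max_age)
  p <- 1 - exp(-a * exp(b * age))
  p[age >= max_age] <- 1
  tibble(age = as.integer(age), p_annual = pmin(p, 1))
}
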