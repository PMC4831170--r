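# Synthetic stand-ins for inputs the published sources summarise but do not
# print: per-period transition matrices, per-band utilities, the national
# life table, and the baseline distribution.  All randomness flows through
# one seeded generator so scenarios are reproducible.

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a banded clinical transition matrix
#'
#' Rows follow a biased random walk over visual-acuity bands: moves of 0,
#' one or two bands dominate (states are two-line bands, so larger
#' per-quarter jumps are clinically implausible).  A positive bias tilts
#' mass toward better bands (treatment effect); a negative bias toward worse
#' bands (natural decline).  Zero bias with zero jitter yields symmetric
#' random-walk rows away from the edges; edge rows are truncated and
#' renormalised.
#'
#' @param n_bands Number of live bands.
#' @param bias Tilt in (-1, 1); upward weights are scaled by `1 + bias`,
#'   downward by `1 - bias`.
#' @param stay_weight,step1_weight,step2_weight Base weights for moves of 0,
#'   1 and 2 bands.
#' @param jitter_sd Log-normal jitter applied multiplicatively to each
#'   weight (0 = deterministic rows); draws come from the current RNG
#'   stream.
#' @return `n_bands x n_bands` row-stochastic matrix.
#' @export
generate_transition_matrix <- function(n_bands, bias = 0,
                                       stay_weight = 0.55,
                                       step1_weight = 0.18,
                                       step2_weight = 0.045,
                                       jitter_sd = 0) {
  if (abs(bias) >= 1) abort("`bias` magnitude must be below 1.")
  base <- c(step2_weight, step1_weight, stay_weight, step1_weight, step2_weight)
  m <- matrix(0, n_bands, n_bands)
  for (i in seq_len(n_bands)) {
    d <- seq_len(n_bands) - i
    w <- numeric(n_bands)
    in_reach <- abs(d) <= 2
    w[in_reach] <- base[d[in_reach] + 3]
    w[d > 0] <- w[d > 0] * (1 + bias)
    w[d < 0] <- w[d < 0] * (1 - bias)
    if (jitter_sd > 0) {
      w[in_reach] <- w[in_reach] * exp(stats::rnorm(sum(in_reach), 0, jitter_sd))
    }
    m[i, ] <- w / sum(w)
  }
  m
}

#' Generate per-strategy transition schedules
#'
#' Builds the observed arm's period matrices (treatment years biased toward
#' improvement, with year 1 stronger than years 2--3; natural history from
#' year 4 biased toward decline), then derives the comparator arms through
#' the relative-efficacy odds ratios: the reference-priced comparator via
#' the inverse odds ratio of the observed arm, and any further arm via its
#' own odds ratio versus that comparator.  Odds-ratio adjustment applies to
#' the cycles listed in `or_cycles` (default the first cycle, months 0--3).
#'
#' @param scenario A `dme_scenario`.
#' @param state_space The scenario's `dme_state_space`.
#' @return Named list of `dme_schedule`, one per strategy.
#' @export
generate_schedules <- function(scenario, state_space = NULL) {
  state_space <- state_space %||% build_state_space(scenario$band_edges,
                                                    scenario$vi_threshold)
  n_bands <- state_space$n_bands
  syn <- scenario$synthetic
  tr <- scenario$transitions

  if (!is.null(tr$matrices)) {
    base_mats <- tr$matrices
    for (m in base_mats) validate_transition_matrix(m)
  } else {
    biases <- c(syn$improvement_bias, -abs(syn$decline_bias))
    if (any(abs(biases) >= 1)) abort("bias magnitudes must be below 1.")
    base_mats <- with_preserved_seed(scenario$seed, {
      out <- lapply(biases, function(b) {
        generate_transition_matrix(
          n_bands, bias = b,
          stay_weight = syn$stay_weight,
          step1_weight = syn$step1_weight,
          step2_weight = syn$step2_weight,
          jitter_sd = syn$jitter_sd
        )
      })
      names(out) <- c(paste0("year", seq_along(syn$improvement_bias)),
                      "natural_history")
      out
    })
  }

  observed <- tr$observed_arm
  ref <- scenario$reference_strategy
  schedules <- list()
  for (nm in names(scenario$strategies)) {
    st <- scenario$strategies[[nm]]
    mats <- base_mats
    if (nm == ref && nm != observed &&
        !is.na(scenario$strategies[[observed]]$or_vs_reference)) {
      # comparator arm: observed arm's first-cycle matrix pushed through the
      # inverse odds ratio of observed-vs-comparator
      mats$year1_adjusted <- apply_odds_ratio_matrix(
        base_mats$year1,
        scenario$strategies[[observed]]$or_vs_reference,
        inverse = TRUE
      )
    } else if (nm != observed && !is.na(st$or_vs_reference)) {
      afl_y1 <- apply_odds_ratio_matrix(
        base_mats$year1,
        scenario$strategies[[observed]]$or_vs_reference,
        inverse = TRUE
      )
      mats$year1_adjusted <- apply_odds_ratio_matrix(afl_y1, st$or_vs_reference)
    }
    schedules[[nm]] <- transition_schedule(
      nm, mats,
      n_treatment_years = scenario$n_treatment_years,
      adjusted_cycles = tr$or_cycles
    )
  }
  schedules
}

#' Synthetic monotone utility vectors
#'
#' Linear interpolation between anchor utilities at the worst and best
#' bands, separately for better-seeing-eye treatment (wider range) and
#' worse-seeing-eye treatment (narrower range).
#'
#' @param n_bands Number of live bands.
#' @param bse_anchors,wse_anchors Length-2 vectors `c(worst, best)`.
#' @return List with monotone vectors `bse` and `wse`.
#' @export
generate_utilities <- function(n_bands,
                               bse_anchors = c(0.50, 0.85),
                               wse_anchors = c(0.70, 0.80)) {
  list(
    bse = seq(bse_anchors[1], bse_anchors[2], length.out = n_bands),
    wse = seq(wse_anchors[1], wse_anchors[2], length.out = n_bands)
  )
}

#' Baseline distribution over bands
#'
#' Mass proportional to each band's letter overlap with the trial
#' recruitment window (at least one eye with BCVA between `window[1]` and
#' `window[2]` letters), emulating a trial-like baseline spread
#' concentrated on the middle bands.
#'
#' @param state_space A `dme_state_space`.
#' @param window Recruitment window on the letter scale (default
#'   `c(39, 78)`).
#' @return Probability vector over live bands.
#' @export
baseline_distribution <- function(state_space, window = c(39, 78)) {
  lo <- pmax(state_space$bands$lower, 0)
  hi <- pmin(state_space$bands$upper, 100)
  overlap <- pmax(0, pmin(hi, window[2]) - pmax(lo, window[1]))
  if (sum(overlap) == 0) abort("recruitment window overlaps no band.")
  overlap / sum(overlap)
}
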