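# Individual-level simulation oracle for the cohort recursion.  Deliberately
# independent of run_cohort(): it tracks n simulated patients, sampling each
# patient's next state from the composed per-cycle transition row, and
# recomputes the age-specific death probability from first principles.
microsimulate <- function(initial, schedule, mortality, horizon_cycles,
                          n = 1e5, start_age = 63, cycle_years = 0.25) {
  n_live <- length(initial)
  n_states <- n_live + 1L
  state <- sample.int(n_live, n, replace = TRUE, prob = initial)
  occ <- matrix(0, horizon_cycles + 1, n_states)
  occ[1, ] <- tabulate(state, n_states) / n
  lt <- mortality$life_table
  for (t in seq_len(horizon_cycles)) {
    age <- floor(start_age + (t - 1) * cycle_years)
    p_annual <- lt$p_annual[match(min(age, max(lt$age)), lt$age)]
    p_death <- if (p_annual >= 1) 1 else {
      1 - exp(-mortality$rr_combined * (-log(1 - p_annual)) * cycle_years)
    }
    clin <- schedule_matrix(schedule, t - 1L)
    full <- cbind(clin * (1 - p_death), p_death)
    full <- rbind(full, c(rep(0, n_live), 1))
    new_state <- state
    for (s in unique(state)) {
      idx <- which(state == s)
      new_state[idx] <- sample.int(n_states, length(idx), replace = TRUE,
                                   prob = full[s, ])
    }
    state <- new_state
    occ[t + 1, ] <- tabulate(state, n_states) / n
  }
  occ
}
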