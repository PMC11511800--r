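# Shared fixtures, built in code.

# Baseline no-intervention matrix as a plain numeric matrix.
base_matrix <- function() {
  matrix(c(
    0.72, 0.07, 0.13, 0.05, 0.03,
    0.59, 0.13, 0.20, 0.05, 0.03,
    0.28, 0.09, 0.20, 0.23, 0.20,
    0.00, 0.00, 0.00, 0.60, 0.40,
    0.00, 0.00, 0.00, 0.00, 1.00
  ), nrow = 5, byrow = TRUE)
}

# Identity transitions: everyone stays put (legal: absorbing everywhere).
identity_tm <- function() transition_matrix(diag(5))

# Everyone dies within one cycle.
all_to_death_tm <- function() {
  m <- matrix(0, 5, 5)
  m[, 5] <- 1
  transition_matrix(m)
}

# A hand-built arm_result, for exercising compare_arms() arithmetic directly.
toy_arm_result <- function(total_qalys, total_cost, n = 173) {
  structure(
    list(total_qalys = total_qalys, total_cost = total_cost,
         qalys_per_participant = total_qalys / n,
         cost_per_participant = total_cost / n,
         cohort_size = n, trace = NULL),
    class = "arm_result"
  )
}

# A constant (flat) mortality schedule covering the model ages.
flat_schedule <- function(q, start_age = 76, horizon = 12) {
  mortality_schedule(start_age + 0:horizon, rep(q, horizon + 1))
}
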