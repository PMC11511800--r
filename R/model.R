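#' Assemble a full cost-effectiveness model
#'
#' Bundles everything a scenario run needs: the scalar configuration, the
#' baseline (no-intervention) transition matrix, the per-state payoffs, the
#' intervention specification and the background mortality schedule. Called
#' with no arguments it returns the base-case model: 173 persons starting in
#' state A at age 76, 12 annual cycles, 3% discounting after the first year,
#' half-cycle correction, rate ratio 0.76 applied in the first year with
#' published-style rounding, and an intervention cost of EUR 121 per
#' participant.
#'
#' @param config A [model_config()].
#' @param matrix The baseline `transition_matrix` (no intervention).
#' @param payoffs A [state_payoffs()].
#' @param intervention An [intervention_spec()].
#' @param schedule A [mortality_schedule()] covering
#'   `config$start_age .. config$start_age + horizon - 1`.
#' @return Object of class `fall_model`.
#' @examples
#' m <- fall_model()
#' run_scenario(m)
#' @export
fall_model <- function(config = model_config(),
                       matrix = fall_transition_matrix(),
                       payoffs = fall_state_payoffs(),
                       intervention = intervention_spec(),
                       schedule = gompertz_schedule(
                         anchor = unclass(matrix)[.A, .E],
                         start_age = config$start_age,
                         horizon = config$horizon)) {
  stopifnot(inherits(config, "model_config"),
            inherits(payoffs, "state_payoffs"),
            inherits(intervention, "intervention_spec"),
            inherits(schedule, "mortality_schedule"))
  validate_transition_matrix(matrix)
  structure(
    list(config = config, matrix = matrix, payoffs = payoffs,
         intervention = intervention, schedule = schedule),
    class = "fall_model"
  )
}

#' @export
print.fall_model <- function(x, ...) {
  cat("Five-state fall prevention cost-effectiveness model\n\n")
  print(x$config); cat("\n")
  print(x$intervention); cat("\n")
  print(x$matrix)
  invisible(x)
}

#' Build the per-cycle transition matrices of one arm
#'
#' Cycle `t` uses the baseline matrix with A->E and B->E age-adjusted to the
#' cohort's age during that cycle (`start_age + t - 1`); at the start age the
#' schedule anchor equals the baseline probability, so cycle 1 is unchanged.
#' For the intervention arm the fall rate ratio is additionally applied during
#' the first `effect_duration` cycles (rounded to two decimals under the
#' `"table"` rounding mode, exact under `"exact"`). Both arms share the
#' identical mortality adjustment.
#'
#' @param model A [fall_model()].
#' @param arm `"no_intervention"` or `"intervention"`.
#' @return List of validated `transition_matrix` objects, one per cycle.
#' @export
build_arm_matrices <- function(model, arm = c("no_intervention", "intervention")) {
  arm <- match.arg(arm)
  cfg <- model$config
  lapply(seq_len(cfg$horizon), function(t) {
    tm <- adjust_mortality(model$matrix, age = cfg$start_age + t - 1L,
                           schedule = model$schedule)
    if (arm == "intervention" && t <= model$intervention$effect_duration) {
      digits <- if (model$intervention$rounding == "table") 2L else NULL
      tm <- apply_rate_ratio(tm, model$intervention$rate_ratio,
                             round_digits = digits)
    }
    attr(tm, "cycles") <- as.character(t)
    tm
  })
}
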