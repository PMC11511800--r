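#' Model configuration
#'
#' Scalar settings of the cohort model. Defaults reproduce the base-case
#' evaluation: a closed cohort of 173 persons entering at mean age 76, run for
#' 12 annual cycles, outcomes discounted at 3% per year after the first year,
#' with half-cycle correction on.
#'
#' @param cohort_size Number of persons entering the model (> 0).
#' @param start_age Age (years) of the cohort at entry.
#' @param horizon Number of annual cycles (>= 1).
#' @param discount_rate Annual discount rate (>= 0) applied to costs and QALYs.
#' @param half_cycle Logical; apply half-cycle correction (mean of adjacent
#'   occupancy vectors) when accumulating outcomes.
#' @param discount_first_year Logical; if `FALSE` (default) the first cycle is
#'   undiscounted and discounting starts after the first year. If `TRUE`,
#'   cycle 1 is already discounted by one year.
#' @param effect_duration Number of initial cycles during which the
#'   intervention effect applies (default 1: first year only).
#' @param initial_state State label in which the whole cohort starts
#'   (default `"A"`).
#' @return Object of class `model_config`.
#' @export
model_config <- function(cohort_size = 173, start_age = 76, horizon = 12,
                         discount_rate = 0.03, half_cycle = TRUE,
                         discount_first_year = FALSE,
                         effect_duration = 1, initial_state = "A") {
  stopifnot(cohort_size > 0, horizon >= 1, discount_rate >= 0,
            effect_duration >= 0, effect_duration <= horizon)
  initial_state <- match.arg(initial_state, state_labels())
  structure(
    list(cohort_size = cohort_size, start_age = start_age,
         horizon = as.integer(horizon), discount_rate = discount_rate,
         half_cycle = isTRUE(half_cycle),
         discount_first_year = isTRUE(discount_first_year),
         effect_duration = as.integer(effect_duration),
         initial_state = initial_state),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("Model configuration\n")
  cat(sprintf("  cohort size     : %g persons\n", x$cohort_size))
  cat(sprintf("  start age       : %g years\n", x$start_age))
  cat(sprintf("  horizon         : %d annual cycles\n", x$horizon))
  cat(sprintf("  discount rate   : %g/year (%s)\n", x$discount_rate,
              if (x$discount_first_year) "from year 1" else "after year 1"))
  cat(sprintf("  half-cycle corr.: %s\n", if (x$half_cycle) "on" else "off"))
  cat(sprintf("  effect duration : %d cycle(s)\n", x$effect_duration))
  invisible(x)
}

new_cohort_trace <- function(occ, cohort_size) {
  dimnames(occ) <- list(cycle = 0:(nrow(occ) - 1L), state = state_labels())
  structure(occ, class = "cohort_trace", cohort_size = cohort_size)
}

#' Validate a cohort trace
#'
#' Checks conservation (every row sums to the cohort size within `tol`),
#' non-negativity, and that occupancy of the absorbing death state never
#' decreases.
#'
#' @param trace A `cohort_trace`.
#' @param tol Tolerance on row sums (default `1e-6` persons).
#' @return The trace, invisibly.
#' @export
validate_cohort_trace <- function(trace, tol = 1e-6) {
  stopifnot(inherits(trace, "cohort_trace"))
  n <- attr(trace, "cohort_size")
  m <- unclass(trace)
  if (any(m < -tol)) stop("negative occupancy in cohort trace", call. = FALSE)
  if (any(abs(rowSums(m) - n) > tol)) {
    stop("cohort not conserved: a trace row does not sum to the cohort size",
         call. = FALSE)
  }
  if (any(diff(m[, .E]) < -tol)) {
    stop("occupancy of the absorbing death state decreased", call. = FALSE)
  }
  invisible(trace)
}

#' Run the cohort occupancy recursion
#'
#' Propagates the expected state occupancy of a closed cohort through one
#' transition matrix per cycle: row `t+1` of the trace is row `t` multiplied
#' by the cycle-(t+1) matrix. Occupancy is fractional (expected-value cohort);
#' persons are conserved every cycle.
#'
#' @param matrices A single `transition_matrix` (used for every cycle) or a
#'   list of them, one per cycle, of length `config$horizon`.
#' @param config A [model_config()].
#' @return A `cohort_trace`: a `(horizon + 1) x 5` occupancy matrix in
#'   persons, whose row 0 is the initial distribution (everyone in
#'   `config$initial_state`).
#' @examples
#' trace <- run_cohort(fall_transition_matrix(), model_config())
#' head(as.data.frame(trace))
#' @export
run_cohort <- function(matrices, config) {
  stopifnot(inherits(config, "model_config"))
  if (inherits(matrices, "transition_matrix")) {
    matrices <- rep(list(matrices), config$horizon)
  }
  if (!is.list(matrices) || length(matrices) != config$horizon) {
    stop(sprintf("`matrices` must supply one transition matrix per cycle (%d needed, %d given)",
                 config$horizon, length(matrices)), call. = FALSE)
  }
  lapply(matrices, validate_transition_matrix)

  occ <- matrix(0, nrow = config$horizon + 1L, ncol = 5L)
  occ[1L, match(config$initial_state, state_labels())] <- config$cohort_size
  for (t in seq_len(config$horizon)) {
    occ[t + 1L, ] <- occ[t, ] %*% unclass(matrices[[t]])
  }
  trace <- new_cohort_trace(occ, config$cohort_size)
  validate_cohort_trace(trace)
  trace
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = 0:(nrow(x) - 1L), unclass(x), row.names = NULL,
             check.names = FALSE)
}

#' @export
print.cohort_trace <- function(x, digits = 2, ...) {
  cat(sprintf("Cohort trace (%g persons, %d cycles)\n",
              attr(x, "cohort_size"), nrow(x) - 1L))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Write a cohort trace to CSV
#'
#' Exports the occupancy trace with header `cycle,A,B,C,D,E`.
#'
#' @param trace A `cohort_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
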