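#' Per-state utilities and annual societal costs
#'
#' Attaches to each health state a quality-of-life weight (QALYs accrued per
#' year spent in the state) and an annual societal cost in euro. By
#' construction death carries zero utility and zero cost, the at-risk state
#' carries zero cost, utilities lie in \[0, 1\] and costs are non-negative.
#'
#' @param utility Numeric vector of length 5 (states A..E): QALY weight per
#'   year, dimensionless.
#' @param cost Numeric vector of length 5: annual societal cost per person in
#'   euro.
#' @return Object of class `state_payoffs`.
#' @examples
#' fall_state_payoffs()
#' @export
state_payoffs <- function(utility, cost) {
  if (length(utility) != 5 || length(cost) != 5) {
    stop("`utility` and `cost` must each have one value per state (5)", call. = FALSE)
  }
  if (any(utility < 0 | utility > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cost < 0)) stop("costs must be non-negative", call. = FALSE)
  if (utility[.E] != 0 || cost[.E] != 0) {
    stop("the death state must carry zero utility and zero cost", call. = FALSE)
  }
  if (cost[.A] != 0) {
    stop("the at-risk state carries no societal cost", call. = FALSE)
  }
  structure(
    list(utility = stats::setNames(as.numeric(utility), state_labels()),
         cost = stats::setNames(as.numeric(cost), state_labels())),
    class = "state_payoffs"
  )
}

#' @export
print.state_payoffs <- function(x, ...) {
  cat("Per-state payoffs (annual)\n")
  print(data.frame(state = state_labels(), utility = unname(x$utility),
                   cost_eur = unname(x$cost)), row.names = FALSE)
  invisible(x)
}

#' Discount factor for an annual cycle
#'
#' Present-value multiplier for outcomes accrued in cycle `cycle` (1-based).
#' Under the default convention the first year is undiscounted and discounting
#' at `rate` applies after the first year: the factor is 1 for cycle 1 and
#' \eqn{(1 + r)^{-(t - 1)}} for cycle \eqn{t \ge 2}. With
#' `first_year_discounted = TRUE` the exponent is \eqn{t} instead.
#'
#' @param cycle Integer cycle index, 1-based; vectorised.
#' @param rate Annual discount rate (>= 0).
#' @param first_year_discounted Logical, default `FALSE`.
#' @return Numeric multiplier(s) in (0, 1].
#' @examples
#' discount_factor(1:12, 0.03)
#' @export
discount_factor <- function(cycle, rate, first_year_discounted = FALSE) {
  if (any(cycle < 1)) stop("`cycle` is 1-based and must be >= 1", call. = FALSE)
  stopifnot(rate >= 0)
  expo <- if (isTRUE(first_year_discounted)) cycle else cycle - 1
  (1 + rate)^(-expo)
}

#' Accumulate discounted QALYs and costs over a cohort trace
#'
#' For each cycle the state-membership QALYs and societal costs are computed
#' on the half-cycle-corrected occupancy (the arithmetic mean of the occupancy
#' at the start and at the end of the cycle), multiplied by the cycle's
#' discount factor, and summed over the horizon. Intervention acquisition
#' costs are *not* added here; see [compare_arms()].
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param payoffs A [state_payoffs()].
#' @param config The [model_config()] used to build the trace (supplies the
#'   discount rate and the half-cycle flag).
#' @param timing Occupancy used to credit each cycle's outcomes: `"half"`
#'   (trapezoid, the default when `config$half_cycle` is on), `"start"` or
#'   `"end"` of cycle. Overrides the config flag when given.
#' @return Object of class `arm_result`: total and per-participant discounted
#'   QALYs and costs, with the trace attached.
#' @examples
#' cfg <- model_config()
#' trace <- run_cohort(fall_transition_matrix(), cfg)
#' accumulate_outcomes(trace, fall_state_payoffs(), cfg)
#' @export
accumulate_outcomes <- function(trace, payoffs, config,
                                timing = NULL) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(payoffs, "state_payoffs"),
            inherits(config, "model_config"))
  if (nrow(trace) != config$horizon + 1L) {
    stop("trace and config disagree on the horizon", call. = FALSE)
  }
  if (is.null(timing)) timing <- if (config$half_cycle) "half" else "end"
  timing <- match.arg(timing, c("half", "start", "end"))

  m <- unclass(trace)
  occ <- switch(timing,
    half  = (m[-nrow(m), , drop = FALSE] + m[-1L, , drop = FALSE]) / 2,
    start = m[-nrow(m), , drop = FALSE],
    end   = m[-1L, , drop = FALSE]
  )
  df <- discount_factor(seq_len(config$horizon), config$discount_rate,
                        config$discount_first_year)
  qalys <- sum((occ %*% payoffs$utility) * df)
  costs <- sum((occ %*% payoffs$cost) * df)
  structure(
    list(total_qalys = qalys, total_cost = costs,
         qalys_per_participant = qalys / config$cohort_size,
         cost_per_participant = costs / config$cohort_size,
         cohort_size = config$cohort_size, trace = trace),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm result (n = %g)\n", x$cohort_size))
  cat(sprintf("  discounted QALYs: %.3f total, %.3f per participant\n",
              x$total_qalys, x$qalys_per_participant))
  cat(sprintf("  discounted cost : EUR %.0f total, EUR %.0f per participant\n",
              x$total_cost, x$cost_per_participant))
  invisible(x)
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental QALYs and costs (reference minus comparator), adding
#' the one-off intervention acquisition cost to the reference arm at time zero
#' (undiscounted, no half-cycle correction), and classifies the result:
#' *dominant* (more effective and cheaper), *dominated* (less effective and
#' more expensive), an ICER \eqn{\Delta C / \Delta E} otherwise, or
#' "cost difference only" when effects are tied but costs differ.
#'
#' @param reference `arm_result` of the intervention arm.
#' @param comparator `arm_result` of the no-intervention arm.
#' @param intervention_cost_per_participant One-off acquisition cost in euro
#'   per participant, charged to the reference arm at time zero (>= 0).
#' @param tol Absolute tolerance below which an incremental QALY or cost
#'   difference is treated as zero.
#' @return Object of class `ce_result` with per-participant and total
#'   incrementals, the verdict, and the unrounded ICER when defined (round
#'   only for presentation).
#' @examples
#' m <- fall_model()
#' res <- run_scenario(m)
#' res$ce
#' @export
compare_arms <- function(reference, comparator,
                         intervention_cost_per_participant = 0,
                         tol = 1e-12) {
  stopifnot(inherits(reference, "arm_result"), inherits(comparator, "arm_result"))
  if (reference$cohort_size != comparator$cohort_size) {
    stop("arms must share the cohort size", call. = FALSE)
  }
  if (intervention_cost_per_participant < 0) {
    stop("intervention cost must be non-negative", call. = FALSE)
  }
  n <- reference$cohort_size
  d_qalys <- reference$total_qalys - comparator$total_qalys
  d_cost <- (reference$total_cost + n * intervention_cost_per_participant) -
    comparator$total_cost
  dq <- d_qalys / n
  dc <- d_cost / n

  eff0 <- abs(dq) <= tol
  cost0 <- abs(dc) <= tol
  verdict <- if (eff0 && cost0) {
    "no difference"
  } else if (eff0) {
    "cost difference only"
  } else if (dq > 0 && dc < 0) {
    "dominant"
  } else if (dq < 0 && dc > 0) {
    "dominated"
  } else {
    "ICER"
  }
  icer <- if (verdict == "ICER") d_cost / d_qalys else NA_real_

  structure(
    list(delta_qalys_per_participant = dq,
         delta_cost_per_participant = dc,
         delta_qalys_total = d_qalys,
         delta_cost_total = d_cost,
         intervention_cost_per_participant = intervention_cost_per_participant,
         verdict = verdict, icer = icer, cohort_size = n),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Incremental cost-effectiveness (reference - comparator)\n")
  cat(sprintf("  incremental QALYs: %+.3f per participant (%+.3f total)\n",
              x$delta_qalys_per_participant, x$delta_qalys_total))
  cat(sprintf("  incremental cost : EUR %+.0f per participant (EUR %+.0f total)\n",
              x$delta_cost_per_participant, x$delta_cost_total))
  if (x$verdict == "ICER") {
    cat(sprintf("  verdict: ICER = EUR %s per QALY gained\n",
                format(round_half_up(x$icer), big.mark = " ")))
  } else {
    cat(sprintf("  verdict: %s\n", x$verdict))
  }
  invisible(x)
}
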