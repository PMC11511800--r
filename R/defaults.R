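#' Baseline annual transition matrix of the fall model
#'
#' The literature-derived annual transition probabilities between the five
#' states, for either strategy. The intervention matrix differs only in the
#' first-year fall-related transitions (A->B, A->C, B->C reduced by the fall
#' rate ratio, with the removed mass returned to A->A and B->A, entries
#' rounded to whole percent).
#'
#' @param arm `"no_intervention"` (default) or `"intervention"` (the
#'   first-year matrix with the base-case rate ratio of 0.76 applied and
#'   rounded to two decimals).
#' @return A validated `transition_matrix`.
#' @examples
#' fall_transition_matrix()
#' fall_transition_matrix("intervention")
#' @export
fall_transition_matrix <- function(arm = c("no_intervention", "intervention")) {
  arm <- match.arg(arm)
  base <- matrix(c(
    0.72, 0.07, 0.13, 0.05, 0.03,   # A: at risk
    0.59, 0.13, 0.20, 0.05, 0.03,   # B: minor consequences
    0.28, 0.09, 0.20, 0.23, 0.20,   # C: major consequences
    0.00, 0.00, 0.00, 0.60, 0.40,   # D: special housing
    0.00, 0.00, 0.00, 0.00, 1.00    # E: death (absorbing)
  ), nrow = 5, byrow = TRUE)
  tm <- transition_matrix(base, arm = "no_intervention")
  if (arm == "intervention") {
    tm <- apply_rate_ratio(tm, 0.76, round_digits = 2)
    attr(tm, "cycles") <- "1"
  }
  tm
}

#' Baseline per-state utilities and annual costs
#'
#' Quality-of-life weights and annual societal costs (euro, December 2021
#' values) per state: at risk 0.86 / 0; minor consequences 0.72 / 707; major
#' consequences 0.59 / 18 625; special housing 0.41 / 99 727; death 0 / 0.
#' Costs take a societal perspective (regional care, municipal care, informal
#' care).
#'
#' @return A `state_payoffs` object.
#' @export
fall_state_payoffs <- function() {
  state_payoffs(
    utility = c(0.86, 0.72, 0.59, 0.41, 0),
    cost = c(0, 707, 18625, 99727, 0)
  )
}

#' Baseline intervention cost components
#'
#' The cost ledger of the digital exercise intervention as delivered in a
#' municipality setting: recruitment (brochure, bus advertisement, oral
#' presentations), supportive strategies (group exercise sessions,
#' introductory/technical-support drop-in meetings) and annual application
#' maintenance. Totals in euro; spread over 173 participants these yield
#' per-participant category costs of EUR 52, 42 and 27 (EUR 121 in total).
#'
#' @return A list of [cost_component()] objects.
#' @examples
#' build_cost_ledger(fall_cost_components(), 173)
#' @export
fall_cost_components <- function() {
  list(
    cost_component("brochure", "recruitment", total = 6707, units = 7500),
    cost_component("bus advertisement", "recruitment", total = 1600, units = 64),
    cost_component("oral presentations", "recruitment", total = 600, units = 23),
    cost_component("group exercise sessions", "support", total = 6900, units = 30),
    cost_component("drop-in support meetings", "support", total = 256, units = 10),
    cost_component("application maintenance", "maintenance", total = 4581)
  )
}
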