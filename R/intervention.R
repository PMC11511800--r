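#' A single intervention cost component
#'
#' One line of the intervention cost ledger: a labelled total cost in euro
#' belonging to one of three categories (recruitment, supportive strategies,
#' application maintenance).
#'
#' @param label Free-text label, e.g. `"brochure"`.
#' @param category One of `"recruitment"`, `"support"`, `"maintenance"`.
#' @param total Total cost of the component in euro (>= 0).
#' @param units Optional unit count (e.g. copies printed, staff hours).
#' @return Object of class `cost_component`.
#' @export
cost_component <- function(label, category = c("recruitment", "support", "maintenance"),
                           total, units = NA_real_) {
  category <- match.arg(category)
  if (total < 0) stop("component cost must be non-negative", call. = FALSE)
  structure(list(label = label, category = category,
                 total = as.numeric(total), units = units),
            class = "cost_component")
}

#' Build the per-participant intervention cost ledger
#'
#' Divides category cost totals by the cohort size and rounds each category's
#' per-participant cost *up* to the next whole euro; the per-participant grand
#' total is the sum of the rounded category costs. Rounding up at category
#' level is the presentation convention this package adopts for whole-euro
#' ledgers; component-level per-participant costs are also reported
#' (nearest-euro) for information but the category figures are authoritative.
#'
#' @param components List of [cost_component()] objects (non-empty).
#' @param cohort_size Number of participants the cost is spread over (> 0).
#' @param category_multipliers Optional named numeric vector scaling the cost
#'   totals of whole categories, e.g. `c(recruitment = 1.5)` for a 50% larger
#'   recruitment campaign.
#' @return Object of class `cost_ledger`: a component table, per-participant
#'   category costs, and the per-participant grand total in euro.
#' @examples
#' build_cost_ledger(fall_cost_components(), cohort_size = 173)
#' @export
build_cost_ledger <- function(components, cohort_size,
                              category_multipliers = NULL) {
  if (length(components) == 0) stop("no cost components supplied", call. = FALSE)
  stopifnot(cohort_size > 0)
  if (inherits(components, "cost_component")) components <- list(components)
  ok <- vapply(components, inherits, logical(1), "cost_component")
  if (!all(ok)) stop("`components` must be cost_component objects", call. = FALSE)

  tab <- data.frame(
    label = vapply(components, `[[`, character(1), "label"),
    category = vapply(components, `[[`, character(1), "category"),
    units = vapply(components, function(x) as.numeric(x$units), numeric(1)),
    total = vapply(components, `[[`, numeric(1), "total")
  )
  if (!is.null(category_multipliers)) {
    for (cat in names(category_multipliers)) {
      tab$total[tab$category == cat] <- tab$total[tab$category == cat] *
        category_multipliers[[cat]]
    }
  }
  tab$per_participant <- round_half_up(tab$total / cohort_size)

  cats <- c("recruitment", "support", "maintenance")
  cat_total <- vapply(cats, function(cc) sum(tab$total[tab$category == cc]),
                      numeric(1))
  cat_pp <- ceiling(cat_total / cohort_size)
  structure(
    list(components = tab,
         cohort_size = cohort_size,
         category_total = cat_total,
         category_per_participant = cat_pp,
         total = sum(cat_total),
         total_per_participant = sum(cat_pp)),
    class = "cost_ledger"
  )
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat(sprintf("Intervention cost ledger (n = %g participants)\n", x$cohort_size))
  print(x$components, row.names = FALSE)
  cat("Per participant, by category (EUR):\n")
  print(x$category_per_participant)
  cat(sprintf("Total per participant: EUR %d\n", x$total_per_participant))
  invisible(x)
}

#' Intervention specification
#'
#' The intervention is modelled as (i) a multiplicative reduction of the rate
#' of falls, applied to the fall-related transitions A->B, A->C and B->C for a
#' limited number of initial cycles, and (ii) a one-off acquisition cost per
#' participant charged at time zero.
#'
#' @param rate_ratio Fall rate ratio in (0, 1]; 0.76 means a 24% reduction in
#'   the rate of falls.
#' @param effect_duration Number of initial cycles the effect lasts
#'   (default 1: the first year only).
#' @param cost_per_participant One-off intervention cost per participant in
#'   euro; defaults to the ledger total of [fall_cost_components()].
#' @param rounding `"table"`: after multiplying by the rate ratio, round the
#'   modified probabilities to two decimals before rebalancing (reproduces a
#'   published-style whole-percent matrix); `"exact"`: keep unrounded
#'   products (used by the sensitivity scenarios, where e.g. a 0.98 ratio
#'   would otherwise round away entirely).
#' @return Object of class `intervention_spec`.
#' @export
intervention_spec <- function(rate_ratio = 0.76, effect_duration = 1,
                              cost_per_participant = NULL,
                              rounding = c("table", "exact")) {
  rounding <- match.arg(rounding)
  if (rate_ratio <= 0 || rate_ratio > 1) {
    stop("the rate ratio must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(cost_per_participant)) {
    cost_per_participant <-
      build_cost_ledger(fall_cost_components(), 173)$total_per_participant
  }
  if (cost_per_participant < 0) {
    stop("intervention cost must be non-negative", call. = FALSE)
  }
  structure(
    list(rate_ratio = rate_ratio,
         effect_duration = as.integer(effect_duration),
         cost_per_participant = cost_per_participant,
         rounding = rounding),
    class = "intervention_spec"
  )
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat("Intervention specification\n")
  cat(sprintf("  fall rate ratio : %g (%s effect application)\n",
              x$rate_ratio, x$rounding))
  cat(sprintf("  effect duration : %d cycle(s)\n", x$effect_duration))
  cat(sprintf("  cost            : EUR %g per participant, once at time zero\n",
              x$cost_per_participant))
  invisible(x)
}

#' Apply a fall rate ratio to a transition matrix
#'
#' Multiplies the fall-related transitions A->B, A->C and B->C by
#' `rate_ratio`; the probability mass removed from row A is returned to the
#' stay probability A->A, and the mass removed from row B to the recovery
#' transition B->A, so rows remain stochastic. With `round_digits` set, the
#' multiplied entries are rounded to that many decimals before rebalancing
#' (presentation-style matrices).
#'
#' @param tm A validated `transition_matrix`.
#' @param rate_ratio Rate ratio in (0, 1].
#' @param round_digits `NULL` (exact, default) or an integer number of
#'   decimals for the modified entries.
#' @return A new validated `transition_matrix`, tagged as the intervention arm.
#' @examples
#' apply_rate_ratio(fall_transition_matrix(), 0.76, round_digits = 2)
#' @export
apply_rate_ratio <- function(tm, rate_ratio, round_digits = NULL) {
  validate_transition_matrix(tm)
  if (rate_ratio <= 0 || rate_ratio > 1) {
    stop("the rate ratio must lie in (0, 1]", call. = FALSE)
  }
  m <- unclass(tm)
  targets <- list(c(.A, .B), c(.A, .C), c(.B, .C))
  for (ix in targets) {
    old <- m[ix[1], ix[2]]
    new <- old * rate_ratio
    if (!is.null(round_digits)) new <- round_half_up(new, round_digits)
    m[ix[1], ix[2]] <- new
    m[ix[1], .A] <- m[ix[1], .A] + (old - new)
  }
  if (any(m < 0 | m > 1)) {
    stop("rate-ratio application drove a probability outside [0, 1]", call. = FALSE)
  }
  out <- structure(m, class = "transition_matrix", arm = "intervention",
                   cycles = attr(tm, "cycles"))
  validate_transition_matrix(out)
  out
}
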