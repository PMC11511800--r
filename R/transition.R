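#' Construct an annual transition matrix
#'
#' Wraps a 5x5 matrix of annual transition probabilities (rows = origin state,
#' columns = destination state, order A, B, C, D, E) and validates it against
#' the structural rules of the model: rows are stochastic, death is absorbing,
#' and special housing can only persist or end in death.
#'
#' @param x Numeric 5x5 matrix (or something coercible to one). Row and column
#'   order is A, B, C, D, E.
#' @param arm Which strategy the matrix belongs to, `"no_intervention"` or
#'   `"intervention"`. Informational tag only.
#' @param cycles Cycle applicability tag, e.g. `"all"` or `"1"`. Informational.
#' @return A validated object of class `transition_matrix`.
#' @seealso [validate_transition_matrix()], [adjust_mortality()],
#'   [apply_rate_ratio()]
#' @examples
#' tm <- fall_transition_matrix("no_intervention")
#' tm
#' @export
transition_matrix <- function(x, arm = c("no_intervention", "intervention"),
                              cycles = "all") {
  arm <- match.arg(arm)
  x <- as.matrix(x)
  if (!is.numeric(x) || !identical(dim(x), c(5L, 5L))) {
    stop("a transition matrix must be a numeric 5x5 matrix", call. = FALSE)
  }
  dimnames(x) <- list(state_labels(), state_labels())
  structure(x, class = "transition_matrix", arm = arm, cycles = cycles) |>
    validate_transition_matrix()
}

#' Validate a transition matrix
#'
#' Checks that every entry lies in \[0, 1\], that every row sums to 1 within
#' `tol`, that row E is (0, 0, 0, 0, 1) (death is absorbing), and that row D
#' has zero probability of returning to A, B or C. Structural violations and
#' non-stochastic rows are reported distinctly, naming the offending row (and
#' its sum, for row-sum failures).
#'
#' @param tm A `transition_matrix` or plain 5x5 numeric matrix.
#' @param tol Tolerance on row sums (default `1e-9`).
#' @return The validated matrix, invisibly unchanged, for use in pipes.
#' @export
validate_transition_matrix <- function(tm, tol = 1e-9) {
  m <- unclass(tm)
  if (!is.numeric(m) || !identical(dim(m), c(5L, 5L))) {
    stop("a transition matrix must be a numeric 5x5 matrix", call. = FALSE)
  }
  if (anyNA(m)) stop("transition matrix contains missing values", call. = FALSE)
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "transition probability out of [0, 1]: %s -> %s is %.6g",
      state_labels()[bad[1, 1]], state_labels()[bad[1, 2]], m[bad[1, , drop = FALSE]]
    ), call. = FALSE)
  }
  sums <- rowSums(m)
  off <- which(abs(sums - 1) > tol)
  if (length(off) > 0) {
    stop(sprintf(
      "row %s is not stochastic: sum = %.10g",
      paste(state_labels()[off], collapse = ", "), sums[off[1]]
    ), call. = FALSE)
  }
  if (any(abs(m[.E, ] - c(0, 0, 0, 0, 1)) > tol)) {
    stop("structural violation: row E must be (0, 0, 0, 0, 1); death is absorbing",
         call. = FALSE)
  }
  if (any(m[.D, c(.A, .B, .C)] > tol)) {
    stop("structural violation: row D may only transition to D or E",
         call. = FALSE)
  }
  invisible(tm)
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Annual transition matrix (%s, cycles: %s)\n",
              attr(x, "arm"), attr(x, "cycles")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Age-indexed annual mortality schedule
#'
#' A lookup from integer age (years) to annual probability of death, used to
#' age-adjust the A->E and B->E transitions from the second cycle onwards.
#' Must be anchored so that the value at the cohort start age equals the
#' baseline A->E probability, and must be non-decreasing with age.
#'
#' @param ages Integer vector of ages (years).
#' @param qx Numeric vector of annual death probabilities, same length.
#' @return Object of class `mortality_schedule` (a named numeric vector).
#' @seealso [gompertz_schedule()] for the bundled parametric default.
#' @export
mortality_schedule <- function(ages, qx) {
  ages <- as.integer(ages)
  if (length(ages) != length(qx) || length(ages) == 0) {
    stop("`ages` and `qx` must be non-empty vectors of equal length", call. = FALSE)
  }
  if (any(qx < 0 | qx > 1)) {
    stop("mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  o <- order(ages)
  ages <- ages[o]; qx <- qx[o]
  if (is.unsorted(qx)) {
    stop("mortality must be non-decreasing with age", call. = FALSE)
  }
  structure(stats::setNames(as.numeric(qx), ages), class = "mortality_schedule")
}

#' Look up the annual death probability at an age
#'
#' @param schedule A `mortality_schedule`.
#' @param age Integer age in years (must be tabulated in the schedule).
#' @return Annual probability of death.
#' @export
schedule_at <- function(schedule, age) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  key <- as.character(as.integer(age))
  miss <- !(key %in% names(schedule))
  if (any(miss)) {
    stop(sprintf("age %s not tabulated in the mortality schedule",
                 paste(age[miss], collapse = ", ")), call. = FALSE)
  }
  unname(unclass(schedule)[key])
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat("Annual mortality schedule (age: q)\n")
  print(round(unclass(x), 5))
  invisible(x)
}

#' Age-adjust background mortality in a transition matrix
#'
#' Replaces the A->E and B->E probabilities by the schedule value at `age`,
#' compensating the change from the A->A (row A) and B->A (row B) entries so
#' rows remain stochastic. The death probabilities of rows C and D are
#' event-conditional (post hip fracture, long-term care) and are left
#' untouched. If the compensation would drive the donor entry below zero, the
#' donor is clamped at 0, the remaining non-death entries of the row are
#' rescaled proportionally, and a warning is raised.
#'
#' @param tm A validated `transition_matrix`.
#' @param age Integer age (years) of the cohort during the cycle.
#' @param schedule A `mortality_schedule` covering `age`.
#' @param compensate `"stay"` (default): deduct the mortality increase from
#'   the A->A / B->A entries; `"proportional"`: rescale all non-death entries
#'   of the row so it sums to one.
#' @return A new validated `transition_matrix`.
#' @examples
#' tm <- fall_transition_matrix()
#' sch <- gompertz_schedule()
#' adjust_mortality(tm, age = 80, schedule = sch)
#' @export
adjust_mortality <- function(tm, age, schedule,
                             compensate = c("stay", "proportional")) {
  validate_transition_matrix(tm)
  compensate <- match.arg(compensate)
  q_new <- schedule_at(schedule, age)
  m <- unclass(tm)
  for (row in c(.A, .B)) {
    delta <- q_new - m[row, .E]
    m[row, .E] <- q_new
    if (compensate == "stay") {
      donor <- .A  # A->A for row A, B->A for row B
      if (m[row, donor] - delta < 0) {
        warning(sprintf(
          "mortality adjustment exhausts %s->%s; clamping and rescaling row %s",
          state_labels()[row], state_labels()[donor], state_labels()[row]
        ), call. = FALSE)
        m[row, donor] <- 0
        live <- setdiff(seq_len(5L), .E)
        mass <- sum(m[row, live])
        if (mass > 0) m[row, live] <- m[row, live] * (1 - q_new) / mass
      } else {
        m[row, donor] <- m[row, donor] - delta
      }
    } else {
      live <- setdiff(seq_len(5L), .E)
      mass <- sum(m[row, live])
      if (mass > 0) m[row, live] <- m[row, live] * (1 - q_new) / mass
    }
  }
  out <- structure(m, class = "transition_matrix",
                   arm = attr(tm, "arm"),
                   cycles = attr(tm, "cycles"))
  validate_transition_matrix(out)
  out
}
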