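#' The five-state fall model state space
#'
#' The model tracks a closed cohort of community-dwelling older adults through
#' five health states over annual cycles:
#'
#' * `A` -- at risk for a fall (community-dwelling, no recent consequential fall),
#' * `B` -- minor consequences after a fall (emergency visit, no admission),
#' * `C` -- major consequences after a fall (emergency visit with hospital
#'   admission, e.g. hip fracture),
#' * `D` -- special housing after a fall (long-term residential care),
#' * `E` -- death (absorbing).
#'
#' Structural constraints: `E` is absorbing, and from `D` only `D` or `E` are
#' reachable (recovery from long-term care is treated as negligible).
#'
#' @return Character vector of the five state labels, named by a short
#'   description of each state.
#' @examples
#' fall_states()
#' @export
fall_states <- function() {
  c(
    "at risk for fall"                = "A",
    "minor consequences after a fall" = "B",
    "major consequences after a fall" = "C",
    "special housing after a fall"    = "D",
    "death"                           = "E"
  )
}

# Number of states; fixed by design (dense 5x5 engine, no generic-size support).
n_states <- function() 5L

state_labels <- function() unname(fall_states())

# index helpers used throughout the engine
.A <- 1L; .B <- 2L; .C <- 3L; .D <- 4L; .E <- 5L

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
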