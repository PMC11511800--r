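#' Gompertz-style annual mortality schedule
#'
#' Parametric stand-in for a national life table: the annual probability of
#' death grows exponentially with age,
#' \eqn{q(a) = \min(1, q_0 \exp(b (a - a_0)))}, anchored so that
#' \eqn{q(a_0) = q_0}. The default (`anchor = 0.03` at age 76, slope 0.08 per
#' year) matches the baseline background mortality of a 76-year-old and
#' approximates Swedish old-age mortality over ages 76-88. Fully overridable:
#' any [mortality_schedule()] can be supplied to the model instead.
#'
#' @param anchor Annual death probability at `start_age`, in (0, 1).
#' @param slope Log-linear growth per year of age (>= 0).
#' @param start_age First tabulated age (years).
#' @param horizon Number of one-year steps beyond `start_age` to tabulate.
#' @return A [mortality_schedule()] covering `start_age` to
#'   `start_age + horizon`.
#' @examples
#' gompertz_schedule()
#' @export
gompertz_schedule <- function(anchor = 0.03, slope = 0.08,
                              start_age = 76, horizon = 12) {
  if (anchor <= 0 || anchor >= 1) stop("`anchor` must lie in (0, 1)", call. = FALSE)
  if (slope < 0) stop("`slope` must be non-negative", call. = FALSE)
  ages <- start_age + 0:horizon
  mortality_schedule(ages, pmin(1, anchor * exp(slope * (ages - start_age))))
}

#' Generate a random structurally valid model instance
#'
#' Draws a random five-state model for property testing: row-stochastic
#' transition rows for A, B and C (Dirichlet via normalised gamma draws), a
#' restricted special-housing row (mass only on D and E), an absorbing death
#' row, utilities descending A >= B >= C >= D >= 0 with zero for death, and
#' costs ascending A <= B <= C <= D with zero for A and death. Reproducible:
#' the seed fixes every generated artefact.
#'
#' @param seed Integer seed.
#' @param cohort_size Persons entering the cohort (default 100).
#' @param horizon Number of annual cycles (default 6).
#' @param concentration Dirichlet concentration for the free rows; larger
#'   values give more uniform rows (default 1).
#' @return A list with elements `matrix` (a `transition_matrix`), `payoffs`
#'   (a `state_payoffs`) and `config` (a `model_config`).
#' @examples
#' mod <- generate_random_model(seed = 1)
#' validate_transition_matrix(mod$matrix)
#' @export
generate_random_model <- function(seed, cohort_size = 100, horizon = 6,
                                  concentration = 1) {
  set.seed(seed)
  rdirichlet <- function(k) {
    g <- stats::rgamma(k, shape = concentration, rate = 1)
    # guard against an all-zero draw at tiny concentrations
    if (sum(g) == 0) g <- rep(1, k)
    g / sum(g)
  }
  m <- matrix(0, 5, 5)
  for (r in 1:3) m[r, ] <- rdirichlet(5)
  m[4, 4:5] <- rdirichlet(2)
  m[5, 5] <- 1
  tm <- transition_matrix(m)

  u <- c(sort(stats::runif(4), decreasing = TRUE), 0)
  costs <- c(0, sort(stats::runif(3, 100, 100000)), 0)
  payoffs <- state_payoffs(u, costs)

  cfg <- model_config(cohort_size = cohort_size, horizon = horizon,
                      discount_rate = 0.03)
  list(matrix = tm, payoffs = payoffs, config = cfg)
}

#' Individual-level microsimulation oracle
#'
#' Simulates individual state paths cycle by cycle from the initial state and
#' accrues discounted, half-cycle-corrected QALYs and costs per individual,
#' using its own per-individual trapezoid accrual (the mean of the state
#' payoff at the start and at the end of each cycle) rather than the cohort
#' engine's matrix algebra. Its mean converges to the cohort engine's
#' per-participant value by the law of large numbers, which makes it an
#' independent cross-check of [run_cohort()] plus [accumulate_outcomes()].
#'
#' @param matrices A single `transition_matrix` or a list of one per cycle.
#' @param payoffs A [state_payoffs()].
#' @param config A [model_config()]. The cohort size is ignored; `n_sim`
#'   individuals are simulated.
#' @param n_sim Number of simulated individuals (>= 1).
#' @param seed Integer seed; fixes the simulated paths.
#' @return Object of class `microsim_result`: mean QALYs and cost per
#'   participant, Monte Carlo standard errors, final-state counts, `n_sim`
#'   and the seed.
#' @examples
#' mod <- generate_random_model(seed = 7)
#' microsimulate(mod$matrix, mod$payoffs, mod$config, n_sim = 500, seed = 7)
#' @export
microsimulate <- function(matrices, payoffs, config, n_sim = 1e5, seed = 1) {
  stopifnot(inherits(payoffs, "state_payoffs"), inherits(config, "model_config"))
  if (n_sim < 1) stop("`n_sim` must be at least 1", call. = FALSE)
  n_sim <- as.integer(n_sim)
  if (inherits(matrices, "transition_matrix")) {
    matrices <- rep(list(matrices), config$horizon)
  }
  if (length(matrices) != config$horizon) {
    stop("one transition matrix per cycle is required", call. = FALSE)
  }
  lapply(matrices, validate_transition_matrix)
  set.seed(seed)

  u <- unname(payoffs$utility)
  cost <- unname(payoffs$cost)
  df <- discount_factor(seq_len(config$horizon), config$discount_rate,
                        config$discount_first_year)
  state <- rep(match(config$initial_state, state_labels()), n_sim)
  q_acc <- numeric(n_sim)
  c_acc <- numeric(n_sim)
  occupancy <- matrix(0L, nrow = config$horizon + 1L, ncol = 5L,
                      dimnames = list(cycle = 0:config$horizon,
                                      state = state_labels()))
  occupancy[1L, ] <- tabulate(state, 5L)

  for (t in seq_len(config$horizon)) {
    P <- unclass(matrices[[t]])
    cum <- t(apply(P, 1L, cumsum))
    cum[, 5L] <- 1  # guard the last bin against floating-point undershoot
    r <- stats::runif(n_sim)
    # draw the next state for everyone in one pass, grouped by current state
    nxt <- integer(n_sim)
    for (s in 1:5) {
      idx <- which(state == s)
      if (length(idx)) {
        nxt[idx] <- findInterval(r[idx], cum[s, ], left.open = TRUE) + 1L
      }
    }
    if (config$half_cycle) {
      q_acc <- q_acc + (u[state] + u[nxt]) / 2 * df[t]
      c_acc <- c_acc + (cost[state] + cost[nxt]) / 2 * df[t]
    } else {
      q_acc <- q_acc + u[nxt] * df[t]
      c_acc <- c_acc + cost[nxt] * df[t]
    }
    state <- nxt
    occupancy[t + 1L, ] <- tabulate(state, 5L)
  }

  structure(
    list(mean_qalys = mean(q_acc), mean_cost = mean(c_acc),
         se_qalys = stats::sd(q_acc) / sqrt(n_sim),
         se_cost = stats::sd(c_acc) / sqrt(n_sim),
         occupancy = occupancy,
         n_sim = n_sim, seed = seed),
    class = "microsim_result"
  )
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("Microsimulation (%d individuals, seed %d)\n", x$n_sim, x$seed))
  cat(sprintf("  mean QALYs/participant: %.4f (SE %.4f)\n", x$mean_qalys, x$se_qalys))
  cat(sprintf("  mean cost/participant : EUR %.0f (SE %.0f)\n", x$mean_cost, x$se_cost))
  invisible(x)
}
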