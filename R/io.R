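#' Read a model definition from a YAML configuration file
#'
#' The configuration mirrors the model structure in nested sections:
#' `config` (scalars), `transition_matrix` (one row per origin state, in
#' state order A..E), `payoffs` (`utility` and `cost` per state),
#' `intervention` (`rate_ratio`, `effect_duration`, `rounding`, and either
#' `cost_per_participant` or a `cost_components` list), and
#' `mortality_schedule` (either `type: gompertz` with `anchor`/`slope`, or
#' explicit `ages`/`qx` vectors). The bundled base-case file is at
#' `system.file("extdata", "base_case.yaml", package = "fallcea")`.
#'
#' @param path Path to a YAML file.
#' @return A [fall_model()].
#' @examples
#' cfg <- system.file("extdata", "base_case.yaml", package = "fallcea")
#' m <- read_model_config(cfg)
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(model_config, y$config)

  tmat <- do.call(rbind, y$transition_matrix[state_labels()])
  tm <- transition_matrix(tmat)

  payoffs <- state_payoffs(
    utility = unlist(y$payoffs$utility[state_labels()]),
    cost = unlist(y$payoffs$cost[state_labels()])
  )

  iv_raw <- y$intervention
  cost_pp <- iv_raw$cost_per_participant
  if (is.null(cost_pp) && !is.null(iv_raw$cost_components)) {
    comps <- lapply(iv_raw$cost_components, function(cc) {
      cost_component(cc$label, cc$category, total = cc$total,
                     units = if (is.null(cc$units)) NA_real_ else cc$units)
    })
    cost_pp <- build_cost_ledger(comps, cfg$cohort_size)$total_per_participant
  }
  iv <- intervention_spec(
    rate_ratio = iv_raw$rate_ratio,
    effect_duration = if (is.null(iv_raw$effect_duration)) 1 else iv_raw$effect_duration,
    cost_per_participant = cost_pp,
    rounding = if (is.null(iv_raw$rounding)) "table" else iv_raw$rounding
  )

  sch_raw <- y$mortality_schedule
  schedule <- if (!is.null(sch_raw$type) && sch_raw$type == "gompertz") {
    gompertz_schedule(anchor = sch_raw$anchor, slope = sch_raw$slope,
                      start_age = cfg$start_age, horizon = cfg$horizon)
  } else {
    mortality_schedule(sch_raw$ages, sch_raw$qx)
  }

  fall_model(config = cfg, matrix = tm, payoffs = payoffs,
             intervention = iv, schedule = schedule)
}

#' Write a model definition to a YAML configuration file
#'
#' Serialises a [fall_model()] in the same format [read_model_config()]
#' consumes (the mortality schedule is written as explicit age/probability
#' vectors).
#'
#' @param model A [fall_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "fall_model"))
  m <- unclass(model$matrix)
  y <- list(
    config = unclass(model$config),
    transition_matrix = stats::setNames(
      lapply(seq_len(5), function(i) unname(m[i, ])), state_labels()),
    payoffs = list(utility = as.list(model$payoffs$utility),
                   cost = as.list(model$payoffs$cost)),
    intervention = list(
      rate_ratio = model$intervention$rate_ratio,
      effect_duration = model$intervention$effect_duration,
      rounding = model$intervention$rounding,
      cost_per_participant = model$intervention$cost_per_participant
    ),
    mortality_schedule = list(
      ages = as.integer(names(model$schedule)),
      qx = unname(unclass(model$schedule))
    )
  )
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
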