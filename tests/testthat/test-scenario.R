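test_that("the base case is dominant: health gained, money saved", {
  res <- run_scenario(fall_model())
  expect_identical(res$ce$verdict, "dominant")
  expect_gt(res$ce$delta_qalys_per_participant, 0)
  expect_lt(res$ce$delta_cost_per_participant, 0)
})

test_that("a null intervention (ratio 1, zero cost) leaves both arms identical", {
  m <- fall_model(intervention = intervention_spec(rate_ratio = 1,
                                                   cost_per_participant = 0))
  res <- run_scenario(m)
  expect_equal(res$ce$delta_qalys_total, 0)
  expect_equal(res$ce$delta_cost_total, 0)
  expect_identical(res$ce$verdict, "no difference")
})

test_that("raising recruitment costs changes only the cost increment, by the EUR 26 delta", {
  m <- fall_model()
  base <- run_scenario(m)
  s2 <- run_scenario(m, scenario_spec("scenario 2", recruitment_multiplier = 1.5))
  expect_equal(s2$ce$delta_qalys_per_participant,
               base$ce$delta_qalys_per_participant)
  expect_equal(s2$ce$delta_cost_per_participant -
                 base$ce$delta_cost_per_participant, 26)
})

test_that("first-year falls prevented counts whole falls", {
  m <- fall_model()
  # 173 * ((0.07 + 0.13) - (0.05 + 0.10)) = 8.65, truncated to 8
  expect_equal(falls_prevented_first_cycle(m, fractional = TRUE), 8.65)
  expect_identical(falls_prevented_first_cycle(m), 8)

  # identical arms prevent nothing
  null_m <- fall_model(intervention = intervention_spec(rate_ratio = 1,
                                                        cost_per_participant = 0))
  expect_identical(falls_prevented_first_cycle(null_m), 0)

  # a halved fall rate applied unrounded: 173 * 0.10 = 17.3, truncated to 17
  strong <- fall_model(intervention = intervention_spec(
    rate_ratio = 0.5, cost_per_participant = 0, rounding = "exact"))
  expect_identical(falls_prevented_first_cycle(strong), 17)
})

test_that("the full report has one row per scenario with the expected verdicts", {
  m <- fall_model()
  report <- run_all(m)
  expect_equal(nrow(report), 4)
  expect_equal(report$scenario,
               c("base case", "scenario 1", "scenario 2", "scenario 3"))
  expect_equal(report$verdict, c("dominant", "dominant", "dominant", "ICER"))
  expect_true(is.na(report$icer[1]) && report$icer[4] > 0)
  # totals and per-participant columns are consistent
  expect_equal(report$inc_qalys_total, report$inc_qalys_pp * 173)

  base_only <- run_all(m, scenarios = list())
  expect_equal(nrow(base_only), 1)
})

test_that("rerunning the same configuration writes byte-identical CSV output", {
  m <- fall_model()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(run_all(m), p1)
  write_summary_csv(run_all(m), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("incremental QALYs fall and incremental costs rise as the rate ratio approaches 1", {
  m <- fall_model()
  ratios <- c(0.76, 0.84, 0.90, 0.98)
  runs <- lapply(ratios, function(r)
    run_scenario(m, scenario_spec(paste(r), rate_ratio = r))$ce)
  dq <- vapply(runs, `[[`, numeric(1), "delta_qalys_per_participant")
  dc <- vapply(runs, `[[`, numeric(1), "delta_cost_per_participant")
  expect_true(all(diff(dq) < 0))
  expect_true(all(diff(dc) > 0))
})

test_that("incremental QALYs scale near-linearly with the fall-rate reduction", {
  m <- fall_model()
  # use the unrounded 0.76 run as the reference so the comparison is like-for-like
  ref <- run_scenario(m, scenario_spec("ref", rate_ratio = 0.76))$ce
  for (r in c(0.84, 0.98)) {
    ce <- run_scenario(m, scenario_spec(paste(r), rate_ratio = r))$ce
    ratio <- ce$delta_qalys_per_participant / ref$delta_qalys_per_participant
    expect_equal(ratio, (1 - r) / 0.24, tolerance = 0.1)
  }
})

test_that("schedule perturbations move arm totals far more than the incrementals", {
  m <- fall_model()
  base <- run_scenario(m)
  for (f in c(0.8, 1.2)) {
    sch <- mortality_schedule(as.integer(names(m$schedule)),
                              pmin(1, unclass(m$schedule) * f))
    pert <- run_scenario(fall_model(schedule = sch))
    shift_abs <- abs(pert$no_intervention$qalys_per_participant -
                       base$no_intervention$qalys_per_participant)
    shift_inc <- abs(pert$ce$delta_qalys_per_participant -
                       base$ce$delta_qalys_per_participant)
    expect_lt(shift_inc, 0.25 * shift_abs)
    shift_abs_c <- abs(pert$no_intervention$cost_per_participant -
                         base$no_intervention$cost_per_participant)
    shift_inc_c <- abs(pert$ce$delta_cost_per_participant -
                         base$ce$delta_cost_per_participant)
    expect_lt(shift_inc_c, 0.25 * shift_abs_c)
  }
})

test_that("the bundled YAML base case round-trips and matches the in-code defaults", {
  path <- system.file("extdata", "base_case.yaml", package = "fallcea")
  m <- read_model_config(path)
  expect_equal(run_all(m), run_all(fall_model()))

  out <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, out)
  m2 <- read_model_config(out)
  expect_equal(run_all(m2), run_all(m), tolerance = 1e-9)
})
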