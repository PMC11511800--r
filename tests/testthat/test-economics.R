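test_that("payoff validation enforces the state conventions", {
  expect_silent(fall_state_payoffs())
  expect_error(state_payoffs(c(0.9, 0.7, 0.6, 0.4, 0.1), c(0, 1, 2, 3, 0)),
               "death state")
  expect_error(state_payoffs(c(0.9, 0.7, 0.6, 0.4, 0), c(5, 1, 2, 3, 0)),
               "at-risk state")
  expect_error(state_payoffs(c(1.2, 0.7, 0.6, 0.4, 0), c(0, 1, 2, 3, 0)),
               "\\[0, 1\\]")
})

test_that("discounting leaves year one untouched and compounds afterwards", {
  expect_identical(discount_factor(1, 0.03), 1)
  expect_equal(discount_factor(2, 0.03), 0.970873786407767)
  expect_equal(discount_factor(12, 0.03), 1.03^-11)
  expect_equal(discount_factor(12, 0.03), 0.722421276598762)
  expect_error(discount_factor(0, 0.03), ">= 1")
  # alternative convention: discounting from year one
  expect_equal(discount_factor(1, 0.03, first_year_discounted = TRUE), 1 / 1.03)
})

test_that("accumulation reproduces closed forms for degenerate cohorts", {
  payoffs <- fall_state_payoffs()

  # one person fixed in A, no discounting: 12 * 0.86 QALYs, zero cost
  cfg <- model_config(cohort_size = 1, discount_rate = 0)
  still <- accumulate_outcomes(run_cohort(identity_tm(), cfg), payoffs, cfg)
  expect_equal(still$total_qalys, 10.32)
  expect_equal(still$total_cost, 0)

  # one person starting dead accrues nothing
  cfg_e <- model_config(cohort_size = 1, discount_rate = 0, initial_state = "E")
  dead <- accumulate_outcomes(run_cohort(identity_tm(), cfg_e), payoffs, cfg_e)
  expect_equal(dead$total_qalys, 0)
  expect_equal(dead$total_cost, 0)

  # death within the first cycle credits half a year in A: 0.5 * 0.86
  cfg1 <- model_config(cohort_size = 1, discount_rate = 0, horizon = 1)
  gone <- accumulate_outcomes(run_cohort(all_to_death_tm(), cfg1), payoffs, cfg1)
  expect_equal(gone$total_qalys, 0.43)
})

test_that("per-participant values scale exactly and discounting is monotone", {
  mod <- generate_random_model(seed = 42)
  trace <- run_cohort(mod$matrix, mod$config)
  res <- accumulate_outcomes(trace, mod$payoffs, mod$config)
  expect_equal(res$qalys_per_participant * mod$config$cohort_size,
               res$total_qalys)
  expect_equal(res$cost_per_participant * mod$config$cohort_size,
               res$total_cost)

  totals <- vapply(c(0, 0.03, 0.1, 0.5), function(r) {
    cfg <- mod$config
    cfg$discount_rate <- r
    accumulate_outcomes(trace, mod$payoffs, cfg)$total_qalys
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("half-cycle totals lie between start-of-cycle and end-of-cycle totals", {
  for (seed in 1:5) {
    mod <- generate_random_model(seed)
    trace <- run_cohort(mod$matrix, mod$config)
    acc <- function(t) accumulate_outcomes(trace, mod$payoffs, mod$config,
                                           timing = t)
    lo_hi <- range(acc("start")$total_qalys, acc("end")$total_qalys)
    expect_gte(acc("half")$total_qalys, lo_hi[1])
    expect_lte(acc("half")$total_qalys, lo_hi[2])
    lo_hi_c <- range(acc("start")$total_cost, acc("end")$total_cost)
    expect_gte(acc("half")$total_cost, lo_hi_c[1])
    expect_lte(acc("half")$total_cost, lo_hi_c[2])
  }
})

test_that("arm comparison classifies dominance, dominated, ICER and ties", {
  n <- 173
  ref <- toy_arm_result(4.548 * n, 103535 * n)   # more QALYs, cheaper
  cmp <- toy_arm_result(4.490 * n, 104370 * n)
  dom <- compare_arms(ref, cmp, intervention_cost_per_participant = 0)
  expect_identical(dom$verdict, "dominant")
  expect_equal(dom$delta_qalys_per_participant, 0.058)
  expect_equal(dom$delta_cost_per_participant, -835)
  expect_true(is.na(dom$icer))

  # totals 6 375 EUR / 0.837 QALYs: ICER rounds to 7 616 EUR per QALY
  ref3 <- toy_arm_result(cmp$total_qalys + 0.837, cmp$total_cost + 6375)
  icer <- compare_arms(ref3, cmp)
  expect_identical(icer$verdict, "ICER")
  expect_equal(round(icer$icer), 7616)

  # identical arms at zero intervention cost: no verdict to give
  tie <- compare_arms(cmp, cmp)
  expect_identical(tie$verdict, "no difference")
  expect_equal(tie$delta_qalys_total, 0)

  # tied effects with a cost difference: ICER undefined, signalled
  costly <- toy_arm_result(cmp$total_qalys, cmp$total_cost + 100)
  only_cost <- compare_arms(costly, cmp)
  expect_identical(only_cost$verdict, "cost difference only")
  expect_true(is.na(only_cost$icer))

  # the acquisition cost is charged undiscounted to the reference arm
  flipped <- compare_arms(ref, cmp, intervention_cost_per_participant = 2000)
  expect_equal(flipped$delta_cost_per_participant, -835 + 2000)
  expect_identical(flipped$verdict, "ICER")
})

test_that("swapping the arms negates the increments and swaps the verdict", {
  for (seed in 1:5) {
    mod <- generate_random_model(seed)
    a <- toy_arm_result(stats::runif(1, 1, 10) * 100, stats::runif(1, 1e4, 1e6),
                        n = mod$config$cohort_size)
    b <- toy_arm_result(stats::runif(1, 1, 10) * 100, stats::runif(1, 1e4, 1e6),
                        n = mod$config$cohort_size)
    ab <- compare_arms(a, b)
    ba <- compare_arms(b, a)
    expect_equal(ab$delta_qalys_total, -ba$delta_qalys_total)
    expect_equal(ab$delta_cost_total, -ba$delta_cost_total)
    if (ab$verdict == "dominant") expect_identical(ba$verdict, "dominated")
    if (ab$verdict == "dominated") expect_identical(ba$verdict, "dominant")
    if (ab$verdict == "ICER") expect_equal(ab$icer, ba$icer)
  }
})
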