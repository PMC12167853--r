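test_that("builtin catalogue holds the seven published scenarios", {
  sc <- builtin_scenarios()
  expect_length(sc, 7)
  expect_setequal(
    vapply(sc, `[[`, character(1), "name"),
    c("Remove Dead Ash Only (Control)", "Remove Dead Ash then Replant",
      "Preemptive Removal then Replant",
      "Replant, Inject, then Preemptive Removal",
      "Inject, Preemptive Removal, and Replant", "Injection in Perpetuity",
      "Injection in Perpetuity with Replanting"))
  for (s in sc) expect_s3_class(s, "scenario_spec")
})

test_that("spec validation lists offending fields", {
  expect_error(scenario_spec("x", inject = "perpetuity",
                             preemptive_start = 3),
               "perpetual injection excludes preemptive removal")
  expect_error(scenario_spec("x", replant_lag = 2), "replant_lag")
  expect_error(scenario_spec("x", preemptive_start = 0, preemptive_rate = -5),
               "rates must be >= 0.*preemptive_start", perl = TRUE)
  expect_error(scenario_spec("x", inject = "window", inject_start = 5,
                             inject_end = 2), "injection window")
})

test_that("published ash trajectories are reproduced year by year", {
  runs <- default_runs()
  yrs <- c(1, 5, 10, 15, 20)
  expect_identical(at_years(runs$control, yrs, "ash_count"),
                   c(1192L, 490L, 162L, 55L, 20L))
  expect_identical(at_years(runs$control, 1:5, "ash_count"),
                   c(1192L, 954L, 764L, 612L, 490L))
  expect_identical(at_years(runs$perpetuity, yrs, "ash_count"),
                   c(1449L, 1295L, 1125L, 979L, 852L))
  expect_identical(at_years(runs$perpetuity_replant, yrs, "ash_count"),
                   c(1449L, 1295L, 1125L, 979L, 852L))
  expect_identical(at_years(runs$preemptive_replant, yrs, "ash_count"),
                   c(1090L, 0L, 0L, 0L, 0L))
  expect_identical(at_years(runs$replant_inject_remove, yrs, "ash_count"),
                   c(1449L, 1295L, 0L, 0L, 0L))
  expect_identical(at_years(runs$inject_remove_replant, yrs, "ash_count"),
                   c(1449L, 1295L, 0L, 0L, 0L))
})

test_that("published planted-cohort counts are reproduced", {
  runs <- default_runs()
  yrs <- c(1, 5, 10, 15, 20)
  expect_identical(at_years(runs$control, yrs, "nonash_count"),
                   rep(0L, 5))
  expect_identical(at_years(runs$remove_replant, yrs, "nonash_count"),
                   c(0L, 697L, 953L, 1033L, 1056L))
  expect_identical(at_years(runs$preemptive_replant, yrs, "nonash_count"),
                   c(366L, 1130L, 1059L, 1024L, 989L))
  expect_identical(at_years(runs$inject_remove_replant, yrs, "nonash_count"),
                   c(38L, 158L, 1122L, 1069L, 1039L))
  expect_identical(at_years(runs$perpetuity_replant, yrs, "nonash_count"),
                   c(38L, 158L, 292L, 403L, 504L))
})

test_that("each year's tallies reconcile with cohort deltas", {
  for (run in default_runs()) {
    r <- run$records
    for (i in 2:nrow(r)) {
      expect_identical(r$ash_count[i],
                       r$ash_count[i - 1] - r$ash_deaths[i] -
                         r$ash_removals[i])
      expect_identical(r$nonash_count[i],
                       r$nonash_count[i - 1] + r$plantings[i] -
                         r$nonash_deaths[i])
    }
  }
})

test_that("ash counts are monotone non-increasing in every scenario", {
  for (run in default_runs())
    expect_true(all(diff(run$records$ash_count) <= 0))
})

test_that("preemptive removal empties the ash population on schedule", {
  spec <- builtin_scenarios()$preemptive_replant
  p <- demography_params()
  run <- run_scenario(spec, p)
  bound <- ceiling(p$initial_ash_count / spec$preemptive_rate) +
    spec$preemptive_start - 1
  expect_identical(run$records$ash_count[run$records$year == bound], 0L)
})

test_that("match-mode plantings never exceed the lagged ash losses", {
  for (run in default_runs()) {
    if (run$spec$replant_mode != "match") next
    r <- run$records
    losses <- r$ash_deaths + r$ash_removals
    lag <- run$spec$replant_lag
    for (i in 2:nrow(r)) {
      basis <- if (lag == 0) losses[i] else losses[i - 1]
      expect_lte(r$plantings[i], basis)
    }
  }
})

test_that("total plantings respect the proactive cap", {
  run <- default_runs()$replant_inject_remove
  expect_lte(sum(run$records$plantings), run$spec$replant_cap)
  expect_equal(sum(run$records$plantings), run$spec$replant_cap)
})

test_that("a dead world is constant", {
  p <- demography_params(natural_mortality = 0, injected_ash_mortality = 0,
                         noninjected_ash_mortality = 0, ash_growth = 0,
                         nonash_growth = 0,
                         warranty_survival = rep(1, 4))
  run <- run_scenario(scenario_spec("static", inject = "never"), p)
  expect_true(all(run$records$ash_count == p$initial_ash_count))
  expect_true(all(run$records$ash_basal == run$records$ash_basal[1]))
})

test_that("runs are deterministic bit-for-bit", {
  spec <- builtin_scenarios()$perpetuity_replant
  expect_identical(run_scenario(spec)$records, run_scenario(spec)$records)
})

test_that("stepping past the horizon is an error", {
  spec <- scenario_spec("short", horizon = 1L)
  p <- demography_params()
  out <- step_year(eabsim:::initial_state(p), spec, p)
  expect_error(step_year(out$state, spec, p), "horizon")
})

test_that("perpetual injection equals the closed-form recurrence oracle", {
  run <- default_runs()$perpetuity
  expect_identical(run$records$ash_count[-1],
                   oracle_ceiling_series(1490, 0.028, 20))
})
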