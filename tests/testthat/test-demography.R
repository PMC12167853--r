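test_that("annual mortality uses the ceiling convention", {
  expect_identical(apply_annual_mortality(1490, 0.20), 1192L)
  expect_identical(apply_annual_mortality(1490, 0.028), 1449L)
  expect_identical(apply_annual_mortality(1000, 0), 1000L)

  # five successive years at 20% reach the published Year-5 count
  n <- 1490L
  for (i in 1:5) n <- apply_annual_mortality(n, 0.20)
  expect_identical(n, 490L)

  expect_error(apply_annual_mortality(-1, 0.1), "non-negative")
  expect_error(apply_annual_mortality(10, 1.2), "\\[0, 1\\]")
  expect_error(apply_annual_mortality(10, -0.1), "\\[0, 1\\]")
})

test_that("mortality is monotone and matches the recurrence oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n0 <- sample(0:5000, 1)
    r1 <- runif(1)
    r2 <- runif(1, r1, 1)
    s1 <- apply_annual_mortality(n0, r1)
    s2 <- apply_annual_mortality(n0, r2)
    expect_lte(s2, s1)       # monotone non-increasing in rate
    expect_lte(s1, n0)       # never increases the count
    # iterated application equals the independent recurrence
    yrs <- sample(1:30, 1)
    n <- n0
    for (t in seq_len(yrs)) n <- apply_annual_mortality(n, r1)
    expect_identical(n, oracle_ceiling_series(n0, r1, yrs)[yrs])
  }
})

test_that("deterministic trajectory tracks a Bernoulli micro-simulation", {
  # per-tree survival draws should have a mean within 3 standard errors of
  # the deterministic count (ceiling adds at most +1 per year)
  set.seed(7)
  n0 <- 1490
  rate <- 0.20
  reps <- 400
  sims <- rbinom(reps, n0, 1 - rate)
  se <- sd(sims) / sqrt(reps)
  det <- apply_annual_mortality(n0, rate)
  expect_lt(abs(mean(sims) - det), 3 * se + 1)
})

test_that("post-planting survival follows the warranty schedule", {
  p <- demography_params()
  expect_equal(survival_rate(1, p), 0.915)
  expect_equal(survival_rate(2, p), 0.883)
  expect_equal(survival_rate(3, p), 0.958)
  expect_equal(survival_rate(4, p), 0.939)
  expect_equal(survival_rate(7, p), 0.9915)
  expect_equal(survival_rate(30, p), 1 - p$natural_mortality)
  expect_error(survival_rate(0, p), ">= 1")
})

test_that("growth is additive and validated", {
  expect_equal(grow_dbh(27.181, 0.3), 27.481)
  expect_equal(grow_dbh(6.0, 0.47), 6.47)
  expect_equal(grow_dbh(10, 0), 10)
  expect_error(grow_dbh(-1, 0.3), ">= 0")
})

test_that("advance_cohort reproduces published cohort transitions", {
  p <- demography_params()
  # newly planted non-ash cohort in its planting year
  planted <- tree_cohort(41, p$planting_dbh, "nonash", planting_year = 1L)
  expect_identical(advance_cohort(planted, 1L, p)$count, 38L)
  planted400 <- tree_cohort(400, p$planting_dbh, "nonash", planting_year = 1L)
  expect_identical(advance_cohort(planted400, 1L, p)$count, 366L)

  # injected ash year over year, chained to the published Year-5 count
  ash <- tree_cohort(1449, 27.481, "ash", injected = TRUE)
  expect_identical(advance_cohort(ash, 2L, p)$count, 1409L)
  for (y in 2:5) ash <- advance_cohort(ash, y, p)
  expect_identical(ash$count, 1295L)

  # identity at zero mortality and zero growth
  p0 <- demography_params(ash_growth = 0, noninjected_ash_mortality = 0)
  c0 <- tree_cohort(123, 15, "ash")
  expect_identical(advance_cohort(c0, 3L, p0)[, c("count", "dbh")],
                   c0[, c("count", "dbh")])

  # mortality override wins over the derived rate
  expect_identical(advance_cohort(tree_cohort(100, 10, "ash"), 1L, p,
                                  mortality_override = 0)$count, 100L)
})

test_that("ash DBH grows linearly with no compounding drift", {
  p <- demography_params()
  co <- tree_cohort(p$initial_ash_count, p$initial_ash_dbh, "ash",
                    injected = TRUE)
  for (y in 1:20) co <- advance_cohort(co, y, p)
  expect_equal(co$dbh, p$initial_ash_dbh + 20 * p$ash_growth)
})

test_that("initial DBH calibration inverts the basal-area formula", {
  # independent oracle: numerical root of the forward formula
  oracle <- function(basal, count, growth) {
    f <- function(d0) pi * ((d0 + growth) / 2)^2 * count / 1000 - basal
    uniroot(f, c(0.001, 500), tol = 1e-10)$root
  }
  d0 <- calibrate_initial_dbh(707.0, 1192, 0.3)
  expect_equal(d0, oracle(707.0, 1192, 0.3), tolerance = 1e-8)
  expect_equal(d0, 27.181, tolerance = 0.01)

  # round-trip of a constructed input
  basal <- pi * (10.3 / 2)^2 * 100 / 1000
  expect_equal(calibrate_initial_dbh(basal, 100, 0.3), 10.0,
               tolerance = 1e-10)

  # forward check at Year 20: per-tree trunk area at the calibrated DBH
  d20 <- d0 + 20 * 0.3
  expect_equal(pi * (d20 / 2)^2, 864.9, tolerance = 0.1)

  expect_error(calibrate_initial_dbh(-1, 10, 0.3), "> 0")
})

test_that("parameter and cohort validation rejects bad domains", {
  expect_error(demography_params(natural_mortality = 1.5), "\\[0, 1\\]")
  expect_error(demography_params(warranty_survival = c(0.9, 0.9)),
               "warranty_survival")
  expect_error(demography_params(ash_growth = -1), ">= 0")
  expect_error(tree_cohort(5, 10, "nonash", injected = TRUE), "ash")
  expect_error(tree_cohort(-1, 10, "ash"), "non-negative")
})
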