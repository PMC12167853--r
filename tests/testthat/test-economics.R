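test_that("bracket lookup is upper-inclusive and matches the price table", {
  rb <- default_brackets("removal")
  pb <- default_brackets("pruning")
  expect_equal(bracket_cost(27.5, rb), 305)
  expect_equal(bracket_cost(125, rb), 5700)
  expect_equal(bracket_cost(70, pb), 460)
  expect_equal(bracket_cost(20, rb), 105)     # boundary: closed first bracket
  expect_equal(bracket_cost(20.0001, rb), 305)
  expect_equal(bracket_cost(0, rb), 105)
  expect_error(bracket_cost(5, data.frame()), "empty")
  expect_error(bracket_cost(-1, rb), ">= 0")
})

test_that("bracket lookup agrees with a linear-scan oracle", {
  set.seed(11)
  rb <- default_brackets("removal")
  dbh <- runif(10000, 0, 200)
  expect_equal(bracket_cost(dbh, rb), oracle_bracket_scan(dbh, rb))
  # non-decreasing in dbh for the default schedule
  d <- sort(dbh)
  expect_true(all(diff(bracket_cost(d, rb)) >= 0))
})

test_that("injection cost is a direct product", {
  expect_equal(injection_cost(30, 3.325), 99.75)
  expect_equal(injection_cost(0, 3.325), 0)
  expect_equal(injection_cost(27.481, 3.325), 27.481 * 3.325)
})

test_that("planting charges honour the contractor warranty", {
  expect_equal(planting_charge(1, 849.91), 0)
  expect_equal(planting_charge(2, 849.91), 0)
  expect_equal(planting_charge(3, 849.91), 849.91)
  expect_equal(planting_charge(NA, 849.91), 849.91)  # scheduled planting
})

test_that("CTLA trunk formula evaluates as printed", {
  ones <- rating_set(1, 1, 1)
  expect_equal(ctla_value(20, 4.5, ones), (20 / 2)^2 * pi * 4.5)
  expect_equal(ctla_value(20, 4.5, ones), 1413.72, tolerance = 1e-5)
  expect_equal(ctla_value(35, 4.5, rating_set(0.3, 0, 0.9)), 0)
  ash <- rating_set(0.50, 0.75, 0.10)
  expect_equal(ctla_value(27.481, 4.5, ash),
               (27.481 / 2)^2 * pi * 4.5 * 0.50 * 0.75 * 0.10)

  # strictly increasing in dbh; homogeneous of degree 1 in NT and ratings
  d <- seq(1, 100, by = 0.5)
  expect_true(all(diff(ctla_value(d, 4.5, ash)) > 0))
  expect_equal(ctla_value(30, 9, ash), 2 * ctla_value(30, 4.5, ash))
  expect_equal(ctla_value(30, 4.5, rating_set(1, 0.75, 0.10)),
               2 * ctla_value(30, 4.5, ash))
})

test_that("present value compounds inflation against discounting", {
  e <- econ_params()
  expect_equal(present_value(100, 0, e), 100)
  expect_equal(present_value(1000, 1, e), 991.93, tolerance = 1e-4)
  eq <- econ_params(inflation = 0.03, discount = 0.03)
  expect_equal(present_value(777, 13, eq), 777)
  expect_error(present_value(1, -1, e), ">= 0")

  # multiplicativity across years
  f <- function(t) present_value(1, t, e)
  for (t1 in c(0, 3, 7)) for (t2 in c(1, 5))
    expect_equal(f(t1 + t2), f(t1) * f(t2))

  # discount 0 yields the inflated future value
  e0 <- econ_params(discount = 0)
  expect_equal(present_value(100, 10, e0), 100 * 1.02^10)
})

test_that("annual event costing matches hand computation", {
  e <- econ_params()
  empty <- data.frame(type = character(0), dbh = numeric(0), n = numeric(0))
  z <- annual_cost(empty, 1, e)
  expect_equal(z$total, 0)
  expect_equal(z$total_pv, 0)

  ev <- data.frame(type = c("removal", "injection", "replacement_warranty",
                            "replacement_postwarranty", "planting"),
                   dbh = c(27.48, 27.48, 7, 9, 6.47),
                   n = c(298, 1449 / 2, 5, 3, 10))
  out <- annual_cost(ev, 1, e)
  expect_equal(out$removal, 298 * 305)
  expect_equal(out$injection, (1449 / 2) * 3.325 * 27.48)
  expect_equal(out$planting, (3 + 10) * 849.91)  # warranty deaths are free
  expect_equal(out$total,
               out$removal + out$injection + out$planting + out$pruning)
  expect_equal(out$total_pv, present_value(out$total, 1, e))
  expect_error(annual_cost(data.frame(type = "bogus", dbh = 1, n = 1), 1, e),
               "unknown event type")
})

test_that("cumulative discounted cost is non-decreasing, minimised by control", {
  runs <- default_runs()
  for (run in runs)
    expect_true(all(diff(run$records$cumulative_cost_pv) >= -1e-9))
  final <- vapply(runs, function(r)
    r$records$cumulative_cost_pv[nrow(r$records)], numeric(1))
  expect_equal(names(which.min(final)), "control")
})

test_that("cost schedule validation rejects malformed brackets", {
  expect_error(cost_schedule(removal_brackets =
                               data.frame(dbh_upper = c(40, 20),
                                          cost = c(1, 2))),
               "strictly increasing")
  expect_error(cost_schedule(removal_brackets =
                               data.frame(dbh_upper = c(20, 40),
                                          cost = c(1, 2))),
               "open-ended")
  expect_error(rating_set(1.2, 0.5, 0.5), "\\[0, 1\\]")
})
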