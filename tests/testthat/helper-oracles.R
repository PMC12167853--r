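# Independent oracles, deliberately written without reference to package
# internals: plain recurrences and closed forms used to freeze expected
# values.

# per-year ceiling mortality recurrence
oracle_ceiling_series <- function(n0, rate, years) {
  out <- integer(years)
  n <- n0
  for (t in seq_len(years)) {
    n <- as.integer(ceiling(n * (1 - rate)))
    out[t] <- n
  }
  out
}

# age-based survival chain for a planted cohort: survival applies in the
# planting year (age 1), warranty schedule years 1-4, background after
oracle_planted_chain <- function(n0, plant_year, upto,
                                 sched = c(0.915, 0.883, 0.958, 0.939),
                                 background = 1 - 0.0085) {
  n <- n0
  for (y in plant_year:upto) {
    age <- y - plant_year + 1
    s <- if (age <= 4) sched[age] else background
    n <- ceiling(n * s)
  }
  n
}

# linear-scan bracket lookup (upper-inclusive)
oracle_bracket_scan <- function(dbh, brackets) {
  vapply(dbh, function(d) {
    for (i in seq_len(nrow(brackets)))
      if (d <= brackets$dbh_upper[i]) return(brackets$cost[i])
    stop("no bracket")
  }, numeric(1))
}

# printed basal units for a uniform cohort
oracle_basal <- function(count, dbh) count * pi * (dbh / 2)^2 / 1000

default_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_builtin_scenarios()
    cache
  }
})

at_years <- function(run, years, col) {
  run$records[[col]][match(years, run$records$year)]
}
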