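#' Declarative management scenario
#'
#' A scenario is a rule-set over the 20-year horizon: whether and when ash
#' are injected, whether live ash are removed preemptively on a schedule,
#' whether dead trees are removed, and how replacement non-ash trees are
#' planted. The seven published management options are all expressible in
#' this vocabulary (see [builtin_scenarios()]).
#'
#' @param name Scenario label used in outputs.
#' @param inject One of `"never"`, `"window"`, `"perpetuity"`.
#' @param inject_start,inject_end Injection window (inclusive), used when
#'   `inject = "window"`.
#' @param preemptive_start First year of scheduled live-ash removal, or `NA`
#'   for none. During preemptive-removal years EAB mortality is suppressed:
#'   dying trees are assumed to be among those removed.
#' @param preemptive_rate Live ash removed per year, trees/yr.
#' @param remove_dead Remove (and stump) trees in the year they die.
#' @param replant_mode `"none"`, `"match"` (plant one non-ash per ash lost,
#'   same site), or `"proactive"` (plant at a fixed rate at alternative
#'   sites).
#' @param replant_rate Trees planted per year in proactive mode.
#' @param replant_start First planting year.
#' @param replant_lag 0 (same year) or 1 (following year), match mode only.
#' @param replant_cap Lifetime cap on trees planted, or `NA` for none.
#' @param horizon Simulation length in years.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name,
                          inject = c("never", "window", "perpetuity"),
                          inject_start = 1L, inject_end = 5L,
                          preemptive_start = NA_integer_,
                          preemptive_rate = 400L,
                          remove_dead = TRUE,
                          replant_mode = c("none", "match", "proactive"),
                          replant_rate = 400L,
                          replant_start = 1L,
                          replant_lag = 0L,
                          replant_cap = NA_integer_,
                          horizon = 20L) {
  spec <- list(name = name, inject = match.arg(inject),
               inject_start = as.integer(inject_start),
               inject_end = as.integer(inject_end),
               preemptive_start = as.integer(preemptive_start),
               preemptive_rate = as.numeric(preemptive_rate),
               remove_dead = isTRUE(remove_dead),
               replant_mode = match.arg(replant_mode),
               replant_rate = as.numeric(replant_rate),
               replant_start = as.integer(replant_start),
               replant_lag = as.integer(replant_lag),
               replant_cap = as.numeric(replant_cap),
               horizon = as.integer(horizon))
  class(spec) <- "scenario_spec"
  validate_scenario_spec(spec)
  spec
}

validate_scenario_spec <- function(spec) {
  bad <- character(0)
  if (spec$horizon < 1) bad <- c(bad, "horizon must be >= 1")
  if (spec$preemptive_rate < 0 || spec$replant_rate < 0)
    bad <- c(bad, "rates must be >= 0")
  if (!spec$replant_lag %in% c(0L, 1L))
    bad <- c(bad, "replant_lag must be 0 or 1")
  if (spec$inject == "window" &&
      (spec$inject_start < 1 || spec$inject_end < spec$inject_start))
    bad <- c(bad, "injection window must satisfy 1 <= start <= end")
  if (spec$inject == "perpetuity" && !is.na(spec$preemptive_start))
    bad <- c(bad, "perpetual injection excludes preemptive removal")
  if (!is.na(spec$preemptive_start) && spec$preemptive_start < 1)
    bad <- c(bad, "preemptive_start must be >= 1")
  if (spec$replant_start < 1) bad <- c(bad, "replant_start must be >= 1")
  if (!is.na(spec$replant_cap) && spec$replant_cap < 0)
    bad <- c(bad, "replant_cap must be >= 0")
  if (length(bad))
    stop("invalid scenario spec: ", paste(bad, collapse = "; "),
         call. = FALSE)
  invisible(spec)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s\n", x$name))
  inj <- switch(x$inject, never = "never",
                window = sprintf("years %d-%d", x$inject_start, x$inject_end),
                perpetuity = "in perpetuity")
  cat(sprintf("  inject: %s | preemptive removal: %s | remove dead: %s\n",
              inj,
              if (is.na(x$preemptive_start)) "off"
              else sprintf("%g/yr from year %d", x$preemptive_rate,
                           x$preemptive_start),
              x$remove_dead))
  cat(sprintf("  replant: %s%s | horizon: %d yr\n", x$replant_mode,
              if (x$replant_mode == "none") ""
              else sprintf(" (rate %g, start %d, lag %d, cap %s)",
                           x$replant_rate, x$replant_start, x$replant_lag,
                           if (is.na(x$replant_cap)) "none"
                           else format(x$replant_cap)),
              x$horizon))
  invisible(x)
}

#' The seven published management scenarios
#'
#' Returns the scenario specifications that reproduce the published 20-year
#' trajectories, keyed by short slug. Names match the published table
#' labels. Notable conventions: the inject-then-remove scenarios start
#' removals in Year 6 (the year after the fifth injection year); replanting
#' lags one year in "Remove Dead Ash then Replant" but is same-year
#' elsewhere; the proactive-planting scenario caps total plantings at the
#' initial ash count (1:1 replacement).
#'
#' @param params A [demography_params()] object (supplies the proactive cap
#'   and horizon context).
#' @return Named list of 7 [scenario_spec()] objects.
#' @export
builtin_scenarios <- function(params = demography_params()) {
  list(
    control = scenario_spec(
      "Remove Dead Ash Only (Control)", inject = "never"),
    remove_replant = scenario_spec(
      "Remove Dead Ash then Replant", inject = "never",
      replant_mode = "match", replant_lag = 1L),
    preemptive_replant = scenario_spec(
      "Preemptive Removal then Replant", inject = "never",
      preemptive_start = 1L, preemptive_rate = 400,
      replant_mode = "match", replant_lag = 0L),
    replant_inject_remove = scenario_spec(
      "Replant, Inject, then Preemptive Removal", inject = "window",
      inject_start = 1L, inject_end = 5L,
      preemptive_start = 6L, preemptive_rate = 400,
      replant_mode = "proactive", replant_rate = 400, replant_start = 1L,
      replant_cap = params$initial_ash_count),
    inject_remove_replant = scenario_spec(
      "Inject, Preemptive Removal, and Replant", inject = "window",
      inject_start = 1L, inject_end = 5L,
      preemptive_start = 6L, preemptive_rate = 400,
      replant_mode = "match", replant_lag = 0L),
    perpetuity = scenario_spec(
      "Injection in Perpetuity", inject = "perpetuity"),
    perpetuity_replant = scenario_spec(
      "Injection in Perpetuity with Replanting", inject = "perpetuity",
      replant_mode = "match", replant_lag = 0L)
  )
}

initial_state <- function(params) {
  cohorts <- tree_cohort(params$initial_ash_count, params$initial_ash_dbh,
                         species = "ash")
  list(year = 0L, cohorts = as.data.frame(cohorts),
       prev_ash_losses = 0L, planted_total = 0L,
       tallies = empty_tallies())
}

empty_tallies <- function() {
  list(ash_deaths = 0L, ash_removals = 0L, nonash_deaths = 0L,
       plantings = 0L, injections = 0, prunings = 0)
}

injection_active <- function(spec, year) {
  switch(spec$inject,
         never = FALSE,
         perpetuity = TRUE,
         window = year >= spec$inject_start && year <= spec$inject_end)
}

#' Advance the population by one management year
#'
#' Executes the annual event loop, in order: (1) advance the year and grow
#' all cohorts; (2) if preemptive removal is active, remove scheduled live
#' ash WITHOUT applying EAB mortality that year (dying trees are assumed to
#' be among those removed), otherwise apply species/age-appropriate
#' mortality with ceiling rounding; (3) remove dead trees; (4) plant
#' replacement non-ash cohorts per the replanting mode, applying first-year
#' survival in the planting year; (5) tally injection (half the injected
#' population) and pruning (a quarter of all living trees) cycle events; (6)
#' cost the events and emit the annual record. Counts in records are
#' end-of-year states.
#'
#' @param state A population state as produced by [run_scenario()]
#'   internals or a previous `step_year()` call.
#' @param spec A [scenario_spec()].
#' @param params A [demography_params()].
#' @param econ An [econ_params()] used to cost the year's events.
#' @return A list with elements `state`, `record` (one-row data frame) and
#'   `events` (the costed event table).
#' @export
step_year <- function(state, spec, params, econ = econ_params()) {
  if (state$year >= spec$horizon)
    stop("simulation horizon already reached", call. = FALSE)
  y <- state$year + 1L
  co <- state$cohorts
  tal <- empty_tallies()
  events <- list()

  # (1) growth, including cohorts planted in earlier years
  is_ash <- co$species == "ash"
  co$dbh[is_ash] <- grow_dbh(co$dbh[is_ash], params$ash_growth)
  co$dbh[!is_ash] <- grow_dbh(co$dbh[!is_ash], params$nonash_growth)

  injected_now <- injection_active(spec, y)
  co$injected[is_ash] <- injected_now

  # (2) ash transition: scheduled removal supersedes mortality
  ash_living <- sum(co$count[is_ash])
  preempt_on <- !is.na(spec$preemptive_start) && y >= spec$preemptive_start &&
    ash_living > 0
  if (preempt_on) {
    removed <- as.integer(min(spec$preemptive_rate, ash_living))
    remaining <- removed
    for (i in which(is_ash)) {
      take <- min(co$count[i], remaining)
      co$count[i] <- co$count[i] - take
      remaining <- remaining - take
      if (take > 0)
        events[[length(events) + 1L]] <-
          data.frame(type = "removal", dbh = co$dbh[i], n = take)
    }
    tal$ash_removals <- removed
  } else {
    rate <- if (injected_now) params$injected_ash_mortality
            else params$noninjected_ash_mortality
    for (i in which(is_ash)) {
      survivors <- apply_annual_mortality(co$count[i], rate)
      deaths <- co$count[i] - survivors
      co$count[i] <- survivors
      tal$ash_deaths <- tal$ash_deaths + deaths
      if (deaths > 0 && spec$remove_dead)
        events[[length(events) + 1L]] <-
          data.frame(type = "removal", dbh = co$dbh[i], n = deaths)
    }
  }

  # non-ash transition: age-based survival, ceiling per cohort-year
  for (i in which(!is_ash)) {
    age <- y - co$planting_year[i] + 1L
    survivors <- as.integer(ceiling(co$count[i] * survival_rate(age, params)))
    deaths <- co$count[i] - survivors
    co$count[i] <- survivors
    if (deaths > 0) {
      tal$nonash_deaths <- tal$nonash_deaths + deaths
      # replacement is a cost-only event tracked over the 4-yr post-planting
      # window: free under warranty (ages 1-2), charged post-warranty (3-4);
      # older deaths are ordinary background losses. Removal/stumping
      # charges apply to ash only.
      if (spec$replant_mode != "none" && age <= 4)
        events[[length(events) + 1L]] <- data.frame(
          type = if (age <= 2) "replacement_warranty"
                 else "replacement_postwarranty",
          dbh = co$dbh[i], n = deaths)
    }
  }

  # (4) replanting
  n_plant <- 0L
  if (spec$replant_mode == "match" && y >= spec$replant_start) {
    losses <- if (spec$replant_lag == 0L)
      tal$ash_deaths + tal$ash_removals else state$prev_ash_losses
    n_plant <- as.integer(losses)
  } else if (spec$replant_mode == "proactive" && y >= spec$replant_start) {
    n_plant <- as.integer(spec$replant_rate)
  }
  if (!is.na(spec$replant_cap))
    n_plant <- max(0L, min(n_plant,
                           as.integer(spec$replant_cap) - state$planted_total))
  if (n_plant > 0L) {
    survivors <- as.integer(ceiling(n_plant * survival_rate(1L, params)))
    dbh_new <- grow_dbh(params$planting_dbh, params$nonash_growth)
    co <- rbind(co, data.frame(species = "nonash", injected = FALSE,
                               planting_year = y, count = survivors,
                               dbh = dbh_new, stringsAsFactors = FALSE))
    tal$plantings <- n_plant
    tal$nonash_deaths <- tal$nonash_deaths + (n_plant - survivors)
    events[[length(events) + 1L]] <-
      data.frame(type = "planting", dbh = dbh_new, n = n_plant)
  }

  co <- co[co$count > 0L, , drop = FALSE]
  rownames(co) <- NULL
  is_ash <- co$species == "ash"

  # (5) injection and pruning cycle tallies on end-of-year populations
  if (injected_now && any(is_ash)) {
    for (i in which(is_ash)) {
      events[[length(events) + 1L]] <-
        data.frame(type = "injection", dbh = co$dbh[i], n = co$count[i] / 2)
      tal$injections <- tal$injections + co$count[i] / 2
    }
  }
  for (i in seq_len(nrow(co))) {
    events[[length(events) + 1L]] <-
      data.frame(type = "pruning", dbh = co$dbh[i], n = co$count[i] / 4)
    tal$prunings <- tal$prunings + co$count[i] / 4
  }

  events <- if (length(events)) do.call(rbind, events)
            else data.frame(type = character(0), dbh = numeric(0),
                            n = numeric(0))

  # (6) cost and value
  cost <- annual_cost(events, y, econ)
  ctla_nom <- cohort_ctla(co, econ)
  pvf <- present_value(1, y, econ)

  record <- data.frame(
    year = y,
    ash_count = sum(co$count[is_ash]),
    nonash_count = sum(co$count[!is_ash]),
    ash_basal = basal_printed(co[is_ash, , drop = FALSE]),
    nonash_basal = basal_printed(co[!is_ash, , drop = FALSE]),
    ash_deaths = tal$ash_deaths, ash_removals = tal$ash_removals,
    nonash_deaths = tal$nonash_deaths, plantings = tal$plantings,
    injections = tal$injections, prunings = tal$prunings,
    cost_removal = cost$removal, cost_pruning = cost$pruning,
    cost_injection = cost$injection, cost_planting = cost$planting,
    annual_cost_nominal = cost$total,
    annual_cost_pv = cost$total_pv,
    ctla_value_nominal = ctla_nom,
    ctla_value_pv = ctla_nom * pvf
  )

  state$year <- y
  state$cohorts <- co
  state$prev_ash_losses <- tal$ash_deaths + tal$ash_removals
  state$planted_total <- state$planted_total + tal$plantings
  state$tallies <- tal
  list(state = state, record = record, events = events)
}

cohort_ctla <- function(cohorts, econ) {
  if (!nrow(cohorts)) return(0)
  val <- numeric(nrow(cohorts))
  for (i in seq_len(nrow(cohorts))) {
    r <- if (cohorts$species[i] == "ash") econ$ash_ratings
         else econ$nonash_ratings
    val[i] <- cohorts$count[i] *
      ctla_value(cohorts$dbh[i], econ$cost_schedule$new_tree_unit_cost, r)
  }
  sum(val)
}

#' Run one scenario over its horizon
#'
#' Deterministically iterates [step_year()] from the initial remnant-ash
#' state, accumulating one annual record per year plus a Year-0 row for the
#' initial state. Identical inputs give identical outputs bit-for-bit.
#'
#' @param spec A [scenario_spec()].
#' @param params A [demography_params()].
#' @param econ An [econ_params()].
#' @return An object of class `eab_run`: list with `spec`, `params`, `econ`,
#'   and `records` (a data frame with rows for years 0..horizon, including
#'   counts, basal area in printed units (total cm^2 / 1000), cost
#'   components, cumulative discounted cost, CTLA value and net value).
#' @export
#' @examples
#' run <- run_scenario(builtin_scenarios()$control, demography_params(),
#'                     econ_params())
#' subset(run$records, year %in% c(1, 5, 10, 15, 20),
#'        c(year, ash_count, ash_basal))
run_scenario <- function(spec, params = demography_params(),
                         econ = econ_params()) {
  validate_scenario_spec(spec)
  validate_demography_params(params)
  state <- initial_state(params)
  co0 <- state$cohorts
  pv0 <- cohort_ctla(co0, econ)
  records <- vector("list", spec$horizon + 1L)
  records[[1]] <- data.frame(
    year = 0L,
    ash_count = sum(co0$count[co0$species == "ash"]),
    nonash_count = sum(co0$count[co0$species == "nonash"]),
    ash_basal = basal_printed(co0[co0$species == "ash", , drop = FALSE]),
    nonash_basal = basal_printed(co0[co0$species == "nonash", , drop = FALSE]),
    ash_deaths = 0L, ash_removals = 0L, nonash_deaths = 0L, plantings = 0L,
    injections = 0, prunings = 0,
    cost_removal = 0, cost_pruning = 0, cost_injection = 0, cost_planting = 0,
    annual_cost_nominal = 0, annual_cost_pv = 0,
    ctla_value_nominal = pv0, ctla_value_pv = pv0
  )
  for (y in seq_len(spec$horizon)) {
    out <- step_year(state, spec, params, econ)
    state <- out$state
    records[[y + 1L]] <- out$record
  }
  records <- do.call(rbind, records)
  records$cumulative_cost_pv <- cumsum(records$annual_cost_pv)
  records$net_value_pv <- net_value(records$ctla_value_pv,
                                    records$cumulative_cost_pv)
  res <- list(spec = spec, params = params, econ = econ, records = records,
              final_state = state)
  class(res) <- "eab_run"
  res
}

#' @export
print.eab_run <- function(x, ...) {
  cat(sprintf("<eab_run> %s (%d yr)\n", x$spec$name, x$spec$horizon))
  yrs <- intersect(c(1, 5, 10, 15, 20), x$records$year)
  cols <- c("year", "ash_count", "nonash_count", "ash_basal", "nonash_basal",
            "cumulative_cost_pv", "net_value_pv")
  print(x$records[x$records$year %in% yrs, cols], row.names = FALSE,
        digits = 6)
  invisible(x)
}

#' Run every builtin scenario
#'
#' @inheritParams run_scenario
#' @return Named list of [run_scenario()] results, one per builtin scenario.
#' @export
run_builtin_scenarios <- function(params = demography_params(),
                                  econ = econ_params()) {
  lapply(builtin_scenarios(params), run_scenario, params = params,
         econ = econ)
}
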