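#' Basal area in printed units
#'
#' Total trunk cross-sectional area of a cohort table,
#' `sum(count * pi * (dbh/2)^2)` in cm^2, divided by 1000 — the unit in
#' which the published tables report basal area.
#'
#' @param cohorts A cohort data frame (`count`, `dbh` columns).
#' @return Basal area in printed units (cm^2 / 1000).
#' @export
#' @examples
#' basal_printed(tree_cohort(1192, 27.481, "ash"))  # 707.0
basal_printed <- function(cohorts) {
  if (!nrow(cohorts)) return(0)
  sum(cohorts$count * pi * (cohorts$dbh / 2)^2) / 1000
}

#' Net value of the urban forest
#'
#' Discounted CTLA appraisal of the standing population minus the
#' discounted cumulative management cost.
#'
#' @param ctla_pv Discounted CTLA value, $.
#' @param cumulative_cost_pv Discounted cumulative cost, $.
#' @return `ctla_pv - cumulative_cost_pv`.
#' @export
net_value <- function(ctla_pv, cumulative_cost_pv) {
  ctla_pv - cumulative_cost_pv
}

#' Discounted annual cost per tree and per basal unit
#'
#' Normalizes a year's discounted cost by the living population size and by
#' the basal area in printed units, enabling comparison across scenarios of
#' different scale. Zero denominators yield `NA` (rendered as missing in
#' CSV output), not an error.
#'
#' @param record One or more rows of an `eab_run` record table.
#' @return Data frame with `year`, `cost_per_tree`, `cost_per_basal`.
#' @export
normalized_costs <- function(record) {
  trees <- record$ash_count + record$nonash_count
  basal <- record$ash_basal + record$nonash_basal
  data.frame(
    year = record$year,
    cost_per_tree = ifelse(trees > 0, record$annual_cost_pv / trees, NA_real_),
    cost_per_basal = ifelse(basal > 0, record$annual_cost_pv / basal,
                            NA_real_)
  )
}

#' Cost ratio of a scenario to the control
#'
#' Elementwise ratio of a scenario's discounted annual and cumulative costs
#' to the control scenario ("Remove Dead Ash Only"), the tradeoff metric of
#' the published analysis. Zero control values yield `NA`.
#'
#' @param run An `eab_run` for the scenario of interest.
#' @param control_run An `eab_run` for the control (equal horizon).
#' @return Data frame with `year`, `annual_ratio`, `cumulative_ratio`.
#' @export
ratio_to_control <- function(run, control_run) {
  r <- run$records
  c0 <- control_run$records
  if (nrow(r) != nrow(c0))
    stop("runs must share the same horizon", call. = FALSE)
  data.frame(
    year = r$year,
    annual_ratio = ifelse(c0$annual_cost_pv > 0,
                          r$annual_cost_pv / c0$annual_cost_pv, NA_real_),
    cumulative_ratio = ifelse(c0$cumulative_cost_pv > 0,
                              r$cumulative_cost_pv / c0$cumulative_cost_pv,
                              NA_real_)
  )
}

#' Objectives recognised by scenario ranking and sweep optimisation
#' @export
eab_objectives <- c("trees", "basal", "ash", "cost", "net_value")

final_summary <- function(run) {
  last <- run$records[nrow(run$records), ]
  data.frame(
    scenario = run$spec$name,
    trees = last$ash_count + last$nonash_count,
    basal = last$ash_basal + last$nonash_basal,
    ash = last$ash_count,
    cost = last$cumulative_cost_pv,
    net_value = last$net_value_pv,
    stringsAsFactors = FALSE
  )
}

#' Rank scenarios against each management objective
#'
#' For each of the five published objectives — preserve tree count, preserve
#' basal area, preserve the ash population, cost reduction, value
#' maximization — orders the supplied runs by their final-year criterion
#' (total trees; total basal; ash count; lowest cumulative discounted cost;
#' net value). Ties are broken by lower cumulative cost, then by scenario
#' name.
#'
#' @param runs List of `eab_run` objects with equal horizons.
#' @return Data frame with columns `objective`, `rank`, `scenario`,
#'   `criterion` (the value ranked on).
#' @export
objective_rankings <- function(runs) {
  if (!length(runs)) stop("no runs supplied", call. = FALSE)
  horizons <- vapply(runs, function(r) r$spec$horizon, integer(1))
  if (length(unique(horizons)) != 1L)
    stop("all runs must share the same horizon", call. = FALSE)
  summ <- do.call(rbind, lapply(runs, final_summary))
  out <- lapply(eab_objectives, function(obj) {
    key <- if (obj == "cost") -summ$cost else summ[[obj]]
    ord <- order(-key, summ$cost, summ$scenario)
    data.frame(objective = obj, rank = seq_along(ord),
               scenario = summ$scenario[ord], criterion = summ[[obj]][ord],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
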