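#' Grid of management decisions to sweep
#'
#' The published sensitivity analysis varies four management decisions: the
#' year injections end, the year removals start (both 1-20), and the annual
#' removal and planting rates (both 100-1000 trees/yr). A decision can only
#' be varied if the base scenario actually uses it (e.g. a planting rate
#' requires proactive replanting).
#'
#' @param base_scenario A [scenario_spec()] whose decisions are varied.
#' @param injection_end_years,removal_start_years Integer year vectors, or
#'   `NULL` to hold fixed.
#' @param removal_rates,planting_rates Trees/yr vectors, or `NULL`.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(base_scenario,
                       injection_end_years = NULL,
                       removal_start_years = NULL,
                       removal_rates = NULL,
                       planting_rates = NULL) {
  g <- list(base_scenario = base_scenario,
            injection_end_years = injection_end_years,
            removal_start_years = removal_start_years,
            removal_rates = removal_rates,
            planting_rates = planting_rates)
  class(g) <- "sweep_grid"
  validate_sweep_grid(g)
  g
}

sweep_dims <- c("injection_end_years", "removal_start_years",
                "removal_rates", "planting_rates")

validate_sweep_grid <- function(g) {
  spec <- g$base_scenario
  if (all(vapply(g[sweep_dims], is.null, logical(1))))
    stop("sweep grid is empty: no decision varied", call. = FALSE)
  if (!is.null(g$injection_end_years) && spec$inject != "window")
    stop("cannot vary injection end: base scenario has no injection window",
         call. = FALSE)
  if ((!is.null(g$removal_start_years) || !is.null(g$removal_rates)) &&
      is.na(spec$preemptive_start))
    stop("cannot vary removals: base scenario has no preemptive removal",
         call. = FALSE)
  if (!is.null(g$planting_rates) && spec$replant_mode != "proactive")
    stop("cannot vary planting rate: base scenario has no proactive planting",
         call. = FALSE)
  for (d in sweep_dims)
    if (!is.null(g[[d]]) && any(g[[d]] < 1))
      stop(sprintf("`%s` values must be >= 1", d), call. = FALSE)
  invisible(g)
}

apply_decision <- function(spec, decision, value) {
  switch(decision,
         injection_end_years = {
           # in inject-then-remove scenarios the removal start is tied to
           # the injection end: preserve the base offset when it moves
           if (!is.na(spec$preemptive_start) &&
               spec$preemptive_start > spec$inject_end) {
             offset <- spec$preemptive_start - spec$inject_end
             spec$preemptive_start <- as.integer(value) + offset
           }
           spec$inject_end <- as.integer(value)
         },
         removal_start_years = { spec$preemptive_start <- as.integer(value) },
         removal_rates = { spec$preemptive_rate <- as.numeric(value) },
         planting_rates = { spec$replant_rate <- as.numeric(value) },
         stop(sprintf("unknown decision '%s'", decision), call. = FALSE))
  validate_scenario_spec(spec)
  spec
}

#' Sweep management decisions over a grid
#'
#' Runs the base scenario once per grid point and summarises the final-year
#' outcome. By default decisions are varied one at a time with the others
#' held at the base scenario's values (the published convention);
#' `factorial = TRUE` crosses all supplied dimensions.
#'
#' @param grid A [sweep_grid()].
#' @param params A [demography_params()].
#' @param econ An [econ_params()].
#' @param factorial Cross all dimensions instead of one-at-a-time.
#' @return Data frame with one row per grid point: the four decision values
#'   applied, plus final-year `trees`, `basal`, `ash`, `cost`
#'   (cumulative discounted) and `net_value`.
#' @export
run_sweep <- function(grid, params = demography_params(),
                      econ = econ_params(), factorial = FALSE) {
  validate_sweep_grid(grid)
  base <- grid$base_scenario
  base_vals <- list(injection_end_years = base$inject_end,
                    removal_start_years = base$preemptive_start,
                    removal_rates = base$preemptive_rate,
                    planting_rates = base$replant_rate)
  active <- sweep_dims[!vapply(grid[sweep_dims], is.null, logical(1))]

  points <- if (factorial) {
    vals <- lapply(active, function(d) grid[[d]])
    names(vals) <- active
    pts <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(pts)), function(i) as.list(pts[i, , drop = FALSE]))
  } else {
    unlist(lapply(active, function(d) {
      lapply(grid[[d]], function(v) stats::setNames(list(v), d))
    }), recursive = FALSE)
  }

  rows <- lapply(points, function(pt) {
    spec <- base
    for (d in names(pt)) spec <- apply_decision(spec, d, pt[[d]])
    run <- run_scenario(spec, params, econ)
    vals <- base_vals
    vals[names(pt)] <- pt
    cbind(data.frame(injection_end = vals$injection_end_years,
                     removal_start = vals$removal_start_years,
                     removal_rate = vals$removal_rates,
                     planting_rate = vals$planting_rates),
          final_summary(run)[, -1, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best grid point(s) for an objective
#'
#' Argmax rows of a sweep table under one of the five objectives (`cost` is
#' minimised, the rest maximised). Ties are all reported.
#'
#' @param sweep_table Output of [run_sweep()].
#' @param objective One of `r paste(eab_objectives, collapse = ", ")`.
#' @return The optimal row(s) of `sweep_table`.
#' @export
optima_summary <- function(sweep_table, objective) {
  if (!nrow(sweep_table)) stop("empty sweep table", call. = FALSE)
  if (!objective %in% eab_objectives)
    stop(sprintf("unknown objective '%s' (expected one of: %s)", objective,
                 paste(eab_objectives, collapse = ", ")), call. = FALSE)
  key <- if (objective == "cost") -sweep_table$cost
         else sweep_table[[objective]]
  best <- max(key)
  sweep_table[abs(key - best) < 1e-9, , drop = FALSE]
}
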