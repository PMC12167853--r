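#' Default run configuration
#'
#' The plain-list form of every model parameter, with the published
#' Mississauga defaults filled in. [load_config()] merges a user file over
#' this structure, so an empty file yields exactly this configuration.
#'
#' @return A nested list (`demography`, `econ`, `scenarios`, `horizon`,
#'   `discount_override`, `output_dir`).
#' @export
default_config <- function() {
  list(
    demography = list(
      natural_mortality = 0.0085,
      injected_ash_mortality = 0.028,
      noninjected_ash_mortality = 0.20,
      ash_growth = 0.3,
      nonash_growth = 0.47,
      warranty_survival = c(0.915, 0.883, 0.958, 0.939),
      planting_dbh = 6,
      initial_ash_count = 1490,
      initial_ash_dbh = 27.181
    ),
    econ = list(
      inflation = 0.02,
      discount = 0.0283,
      ash_ratings = list(TC = 0.50, FL = 0.75, EL = 0.10),
      nonash_ratings = list(TC = 0.75, FL = 0.75, EL = 0.90),
      cost_schedule = list(
        removal_brackets = list(
          dbh_upper = c(20, 40, 60, 80, 100, 120, Inf),
          cost = c(105, 305, 855, 1450, 2950, 2950, 5700)),
        pruning_brackets = list(
          dbh_upper = c(20, 40, 60, 80, 100, 120, Inf),
          cost = c(60, 118, 268, 460, 610, 710, 862)),
        injection_per_cm = 3.325,
        planting_cost = 849.91,
        new_tree_unit_cost = 4.5
      )
    ),
    scenarios = c("control", "remove_replant", "preemptive_replant",
                  "replant_inject_remove", "inject_remove_replant",
                  "perpetuity", "perpetuity_replant"),
    horizon = 20,
    discount_override = NULL,
    output_dir = "."
  )
}

# recursive right-biased merge; scalars/vectors in `over` replace defaults
merge_config <- function(base, over) {
  if (is.null(over)) return(base)
  if (!is.list(over) || !is.list(base)) return(over)
  for (k in names(over)) {
    base[[k]] <- if (k %in% names(base)) merge_config(base[[k]], over[[k]])
                 else over[[k]]
  }
  base
}

# YAML/JSON may deliver bracket columns as heterogeneous lists
as_brackets <- function(b) {
  data.frame(dbh_upper = as.numeric(unlist(b$dbh_upper)),
             cost = as.numeric(unlist(b$cost)))
}

# open-ended brackets survive JSON by encoding Inf as the string "Inf"
thaw_inf <- function(x) {
  if (is.list(x)) return(lapply(x, thaw_inf))
  if (is.character(x)) {
    num <- suppressWarnings(as.numeric(sub("^\\.inf$", "Inf", x)))
    if (!anyNA(num)) return(num)
  }
  x
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, fills omitted fields with the
#' published defaults ([default_config()]), validates every block, and
#' resolves it into parameter objects. Validation errors name the offending
#' key. An empty file yields the full default configuration; setting
#' `discount_override: 0` reproduces the undiscounted future-value variant.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `run_config`: list with `demography`
#'   ([demography_params()]), `econ` ([econ_params()]), `scenarios` (named
#'   list of [scenario_spec()]), `horizon`, `output_dir`, and `raw` (the
#'   merged plain-list form, for the provenance manifest).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  resolve_config(merge_config(default_config(), thaw_inf(raw)))
}

#' Resolve a plain-list configuration into parameter objects
#'
#' @param raw A list shaped like [default_config()].
#' @return A `run_config` object (see [load_config()]).
#' @export
resolve_config <- function(raw) {
  d <- raw$demography
  demog <- tryCatch(
    demography_params(
      natural_mortality = d$natural_mortality,
      injected_ash_mortality = d$injected_ash_mortality,
      noninjected_ash_mortality = d$noninjected_ash_mortality,
      ash_growth = d$ash_growth, nonash_growth = d$nonash_growth,
      warranty_survival = d$warranty_survival,
      planting_dbh = d$planting_dbh,
      initial_ash_count = d$initial_ash_count,
      initial_ash_dbh = d$initial_ash_dbh),
    error = function(e) stop("config key `demography`: ",
                             conditionMessage(e), call. = FALSE))
  e <- raw$econ
  if (!is.null(raw$discount_override)) e$discount <- raw$discount_override
  econ <- tryCatch(
    econ_params(
      inflation = e$inflation, discount = e$discount,
      ash_ratings = rating_set(e$ash_ratings$TC, e$ash_ratings$FL,
                               e$ash_ratings$EL),
      nonash_ratings = rating_set(e$nonash_ratings$TC, e$nonash_ratings$FL,
                                  e$nonash_ratings$EL),
      cost_schedule = cost_schedule(
        removal_brackets = as_brackets(e$cost_schedule$removal_brackets),
        pruning_brackets = as_brackets(e$cost_schedule$pruning_brackets),
        injection_per_cm = e$cost_schedule$injection_per_cm,
        planting_cost = e$cost_schedule$planting_cost,
        new_tree_unit_cost = e$cost_schedule$new_tree_unit_cost)),
    error = function(err) stop("config key `econ`: ",
                               conditionMessage(err), call. = FALSE))
  builtins <- builtin_scenarios(demog)
  scen <- raw$scenarios
  scenarios <- if (is.character(scen)) {
    unknown <- setdiff(scen, names(builtins))
    if (length(unknown))
      stop("config key `scenarios`: unknown builtin(s) ",
           paste(unknown, collapse = ", "), call. = FALSE)
    builtins[scen]
  } else {
    # list of explicit spec definitions
    specs <- lapply(scen, function(s) {
      tryCatch(do.call(scenario_spec, c(s, list(horizon = raw$horizon))),
               error = function(err) stop("config key `scenarios`: ",
                                          conditionMessage(err),
                                          call. = FALSE))
    })
    stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
  }
  scenarios <- lapply(scenarios, function(s) {
    s$horizon <- as.integer(raw$horizon); s
  })
  cfg <- list(demography = demog, econ = econ, scenarios = scenarios,
              horizon = as.integer(raw$horizon),
              output_dir = raw$output_dir, raw = raw)
  class(cfg) <- "run_config"
  cfg
}

#' Generate a random valid configuration
#'
#' Property-testing fixture: draws a reproducible random configuration
#' (mortality fractions in `[0, 1]`, counts up to 10^4, sorted cost
#' brackets, horizon 1-40, a randomized scenario rule-set) that is
#' guaranteed to pass configuration validation. The same seed always yields
#' the identical configuration; the simulator itself contains no
#' randomness.
#'
#' @param seed Integer RNG seed.
#' @return A `run_config` object (see [load_config()]).
#' @export
fixture_generator <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  horizon <- sample(1:40, 1)
  n_brk <- sample(2:8, 1)
  uppers <- sort(stats::runif(n_brk - 1, 5, 150))
  raw <- default_config()
  raw$demography <- list(
    natural_mortality = stats::runif(1),
    injected_ash_mortality = stats::runif(1),
    noninjected_ash_mortality = stats::runif(1),
    ash_growth = stats::runif(1, 0, 2),
    nonash_growth = stats::runif(1, 0, 2),
    warranty_survival = stats::runif(4),
    planting_dbh = stats::runif(1, 1, 20),
    initial_ash_count = sample(0:10000, 1),
    initial_ash_dbh = stats::runif(1, 1, 100)
  )
  raw$econ$inflation <- stats::runif(1, 0, 0.1)
  raw$econ$discount <- stats::runif(1, 0, 0.1)
  raw$econ$ash_ratings <- list(TC = stats::runif(1), FL = stats::runif(1),
                               EL = stats::runif(1))
  raw$econ$nonash_ratings <- list(TC = stats::runif(1), FL = stats::runif(1),
                                  EL = stats::runif(1))
  raw$econ$cost_schedule$removal_brackets <-
    list(dbh_upper = c(uppers, Inf), cost = stats::runif(n_brk, 0, 5000))
  raw$econ$cost_schedule$pruning_brackets <-
    list(dbh_upper = c(uppers, Inf), cost = stats::runif(n_brk, 0, 1000))
  raw$horizon <- horizon
  pick <- function(v) v[sample.int(length(v), 1)]  # safe for length-1 v
  inj <- pick(c("never", "window", "perpetuity"))
  pre_on <- inj != "perpetuity" && stats::runif(1) < 0.5
  mode <- pick(c("none", "match", "proactive"))
  i_start <- pick(seq_len(horizon))
  raw$scenarios <- list(list(
    name = sprintf("random scenario (seed %d)", seed),
    inject = inj,
    inject_start = i_start,
    inject_end = pick(i_start:horizon),
    preemptive_start = if (pre_on) pick(seq_len(horizon)) else NA,
    preemptive_rate = pick(0:1000),
    remove_dead = stats::runif(1) < 0.9,
    replant_mode = mode,
    replant_rate = pick(0:1000),
    replant_start = pick(seq_len(horizon)),
    replant_lag = if (mode == "match") pick(0:1) else 0,
    replant_cap = if (stats::runif(1) < 0.5) pick(0:10000) else NA
  ))
  resolve_config(raw)
}

#' Run a full configuration
#'
#' @param cfg A `run_config` from [load_config()], [resolve_config()] or
#'   [fixture_generator()].
#' @return Named list of `eab_run` objects, one per configured scenario.
#' @export
run_config <- function(cfg) {
  lapply(cfg$scenarios, run_scenario, params = cfg$demography,
         econ = cfg$econ)
}

freeze_inf <- function(x) {
  if (is.list(x)) return(lapply(x, freeze_inf))
  if (is.numeric(x) && any(is.infinite(x))) {
    x <- as.character(x)
  }
  x
}

#' Write simulation outputs as CSV plus a provenance manifest
#'
#' Emits `counts_basal.csv` (one row per scenario x species-group x metric,
#' years as columns, in the shape of the published count/basal table),
#' `economics.csv` (long per-year cost, CTLA value and net value),
#' optionally `sweep.csv`, and `manifest.json` holding every resolved
#' parameter so a run can be reproduced from its outputs alone.
#'
#' @param runs Named list of `eab_run` objects.
#' @param dir Output directory (created if needed).
#' @param cfg Optional `run_config` recorded in the manifest.
#' @param sweep_table Optional [run_sweep()] result.
#' @param report_years Years to report in `counts_basal.csv` (default: all
#'   years 0..horizon).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_outputs <- function(runs, dir, cfg = NULL, sweep_table = NULL,
                          report_years = NULL) {
  if (!length(runs)) stop("no run results supplied", call. = FALSE)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  horizon <- runs[[1]]$spec$horizon
  years <- if (is.null(report_years)) 0:horizon else sort(report_years)

  groups <- list(ash = c("ash_count", "ash_basal"),
                 nonash = c("nonash_count", "nonash_basal"))
  rows <- list()
  for (run in runs) {
    rec <- run$records[match(years, run$records$year), ]
    for (metric in c("count", "basal")) {
      vals <- list(
        ash = rec[[paste0("ash_", metric)]],
        nonash = rec[[paste0("nonash_", metric)]])
      vals$all <- vals$ash + vals$nonash
      for (g in names(vals)) {
        row <- data.frame(scenario = run$spec$name, species_group = g,
                          metric = metric, stringsAsFactors = FALSE)
        row[paste0("year_", years)] <- as.list(vals[[g]])
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  counts_basal <- do.call(rbind, rows)
  f_counts <- file.path(dir, "counts_basal.csv")
  utils::write.csv(counts_basal, f_counts, row.names = FALSE)

  econ_rows <- lapply(runs, function(run) {
    cbind(data.frame(scenario = run$spec$name, stringsAsFactors = FALSE),
          run$records[, c("year", "cost_removal", "cost_pruning",
                          "cost_injection", "cost_planting",
                          "annual_cost_nominal", "annual_cost_pv",
                          "cumulative_cost_pv", "ctla_value_pv",
                          "net_value_pv")])
  })
  economics <- do.call(rbind, econ_rows)
  rownames(economics) <- NULL
  f_econ <- file.path(dir, "economics.csv")
  utils::write.csv(economics, f_econ, row.names = FALSE)

  files <- c(counts_basal = f_counts, economics = f_econ)

  if (!is.null(sweep_table)) {
    f_sweep <- file.path(dir, "sweep.csv")
    utils::write.csv(sweep_table, f_sweep, row.names = FALSE)
    files <- c(files, sweep = f_sweep)
  }

  manifest <- list(
    package = "eabsim",
    version = as.character(utils::packageVersion("eabsim")),
    scenarios = vapply(runs, function(r) r$spec$name, character(1)),
    horizon = horizon,
    config = if (!is.null(cfg)) freeze_inf(cfg$raw) else NULL
  )
  f_manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, manifest = f_manifest)
  invisible(files)
}

#' Command-line interface
#'
#' Subcommands:
#' \describe{
#'   \item{run}{`eabsim run [--config FILE] [--out DIR] [--report-years Y1,Y2,...]`
#'     — run the configured scenarios and write CSV outputs.}
#'   \item{sweep}{`eabsim sweep --scenario SLUG --vary DIM=FROM:TO:BY [--config FILE] [--out DIR]`
#'     — grid sweep over a management decision (`DIM` one of
#'     `injection_end_years`, `removal_start_years`, `removal_rates`,
#'     `planting_rates`).}
#'   \item{calibrate}{`eabsim calibrate --basal B --count N --growth G` —
#'     recover the initial median ash DBH from a printed Year-1 basal area.}
#' }
#'
#' @param args Character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return Exit status, invisibly: 0 on success.
#' @export
eab_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: eabsim <run|sweep|calibrate> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  cfg <- if (!is.null(opts[["config"]])) load_config(opts[["config"]])
         else resolve_config(default_config())
  out_dir <- if (!is.null(opts[["out"]])) opts[["out"]] else cfg$output_dir

  if (cmd == "run") {
    runs <- run_config(cfg)
    ry <- if (!is.null(opts[["report-years"]]))
      as.integer(strsplit(opts[["report-years"]], ",")[[1]]) else NULL
    files <- write_outputs(runs, out_dir, cfg = cfg, report_years = ry)
    message("wrote: ", paste(files, collapse = ", "))
    return(invisible(0L))
  }
  if (cmd == "sweep") {
    slug <- opts[["scenario"]]
    if (is.null(slug) || !slug %in% names(cfg$scenarios))
      stop("--scenario must name a configured scenario", call. = FALSE)
    vary <- opts[["vary"]]
    if (is.null(vary)) stop("--vary DIM=FROM:TO:BY required", call. = FALSE)
    kv <- strsplit(vary, "=")[[1]]
    rng <- as.numeric(strsplit(kv[2], ":")[[1]])
    values <- seq(rng[1], rng[2], by = if (length(rng) >= 3) rng[3] else 1)
    grid_args <- stats::setNames(list(values), kv[1])
    grid <- do.call(sweep_grid,
                    c(list(base_scenario = cfg$scenarios[[slug]]), grid_args))
    tab <- run_sweep(grid, cfg$demography, cfg$econ)
    files <- write_outputs(run_config(cfg)[slug], out_dir, cfg = cfg,
                           sweep_table = tab)
    message("wrote: ", paste(files, collapse = ", "))
    return(invisible(0L))
  }
  if (cmd == "calibrate") {
    d0 <- calibrate_initial_dbh(as.numeric(opts[["basal"]]),
                                as.numeric(opts[["count"]]),
                                as.numeric(opts[["growth"]]))
    cat(sprintf("initial ash DBH: %.3f cm\n", d0))
    return(invisible(0L))
  }
  stop("unknown subcommand: ", cmd, call. = FALSE)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i + 1L > length(args))
      stop("missing value for --", key, call. = FALSE)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
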