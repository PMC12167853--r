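#' Demographic parameters for the ash management model
#'
#' Bundles the mortality, growth and post-planting survival parameters that
#' drive the annual cohort recurrence. Defaults are the City of Mississauga
#' rates for a late-stage emerald ash borer (EAB) infestation: non-injected
#' ash die at 20\%/yr, ash under a TreeAzin injection program at 2.8\%/yr,
#' and all established trees at a background rate of 0.85\%/yr. Newly planted
#' trees follow an empirical four-year survival schedule (warranty years 1-2,
#' post-warranty years 3-4) before reverting to background mortality.
#'
#' @param natural_mortality Background annual mortality, all species
#'   (fraction).
#' @param injected_ash_mortality Annual mortality of ash while injected
#'   (fraction).
#' @param noninjected_ash_mortality Annual mortality of uninjected ash under
#'   EAB (fraction).
#' @param ash_growth Annual DBH growth of ash, cm/yr.
#' @param nonash_growth Annual DBH growth of non-ash, cm/yr.
#' @param warranty_survival Numeric vector of length 4: survival fractions
#'   for years 1-4 after planting. Years >= 5 use
#'   `1 - natural_mortality`.
#' @param planting_dbh Caliper of a newly planted tree, cm (treated as DBH).
#' @param initial_ash_count Remnant city-owned ash population at Year 0.
#' @param initial_ash_dbh Median DBH of that population at Year 0, cm. The
#'   default is the calibrated constant recovered by
#'   [calibrate_initial_dbh()]; it is not observed directly.
#'
#' @return An object of class `demography_params`.
#' @seealso [calibrate_initial_dbh()], [advance_cohort()]
#' @export
#' @examples
#' p <- demography_params()
#' survival_rate(1, p)   # first-year post-planting survival, 0.915
#' survival_rate(7, p)   # background survival, 0.9915
demography_params <- function(natural_mortality = 0.0085,
                              injected_ash_mortality = 0.028,
                              noninjected_ash_mortality = 0.20,
                              ash_growth = 0.3,
                              nonash_growth = 0.47,
                              warranty_survival = c(0.915, 0.883, 0.958, 0.939),
                              planting_dbh = 6,
                              initial_ash_count = 1490,
                              initial_ash_dbh = 27.181) {
  p <- list(
    natural_mortality = natural_mortality,
    injected_ash_mortality = injected_ash_mortality,
    noninjected_ash_mortality = noninjected_ash_mortality,
    ash_growth = ash_growth,
    nonash_growth = nonash_growth,
    warranty_survival = warranty_survival,
    planting_dbh = planting_dbh,
    initial_ash_count = initial_ash_count,
    initial_ash_dbh = initial_ash_dbh
  )
  class(p) <- "demography_params"
  validate_demography_params(p)
  p
}

validate_demography_params <- function(p) {
  fr <- c("natural_mortality", "injected_ash_mortality",
          "noninjected_ash_mortality")
  for (f in fr) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a single fraction in [0, 1]", f),
           call. = FALSE)
  }
  if (any(p$warranty_survival < 0) || any(p$warranty_survival > 1) ||
      length(p$warranty_survival) != 4L)
    stop("`warranty_survival` must be 4 fractions in [0, 1] (years 1-4)",
         call. = FALSE)
  if (p$ash_growth < 0 || p$nonash_growth < 0)
    stop("growth rates must be >= 0", call. = FALSE)
  if (p$initial_ash_count < 0)
    stop("`initial_ash_count` must be >= 0", call. = FALSE)
  if (p$planting_dbh <= 0 || p$initial_ash_dbh <= 0)
    stop("DBH values must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.demography_params <- function(x, ...) {
  cat("Demographic parameters\n")
  cat(sprintf("  mortality: natural %.2f%%, injected ash %.2f%%, uninjected ash %.2f%%\n",
              100 * x$natural_mortality, 100 * x$injected_ash_mortality,
              100 * x$noninjected_ash_mortality))
  cat(sprintf("  growth (cm/yr): ash %.2f, non-ash %.2f\n",
              x$ash_growth, x$nonash_growth))
  cat(sprintf("  post-planting survival (yrs 1-4): %s\n",
              paste(x$warranty_survival, collapse = ", ")))
  cat(sprintf("  initial population: %d ash at %.3f cm DBH\n",
              x$initial_ash_count, x$initial_ash_dbh))
  invisible(x)
}

#' Annual mortality with ceiling rounding
#'
#' Applies one year of deterministic mortality to an integer tree count,
#' rounding survivors UP: `ceil(count * (1 - rate))`. Ceiling after every
#' cohort-year is the rounding convention that makes the model's published
#' trajectories integer-exact (1490 uninjected ash at 20\%/yr give
#' 1192, 954, 764, 612, 490, ...).
#'
#' @param count Non-negative integer tree count.
#' @param rate Annual mortality fraction in `[0, 1]`.
#' @return Integer count of survivors (`<= count`).
#' @export
#' @examples
#' apply_annual_mortality(1490, 0.20)   # 1192
#' apply_annual_mortality(1490, 0.028)  # 1449
apply_annual_mortality <- function(count, rate) {
  if (any(count < 0) || any(count != floor(count)))
    stop("`count` must be a non-negative integer", call. = FALSE)
  if (any(rate < 0) || any(rate > 1) || any(is.na(rate)))
    stop("`rate` must be in [0, 1]", call. = FALSE)
  as.integer(ceiling(count * (1 - rate)))
}

#' Age-dependent post-planting survival
#'
#' Survival fraction applied to a planted cohort in its `years_since_planting`-th
#' year: the empirical warranty-period schedule for years 1-4, reverting to
#' `1 - natural_mortality` from year 5 onward.
#'
#' @param years_since_planting Integer age >= 1 (1 = the planting year).
#' @param params A [demography_params()] object.
#' @return Survival fraction.
#' @export
survival_rate <- function(years_since_planting, params) {
  if (any(years_since_planting < 1) ||
      any(years_since_planting != floor(years_since_planting)))
    stop("`years_since_planting` must be an integer >= 1", call. = FALSE)
  ifelse(years_since_planting <= 4L,
         params$warranty_survival[pmin(years_since_planting, 4L)],
         1 - params$natural_mortality)
}

#' One year of diameter growth
#'
#' DBH grows by a fixed species-specific increment each simulated year,
#' including the planting year of a new cohort (a 6 cm caliper non-ash tree
#' ends its first year at 6.47 cm).
#'
#' @param dbh Diameter at breast height, cm (>= 0).
#' @param growth Annual increment, cm/yr (>= 0).
#' @return `dbh + growth`.
#' @export
grow_dbh <- function(dbh, growth) {
  if (any(dbh < 0) || any(growth < 0))
    stop("`dbh` and `growth` must be >= 0", call. = FALSE)
  dbh + growth
}

#' Construct a tree cohort table
#'
#' Cohorts are the model's unit of account: a group of identically
#' parameterized trees. Ash cohorts are pre-existing (`planting_year = NA`);
#' non-ash cohorts carry their planting year so the age-dependent survival
#' schedule can be applied.
#'
#' @param count Integer tree count (>= 0).
#' @param dbh DBH in cm.
#' @param species `"ash"` or `"nonash"`.
#' @param injected Logical; only ash may be injected.
#' @param planting_year Integer year planted, or `NA` for pre-existing trees.
#' @return A one-row `data.frame` with class `tree_cohort` prepended.
#' @export
tree_cohort <- function(count, dbh, species = c("ash", "nonash"),
                        injected = FALSE, planting_year = NA_integer_) {
  species <- match.arg(species)
  if (count < 0 || count != floor(count))
    stop("`count` must be a non-negative integer", call. = FALSE)
  if (dbh < 0) stop("`dbh` must be >= 0", call. = FALSE)
  if (species == "nonash" && injected)
    stop("only ash cohorts can be injected", call. = FALSE)
  structure(
    data.frame(species = species, injected = injected,
               planting_year = as.integer(planting_year),
               count = as.integer(count), dbh = as.numeric(dbh),
               stringsAsFactors = FALSE),
    class = c("tree_cohort", "data.frame")
  )
}

#' Advance one cohort by one year
#'
#' Composes growth and mortality for a single cohort-year: survivors are
#' `ceil(count * s)` where `s` is the species- and age-appropriate survival
#' (injection status for pre-existing ash, the post-planting schedule for
#' planted cohorts), and DBH increases by the species growth rate. The
#' ceiling is applied at every cohort-year transition.
#'
#' @param cohort A [tree_cohort()] (one row).
#' @param year Current simulation year (>= 1); determines cohort age.
#' @param params A [demography_params()] object.
#' @param mortality_override Optional fraction replacing the derived
#'   mortality for this transition.
#' @return The advanced cohort.
#' @export
advance_cohort <- function(cohort, year, params, mortality_override = NULL) {
  if (year < 1) stop("`year` must be >= 1", call. = FALSE)
  if (!is.null(mortality_override)) {
    s <- 1 - mortality_override
    if (s < 0 || s > 1)
      stop("`mortality_override` must be in [0, 1]", call. = FALSE)
  } else if (cohort$species == "ash") {
    s <- 1 - if (isTRUE(cohort$injected)) params$injected_ash_mortality
             else params$noninjected_ash_mortality
  } else if (!is.na(cohort$planting_year)) {
    s <- survival_rate(year - cohort$planting_year + 1L, params)
  } else {
    s <- 1 - params$natural_mortality
  }
  g <- if (cohort$species == "ash") params$ash_growth else params$nonash_growth
  cohort$count <- as.integer(ceiling(cohort$count * s))
  cohort$dbh <- grow_dbh(cohort$dbh, g)
  cohort
}

#' Calibrate the initial median ash DBH from a printed basal area
#'
#' The model's Year-0 median ash DBH is not observed; it is recovered from
#' internal consistency of the published Year-1 outputs. Given the printed
#' Year-1 ash basal area (in printed units, total cm^2 / 1000), the Year-1
#' count, and the annual growth already applied by Year 1, this inverts
#' `pi * ((d0 + growth) / 2)^2 * count / 1000 = basal` for `d0`.
#'
#' @param year1_basal_printed Printed Year-1 basal area (cm^2 / 1000).
#' @param year1_count Year-1 tree count.
#' @param growth Annual DBH growth, cm/yr.
#' @return Initial DBH `d0` in cm. With the default demography
#'   (707.0 printed units over 1192 trees, 0.3 cm/yr) this is 27.181 cm.
#' @export
#' @examples
#' calibrate_initial_dbh(707.0, 1192, 0.3)
calibrate_initial_dbh <- function(year1_basal_printed, year1_count, growth) {
  if (year1_basal_printed <= 0 || year1_count <= 0 || growth <= 0)
    stop("all calibration inputs must be > 0", call. = FALSE)
  2 * sqrt(year1_basal_printed * 1000 / (year1_count * pi)) - growth
}
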