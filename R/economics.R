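#' Cost schedule: event prices for tree operations
#'
#' Holds the DBH-bracketed removal and pruning prices, the per-cm injection
#' rate, the planting-and-establishment cost, and the per-cm^2 replacement
#' unit cost used by the CTLA trunk formula. Defaults are the 2024 City of
#' Mississauga procurement rates. Stumping carries no separate schedule and
#' is treated as included in the removal bracket price.
#'
#' @param removal_brackets,pruning_brackets Data frames with columns
#'   `dbh_upper` (strictly increasing, last entry `Inf`) and `cost`.
#' @param injection_per_cm TreeAzin injection cost, $/cm DBH.
#' @param planting_cost Cost to plant and establish one tree, $.
#' @param new_tree_unit_cost Replacement-tree cost per cm^2 of trunk area
#'   (the `NT` term of the CTLA formula), $/cm^2.
#' @return An object of class `cost_schedule`.
#' @export
cost_schedule <- function(removal_brackets = default_brackets("removal"),
                          pruning_brackets = default_brackets("pruning"),
                          injection_per_cm = 3.325,
                          planting_cost = 849.91,
                          new_tree_unit_cost = 4.5) {
  s <- list(removal_brackets = removal_brackets,
            pruning_brackets = pruning_brackets,
            injection_per_cm = injection_per_cm,
            planting_cost = planting_cost,
            new_tree_unit_cost = new_tree_unit_cost)
  class(s) <- "cost_schedule"
  validate_cost_schedule(s)
  s
}

default_brackets <- function(which = c("removal", "pruning")) {
  which <- match.arg(which)
  upper <- c(20, 40, 60, 80, 100, 120, Inf)
  cost <- switch(which,
                 removal = c(105, 305, 855, 1450, 2950, 2950, 5700),
                 pruning = c(60, 118, 268, 460, 610, 710, 862))
  data.frame(dbh_upper = upper, cost = cost)
}

validate_cost_schedule <- function(s) {
  for (nm in c("removal_brackets", "pruning_brackets")) {
    b <- s[[nm]]
    if (!is.data.frame(b) || nrow(b) == 0 ||
        !all(c("dbh_upper", "cost") %in% names(b)))
      stop(sprintf("`%s` must be a non-empty data frame with columns dbh_upper, cost", nm),
           call. = FALSE)
    if (is.unsorted(b$dbh_upper, strictly = TRUE))
      stop(sprintf("`%s$dbh_upper` must be strictly increasing", nm),
           call. = FALSE)
    if (!is.infinite(b$dbh_upper[nrow(b)]))
      stop(sprintf("`%s` final bracket must be open-ended (dbh_upper = Inf)", nm),
           call. = FALSE)
    if (any(b$cost < 0)) stop("bracket costs must be >= 0", call. = FALSE)
  }
  if (s$injection_per_cm < 0 || s$planting_cost < 0 ||
      s$new_tree_unit_cost < 0)
    stop("costs must be >= 0", call. = FALSE)
  invisible(s)
}

#' CTLA appraisal ratings
#'
#' Condition (TC), functional-limitations (FL) and external-limitations (EL)
#' ratings, each a fraction in `[0, 1]`, that depreciate the trunk-formula
#' replacement value. Ash carries EL = 0.10 per CTLA guidance when a lethal
#' pest is present.
#'
#' @param TC,FL,EL Fractions in `[0, 1]`.
#' @return An object of class `rating_set`.
#' @export
rating_set <- function(TC, FL, EL) {
  r <- list(TC = TC, FL = FL, EL = EL)
  if (any(unlist(r) < 0) || any(unlist(r) > 1))
    stop("ratings must be fractions in [0, 1]", call. = FALSE)
  class(r) <- "rating_set"
  r
}

#' Economic parameters
#'
#' @param inflation Annual inflation rate (fraction).
#' @param discount Annual discount rate (fraction). Set to 0 to obtain the
#'   undiscounted future-value variant.
#' @param ash_ratings,nonash_ratings [rating_set()] objects.
#' @param cost_schedule A [cost_schedule()] object.
#' @return An object of class `econ_params`.
#' @export
econ_params <- function(inflation = 0.02,
                        discount = 0.0283,
                        ash_ratings = rating_set(0.50, 0.75, 0.10),
                        nonash_ratings = rating_set(0.75, 0.75, 0.90),
                        cost_schedule = eabsim::cost_schedule()) {
  if (inflation < 0 || discount < 0)
    stop("`inflation` and `discount` must be >= 0", call. = FALSE)
  e <- list(inflation = inflation, discount = discount,
            ash_ratings = ash_ratings, nonash_ratings = nonash_ratings,
            cost_schedule = cost_schedule)
  class(e) <- "econ_params"
  e
}

#' DBH-bracket price lookup
#'
#' Returns the price of the first bracket whose upper bound is at or above
#' the given DBH; boundaries are inclusive on the upper end, so a 20 cm tree
#' falls in the "0-20" bracket and a 20.1 cm tree in "> 20-40".
#'
#' @param dbh DBH in cm (vectorized, >= 0).
#' @param brackets A bracket data frame (`dbh_upper`, `cost`).
#' @return Price(s) in $.
#' @export
#' @examples
#' bracket_cost(27.5, default_brackets("removal"))  # 305
bracket_cost <- function(dbh, brackets) {
  if (!is.data.frame(brackets) || nrow(brackets) == 0)
    stop("empty bracket schedule", call. = FALSE)
  if (any(dbh < 0)) stop("`dbh` must be >= 0", call. = FALSE)
  idx <- findInterval(dbh, brackets$dbh_upper, left.open = TRUE) + 1L
  brackets$cost[idx]
}

#' Injection cost for one tree
#'
#' @param dbh DBH in cm.
#' @param rate $/cm.
#' @return `rate * dbh`.
#' @export
injection_cost <- function(dbh, rate) {
  if (any(dbh < 0)) stop("`dbh` must be >= 0", call. = FALSE)
  rate * dbh
}

#' Replacement/planting charge under the contractor warranty
#'
#' A planted tree that dies within 2 years of planting is replaced free of
#' charge under the contractor warranty; from year 3 the city pays the full
#' planting cost. Scheduled new plantings are always charged.
#'
#' @param years_since_planting Integer age at death (>= 1), or `NA` for a
#'   scheduled new planting.
#' @param cost Planting-and-establishment cost, $.
#' @return 0 for warranty deaths, `cost` otherwise.
#' @export
planting_charge <- function(years_since_planting, cost) {
  ifelse(!is.na(years_since_planting) & years_since_planting <= 2, 0, cost)
}

#' CTLA trunk-formula appraisal of one tree
#'
#' `value = (DBH/2)^2 * pi * NT * TC * FL * EL`: the replacement cost of the
#' trunk cross-sectional area depreciated by the condition, functional and
#' external ratings.
#'
#' @param dbh DBH in cm.
#' @param NT Replacement cost per cm^2 of trunk area, $/cm^2.
#' @param ratings A [rating_set()].
#' @return Appraised value, $.
#' @export
ctla_value <- function(dbh, NT, ratings) {
  if (any(dbh < 0)) stop("`dbh` must be >= 0", call. = FALSE)
  (dbh / 2)^2 * pi * NT * ratings$TC * ratings$FL * ratings$EL
}

#' Present value under compound inflation and discounting
#'
#' Nominal (2024) dollars incurred in year `t` are inflated and discounted
#' end-of-year: `nominal * ((1 + inflation) / (1 + discount))^t`. With a
#' discount rate of 0 this yields the inflated future value.
#'
#' @param nominal Amount in year-0 dollars.
#' @param t Years since Year 0 (>= 0).
#' @param econ An [econ_params()] object.
#' @return Present value, $.
#' @export
present_value <- function(nominal, t, econ) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  nominal * ((1 + econ$inflation) / (1 + econ$discount))^t
}

#' Cost an annual event tally
#'
#' Converts the event table emitted by [step_year()] into management cost
#' components: removal (stumping included), pruning (a quarter of the living
#' population per year), injection (half of the injected population per
#' year), and planting/replacement (warranty replacements free). Components
#' are returned in nominal 2024 dollars and at present value for year `t`.
#'
#' @param events Data frame with columns `type` (one of `removal`,
#'   `pruning`, `injection`, `planting`, `replacement_warranty`,
#'   `replacement_postwarranty`), `dbh`, `n` (tree-events; may be
#'   fractional for cycle-based pruning/injection tallies).
#' @param t Simulation year of the events (for discounting).
#' @param econ An [econ_params()] object.
#' @return A one-row data frame: `removal`, `pruning`, `injection`,
#'   `planting`, `total` (nominal) and `total_pv`.
#' @export
annual_cost <- function(events, t, econ) {
  cs <- econ$cost_schedule
  comp <- c(removal = 0, pruning = 0, injection = 0, planting = 0)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      comp <- comp + switch(
        ev$type,
        removal = c(bracket_cost(ev$dbh, cs$removal_brackets) * ev$n, 0, 0, 0),
        pruning = c(0, bracket_cost(ev$dbh, cs$pruning_brackets) * ev$n, 0, 0),
        injection = c(0, 0, injection_cost(ev$dbh, cs$injection_per_cm) * ev$n, 0),
        planting = c(0, 0, 0, cs$planting_cost * ev$n),
        replacement_warranty = c(0, 0, 0, 0),
        replacement_postwarranty = c(0, 0, 0, cs$planting_cost * ev$n),
        stop(sprintf("unknown event type '%s'", ev$type), call. = FALSE)
      )
    }
  }
  total <- sum(comp)
  data.frame(removal = comp[["removal"]], pruning = comp[["pruning"]],
             injection = comp[["injection"]], planting = comp[["planting"]],
             total = total, total_pv = present_value(total, t, econ))
}
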