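#' Build and validate transition rates for the cohort engine
#'
#' The cohort engine runs a three-state annual-cycle Markov model — no
#' dementia, dementia, death — per gender, age and activity level. Rates
#' are supplied per age: `incidence` is the annual dementia-onset
#' probability for the inactive reference (scaled by the level's relative
#' risk), `mort_nodem` and `mort_dem` are annual death probabilities
#' without and with dementia. Dementia carries excess mortality, so
#' `mort_dem >= mort_nodem` is enforced at every age.
#'
#' @param age integer vector of ages (years).
#' @param incidence,mort_nodem,mort_dem annual probabilities per age.
#' @param gender optional gender label attached to the table.
#' @return a validated tibble `age`, `incidence`, `mort_nodem`, `mort_dem`
#'   (plus `gender` if given).
#' @export
transition_rates <- function(age, incidence, mort_nodem, mort_dem,
                             gender = NULL) {
  rates <- tibble::tibble(age = as.integer(age), incidence = incidence,
                          mort_nodem = mort_nodem, mort_dem = mort_dem)
  if (!is.null(gender)) rates$gender <- gender
  validate_transition_rates(rates)
  rates
}

#' @rdname transition_rates
#' @param rates a transition-rate tibble.
#' @export
validate_transition_rates <- function(rates) {
  required <- c("age", "incidence", "mort_nodem", "mort_dem")
  missing <- setdiff(required, names(rates))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Transition rates missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "cycledem_schema_error")
  }
  probs <- unlist(rates[c("incidence", "mort_nodem", "mort_dem")])
  if (any(probs < 0) || any(probs > 1)) {
    rlang::abort("Transition probabilities must lie in [0, 1]",
                 class = "cycledem_validation_error")
  }
  bad <- rates$mort_dem < rates$mort_nodem
  if (any(bad)) {
    rlang::abort(sprintf(
      "mort_dem < mort_nodem at age %d (dementia excess mortality required)",
      rates$age[which(bad)[1]]
    ), class = "cycledem_validation_error")
  }
  if (anyDuplicated(rates$age)) {
    rlang::abort("Duplicate ages in transition rates",
                 class = "cycledem_schema_error")
  }
  invisible(rates)
}

# annual transition matrix at one age, states (nodem, dem, dead);
# death is evaluated per state, incidence applies to no-dementia survivors
transition_matrix <- function(inc, mort_nodem, mort_dem, rr = 1) {
  p_onset <- inc * rr
  if (p_onset > 1 + 1e-12) {
    rlang::abort(sprintf(
      "Relative-risk-scaled incidence %.4f exceeds 1", p_onset
    ), class = "cycledem_validation_error")
  }
  p_onset <- min(p_onset, 1)
  matrix(c(
    (1 - mort_nodem) * (1 - p_onset), (1 - mort_nodem) * p_onset, mort_nodem,
    0,                                1 - mort_dem,               mort_dem,
    0,                                0,                          1
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("nodem", "dem", "dead"), c("nodem", "dem", "dead")))
}

#' Propagate a cohort through the three-state Markov model
#'
#' Starting from a cohort entirely in the no-dementia state at `start_age`,
#' applies one annual cycle per year of age up to `max_age`. Within a
#' cycle, death is evaluated per state and dementia onset applies to the
#' no-dementia survivors with probability `incidence(age) * rr`; there is
#' no remission and death is absorbing. Occupancy sums to 1 at every cycle.
#'
#' @param rates transition-rate table covering ages
#'   `start_age..(max_age - 1)` (see [transition_rates()]).
#' @param rr relative risk of dementia for the cohort's activity level
#'   (1 for the inactive reference).
#' @param start_age,max_age cohort entry age and final age; `max_age -
#'   start_age` annual cycles are run.
#' @return a tibble with one row per cycle (including cycle 0 at entry):
#'   `cycle`, `age`, `nodem`, `dem`, `dead`.
#' @export
#' @examples
#' r <- transition_rates(60:64, incidence = 0.1, mort_nodem = 0.05,
#'                       mort_dem = 0.2)
#' propagate(r, rr = 1, start_age = 60, max_age = 63)
propagate <- function(rates, rr = 1, start_age = 16, max_age = 100) {
  validate_transition_rates(rates)
  stopifnot(start_age < max_age, rr > 0)
  ages <- start_age:(max_age - 1)
  missing <- setdiff(ages, rates$age)
  if (length(missing) > 0) {
    rlang::abort(sprintf("Rates not defined for age(s) %s",
                         paste(utils::head(missing, 5), collapse = ", ")),
                 class = "cycledem_validation_error")
  }
  rates <- rates[match(ages, rates$age), ]
  n <- length(ages)
  occ <- matrix(0, nrow = n + 1, ncol = 3,
                dimnames = list(NULL, c("nodem", "dem", "dead")))
  occ[1, ] <- c(1, 0, 0)
  state <- occ[1, ]
  for (i in seq_len(n)) {
    P <- transition_matrix(rates$incidence[i], rates$mort_nodem[i],
                           rates$mort_dem[i], rr = rr)
    state <- as.numeric(state %*% P)
    occ[i + 1, ] <- state
  }
  tibble::tibble(cycle = 0:n, age = c(ages, max_age),
                 nodem = occ[, "nodem"], dem = occ[, "dem"],
                 dead = occ[, "dead"])
}

#' Lifetime outputs from a cohort trajectory
#'
#' Expected person-years with dementia, life expectancy from entry, and
#' discounted lifetime costs per category. Other-disease health and social
#' care costs accrue per person-year alive (either alive state);
#' dementia-specific care costs accrue per person-year with dementia; the
#' unpaid-care cost is years-with-dementia times the annual unpaid-care
#' rate. Occupancy at the end of each cycle counts as that cycle's
#' person-years (no half-cycle correction).
#'
#' @param trajectory output of [propagate()].
#' @param annual_costs named list of annual per-person costs in GBP:
#'   `hc_dementia`, `sc_dementia` (per year with dementia), `hc_other`,
#'   `sc_other` (per year alive), `unpaid_rate` (per year with dementia).
#' @param discount_rate annual discount rate (fraction, default 0).
#' @return a one-row tibble: `years_with_dementia`, `life_expectancy`, the
#'   five lifetime cost categories in GBP thousands, and their `total`.
#' @export
lifetime_outputs <- function(trajectory, annual_costs, discount_rate = 0) {
  if (discount_rate < 0) {
    rlang::abort("Discount rate must be non-negative",
                 class = "cycledem_validation_error")
  }
  required <- c("hc_dementia", "hc_other", "sc_dementia", "sc_other",
                "unpaid_rate")
  missing <- setdiff(required, names(annual_costs))
  if (length(missing) > 0) {
    rlang::abort(sprintf("annual_costs missing: %s",
                         paste(missing, collapse = ", ")),
                 class = "cycledem_schema_error")
  }
  cyc <- trajectory[trajectory$cycle > 0, ]
  disc <- (1 + discount_rate)^(-cyc$cycle)
  alive <- cyc$nodem + cyc$dem
  ywd <- sum(cyc$dem)
  le <- sum(alive)
  k <- function(x) x / 1000
  out <- tibble::tibble(
    years_with_dementia = ywd,
    life_expectancy = le,
    hc_dementia = k(sum(cyc$dem * disc) * annual_costs$hc_dementia),
    hc_other = k(sum(alive * disc) * annual_costs$hc_other),
    sc_dementia = k(sum(cyc$dem * disc) * annual_costs$sc_dementia),
    sc_other = k(sum(alive * disc) * annual_costs$sc_other),
    unpaid_care = k(sum(cyc$dem * disc) * annual_costs$unpaid_rate)
  )
  out$total <- out$hc_dementia + out$hc_other + out$sc_dementia +
    out$sc_other + out$unpaid_care
  out
}

#' Regenerate a per-person lifetime cost table from the cohort engine
#'
#' Runs the three-state engine for every gender and activity level and
#' assembles a long cost table in the same schema as
#' [read_cost_table()] (GBP thousands per person). With the published
#' relative risks and level-independent mortality, the generated table
#' reproduces the qualitative pattern of the published per-person costs:
#' dementia-specific categories are highest for the inactive and
#' other-disease categories increase with activity (the longevity effect).
#'
#' @param rates_by_gender named list (by gender) of transition-rate tables.
#' @param rr relative-risk table (see [read_relative_risks()]).
#' @param annual_costs_by_gender named list (by gender) of `annual_costs`
#'   lists as in [lifetime_outputs()].
#' @param start_age,max_age,discount_rate passed to the engine.
#' @return a cost-table tibble `gender`, `level`, `category`, `cost`.
#' @export
cohort_cost_table <- function(rates_by_gender, rr, annual_costs_by_gender,
                              start_age = 16, max_age = 100,
                              discount_rate = 0) {
  rr_vec <- setNames(rr$rr, as.character(rr$level))
  rows <- list()
  for (g in names(rates_by_gender)) {
    for (lvl in activity_levels()) {
      traj <- propagate(rates_by_gender[[g]], rr = rr_vec[[lvl]],
                        start_age = start_age, max_age = max_age)
      res <- lifetime_outputs(traj, annual_costs_by_gender[[g]],
                              discount_rate = discount_rate)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gender = g, level = lvl, category = cost_categories(),
        cost = c(res$hc_dementia, res$hc_other, res$sc_dementia,
                 res$sc_other, res$unpaid_care)
      )
    }
  }
  out <- dplyr::bind_rows(rows) %>%
    dplyr::mutate(level = as_activity_level(.data$level))
  validate_cost_table(out)
  out
}
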