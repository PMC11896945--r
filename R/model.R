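#' Redistribute level counts in response to new cycling uptake
#'
#' Count-space counterpart of [redistribute_activity()]: within each
#' gender (and age band, if present) group, counts are converted to
#' shares, the one-level promotion is applied with the group's
#' `delta_cycling`, and shares are scaled back to counts. Group totals are
#' conserved exactly.
#'
#' @param counts tibble with columns `gender`, `level`, `count` and
#'   optionally `age_band`.
#' @param delta_cycling increase in cycling prevalence as a fraction;
#'   scalar or named by gender.
#' @param policy redistribution policy, see [redistribute_activity()].
#' @return a tibble of the same shape as `counts`.
#' @export
redistribute_counts <- function(counts, delta_cycling,
                                policy = c("proportional",
                                           "uniform_fraction")) {
  policy <- match.arg(policy)
  has_band <- "age_band" %in% names(counts)
  keys <- if (has_band) c("gender", "age_band") else "gender"
  wide <- counts %>%
    dplyr::mutate(level = as.character(.data$level)) %>%
    tidyr::pivot_wider(id_cols = dplyr::all_of(keys),
                       names_from = "level", values_from = "count")
  missing <- setdiff(activity_levels(), names(wide))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Counts missing level(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "cycledem_schema_error")
  }
  S <- as.matrix(wide[, activity_levels()])
  group_total <- rowSums(S)
  shares <- S / ifelse(group_total > 0, group_total, 1)
  if (length(delta_cycling) == 1 && is.null(names(delta_cycling))) {
    delta <- rep(as.numeric(delta_cycling), nrow(wide))
  } else {
    delta_cycling <- unlist(delta_cycling)
    miss_g <- setdiff(unique(wide$gender), names(delta_cycling))
    if (length(miss_g) > 0) {
      rlang::abort(sprintf("delta_cycling missing gender(s): %s",
                           paste(miss_g, collapse = ", ")),
                   class = "cycledem_validation_error")
    }
    delta <- as.numeric(delta_cycling[wide$gender])
  }
  shares_new <- promote_matrix(shares, delta, policy)
  wide[, activity_levels()] <- shares_new * group_total
  wide %>%
    tidyr::pivot_longer(dplyr::all_of(activity_levels()),
                        names_to = "level", values_to = "count") %>%
    dplyr::mutate(level = as_activity_level(.data$level)) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)), .data$level)
}

#' Evaluate the cycling scenarios end to end
#'
#' Runs the full deterministic model: for each scenario, the relative
#' uptake increase is applied to each gender's baseline cycling
#' prevalence, the resulting percentage-point increase becomes the mover
#' mass promoted one activity level, and population lifetime costs are
#' re-aggregated. Returns the per-level cost breakdowns, the savings
#' tables, and the scenario cycling prevalences with gender-gap metrics.
#'
#' @param counts baseline level counts (`gender`, `level`, `count`,
#'   optional `age_band`), e.g. from [counts_by_level()] or
#'   [calibrate_counts_from_totals()].
#' @param cost_table per-person lifetime cost table.
#' @param baseline_props named vector of baseline cycling prevalence
#'   fractions per gender, e.g. `c(women = 0.0279, men = 0.0889)`.
#' @param uptake tibble `gender`, `scenario`, `rel_increase` (fractions);
#'   defaults to the two built-in presets.
#' @param policy redistribution policy.
#' @return a list with elements `breakdowns` (named list of
#'   [cost_breakdown()] tibbles, baseline first), `savings` (named list of
#'   [scenario_savings()] tibbles per scenario), and `cycling` (tibble of
#'   scenario prevalences and gap metrics).
#' @export
#' @examples
#' costs <- read_cost_table(cycledem_example("lifetime_costs_per_person.csv"))
#' pub <- read_published_population_costs(
#'   cycledem_example("published_population_costs.csv"))
#' counts <- calibrate_counts_from_totals(
#'   dplyr::filter(pub, scope == "total")[c("gender", "level", "baseline")] |>
#'     dplyr::rename(total_bn = baseline), costs)
#' res <- evaluate_scenarios(counts, costs,
#'                           c(women = 0.0279, men = 0.0889))
#' res$savings$scenario1
evaluate_scenarios <- function(counts, cost_table, baseline_props,
                               uptake = scenario_presets(),
                               policy = c("proportional",
                                          "uniform_fraction")) {
  policy <- match.arg(policy)
  gs <- unique(uptake$gender)
  missing <- setdiff(gs, names(baseline_props))
  if (length(missing) > 0) {
    rlang::abort(sprintf("baseline_props missing gender(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "cycledem_validation_error")
  }
  breakdowns <- list(baseline = cost_breakdown(counts, cost_table))
  savings <- list()
  cycling <- list()
  for (sc in unique(uptake$scenario)) {
    inc <- uptake[uptake$scenario == sc, ]
    rel <- setNames(inc$rel_increase, inc$gender)[gs]
    props <- apply_uptake(baseline_props[gs], rel)
    delta <- props - baseline_props[gs]
    counts_sc <- redistribute_counts(counts, delta, policy = policy)
    breakdowns[[sc]] <- cost_breakdown(counts_sc, cost_table)
    savings[[sc]] <- scenario_savings(breakdowns$baseline, breakdowns[[sc]])
    gaps <- gender_gaps(props[["women"]], props[["men"]])
    cycling[[sc]] <- tibble::tibble(
      scenario = sc, gender = gs, prop = as.numeric(props),
      absolute_gap = gaps$absolute, relative_gap = gaps$relative
    )
  }
  base_gaps <- gender_gaps(baseline_props[["women"]],
                           baseline_props[["men"]])
  cycling_tbl <- dplyr::bind_rows(
    tibble::tibble(scenario = "baseline", gender = gs,
                   prop = as.numeric(baseline_props[gs]),
                   absolute_gap = base_gaps$absolute,
                   relative_gap = base_gaps$relative),
    dplyr::bind_rows(cycling)
  )
  list(breakdowns = breakdowns, savings = savings, cycling = cycling_tbl)
}

#' Read published population lifetime cost tables
#'
#' Readers for the transcribed published results: per-level population
#' lifetime costs (GBP billions) by scope, gender and scenario, and the
#' gender-total summary table. These are diagnostic inputs — used to
#' back-calibrate the unpublished census counts and to check additivity —
#' not model outputs.
#'
#' @param path CSV path; see the bundled
#'   `published_population_costs.csv` / `published_cost_summary.csv`.
#' @return a tibble.
#' @export
read_published_population_costs <- function(path) {
  df <- read_input_csv(path, c("scope", "gender", "level", "baseline"))
  dplyr::mutate(df, level = as_activity_level(.data$level))
}

#' @rdname read_published_population_costs
#' @export
read_published_cost_summary <- function(path) {
  read_input_csv(path, c("scope", "gender", "baseline"))
}

#' Baseline level counts back-calibrated from the published tables
#'
#' Convenience wrapper: back-solves the per-gender, per-level population
#' counts from the published baseline total lifetime costs and the
#' per-person cost table, the route the package uses when no census
#' population table is supplied.
#'
#' @param published per-level published cost table, as from
#'   [read_published_population_costs()].
#' @param cost_table per-person cost table.
#' @param scope which published scope to solve against (default
#'   `"total"`).
#' @return a tibble `gender`, `level`, `count`.
#' @export
calibrated_baseline_counts <- function(published, cost_table,
                                       scope = "total") {
  pub <- published[published$scope == scope,
                   c("gender", "level", "baseline")]
  names(pub)[names(pub) == "baseline"] <- "total_bn"
  calibrate_counts_from_totals(pub, cost_table, scope = scope)
}
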