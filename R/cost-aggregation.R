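#' Aggregate per-person lifetime costs over the population
#'
#' Population lifetime cost for each (gender, level) cell is the head count
#' times the per-person lifetime cost, converted from persons x GBP
#' thousands to GBP billions (divide by 1e6). The `dementia_related` scope
#' sums dementia health care, dementia social care and unpaid-carer costs;
#' the `total` scope sums all five categories.
#'
#' @param counts level counts, as from [counts_by_level()] or
#'   [calibrate_counts_from_totals()]; any `age_band` column is summed out.
#' @param cost_table per-person cost table (see [read_cost_table()]).
#' @param scope `"dementia_related"` or `"total"`.
#' @return a tibble `gender`, `level`, `cost_bn` (GBP billions).
#' @export
#' @examples
#' costs <- read_cost_table(cycledem_example("lifetime_costs_per_person.csv"))
#' counts <- tibble::tibble(gender = "women", level = "low", count = 1e6)
#' aggregate_costs(counts, costs, "total") # 74.93 bn
aggregate_costs <- function(counts, cost_table,
                            scope = c("dementia_related", "total")) {
  scope <- match.arg(scope)
  cats <- if (scope == "dementia_related") {
    dementia_related_categories()
  } else {
    cost_categories()
  }
  per_person <- cost_table %>%
    dplyr::filter(.data$category %in% cats) %>%
    dplyr::group_by(.data$gender, .data$level) %>%
    dplyr::summarise(per_person = sum(.data$cost), .groups = "drop") %>%
    dplyr::mutate(level = as.character(.data$level))
  counts_gl <- counts %>%
    dplyr::mutate(level = as.character(.data$level)) %>%
    dplyr::group_by(.data$gender, .data$level) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  missing <- dplyr::anti_join(counts_gl, per_person,
                              by = c("gender", "level"))
  if (nrow(missing) > 0) {
    rlang::abort(sprintf(
      "No per-person costs for: %s",
      paste(paste(missing$gender, missing$level, sep = "/"), collapse = ", ")
    ), class = "cycledem_validation_error")
  }
  counts_gl %>%
    dplyr::inner_join(per_person, by = c("gender", "level")) %>%
    dplyr::mutate(level = as_activity_level(.data$level),
                  cost_bn = .data$count * .data$per_person / 1e6) %>%
    dplyr::arrange(.data$gender, .data$level) %>%
    dplyr::select("gender", "level", "cost_bn")
}

#' Both-scope population cost breakdown
#'
#' @inheritParams aggregate_costs
#' @return a tibble `gender`, `level`, `dementia_related`, `total`
#'   (GBP billions).
#' @export
cost_breakdown <- function(counts, cost_table) {
  dem <- aggregate_costs(counts, cost_table, "dementia_related") %>%
    dplyr::rename(dementia_related = "cost_bn")
  tot <- aggregate_costs(counts, cost_table, "total") %>%
    dplyr::rename(total = "cost_bn")
  dplyr::inner_join(dem, tot, by = c("gender", "level"))
}

#' Scenario cost differences
#'
#' Differences between a scenario breakdown and the baseline, per scope,
#' with gender subtotals and grand totals. Negative differences are
#' savings.
#'
#' @param baseline,scenario cost breakdowns from [cost_breakdown()].
#' @return a tibble with columns `scope`, `gender` (including `"total"`),
#'   `baseline`, `scenario`, `diff` (all GBP billions).
#' @export
scenario_savings <- function(baseline, scenario) {
  keyed <- dplyr::inner_join(
    baseline, scenario,
    by = c("gender", "level"), suffix = c("_base", "_scen")
  )
  if (nrow(keyed) != nrow(baseline) || nrow(keyed) != nrow(scenario)) {
    rlang::abort("Baseline and scenario breakdowns have mismatched keys",
                 class = "cycledem_validation_error")
  }
  long <- dplyr::bind_rows(
    keyed %>%
      dplyr::transmute(scope = "dementia_related", gender = .data$gender,
                       baseline = .data$dementia_related_base,
                       scenario = .data$dementia_related_scen),
    keyed %>%
      dplyr::transmute(scope = "total", gender = .data$gender,
                       baseline = .data$total_base,
                       scenario = .data$total_scen)
  )
  by_gender <- long %>%
    dplyr::group_by(.data$scope, .data$gender) %>%
    dplyr::summarise(baseline = sum(.data$baseline),
                     scenario = sum(.data$scenario), .groups = "drop")
  totals <- by_gender %>%
    dplyr::group_by(.data$scope) %>%
    dplyr::summarise(gender = "total", baseline = sum(.data$baseline),
                     scenario = sum(.data$scenario), .groups = "drop")
  dplyr::bind_rows(by_gender, totals) %>%
    dplyr::mutate(diff = .data$scenario - .data$baseline) %>%
    dplyr::arrange(.data$scope, match(.data$gender,
                                      c("women", "men", "total")))
}

#' Back-calibrate population counts from published cost totals
#'
#' Diagnostic solver for the population counts behind published population
#' lifetime costs: `count = published_total_bn * 1e6 / per_person_total_k`.
#' Re-aggregating the calibrated counts reproduces the published totals to
#' machine precision (round-trip identity), which is how the baseline
#' columns of the published result tables are regenerated without the
#' unpublished census counts.
#'
#' @param published_totals tibble `gender`, `level`, `total_bn` of
#'   published population lifetime costs in GBP billions for one scope.
#' @param cost_table per-person cost table.
#' @param scope which per-person scope the published totals refer to.
#' @return a tibble `gender`, `level`, `count` (persons, fractional).
#' @export
#' @examples
#' costs <- read_cost_table(cycledem_example("lifetime_costs_per_person.csv"))
#' pub <- tibble::tibble(gender = "women", level = "low", total_bn = 83.11)
#' calibrate_counts_from_totals(pub, costs) # ~1.109e6 persons
calibrate_counts_from_totals <- function(published_totals, cost_table,
                                         scope = c("total",
                                                   "dementia_related")) {
  scope <- match.arg(scope)
  cats <- if (scope == "dementia_related") {
    dementia_related_categories()
  } else {
    cost_categories()
  }
  per_person <- cost_table %>%
    dplyr::filter(.data$category %in% cats) %>%
    dplyr::group_by(.data$gender, .data$level) %>%
    dplyr::summarise(per_person = sum(.data$cost), .groups = "drop") %>%
    dplyr::mutate(level = as.character(.data$level))
  if (any(per_person$per_person <= 0)) {
    rlang::abort("Per-person cost must be positive to back-calibrate counts",
                 class = "cycledem_validation_error")
  }
  published_totals %>%
    dplyr::mutate(level = as.character(.data$level)) %>%
    dplyr::inner_join(per_person, by = c("gender", "level")) %>%
    dplyr::mutate(level = as_activity_level(.data$level),
                  count = .data$total_bn * 1e6 / .data$per_person) %>%
    dplyr::select("gender", "level", "count")
}

#' Render report tables of population lifetime costs
#'
#' Lays breakdowns out as the published result tables: one row per gender x
#' level plus a per-gender `total` row, one value column per scenario, and
#' a difference column per non-baseline scenario; costs in GBP billions at
#' two decimal places.
#'
#' @param breakdowns a named list of [cost_breakdown()] results; the first
#'   element is the baseline.
#' @param digits decimal places for reporting (default 2). Use `NULL` for
#'   full precision.
#' @return a tibble with columns `scope`, `gender`, `level`, one column per
#'   breakdown, and `diff_<name>` columns for the non-baseline ones.
#' @export
render_report <- function(breakdowns, digits = 2) {
  stopifnot(length(breakdowns) >= 1, !is.null(names(breakdowns)))
  long <- dplyr::bind_rows(lapply(names(breakdowns), function(nm) {
    breakdowns[[nm]] %>%
      dplyr::mutate(run = nm, level = as.character(.data$level)) %>%
      tidyr::pivot_longer(c("dementia_related", "total"),
                          names_to = "scope", values_to = "cost_bn")
  }))
  totals <- long %>%
    dplyr::group_by(.data$run, .data$gender, .data$scope) %>%
    dplyr::summarise(level = "total", cost_bn = sum(.data$cost_bn),
                     .groups = "drop")
  wide <- dplyr::bind_rows(long, totals) %>%
    tidyr::pivot_wider(names_from = "run", values_from = "cost_bn") %>%
    dplyr::arrange(.data$scope, match(.data$gender, c("women", "men")),
                   match(.data$level, c(activity_levels(), "total"))) %>%
    dplyr::select("scope", "gender", "level", dplyr::all_of(names(breakdowns)))
  base_nm <- names(breakdowns)[1]
  for (nm in names(breakdowns)[-1]) {
    wide[[paste0("diff_", nm)]] <- wide[[nm]] - wide[[base_nm]]
  }
  if (!is.null(digits)) {
    num <- vapply(wide, is.numeric, logical(1))
    wide[num] <- lapply(wide[num], round, digits = digits)
  }
  wide
}
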