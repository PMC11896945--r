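#' Path to a bundled input table
#'
#' The package ships plain-text transcriptions of the published model
#' inputs: the Health Survey for England 2021 activity-level distribution,
#' per-person lifetime dementia costs (2024 prices, after Van Baal et al.
#' and Livingston et al.), cycling patterns and scenario uptake increases,
#' and dementia relative risks by activity level.
#'
#' @param file file name under `inst/extdata`, e.g.
#'   `"activity_levels_hse2021.csv"`. With no argument, lists the available
#'   files.
#' @return a file path, or a character vector of file names.
#' @export
#' @examples
#' cycledem_example()
#' cycledem_example("dementia_relative_risks.csv")
cycledem_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cycledem")))
  }
  path <- system.file("extdata", file, package = "cycledem")
  if (identical(path, "")) {
    rlang::abort(sprintf("No bundled file '%s'", file),
                 class = "cycledem_file_error")
  }
  path
}

read_input_csv <- function(path, required_cols) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Input file not found: %s", path),
                 class = "cycledem_file_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                        progress = FALSE)
  if (nrow(df) == 0) {
    rlang::abort(sprintf("Input file is empty: %s", path),
                 class = "cycledem_schema_error")
  }
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf("%s: missing column(s) %s", path,
                         paste(missing, collapse = ", ")),
                 class = "cycledem_schema_error")
  }
  df
}

#' Read and validate an activity-level distribution
#'
#' Reads a long-format table of activity-level percentages by gender and age
#' band, converts percentages to fractions, and validates each
#' (gender, age band) row: all four levels present, shares non-negative, and
#' shares summing to 1 within `tol` (the printed source percentages are
#' rounded, so row sums of 99-101% are accepted).
#'
#' @param path CSV file with columns `gender`, `age_band`, `level`,
#'   `percent`.
#' @param tol tolerance on the deviation of each row sum from 1
#'   (default 0.02).
#' @return a tibble with columns `gender`, `age_band`, `level` (ordered
#'   factor) and `share` (fraction in \[0, 1\]).
#' @export
#' @examples
#' dist <- read_activity_distribution(
#'   cycledem_example("activity_levels_hse2021.csv"))
#' head(dist)
read_activity_distribution <- function(path, tol = 0.02) {
  df <- read_input_csv(path, c("gender", "age_band", "level", "percent"))
  dist <- df %>%
    dplyr::mutate(level = as_activity_level(.data$level),
                  share = .data$percent / 100) %>%
    dplyr::select("gender", "age_band", "level", "share")
  validate_activity_distribution(dist, tol = tol)
  dist
}

#' Validate an activity-level distribution
#'
#' @param dist tibble with columns `gender`, `age_band`, `level`, `share`.
#' @param tol allowed absolute deviation of each (gender, age band) share
#'   sum from 1.
#' @return `dist`, invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_activity_distribution <- function(dist, tol = 0.02) {
  required <- c("gender", "age_band", "level", "share")
  missing <- setdiff(required, names(dist))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Distribution is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "cycledem_schema_error")
  }
  dist <- dplyr::mutate(dist, level = as_activity_level(.data$level))
  if (any(dist$share < 0)) {
    bad <- dist[dist$share < 0, ][1, ]
    rlang::abort(sprintf("Negative share for (%s, %s, %s)",
                         bad$gender, bad$age_band, as.character(bad$level)),
                 class = "cycledem_validation_error")
  }
  counts <- dist %>%
    dplyr::count(.data$gender, .data$age_band)
  if (any(counts$n != 4)) {
    bad <- counts[counts$n != 4, ][1, ]
    rlang::abort(sprintf(
      "Row (%s, %s) has %d levels; all four of %s are required",
      bad$gender, bad$age_band, bad$n,
      paste(activity_levels(), collapse = ", ")
    ), class = "cycledem_schema_error")
  }
  sums <- dist %>%
    dplyr::group_by(.data$gender, .data$age_band) %>%
    dplyr::summarise(total = sum(.data$share), .groups = "drop")
  off <- abs(sums$total - 1) > tol + 1e-12
  if (any(off)) {
    bad <- sums[off, ][1, ]
    rlang::abort(sprintf(
      "Shares for (%s, %s) sum to %.4f, outside 1 +/- %.3g",
      bad$gender, bad$age_band, bad$total, tol
    ), class = "cycledem_validation_error")
  }
  invisible(dist)
}

#' Read and validate a per-person lifetime cost table
#'
#' Reads the per-person lifetime cost table: for each gender and activity
#' level, lifetime health-care and social-care costs split between dementia
#' and other diseases, plus unpaid-carer costs, all in thousands of pounds
#' at 2024 prices.
#'
#' @param path CSV file with columns `gender`, `level`, `category`,
#'   `cost_thousands`.
#' @return a tibble with columns `gender`, `level`, `category`, `cost`
#'   (GBP thousands per person).
#' @export
#' @examples
#' costs <- read_cost_table(cycledem_example("lifetime_costs_per_person.csv"))
#' cost_totals(costs)
read_cost_table <- function(path) {
  df <- read_input_csv(path, c("gender", "level", "category", "cost_thousands"))
  costs <- df %>%
    dplyr::mutate(level = as_activity_level(.data$level)) %>%
    dplyr::rename(cost = "cost_thousands") %>%
    dplyr::select("gender", "level", "category", "cost")
  validate_cost_table(costs)
  costs
}

#' @rdname read_cost_table
#' @param costs a cost table as returned by `read_cost_table()`.
#' @export
validate_cost_table <- function(costs) {
  required <- c("gender", "level", "category", "cost")
  missing <- setdiff(required, names(costs))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Cost table is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "cycledem_schema_error")
  }
  bad_cat <- setdiff(unique(costs$category), cost_categories())
  if (length(bad_cat) > 0) {
    rlang::abort(sprintf("Unknown cost category(s): %s",
                         paste(bad_cat, collapse = ", ")),
                 class = "cycledem_schema_error")
  }
  if (any(costs$cost < 0)) {
    bad <- costs[costs$cost < 0, ][1, ]
    rlang::abort(sprintf("Negative cost for (%s, %s, %s)",
                         bad$gender, as.character(bad$level), bad$category),
                 class = "cycledem_validation_error")
  }
  cells <- costs %>%
    dplyr::count(.data$gender, .data$level)
  if (any(cells$n != length(cost_categories()))) {
    bad <- cells[cells$n != length(cost_categories()), ][1, ]
    rlang::abort(sprintf(
      "Cell (%s, %s) has %d categories; all five of %s are required",
      bad$gender, as.character(bad$level), bad$n,
      paste(cost_categories(), collapse = ", ")
    ), class = "cycledem_schema_error")
  }
  invisible(costs)
}

#' @rdname read_cost_table
#' @return `cost_totals()` returns one row per (gender, level) with the sum
#'   of the five categories (`total`) and the dementia-related subtotal
#'   (`dementia_related` = dementia health care + dementia social care +
#'   unpaid care), both in GBP thousands per person.
#' @export
cost_totals <- function(costs) {
  costs %>%
    dplyr::group_by(.data$gender, .data$level) %>%
    dplyr::summarise(
      dementia_related = sum(.data$cost[.data$category %in%
                                          dementia_related_categories()]),
      total = sum(.data$cost),
      .groups = "drop"
    )
}

#' Read a population-count table
#'
#' Reads population counts by gender and age band (census-style). Bands
#' outside the 16-64 scope of the headline model are dropped with a
#' warning; they never enter the scenario computations.
#'
#' @param path CSV file with columns `gender`, `age_band`, `count`.
#' @param restrict_bands if `TRUE` (default), keep only the five 16-64
#'   bands, warning about any others present.
#' @return a tibble with columns `gender`, `age_band`, `count`.
#' @export
read_population <- function(path, restrict_bands = TRUE) {
  df <- read_input_csv(path, c("gender", "age_band", "count"))
  if (any(df$count < 0)) {
    bad <- df[df$count < 0, ][1, ]
    rlang::abort(sprintf("Negative population count for (%s, %s)",
                         bad$gender, bad$age_band),
                 class = "cycledem_validation_error")
  }
  if (restrict_bands) {
    outside <- setdiff(unique(df$age_band), age_bands())
    if (length(outside) > 0) {
      rlang::warn(sprintf(
        "Excluding age band(s) outside the 16-64 model scope: %s",
        paste(outside, collapse = ", ")
      ))
      df <- dplyr::filter(df, .data$age_band %in% age_bands())
    }
  }
  dplyr::select(df, "gender", "age_band", "count")
}

#' Read cycling patterns and uptake increases
#'
#' `read_cycling_patterns()` reads the published cycling-pattern table:
#' weekly cycling prevalence for women and men (percent) at baseline and
#' under the two off-road cycle-lane scenarios, plus the absolute
#' (percentage-point) and relative (men:women ratio) gender gaps.
#' `read_uptake_increases()` reads the relative uptake increases per gender
#' and scenario (fractions, e.g. 0.403 = +40.3%).
#'
#' @param path CSV path; see the bundled `cycling_patterns.csv` /
#'   `uptake_increases.csv` for the schemas.
#' @return a tibble.
#' @export
read_cycling_patterns <- function(path) {
  df <- read_input_csv(path, c("measure", "baseline"))
  missing <- setdiff(c("women", "men"), df$measure)
  if (length(missing) > 0) {
    rlang::abort(sprintf("Cycling patterns missing row(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "cycledem_schema_error")
  }
  tibble::as_tibble(df)
}

#' @rdname read_cycling_patterns
#' @export
read_uptake_increases <- function(path) {
  df <- read_input_csv(path, c("gender", "scenario", "rel_increase"))
  if (any(df$rel_increase < 0)) {
    rlang::abort("Relative uptake increases must be non-negative",
                 class = "cycledem_validation_error")
  }
  tibble::as_tibble(df)
}

#' Read dementia relative risks by activity level
#'
#' Dementia incidence multipliers relative to the inactive reference
#' (RR = 1). Validated to be in (0, 1\] and non-increasing with activity
#' level.
#'
#' @param path CSV file with columns `level`, `rr`.
#' @return a tibble with columns `level` (ordered factor) and `rr`.
#' @export
read_relative_risks <- function(path) {
  df <- read_input_csv(path, c("level", "rr"))
  rr <- df %>%
    dplyr::mutate(level = as_activity_level(.data$level)) %>%
    dplyr::arrange(.data$level) %>%
    dplyr::select("level", "rr")
  validate_relative_risks(rr)
  rr
}

#' @rdname read_relative_risks
#' @param rr a relative-risk tibble.
#' @export
validate_relative_risks <- function(rr) {
  if (any(rr$rr <= 0) || any(rr$rr > 1)) {
    rlang::abort("Relative risks must be in (0, 1]",
                 class = "cycledem_validation_error")
  }
  v <- rr$rr[order(rr$level)]
  if (is.unsorted(rev(v))) {
    rlang::abort("Relative risks must be non-increasing with activity level",
                 class = "cycledem_validation_error")
  }
  invisible(rr)
}

#' Write model input tables
#'
#' Writers mirroring the readers, so that any valid table round-trips
#' bit-identically at the declared decimal precision.
#'
#' @param x the table to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_distribution <- function(x, path) {
  out <- x %>%
    dplyr::mutate(percent = .data$share * 100) %>%
    dplyr::select("gender", "age_band", "level", "percent")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_activity_distribution
#' @export
write_cost_table <- function(x, path) {
  out <- dplyr::select(dplyr::rename(x, cost_thousands = "cost"),
                       "gender", "level", "category", "cost_thousands")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_activity_distribution
#' @export
write_population <- function(x, path) {
  readr::write_csv(dplyr::select(x, "gender", "age_band", "count"), path)
  invisible(path)
}
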