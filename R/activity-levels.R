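#' Physical activity levels
#'
#' The model stratifies the adult population into four ordered weekly
#' physical-activity levels, following the Health Survey for England (2021)
#' definitions based on minutes of moderate (MPA) and vigorous (VPA)
#' activity per week.
#'
#' @return `activity_levels()` returns the four level names in increasing
#'   order of activity: `"inactive" < "low" < "some" < "meets"`.
#' @export
#' @examples
#' activity_levels()
#' activity_level_definitions()
activity_levels <- function() {
  c("inactive", "low", "some", "meets")
}

#' @rdname activity_levels
#' @return `activity_level_definitions()` returns a tibble with the
#'   minutes-per-week thresholds defining each level (lower bounds of the
#'   MPA and VPA ranges; equivalent combinations also qualify).
#' @export
activity_level_definitions <- function() {
  tibble::tibble(
    level = activity_levels(),
    mpa_min = c(0, 30, 60, 150),
    mpa_max = c(29, 59, 149, Inf),
    vpa_min = c(0, 15, 30, 75),
    vpa_max = c(14, 29, 74, Inf),
    description = c(
      "Less than 30 min MPA or 15 min VPA per week",
      "30-59 min MPA or 15-29 min VPA per week",
      "60-149 min MPA or 30-74 min VPA per week",
      "At least 150 min MPA or 75 min VPA per week"
    )
  )
}

#' @rdname activity_levels
#' @return `cost_categories()` returns the five per-person lifetime cost
#'   categories; the first, third and fifth make up dementia-related costs.
#' @export
cost_categories <- function() {
  c("hc_dementia", "hc_other", "sc_dementia", "sc_other", "unpaid_care")
}

#' @rdname activity_levels
#' @return `dementia_related_categories()` returns the subset of
#'   [cost_categories()] counted as dementia-related: dementia health care,
#'   dementia social care, and unpaid carers.
#' @export
dementia_related_categories <- function() {
  c("hc_dementia", "sc_dementia", "unpaid_care")
}

#' @rdname activity_levels
#' @return `age_bands()` returns the five working-age bands (16-64) the
#'   headline model covers.
#' @export
age_bands <- function() {
  c("16-24", "25-34", "35-44", "45-54", "55-64")
}

#' @rdname activity_levels
#' @export
genders <- function() {
  c("women", "men")
}

# order a level column by increasing activity; errors on unknown values
as_activity_level <- function(x) {
  bad <- setdiff(unique(as.character(x)), activity_levels())
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Unknown activity level(s): %s (expected %s)",
      paste(bad, collapse = ", "), paste(activity_levels(), collapse = " < ")
    ), class = "cycledem_schema_error")
  }
  factor(as.character(x), levels = activity_levels(), ordered = TRUE)
}
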