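#' Apply a relative cycling-uptake increase
#'
#' The off-road cycle-lane scenarios scale the baseline cycling prevalence
#' of each gender by a relative increase:
#' `new = baseline * (1 + rel_increase)`, capped at 1 with a warning.
#'
#' @param baseline_prop baseline cycling prevalence, a fraction in (0, 1).
#' @param rel_increase relative increase as a fraction (0.403 = +40.3%).
#' @return the scenario cycling prevalence (fraction). Vectorised.
#' @export
#' @examples
#' apply_uptake(0.0889, 0.364) # men, scenario 1 -> 0.1213
#' apply_uptake(0.0279, 1.145) # women, scenario 2 -> 0.0599
apply_uptake <- function(baseline_prop, rel_increase) {
  stopifnot(all(baseline_prop > 0), all(baseline_prop < 1))
  if (any(rel_increase < 0)) {
    rlang::abort("rel_increase must be non-negative",
                 class = "cycledem_validation_error")
  }
  out <- baseline_prop * (1 + rel_increase)
  if (any(out > 1)) {
    rlang::warn("Scenario cycling prevalence exceeded 1 and was capped")
    out <- pmin(out, 1)
  }
  out
}

#' Gender-gap metrics for cycling prevalence
#'
#' @param women_prop,men_prop cycling prevalence fractions.
#' @return a list with `absolute`, the men-minus-women gap in percentage
#'   points, and `relative`, the men:women prevalence ratio.
#' @export
#' @examples
#' gender_gaps(0.040, 0.121) # absolute 8.1 pp, relative ~3.0
gender_gaps <- function(women_prop, men_prop) {
  if (any(women_prop <= 0)) {
    rlang::abort("Relative gap is undefined for zero women's prevalence",
                 class = "cycledem_validation_error")
  }
  list(
    absolute = (men_prop - women_prop) * 100,
    relative = men_prop / women_prop
  )
}

#' Built-in scenario presets
#'
#' The two published off-road cycle-lane scenarios: relative cycling-uptake
#' increases of 40.3% (women) / 36.4% (men) in scenario 1 and 114.5% /
#' 77.1% in scenario 2. The text variants 114% / 77% are accepted by
#' passing them explicitly; they round to the same scenario prevalence at
#' one decimal place.
#'
#' @return a tibble with columns `scenario`, `gender`, `rel_increase`.
#' @export
scenario_presets <- function() {
  tibble::tibble(
    scenario = rep(c("scenario1", "scenario2"), each = 2),
    gender = rep(c("women", "men"), 2),
    rel_increase = c(0.403, 0.364, 1.145, 0.771)
  )
}

# wide gender x band share matrix <-> long tidy distribution ---------------

dist_to_wide <- function(dist) {
  wide <- dist %>%
    dplyr::mutate(level = as.character(.data$level)) %>%
    tidyr::pivot_wider(names_from = "level", values_from = "share")
  for (lvl in activity_levels()) {
    if (!lvl %in% names(wide)) {
      rlang::abort(sprintf("Distribution is missing level '%s'", lvl),
                   class = "cycledem_schema_error")
    }
  }
  wide[, c("gender", "age_band", activity_levels())]
}

wide_to_dist <- function(wide) {
  wide %>%
    tidyr::pivot_longer(dplyr::all_of(activity_levels()),
                        names_to = "level", values_to = "share") %>%
    dplyr::mutate(level = as_activity_level(.data$level)) %>%
    dplyr::arrange(.data$gender, .data$age_band, .data$level)
}

# core one-level promotion on a share matrix with columns
# inactive/low/some/meets; delta is per row (fraction of row mass promoted)
promote_matrix <- function(S, delta, policy) {
  movable <- rowSums(S[, c("inactive", "low", "some"), drop = FALSE])
  if (policy == "proportional") {
    eff <- pmin(delta, movable)
    if (any(delta > movable + 1e-12)) {
      rlang::warn("Mover demand exceeded movable share mass; capped")
    }
    frac <- ifelse(movable > 0, eff / movable, 0)
    movers <- S[, c("inactive", "low", "some"), drop = FALSE] * frac
  } else if (policy == "uniform_fraction") {
    # every movable level promotes the same fraction of itself; the
    # denominator is the non-meets mass of a unit row
    non_meets <- 1 - S[, "meets"]
    f <- ifelse(non_meets > 0, pmin(delta / non_meets, 1), 0)
    if (any(delta > non_meets + 1e-12)) {
      rlang::warn("Promotion fraction exceeded 1; capped (all movers promoted)")
    }
    movers <- S[, c("inactive", "low", "some"), drop = FALSE] * f
  } else {
    rlang::abort(sprintf("Unknown redistribution policy '%s'", policy),
                 class = "cycledem_validation_error")
  }
  out <- S
  out[, "inactive"] <- S[, "inactive"] - movers[, "inactive"]
  out[, "low"] <- S[, "low"] - movers[, "low"] + movers[, "inactive"]
  out[, "some"] <- S[, "some"] - movers[, "some"] + movers[, "low"]
  out[, "meets"] <- S[, "meets"] + movers[, "some"]
  out
}

redistribute_wide <- function(wide, delta, policy) {
  S <- as.matrix(wide[, activity_levels()])
  wide[, activity_levels()] <- promote_matrix(S, delta, policy)
  wide
}

#' Redistribute the population across activity levels
#'
#' Models the stepwise activity response to new cycling uptake: a share of
#' each of the three non-top levels (inactive, low, some) is promoted one
#' level up; people already meeting the aerobic guidelines stay where they
#' are, so `meets` only receives mass. Total share mass is conserved
#' exactly and no share can go negative.
#'
#' The promoted mass per gender equals `delta_cycling` — the
#' percentage-point increase in cycling prevalence expressed as a fraction
#' (the new cyclists are the people who move up a level) — applied
#' identically across age bands. Two split policies are available:
#'
#' * `"proportional"` (default): the total mover mass is split across the
#'   three movable levels in proportion to their current shares.
#' * `"uniform_fraction"`: every movable level promotes the same fraction
#'   `delta_cycling / (1 - share_meets)` of itself.
#'
#' The two coincide whenever the three movable shares are equal. If the
#' requested mover mass exceeds the movable mass, it is capped (everyone
#' movable is promoted once) with a warning.
#'
#' @param dist a validated activity distribution (see
#'   [read_activity_distribution()]).
#' @param delta_cycling the increase in cycling prevalence as a fraction;
#'   either a single number or a named vector/list by gender.
#' @param policy `"proportional"` or `"uniform_fraction"`.
#' @return an activity distribution tibble of the same shape as `dist`.
#' @export
#' @examples
#' dist <- read_activity_distribution(
#'   cycledem_example("activity_levels_hse2021.csv"))
#' redistribute_activity(dist, c(women = 0.0112, men = 0.0324))
redistribute_activity <- function(dist, delta_cycling,
                                  policy = c("proportional",
                                             "uniform_fraction")) {
  policy <- match.arg(policy)
  if (any(unlist(delta_cycling) < 0)) {
    rlang::abort("delta_cycling must be non-negative",
                 class = "cycledem_validation_error")
  }
  wide <- dist_to_wide(dist)
  if (length(delta_cycling) == 1 && is.null(names(delta_cycling))) {
    delta <- rep(as.numeric(delta_cycling), nrow(wide))
  } else {
    delta_cycling <- unlist(delta_cycling)
    missing <- setdiff(unique(wide$gender), names(delta_cycling))
    if (length(missing) > 0) {
      rlang::abort(sprintf("delta_cycling missing gender(s): %s",
                           paste(missing, collapse = ", ")),
                   class = "cycledem_validation_error")
    }
    delta <- as.numeric(delta_cycling[wide$gender])
  }
  wide_to_dist(redistribute_wide(wide, delta, policy))
}

#' Population counts by gender, age band and activity level
#'
#' Multiplies population counts by activity-level shares. Fractional
#' persons are kept by default; `rounding = "largest_remainder"` rounds to
#' integers while conserving each (gender, age band) total exactly.
#'
#' @param pop population tibble (`gender`, `age_band`, `count`).
#' @param dist activity distribution tibble.
#' @param rounding `"none"` (default, fractional persons) or
#'   `"largest_remainder"`.
#' @param normalize if `TRUE`, rescale each (gender, age band) share row to
#'   sum to exactly 1 before multiplying, so level counts add back to the
#'   population exactly. Off by default: the printed source percentages are
#'   rounded and are used as printed.
#' @return a tibble with columns `gender`, `age_band`, `level`, `count`.
#' @export
counts_by_level <- function(pop, dist, rounding = c("none",
                                                    "largest_remainder"),
                            normalize = FALSE) {
  rounding <- match.arg(rounding)
  if (normalize) {
    dist <- dist %>%
      dplyr::group_by(.data$gender, .data$age_band) %>%
      dplyr::mutate(share = .data$share / sum(.data$share)) %>%
      dplyr::ungroup()
  }
  pop_keys <- dplyr::distinct(pop, .data$gender, .data$age_band)
  dist_keys <- dplyr::distinct(dist, .data$gender, .data$age_band)
  missing <- dplyr::anti_join(pop_keys, dist_keys,
                              by = c("gender", "age_band"))
  if (nrow(missing) > 0) {
    rlang::abort(sprintf(
      "No activity shares for population key(s): %s",
      paste(paste(missing$gender, missing$age_band, sep = "/"),
            collapse = ", ")
    ), class = "cycledem_validation_error")
  }
  counts <- dist %>%
    dplyr::inner_join(pop, by = c("gender", "age_band")) %>%
    dplyr::mutate(count = .data$count * .data$share) %>%
    dplyr::select("gender", "age_band", "level", "count")
  if (rounding == "largest_remainder") {
    counts <- counts %>%
      dplyr::group_by(.data$gender, .data$age_band) %>%
      dplyr::mutate(count = largest_remainder_round(.data$count)) %>%
      dplyr::ungroup()
  }
  counts
}

# integer apportionment conserving the (rounded) group total
largest_remainder_round <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}
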