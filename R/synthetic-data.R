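#' Generate a census-like population table
#'
#' Deterministic synthetic stand-in for a census population count table:
#' `total` persons split between genders and across the five 16-64 age
#' bands by the given weights, apportioned to whole persons with the
#' largest-remainder rule so the grand total is conserved exactly. Clearly
#' synthetic — it reconstructs no actual census figures. The default
#' emulates the order of magnitude of the UK population aged 16-64
#' (35 million, 50.3% women).
#'
#' @param total total number of persons.
#' @param gender_split fraction of the total who are women.
#' @param age_band_weights weights over the five bands, summing to 1
#'   (within 1e-9); a single unnamed vector applies to both genders.
#' @param seed integer seed (reserved for perturbed variants; the default
#'   generator is deterministic).
#' @return a population tibble `gender`, `age_band`, `count`.
#' @export
#' @examples
#' simulate_population(1000, 0.5)
simulate_population <- function(total = 35e6, gender_split = 0.503,
                                age_band_weights = rep(0.2, 5), seed = 1) {
  stopifnot(total >= 0, gender_split >= 0, gender_split <= 1)
  if (abs(sum(age_band_weights) - 1) > 1e-9) {
    rlang::abort(sprintf("Age-band weights sum to %.10f, not 1",
                         sum(age_band_weights)),
                 class = "cycledem_validation_error")
  }
  if (length(age_band_weights) != length(age_bands())) {
    rlang::abort(sprintf("Need %d age-band weights", length(age_bands())),
                 class = "cycledem_validation_error")
  }
  raw <- c(total * gender_split * age_band_weights,
           total * (1 - gender_split) * age_band_weights)
  counts <- largest_remainder_round(raw)
  tibble::tibble(
    gender = rep(genders(), each = length(age_bands())),
    age_band = rep(age_bands(), 2),
    count = counts
  )
}

#' Perturb an activity distribution on the simplex
#'
#' Draws, for every (gender, age band) row, a random point on the
#' four-level simplex centred on the template's shares: Dirichlet with
#' parameter `concentration * share` per level (sampled as normalised
#' Gamma variates). Rows sum to exactly 1 by construction, so every draw
#' passes the distribution validator. Larger `concentration` concentrates
#' draws around the template; zero template shares are floored at a small
#' epsilon first.
#'
#' @param template a validated activity distribution.
#' @param concentration Dirichlet concentration (> 0); default 200 keeps
#'   draws within a few percentage points of the template.
#' @param seed integer seed.
#' @param eps floor applied to zero template shares before scaling.
#' @return an activity distribution tibble.
#' @export
simulate_activity_distribution <- function(template, concentration = 200,
                                           seed = 1, eps = 1e-6) {
  stopifnot(concentration > 0)
  wide <- dist_to_wide(template)
  S <- as.matrix(wide[, activity_levels()])
  if (any(S == 0)) {
    rlang::inform("Zero template share(s) floored at eps before scaling")
    S[S == 0] <- eps
  }
  S <- S / rowSums(S)
  withr::with_seed(seed, {
    G <- matrix(stats::rgamma(length(S), shape = concentration * S,
                              scale = 1),
                nrow = nrow(S))
  })
  wide[, activity_levels()] <- G / rowSums(G)
  out <- wide_to_dist(wide)
  validate_activity_distribution(out, tol = 0.02)
  out
}

# the qualitative cost pattern the generator preserves: dementia-specific
# categories maximal for the inactive; other-disease categories
# non-decreasing with activity (longevity effect)
cost_orderings_hold <- function(costs) {
  wide <- costs %>%
    dplyr::mutate(level = as.character(.data$level)) %>%
    tidyr::pivot_wider(names_from = "level", values_from = "cost")
  ok <- TRUE
  for (i in seq_len(nrow(wide))) {
    v <- as.numeric(wide[i, activity_levels()])
    if (wide$category[i] %in% dementia_related_categories()) {
      ok <- ok && all(v[1] >= v[-1])
    } else {
      ok <- ok && !is.unsorted(v)
    }
  }
  ok
}

#' Generate a noisy per-person cost table
#'
#' Multiplies every cost in `base` by independent Gamma noise with mean 1
#' and coefficient of variation `noise_cv`, rejection-sampling each
#' (gender, category) row until the qualitative orderings of the published
#' table hold: dementia-specific categories highest for the inactive,
#' other-disease categories non-decreasing with activity. `noise_cv = 0`
#' returns `base` unchanged.
#'
#' @param base a validated cost table.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param max_attempts per-row rejection-sampling budget.
#' @return a cost-table tibble passing [validate_cost_table()] and the
#'   ordering checks.
#' @export
simulate_cost_table <- function(base, noise_cv = 0.05, seed = 1,
                                max_attempts = 1000) {
  stopifnot(noise_cv >= 0)
  validate_cost_table(base)
  if (noise_cv == 0) {
    return(base)
  }
  shape <- 1 / noise_cv^2
  row_ok <- function(v, category) {
    if (category %in% dementia_related_categories()) {
      all(v[1] >= v[-1])
    } else {
      !is.unsorted(v)
    }
  }
  out <- base %>%
    dplyr::mutate(level = as_activity_level(.data$level)) %>%
    dplyr::arrange(.data$gender, .data$category, .data$level)
  withr::with_seed(seed, {
    for (g in unique(out$gender)) {
      for (cat in unique(out$category)) {
        idx <- which(out$gender == g & out$category == cat)
        accepted <- FALSE
        for (attempt in seq_len(max_attempts)) {
          v <- out$cost[idx] * stats::rgamma(length(idx), shape = shape,
                                             scale = 1 / shape)
          if (row_ok(v, cat)) {
            out$cost[idx] <- v
            accepted <- TRUE
            break
          }
        }
        if (!accepted) {
          rlang::abort(sprintf(
            "No ordering-preserving draw for (%s, %s) in %d attempts; lower noise_cv",
            g, cat, max_attempts
          ), class = "cycledem_validation_error")
        }
      }
    }
  })
  stopifnot(cost_orderings_hold(out))
  out
}

#' Generate Gompertz-shaped transition rates
#'
#' Synthetic age schedules for the cohort engine: dementia incidence and
#' background mortality follow Gompertz curves
#' `p(age) = intercept * exp(slope * (age - 16))`, and mortality with
#' dementia is background mortality times a constant excess factor. An
#' error names the first age at which any probability would exceed 1.
#'
#' @param gender gender label for the table.
#' @param ages integer ages to cover (default 16:99, one row per cycle of
#'   the default engine grid).
#' @param inc_intercept,inc_slope Gompertz parameters of annual dementia
#'   incidence for the inactive reference.
#' @param mort_intercept,mort_slope Gompertz parameters of annual
#'   background (no-dementia) mortality.
#' @param dem_excess multiplicative excess mortality with dementia (>= 1).
#' @param seed integer seed (reserved; the default curves are
#'   deterministic).
#' @return a validated transition-rate tibble.
#' @export
#' @examples
#' r <- simulate_transition_rates("women")
#' head(r)
simulate_transition_rates <- function(gender = "women", ages = 16:99,
                                      inc_intercept = 2e-5,
                                      inc_slope = 0.11,
                                      mort_intercept = 4e-4,
                                      mort_slope = 0.08,
                                      dem_excess = 2.5, seed = 1) {
  stopifnot(dem_excess >= 1)
  gomp <- function(a, b, what) {
    p <- a * exp(b * (ages - 16))
    over <- p > 1
    if (any(over)) {
      rlang::abort(sprintf("%s exceeds 1 at age %d", what,
                           ages[which(over)[1]]),
                   class = "cycledem_validation_error")
    }
    p
  }
  inc <- gomp(inc_intercept, inc_slope, "Incidence")
  mort <- gomp(mort_intercept, mort_slope, "Mortality")
  mort_dem <- gomp(mort_intercept * dem_excess, mort_slope,
                   "Dementia mortality")
  transition_rates(ages, inc, mort, mort_dem, gender = gender)
}
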