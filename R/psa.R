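#' 95% interval for a cost parameter from its mean
#'
#' Cost parameters enter the probabilistic sensitivity analysis with a 95%
#' confidence interval of +/- 20% around the base-case mean.
#'
#' @param mean non-negative cost mean.
#' @return named vector `c(low, high)` = `(0.8, 1.2) * mean`. Vectorised.
#' @export
#' @examples
#' cost_ci_from_mean(100) # 80, 120
cost_ci_from_mean <- function(mean) {
  if (any(mean < 0)) {
    rlang::abort("Cost mean must be non-negative",
                 class = "cycledem_validation_error")
  }
  c(low = 0.8 * mean, high = 1.2 * mean)
}

#' Fit a PSA distribution by method of moments
#'
#' Converts a (mean, 95% CI) specification into distribution parameters
#' using `sd = (high - low) / (2 * 1.96)`:
#' * `gamma` (costs, non-negative): `shape = mean^2 / var`,
#'   `scale = var / mean`;
#' * `beta` (probabilities in \[0, 1\]):
#'   `alpha = mean * nu`, `beta = (1 - mean) * nu` with
#'   `nu = mean * (1 - mean) / var - 1`;
#' * zero-variance (or `family = "fixed"`) specifications degenerate to a
#'   point mass at the mean.
#'
#' @param family `"beta"`, `"gamma"` or `"fixed"`.
#' @param mean the base-case mean.
#' @param ci95 length-2 vector `(low, high)`; ignored for `"fixed"`.
#' @return a list with `family` and the fitted parameters (`shape`/`scale`
#'   for gamma, `alpha`/`beta` for beta, `mean` always).
#' @export
#' @examples
#' fit_psa_distribution("gamma", 100, c(80, 120))
fit_psa_distribution <- function(family = c("beta", "gamma", "fixed"),
                                 mean, ci95 = NULL) {
  family <- match.arg(family)
  if (family == "fixed") {
    return(list(family = "fixed", mean = mean))
  }
  stopifnot(length(ci95) == 2)
  low <- ci95[[1]]; high <- ci95[[2]]
  if (!(low <= mean && mean <= high)) {
    rlang::abort(sprintf(
      "Mean %.4g outside its 95%% CI (%.4g, %.4g)", mean, low, high
    ), class = "cycledem_validation_error")
  }
  sd <- (high - low) / (2 * 1.96)
  v <- sd^2
  if (v <= 0 || mean == 0 || (family == "beta" && mean == 1)) {
    return(list(family = "fixed", mean = mean))
  }
  if (family == "gamma") {
    if (mean < 0) {
      rlang::abort("Gamma requires a non-negative mean",
                   class = "cycledem_validation_error")
    }
    list(family = "gamma", mean = mean,
         shape = mean^2 / v, scale = v / mean)
  } else {
    if (mean < 0 || mean > 1) {
      rlang::abort("Beta requires a mean in [0, 1]",
                   class = "cycledem_validation_error")
    }
    if (v >= mean * (1 - mean)) {
      rlang::abort(sprintf(
        "Implied variance %.3g >= mean(1-mean) = %.3g: invalid beta moments",
        v, mean * (1 - mean)
      ), class = "cycledem_validation_error")
    }
    nu <- mean * (1 - mean) / v - 1
    list(family = "beta", mean = mean,
         alpha = mean * nu, beta = (1 - mean) * nu)
  }
}

#' @rdname fit_psa_distribution
#' @param fit a fitted distribution from `fit_psa_distribution()`.
#' @param n number of draws.
#' @return `sample_psa_distribution()` returns `n` draws.
#' @export
sample_psa_distribution <- function(fit, n) {
  switch(fit$family,
    fixed = rep(fit$mean, n),
    gamma = stats::rgamma(n, shape = fit$shape, scale = fit$scale),
    beta = stats::rbeta(n, shape1 = fit$alpha, shape2 = fit$beta),
    rlang::abort(sprintf("Unknown family '%s'", fit$family),
                 class = "cycledem_validation_error")
  )
}

# deterministic sub-stream seed per parameter id: a string hash folded into
# the global seed, so adding a parameter never shuffles another's draws
param_seed <- function(seed, id) {
  h <- 0
  for (code in utf8ToInt(id)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Default PSA parameter specifications
#'
#' Builds the per-parameter specification table the PSA samples from:
#' activity-level shares and baseline cycling prevalences get Beta
#' distributions, per-person costs and relative uptake increases get Gamma
#' distributions, each with a 95% CI of +/- `ci_halfwidth` (default 20%)
#' around its base-case mean. Rows can be edited — e.g. family set to
#' `"fixed"` — before passing to [run_psa()].
#'
#' @param counts baseline level counts (`gender`, `level`, `count`).
#' @param cost_table per-person cost table.
#' @param baseline_props named baseline cycling prevalences per gender.
#' @param uptake uptake-increase tibble (see [scenario_presets()]).
#' @param ci_halfwidth half-width of the 95% CI as a fraction of the mean.
#' @return a tibble `id`, `family`, `mean`, `low`, `high`.
#' @export
default_psa_specs <- function(counts, cost_table, baseline_props,
                              uptake = scenario_presets(),
                              ci_halfwidth = 0.2) {
  shares <- counts %>%
    dplyr::mutate(level = as.character(.data$level)) %>%
    dplyr::group_by(.data$gender, .data$level) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::group_by(.data$gender) %>%
    dplyr::mutate(share = .data$count / sum(.data$count)) %>%
    dplyr::ungroup()
  specs <- dplyr::bind_rows(
    tibble::tibble(
      id = paste("share", shares$gender, shares$level, sep = ":"),
      family = "beta", mean = shares$share
    ),
    tibble::tibble(
      id = paste("cost", cost_table$gender, as.character(cost_table$level),
                 cost_table$category, sep = ":"),
      family = "gamma", mean = cost_table$cost
    ),
    tibble::tibble(
      id = paste("cycling", names(baseline_props), sep = ":"),
      family = "beta", mean = as.numeric(baseline_props)
    ),
    tibble::tibble(
      id = paste("uptake", uptake$gender, uptake$scenario, sep = ":"),
      family = "gamma", mean = uptake$rel_increase
    )
  )
  specs %>%
    dplyr::mutate(low = (1 - ci_halfwidth) * .data$mean,
                  high = (1 + ci_halfwidth) * .data$mean,
                  family = ifelse(.data$mean == 0, "fixed", .data$family))
}

#' Probabilistic sensitivity analysis of the scenario model
#'
#' Draws every parameter independently from its fitted distribution
#' (Beta for probabilities, Gamma for costs and uptake increases, point
#' mass for `"fixed"`), re-runs the scenario model per draw, and
#' summarises the dementia-related and total lifetime-cost differences as
#' means with 2.5/97.5 percentile intervals. Sampled share vectors are
#' renormalised onto the simplex; the number of draws needing
#' renormalisation beyond numerical noise is reported.
#'
#' Reproducible: a single integer `seed` governs all draws through
#' deterministic per-parameter sub-streams, so the same seed gives
#' bit-identical results and adding a parameter does not change the
#' others' draws.
#'
#' @inheritParams default_psa_specs
#' @param policy redistribution policy, see [redistribute_activity()].
#' @param n_draws number of simulations (default 1000).
#' @param seed integer seed.
#' @param specs parameter specification table; defaults to
#'   [default_psa_specs()] on the supplied inputs.
#' @return a list with `draws` (tibble `draw`, `scenario`, `scope`,
#'   `baseline_bn`, `scenario_bn`, `diff_bn`), `summary` (mean and 2.5/97.5
#'   percentiles of `diff_bn` per scenario and scope), `n_renormalised`,
#'   `n_draws` and `seed`.
#' @export
run_psa <- function(counts, cost_table, baseline_props,
                    uptake = scenario_presets(),
                    policy = c("proportional", "uniform_fraction"),
                    n_draws = 1000, seed = 1, specs = NULL) {
  policy <- match.arg(policy)
  stopifnot(n_draws >= 1)
  if (is.null(specs)) {
    specs <- default_psa_specs(counts, cost_table, baseline_props, uptake)
  }
  gs <- c("women", "men")
  lv <- activity_levels()
  pop <- counts %>%
    dplyr::group_by(.data$gender) %>%
    dplyr::summarise(pop = sum(.data$count), .groups = "drop")
  pop <- setNames(pop$pop, pop$gender)[gs]

  draws_mat <- matrix(NA_real_, nrow = n_draws, ncol = nrow(specs),
                      dimnames = list(NULL, specs$id))
  for (i in seq_len(nrow(specs))) {
    fit <- fit_psa_distribution(specs$family[i], specs$mean[i],
                                c(specs$low[i], specs$high[i]))
    draws_mat[, i] <- withr::with_seed(
      param_seed(seed, specs$id[i]),
      sample_psa_distribution(fit, n_draws)
    )
  }

  col <- function(ids) draws_mat[, ids, drop = FALSE]
  share_ids <- outer(gs, lv, function(g, l) paste("share", g, l, sep = ":"))
  dem_cats <- dementia_related_categories()
  cost_id <- function(g, l, cat) paste("cost", g, l, cat, sep = ":")
  scenarios <- unique(uptake$scenario)
  uptake_key <- function(g, sc) paste("uptake", g, sc, sep = ":")

  n_renorm <- 0L
  out <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    S <- matrix(draws_mat[d, share_ids], nrow = 2,
                dimnames = list(gs, lv))
    rs <- rowSums(S)
    if (any(abs(rs - 1) > 1e-12)) n_renorm <- n_renorm + 1L
    S <- S / rs
    costs_dem <- costs_tot <- matrix(0, nrow = 2, ncol = 4,
                                     dimnames = list(gs, lv))
    for (g in gs) for (l in lv) {
      v <- draws_mat[d, cost_id(g, l, cost_categories())]
      costs_tot[g, l] <- sum(v)
      costs_dem[g, l] <- sum(v[paste("cost", g, l, dem_cats, sep = ":")])
    }
    p0 <- draws_mat[d, paste("cycling", gs, sep = ":")]
    base_counts <- S * pop
    base_dem <- sum(base_counts * costs_dem) / 1e6
    base_tot <- sum(base_counts * costs_tot) / 1e6
    rows <- vector("list", length(scenarios))
    for (si in seq_along(scenarios)) {
      sc <- scenarios[si]
      rel <- draws_mat[d, uptake_key(gs, sc)]
      p1 <- pmin(p0 * (1 + rel), 1)
      S2 <- promote_matrix(S, p1 - p0, policy)
      sc_counts <- S2 * pop
      sc_dem <- sum(sc_counts * costs_dem) / 1e6
      sc_tot <- sum(sc_counts * costs_tot) / 1e6
      rows[[si]] <- tibble::tibble(
        draw = d, scenario = sc,
        scope = c("dementia_related", "total"),
        baseline_bn = c(base_dem, base_tot),
        scenario_bn = c(sc_dem, sc_tot),
        diff_bn = c(sc_dem - base_dem, sc_tot - base_tot)
      )
    }
    out[[d]] <- dplyr::bind_rows(rows)
  }
  draws <- dplyr::bind_rows(out)
  if (n_renorm > 0) {
    rlang::inform(sprintf(
      "PSA: %d of %d draws had share vectors renormalised onto the simplex",
      n_renorm, n_draws
    ))
  }
  summary <- draws %>%
    dplyr::group_by(.data$scenario, .data$scope) %>%
    dplyr::summarise(
      mean = mean(.data$diff_bn),
      lower = as.numeric(stats::quantile(.data$diff_bn, 0.025, type = 7)),
      upper = as.numeric(stats::quantile(.data$diff_bn, 0.975, type = 7)),
      .groups = "drop"
    )
  list(draws = draws, summary = summary, n_renormalised = n_renorm,
       n_draws = n_draws, seed = seed)
}

#' Freeze a PSA specification to its means
#'
#' Sets every parameter's family to `"fixed"`, so the PSA degenerates to
#' the deterministic model — useful for equivalence checks.
#'
#' @param specs a specification tibble from [default_psa_specs()].
#' @return the tibble with `family = "fixed"` everywhere.
#' @export
fix_psa_specs <- function(specs) {
  dplyr::mutate(specs, family = "fixed")
}
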