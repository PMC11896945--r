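# shared fixtures built in code

fixture_dist <- function() {
  read_activity_distribution(cycledem_example("activity_levels_hse2021.csv"))
}

fixture_costs <- function() {
  read_cost_table(cycledem_example("lifetime_costs_per_person.csv"))
}

fixture_published <- function() {
  read_published_population_costs(
    cycledem_example("published_population_costs.csv"))
}

fixture_summary <- function() {
  read_published_cost_summary(cycledem_example("published_cost_summary.csv"))
}

fixture_baseline_props <- function() {
  c(women = 0.0279, men = 0.0889)
}

# a small valid two-gender, two-band distribution built in code
toy_dist <- function(shares = c(0.24, 0.04, 0.14, 0.57) / 0.99) {
  tidyr::crossing(gender = c("women", "men"), age_band = c("16-24", "25-34")) |>
    dplyr::mutate(shares = list(shares)) |>
    tidyr::unnest(shares) |>
    dplyr::mutate(level = rep(c("inactive", "low", "some", "meets"), 4),
                  share = shares, shares = NULL)
}

toy_pop <- function(count = 1000) {
  tidyr::crossing(gender = c("women", "men"),
                  age_band = c("16-24", "25-34")) |>
    dplyr::mutate(count = count)
}

# independent transition-matrix-power oracle for the three-state engine:
# rebuilds each annual matrix from the stated transition rules and
# accumulates the product explicitly
oracle_occupancy <- function(rates, rr, start_age, n_cycles) {
  state <- c(1, 0, 0)
  out <- matrix(NA_real_, nrow = n_cycles + 1, ncol = 3)
  out[1, ] <- state
  for (k in seq_len(n_cycles)) {
    row <- rates[rates$age == start_age + k - 1, ]
    q <- row$mort_nodem
    qd <- row$mort_dem
    onset <- min(row$incidence * rr, 1)
    P <- rbind(
      c((1 - q) * (1 - onset), (1 - q) * onset, q),
      c(0, 1 - qd, qd),
      c(0, 0, 1)
    )
    state <- as.numeric(state %*% P)
    out[k + 1, ] <- state
  }
  colnames(out) <- c("nodem", "dem", "dead")
  out
}

# random simplex rows via normalised gamma draws
random_simplex <- function(n, k = 4) {
  g <- matrix(stats::rgamma(n * k, shape = 1), nrow = n)
  g / rowSums(g)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}
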