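test_that("trajectories match the transition-matrix-power oracle exactly", {
  # 3-cycle toy: incidence 0.1, mortality 0.05 / 0.2, rr 1
  r <- transition_rates(60:64, incidence = 0.1, mort_nodem = 0.05,
                        mort_dem = 0.2)
  traj <- propagate(r, rr = 1, start_age = 60, max_age = 63)
  oracle <- oracle_occupancy(r, rr = 1, start_age = 60, n_cycles = 3)
  expect_equal(as.matrix(traj[, c("nodem", "dem", "dead")]), oracle,
               ignore_attr = TRUE, tolerance = 1e-15)

  # randomized instances with <= 5 cycles, varying rr
  set.seed(11)
  for (k in 1:25) {
    n <- sample(1:5, 1)
    mort <- runif(n, 0, 0.4)
    r <- transition_rates(20:(20 + n - 1) + 0L,
                          incidence = runif(n, 0, 0.5),
                          mort_nodem = mort,
                          mort_dem = mort + runif(n, 0, 0.4))
    rr <- sample(c(0.62, 0.65, 1), 1)
    traj <- propagate(r, rr = rr, start_age = 20, max_age = 20 + n)
    oracle <- oracle_occupancy(r, rr = rr, start_age = 20, n_cycles = n)
    expect_equal(as.matrix(traj[, c("nodem", "dem", "dead")]), oracle,
                 ignore_attr = TRUE, tolerance = 1e-15)
  }
})

test_that("occupancy is normalised every cycle and death is absorbing", {
  r <- simulate_transition_rates("women")
  traj <- propagate(r, rr = 0.65)
  expect_true(all(abs(traj$nodem + traj$dem + traj$dead - 1) < 1e-12))
  expect_true(all(diff(traj$dead) >= 0))
  expect_true(all(traj$nodem >= 0 & traj$dem >= 0))
})

test_that("degenerate rate schedules behave as expected", {
  # zero incidence: nobody ever develops dementia
  r0 <- transition_rates(16:99, incidence = 0, mort_nodem = 0.01,
                         mort_dem = 0.02)
  traj0 <- propagate(r0, rr = 1)
  expect_equal(traj0$dem, rep(0, nrow(traj0)))

  # certain death in the first cycle: no dementia years accrue
  r1 <- transition_rates(16:99, incidence = 0.1, mort_nodem = 1,
                         mort_dem = 1)
  traj1 <- propagate(r1, rr = 1)
  expect_equal(traj1$dead[-1], rep(1, nrow(traj1) - 1))
  ac <- list(hc_dementia = 1, hc_other = 1, sc_dementia = 1, sc_other = 1,
             unpaid_rate = 1)
  expect_equal(lifetime_outputs(traj1, ac)$years_with_dementia, 0)

  # rr-scaled incidence above 1 is rejected
  r2 <- transition_rates(16:17, incidence = 0.9, mort_nodem = 0,
                         mort_dem = 0)
  expect_error(propagate(r2, rr = 1.2, start_age = 16, max_age = 18),
               class = "cycledem_validation_error")
  # rates must cover the age grid
  expect_error(propagate(r2, rr = 1, start_age = 16, max_age = 30),
               class = "cycledem_validation_error")
  # dementia excess mortality is enforced
  expect_error(transition_rates(16, 0.1, mort_nodem = 0.5, mort_dem = 0.2),
               class = "cycledem_validation_error")
})

test_that("lifetime outputs price person-years correctly", {
  # hand-built trajectory: full dementia occupancy for exactly 2 cycles
  traj <- tibble::tibble(cycle = 0:2, age = 60:62,
                         nodem = c(1, 0, 0), dem = c(0, 1, 1),
                         dead = c(0, 0, 0))
  ac <- list(hc_dementia = 0, hc_other = 0, sc_dementia = 0, sc_other = 0,
             unpaid_rate = 1115)
  out <- lifetime_outputs(traj, ac)
  expect_equal(out$years_with_dementia, 2)
  expect_equal(out$unpaid_care, 2.23) # GBP thousands: 2 * 1115 / 1000

  # zero annual costs give zero lifetime costs
  ac0 <- list(hc_dementia = 0, hc_other = 0, sc_dementia = 0, sc_other = 0,
              unpaid_rate = 0)
  r <- simulate_transition_rates("women")
  out0 <- lifetime_outputs(propagate(r, rr = 1), ac0)
  expect_equal(out0$total, 0)

  expect_error(lifetime_outputs(traj, ac, discount_rate = -0.01),
               class = "cycledem_validation_error")
  expect_error(lifetime_outputs(traj, ac[-1]),
               class = "cycledem_schema_error")
})

test_that("discounting agrees with the closed-form geometric sum", {
  # constant occupancy: alive forever, no dementia
  n <- 40
  traj <- tibble::tibble(cycle = 0:n, age = 16:(16 + n),
                         nodem = 1, dem = 0, dead = 0)
  ac <- list(hc_dementia = 0, hc_other = 1000, sc_dementia = 0,
             sc_other = 0, unpaid_rate = 0)
  rte <- 0.035
  out <- lifetime_outputs(traj, ac, discount_rate = rte)
  v <- 1 / (1 + rte)
  closed_form <- v * (1 - v^n) / (1 - v) # sum of v^t, t = 1..n
  expect_equal(out$hc_other, closed_form, tolerance = 1e-12)
  # zero discount equals the undiscounted person-year count
  expect_equal(lifetime_outputs(traj, ac)$hc_other, n)
})

test_that("cohort outputs are monotone in the relative risk", {
  r <- simulate_transition_rates("women")
  ac <- list(hc_dementia = 3000, hc_other = 800, sc_dementia = 1500,
             sc_other = 180, unpaid_rate = 1115)
  rrs <- c(0.62, 0.65, 0.8, 1)
  outs <- lapply(rrs, function(x) lifetime_outputs(propagate(r, rr = x), ac))
  ywd <- sapply(outs, `[[`, "years_with_dementia")
  dem_cost <- sapply(outs, function(o) o$hc_dementia + o$sc_dementia +
                       o$unpaid_care)
  other_cost <- sapply(outs, function(o) o$hc_other + o$sc_other)
  expect_true(all(diff(ywd) > 0))
  expect_true(all(diff(dem_cost) > 0))
  expect_true(all(diff(other_cost) < 0)) # longevity effect
})

test_that("the engine regenerates the qualitative per-person cost pattern", {
  rr <- read_relative_risks(cycledem_example("dementia_relative_risks.csv"))
  rates <- list(women = simulate_transition_rates("women"),
                men = simulate_transition_rates("men",
                                                mort_intercept = 5e-4))
  ac <- list(hc_dementia = 3000, hc_other = 800, sc_dementia = 1500,
             sc_other = 180, unpaid_rate = 1115)
  tab <- cohort_cost_table(rates, rr, list(women = ac, men = ac))
  expect_silent(validate_cost_table(tab))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(tab, level = as.character(level)),
    names_from = level, values_from = cost)
  dem <- dplyr::filter(wide, category == "hc_dementia")
  expect_true(all(dem$meets < dem$low & dem$low < dem$inactive))
  oth <- dplyr::filter(wide, category == "hc_other")
  expect_true(all(oth$inactive < oth$low & oth$some <= oth$meets))

  # rr = 1 everywhere: identical costs across levels
  rr1 <- dplyr::mutate(rr, rr = 1)
  tab1 <- cohort_cost_table(rates["women"], rr1, list(women = ac))
  spread <- tab1 |>
    dplyr::group_by(category) |>
    dplyr::summarise(spread = diff(range(cost)))
  expect_true(all(spread$spread < 1e-12))
})
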