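test_that("apply_uptake reproduces the published scenario prevalences", {
  # men, scenario 1: 8.89% * 1.364 = 12.13% -> printed 12.1
  expect_equal(round(100 * apply_uptake(0.0889, 0.364), 1), 12.1)
  # women, scenario 2: 2.79% * 2.145 = 5.98% -> printed 6.0
  expect_equal(round(100 * apply_uptake(0.0279, 1.145), 1), 6.0)
  # identity at zero increase
  p <- c(0.01, 0.2, 0.97)
  expect_equal(apply_uptake(p, 0), p)
  # capped at 1 with a warning
  expect_warning(out <- apply_uptake(0.9, 0.5), "capped")
  expect_equal(out, 1)
  expect_error(apply_uptake(0.5, -0.1), class = "cycledem_validation_error")
})

test_that("gender gaps match the published gap rows", {
  s1 <- gender_gaps(0.040, 0.121)
  expect_equal(round(s1$absolute, 1), 8.1)
  expect_equal(round(s1$relative, 1), 3.0)
  s2 <- gender_gaps(0.060, 0.158)
  expect_equal(round(s2$absolute, 1), 9.8)
  expect_equal(round(s2$relative, 1), 2.6)
  eq <- gender_gaps(0.3, 0.3)
  expect_equal(eq$absolute, 0)
  expect_equal(eq$relative, 1)
  expect_error(gender_gaps(0, 0.1), class = "cycledem_validation_error")
})

test_that("redistribution with zero delta is the identity", {
  dist <- fixture_dist()
  for (policy in c("proportional", "uniform_fraction")) {
    expect_equal(redistribute_activity(dist, 0, policy = policy),
                 dplyr::arrange(dist, gender, age_band, level))
  }
})

test_that("proportional redistribution matches a hand-enumerated oracle", {
  shares <- c(inactive = 0.24, low = 0.04, some = 0.14, meets = 0.57)
  dist <- toy_dist(unname(shares) / 0.99)
  delta <- 0.0121
  # oracle: mover mass delta split across movable levels by current share
  s <- shares / 0.99
  movable <- s[["inactive"]] + s[["low"]] + s[["some"]]
  m <- delta * s[c("inactive", "low", "some")] / movable
  expected <- c(
    inactive = s[["inactive"]] - m[["inactive"]],
    low = s[["low"]] - m[["low"]] + m[["inactive"]],
    some = s[["some"]] - m[["some"]] + m[["low"]],
    meets = s[["meets"]] + m[["some"]]
  )
  out <- redistribute_activity(dist, delta, policy = "proportional")
  row <- dplyr::filter(out, gender == "women", age_band == "16-24")
  expect_equal(setNames(row$share, as.character(row$level)),
               expected[as.character(row$level)])
})

test_that("uniform_fraction promotes every movable person once at the cap", {
  dist <- toy_dist(c(0.3, 0.2, 0.2, 0.3))
  # delta at (and beyond) 1 - share_meets promotes all movable mass
  out <- redistribute_activity(dist, 0.7, policy = "uniform_fraction")
  row <- dplyr::filter(out, gender == "men", age_band == "16-24")
  expect_equal(setNames(row$share, as.character(row$level)),
               c(inactive = 0, low = 0.3, some = 0.2, meets = 0.5))
  expect_equal(sum(row$share), 1)
  expect_warning(redistribute_activity(dist, 0.9, policy = "uniform_fraction"),
                 "capped")
})

test_that("redistribution conserves mass, promotes monotonically, one level only", {
  set.seed(42)
  n <- 250
  S <- random_simplex(n)
  colnames(S) <- activity_levels()
  dist <- tibble::tibble(
    gender = rep(c("women", "men"), length.out = n),
    age_band = paste0("b", seq_len(n)),
    inactive = S[, 1], low = S[, 2], some = S[, 3], meets = S[, 4]
  ) |>
    tidyr::pivot_longer(dplyr::all_of(activity_levels()),
                        names_to = "level", values_to = "share")
  deltas <- runif(1, 0, 0.05)
  for (policy in c("proportional", "uniform_fraction")) {
    out <- redistribute_activity(dist, deltas, policy = policy)
    wide_in <- tidyr::pivot_wider(dist, names_from = level,
                                  values_from = share)
    wide_out <- tidyr::pivot_wider(
      dplyr::mutate(out, level = as.character(level)),
      names_from = level, values_from = share)
    wide_out <- wide_out[match(paste(wide_in$gender, wide_in$age_band),
                               paste(wide_out$gender, wide_out$age_band)), ]
    # mass conservation at machine precision
    expect_equal(rowSums(wide_out[, activity_levels()]),
                 rowSums(wide_in[, activity_levels()]),
                 tolerance = 1e-14)
    expect_true(all(wide_out[, activity_levels()] >= -1e-15))
    # monotone promotion
    expect_true(all(wide_out$meets >= wide_in$meets - 1e-15))
    expect_true(all(wide_out$inactive <= wide_in$inactive + 1e-15))
    # monotone in delta: a larger delta moves at least as much mass up
    out2 <- redistribute_activity(dist, deltas * 2, policy = policy)
    wide_out2 <- tidyr::pivot_wider(
      dplyr::mutate(out2, level = as.character(level)),
      names_from = level, values_from = share)
    wide_out2 <- wide_out2[match(paste(wide_in$gender, wide_in$age_band),
                                 paste(wide_out2$gender, wide_out2$age_band)), ]
    expect_true(all(wide_out2$meets >= wide_out$meets - 1e-15))
    expect_true(all(wide_out2$inactive <= wide_out$inactive + 1e-15))
    # one-level rule: flows decompose as single-step promotions
    movable <- rowSums(wide_in[, c("inactive", "low", "some")])
    m_in <- wide_in$inactive - wide_out$inactive
    m_some <- wide_out$meets - wide_in$meets
    m_low <- wide_in$low + m_in - wide_out$low
    expect_true(all(m_in >= -1e-15 & m_in <= wide_in$inactive + 1e-15))
    expect_true(all(m_low >= -1e-15 & m_low <= wide_in$low + 1e-15))
    expect_true(all(m_some >= -1e-15 & m_some <= wide_in$some + 1e-15))
    expect_equal(wide_out$some,
                 wide_in$some - m_some + m_low, tolerance = 1e-12)
  }
})

test_that("the two policies agree when movable shares are equal", {
  dist <- toy_dist(c(0.2, 0.2, 0.2, 0.4))
  a <- redistribute_activity(dist, 0.03, policy = "proportional")
  b <- redistribute_activity(dist, 0.03, policy = "uniform_fraction")
  expect_equal(a, b)
  expect_error(redistribute_activity(dist, 0.03, policy = "nonsense"))
})

test_that("counts_by_level multiplies population by shares", {
  pop <- tibble::tibble(gender = "women", age_band = "16-24", count = 1000)
  dist <- dplyr::filter(toy_dist(c(0.24, 0.04, 0.14, 0.57)),
                        gender == "women", age_band == "16-24")
  counts <- counts_by_level(pop, dist)
  expect_equal(setNames(counts$count, as.character(counts$level)),
               c(inactive = 240, low = 40, some = 140, meets = 570))
  # zero population
  counts0 <- counts_by_level(dplyr::mutate(pop, count = 0), dist)
  expect_equal(counts0$count, rep(0, 4))
  # key mismatch names the missing key
  err <- expect_error(
    counts_by_level(tibble::tibble(gender = "women", age_band = "25-34",
                                   count = 1), dist),
    class = "cycledem_validation_error")
  expect_match(conditionMessage(err), "women/25-34")
})

test_that("level counts cross-check against an independent summation", {
  set.seed(7)
  dist <- fixture_dist()
  pop <- tidyr::crossing(gender = c("women", "men"),
                         age_band = age_bands()) |>
    dplyr::mutate(count = round(runif(10, 1e4, 1e6)))
  counts <- counts_by_level(pop,
                            dplyr::filter(dist, age_band %in% age_bands()))
  # spreadsheet-style oracle: explicit loop over cells
  for (g in c("women", "men")) for (b in age_bands()) {
    n <- pop$count[pop$gender == g & pop$age_band == b]
    for (l in activity_levels()) {
      s <- dist$share[dist$gender == g & dist$age_band == b &
                        dist$level == l]
      got <- counts$count[counts$gender == g & counts$age_band == b &
                            counts$level == l]
      expect_equal(got, n * s)
    }
  }
  # with normalised shares, per-cell sums reproduce the population
  # exactly (the printed shares themselves sum to 0.99-1.01 per row)
  counts_n <- counts_by_level(pop,
                              dplyr::filter(dist, age_band %in% age_bands()),
                              normalize = TRUE)
  sums <- counts_n |>
    dplyr::group_by(gender, age_band) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    dplyr::inner_join(pop, by = c("gender", "age_band"))
  expect_true(all(abs(sums$count.x - sums$count.y) < 1))
})

test_that("largest-remainder rounding conserves band totals", {
  pop <- tibble::tibble(gender = "women", age_band = "16-24", count = 1000)
  dist <- dplyr::filter(toy_dist(), gender == "women", age_band == "16-24")
  counts <- counts_by_level(pop, dist, rounding = "largest_remainder")
  expect_true(all(counts$count == floor(counts$count)))
  expect_equal(sum(counts$count), 1000)
})
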