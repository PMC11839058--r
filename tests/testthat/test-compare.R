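test_that("age rescaling applies the factor and inverts exactly", {
  sc <- species_scaling(factor = 4)
  expect_equal(rescale_age(12, sc, "macaque_to_human"), 48)
  ages <- c(1, 6, 30)
  round_trip <- rescale_age(rescale_age(ages, sc, "macaque_to_human"),
                            sc, "human_to_macaque")
  expect_equal(round_trip, ages)
  expect_equal(rescale_age(ages, species_scaling(factor = 1), "macaque_to_human"),
               ages)
  expect_error(species_scaling(factor = -2), "factor")
  expect_error(rescale_age(c(-1, 2), sc), "positive")
})

test_that("baseline adjustment anchors the trajectory at exactly zero", {
  set.seed(1)
  age <- runif(100, 2, 30)
  lin <- fit_gam(data.frame(age = age, value = 1 + 0.5 * age))
  expect_equal(baseline_adjust(lin, 4, 4), 0)
  expect_equal(baseline_adjust(lin, 4, 6), 1.0, tolerance = 1e-6)
  cst <- fit_gam(data.frame(age = age, value = rep(2.2, 100)))
  expect_equal(baseline_adjust(cst, 10, c(3, 15, 28)), rep(0, 3),
               tolerance = 1e-8)
  sat <- fit_gam(saturating_data(100, c(2, 30), 1.2, 0.6, 0.3, noise_sd = 0.05))
  expect_equal(baseline_adjust(sat, 5, 5), 0)
  expect_error(baseline_adjust(sat, 40, 10), "outside")
})

test_that("rescaling and baseline adjustment commute", {
  set.seed(2)
  sc <- species_scaling(factor = 4, human_baseline_age = 8,
                        macaque_baseline_age = 2)
  mac_age <- runif(120, 0.5, 9)
  fit <- fit_gam(data.frame(age = mac_age, value = 1 + 0.3 * log1p(mac_age)))
  hum_grid <- seq(4, 30, length.out = 20)
  # adjust on the macaque clock, then express at rescaled human ages ...
  a1 <- baseline_adjust(fit, sc$macaque_baseline_age,
                        rescale_age(hum_grid, sc, "human_to_macaque"))
  # ... equals evaluating at rescaled ages and adjusting at the rescaled
  # baseline
  a2 <- predict(fit, hum_grid / sc$factor) -
    predict(fit, sc$human_baseline_age / sc$factor)
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("exact 4x time compression is recovered at the grid optimum", {
  set.seed(3)
  # noise-free paired trajectories: macaque at m years = human at 4m years
  h_age <- seq(2, 36, length.out = 120)
  m_age <- seq(0.5, 9, length.out = 120)
  curve <- function(a) 1.2 + 0.6 * (1 - exp(-0.2 * a))
  human <- data.frame(age = h_age, value = curve(h_age))
  mac <- data.frame(age = m_age, value = curve(4 * m_age))
  est <- estimate_scaling(human, mac, candidate_range = c(1, 8))
  expect_equal(est$s_hat, 4, tolerance = 0.05)
  expect_lt(est$objective, 1e-2)
})

test_that("identical species curves give a scaling factor of one", {
  h_age <- seq(1, 30, length.out = 150)
  curve <- function(a) 1 + 0.5 * (1 - exp(-0.3 * a))
  d <- data.frame(age = h_age, value = curve(h_age))
  est <- estimate_scaling(d, d, candidate_range = c(0.5, 4))
  expect_equal(est$s_hat, 1, tolerance = 0.05)
})

test_that("a misspecified compression of three is recovered from noisy data", {
  set.seed(4)
  h_age <- runif(400, 2, 36)
  m_age <- runif(200, 0.5, 12)
  curve <- function(a) 1.2 + 0.6 * (1 - exp(-0.25 * a))
  human <- data.frame(age = h_age, value = curve(h_age) + rnorm(400, 0, 0.03))
  mac <- data.frame(age = m_age, value = curve(3 * m_age) + rnorm(200, 0, 0.03))
  est <- estimate_scaling(human, mac, candidate_range = c(1, 8))
  expect_gte(est$s_hat, 2.7)
  expect_lte(est$s_hat, 3.3)
})

test_that("scaling estimation demands overlapping, populated windows", {
  h <- data.frame(age = seq(30, 36, length.out = 40), value = rnorm(40))
  m <- data.frame(age = seq(0.1, 0.5, length.out = 40), value = rnorm(40))
  expect_error(estimate_scaling(h, m, candidate_range = c(1, 8)), "overlap")
})

test_that("depth-slope ANOVA matches hand-computed tables with guards", {
  slopes <- expand.grid(parcel = 1:4, depth_bin = 1:3)
  slopes$group <- "all"
  slopes$slope <- rep(c(0.5, 0.3, 0.1), each = 4)
  slopes$slope <- slopes$slope + rep(c(-0.01, 0.01), 6)
  out <- depth_slope_anova(slopes)
  # oracle: between SS = 4 * sum((means - 0.3)^2) = 0.32, within SS = 12e-4
  f_oracle <- (0.32 / 2) / (0.0012 / 9)
  expect_equal(out$F, f_oracle, tolerance = 1e-8)
  # identical slopes -> F = 0
  flat <- transform(slopes, slope = 0.2)
  expect_equal(depth_slope_anova(flat)$F, 0)
  # within SS zero -> guarded large finite F with warning
  sep <- transform(slopes, slope = rep(c(1, 1, 3), each = 4))
  expect_warning(res <- depth_slope_anova(sep), "large finite")
  expect_true(res$F > 1e6)
  expect_error(depth_slope_anova(slopes[slopes$depth_bin == 1, ]), ">= 2 bins")
})
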