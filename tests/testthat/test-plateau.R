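test_that("the band collapses onto the derivative when coefficients are exact", {
  set.seed(1)
  # linear data lie in the model family, so the noise-free fit is exact and
  # the coefficient covariance vanishes
  age <- runif(300, 5, 35)
  fit <- fit_gam(data.frame(age = age, value = 1 + 0.02 * age))
  band <- derivative_band(fit, n_draws = 500, seed = 2)
  expect_lt(max(band$upper - band$lower), 1e-4)
  expect_true(all(band$lower <= band$derivative & band$derivative <= band$upper))
})

test_that("a single-point grid reduces to the pointwise normal quantile", {
  set.seed(2)
  d <- saturating_data(100, c(5, 35), 1.2, 0.6, 0.3, noise_sd = 0.1)
  fit <- fit_gam(d)
  band <- derivative_band(fit, age_grid = 20, n_draws = 50000, seed = 3)
  expect_equal(band$crit, stats::qnorm(0.975), tolerance = 0.03)
})

test_that("the critical multiplier grows with nested grids under shared draws", {
  set.seed(3)
  d <- saturating_data(100, c(5, 35), 1.2, 0.6, 0.3, noise_sd = 0.1)
  fit <- fit_gam(d)
  g_small <- seq(10, 30, length.out = 5)
  g_large <- seq(5, 35, length.out = 40)  # superset span, includes extremes
  m_small <- derivative_band(fit, g_small, n_draws = 5000, seed = 7)$crit
  m_large <- derivative_band(fit, c(g_small, g_large), n_draws = 5000, seed = 7)$crit
  expect_gte(m_large, m_small)
  expect_gte(m_small, 0)
})

test_that("plateau classification distinguishes growth, plateau, and flatness", {
  set.seed(4)
  n <- 150
  age <- runif(n, 5, 35)
  # strictly rising line: derivative band excludes zero everywhere
  lin <- fit_gam(data.frame(age = age, value = 1 + 0.05 * age + rnorm(n, 0, 0.05)))
  pl <- plateau_age(derivative_band(lin, n_draws = 2000, seed = 5))
  expect_equal(pl$flag, "no-plateau")
  expect_true(is.na(pl$plateau_age))
  # flat noise: band contains zero everywhere -> earliest grid age, no-growth
  flat <- fit_gam(data.frame(age = age, value = rnorm(n, 0, 0.05)))
  band <- derivative_band(flat, n_draws = 2000, seed = 6)
  pf <- plateau_age(band)
  expect_equal(pf$flag, "no-growth")
  expect_equal(pf$plateau_age, band$age_grid[1])
  # saturating curve: significant growth first, terminal zero-containing run
  sat <- fit_gam(saturating_data(n, c(5, 35), 1.2, 0.6, 0.3, noise_sd = 0.06,
                                 seed = 8))
  ps <- plateau_age(derivative_band(sat, n_draws = 2000, seed = 7))
  expect_equal(ps$flag, "plateau")
  expect_true(ps$plateau_age > 5 && ps$plateau_age < 35)
})

test_that("group summaries compute proportions, timings and the ANOVA", {
  plateaus <- data.frame(
    unit = 1:6,
    plateau_age = c(2, 2, 2, 10, 10, 10),
    flag = "plateau",
    q = 0.01
  )
  groups <- data.frame(unit = 1:6, group = rep(c("g1", "g2"), each = 3))
  # textbook one-way oracle: between SS = 96, within SS = 0 -> guarded F
  expect_warning(s <- plateau_summary(plateaus, groups), "large finite")
  expect_equal(s$by_group$proportion, c(1, 1))
  expect_equal(s$by_group$mean_timing, c(2, 10))
  expect_true(s$anova$F > 1e6)

  # identical ages everywhere: F defined as 0
  pl_same <- transform(plateaus, plateau_age = 5)
  s3 <- plateau_summary(pl_same, groups)
  expect_equal(s3$anova$F, 0)

  # hand-checked unequal case: {2,3,4} vs {8,9,10}
  pl2 <- transform(plateaus, plateau_age = c(2, 3, 4, 8, 9, 10))
  s4 <- plateau_summary(pl2, groups)
  expect_equal(s4$anova$F, 54, tolerance = 1e-8)  # 54 = (54/1)/(4/4)
  expect_equal(s4$anova$df1, 1L)
  expect_equal(s4$anova$df2, 4L)
})

test_that("non-significant units stay in denominators but not timings", {
  plateaus <- data.frame(
    unit = 1:4,
    plateau_age = c(5, 7, 9, 11),
    flag = c("plateau", "plateau", "plateau", "no-plateau"),
    q = c(0.01, 0.2, 0.01, 0.01)
  )
  groups <- data.frame(unit = 1:4, group = c("a", "a", "b", "b"))
  s <- suppressWarnings(plateau_summary(plateaus, groups))
  g_a <- s$by_group[s$by_group$group == "a", ]
  expect_equal(g_a$n_units, 2)
  expect_equal(g_a$n_plateaued, 1)     # unit 2 excluded by q > 0.05
  expect_equal(g_a$proportion, 0.5)
  expect_equal(g_a$mean_timing, 5)
  # group with no eligible plateaus is excluded from the ANOVA with a warning
  plateaus$q[3] <- 0.5
  expect_warning(plateau_summary(plateaus, groups), "excluded from ANOVA")
})

test_that("simultaneous bands cover the true derivative curve jointly", {
  # data generated from the fitted model family itself, so the Bayesian
  # band's nominal coverage applies; scaled-down replicate count
  set.seed(9)
  ages <- runif(120, 5, 35)
  basis <- build_smooth_basis(ages)
  X <- cbind(1, smooth_basis_eval(basis, ages))
  beta_true <- c(1.2, 0.01, 0.08)
  y_mean <- drop(X %*% beta_true)
  grid <- seq(5, 35, length.out = 100)
  Dtrue <- smooth_basis_deriv(basis, grid)
  d_true <- drop(Dtrue %*% beta_true[2:3])
  covered <- replicate(60, {
    d <- data.frame(age = ages, value = y_mean + rnorm(120, 0, 0.1))
    fit <- fit_gam(d)
    band <- derivative_band(fit, grid, n_draws = 1500,
                            seed = sample.int(1e6, 1))
    dt <- drop(smooth_basis_deriv(fit$basis, grid) %*% beta_true[2:3])
    all(band$lower <= dt & dt <= band$upper)
  })
  expect_gte(mean(covered), 0.85)
})
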