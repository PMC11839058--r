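test_that("the rank-3 basis has one penalized direction over {1, age}", {
  set.seed(1)
  ages <- runif(40, 5, 35)
  b <- build_smooth_basis(ages)
  X <- smooth_basis_eval(b, ages)
  expect_equal(colnames(X), c("age", "z"))
  # curvature column is empirically orthogonal to {1, age} and unit RMS
  expect_equal(mean(X[, "z"]), 0, tolerance = 1e-8)
  expect_equal(unname(stats::coef(stats::lm(X[, "z"] ~ ages))[2]), 0,
               tolerance = 1e-8)
  expect_equal(sqrt(mean(X[, "z"]^2)), 1, tolerance = 1e-8)
  expect_error(build_smooth_basis(c(1, 1, 2)), "distinct ages")
})

test_that("constants and lines are reproduced exactly at every lambda", {
  set.seed(2)
  ages <- runif(50, 5, 35)
  sex <- sample(c("F", "M"), 50, TRUE)
  for (lam in c(0, 1, 1e6)) {
    lin <- fit_gam(data.frame(age = ages, value = 2 + 0.5 * ages, sex = sex),
                   lambda = lam)
    expect_lt(max(abs(lin$fitted - (2 + 0.5 * ages))), 1e-6)
    expect_equal(mean_slope(lin), 0.5, tolerance = 1e-6)
    cst <- fit_gam(data.frame(age = ages, value = rep(1.3, 50), sex = sex),
                   lambda = lam)
    expect_lt(max(abs(cst$fitted - 1.3)), 1e-6)
    expect_equal(mean_slope(cst), 0, tolerance = 1e-6)
  }
})

test_that("REML fit matches the mgcv oracle exactly", {
  skip_if_not_installed("mgcv")
  set.seed(3)
  n <- 120
  age <- runif(n, 5, 35)
  sex <- sample(c("F", "M"), n, TRUE)
  y <- 1.2 + 0.6 * (1 - exp(-0.3 * age)) + 0.02 * (sex == "M") + rnorm(n, 0, 0.05)
  fit <- fit_gam(data.frame(age = age, value = y, sex = sex))
  sexc <- ifelse(sex == "M", 0.5, -0.5)
  g <- mgcv::gam(y ~ sexc + s(age, k = 3), method = "REML")
  expect_equal(fit$fitted, unname(g$fitted.values), tolerance = 1e-6)
  expect_equal(fit$edf, sum(g$edf), tolerance = 1e-5)
  expect_equal(fit$sigma2, g$sig2, tolerance = 1e-5)
  # analytic derivative against mgcv finite differences
  grid <- seq(6, 34, length.out = 50)
  eps <- 1e-5
  dg <- (stats::predict(g, data.frame(age = grid + eps, sexc = 0)) -
           stats::predict(g, data.frame(age = grid - eps, sexc = 0))) / (2 * eps)
  expect_lt(max(abs(fit_derivative(fit, grid)$deriv - as.numeric(dg))), 1e-6)
})

test_that("random-intercept REML matches mgcv's re smooth", {
  skip_if_not_installed("mgcv")
  set.seed(4)
  ns <- 25; S <- 5
  subj <- rep(sprintf("s%02d", 1:ns), each = S)
  age <- as.vector(replicate(ns, sort(runif(S, 1, 36))))
  sex <- rep(sample(c("F", "M"), ns, TRUE), each = S)
  y <- 1.3 + 0.5 * (1 - exp(-0.12 * age)) + 0.02 * (sex == "M") +
    rep(rnorm(ns, 0, 0.04), each = S) + rnorm(ns * S, 0, 0.05)
  fit <- fit_gam(data.frame(age = age, value = y, sex = sex, subject = subj),
                 random_intercepts = TRUE)
  sexc <- ifelse(sex == "M", 0.5, -0.5)
  sf <- factor(subj)
  B <- smooth_basis_eval(fit$basis, age)
  Zm <- matrix(B[, "z"], ncol = 1)
  alin <- B[, "age"]
  g <- mgcv::gam(y ~ sexc + alin + Zm + s(sf, bs = "re"),
                 paraPen = list(Zm = list(diag(1))), method = "REML")
  expect_equal(unname(fit$coefficients[1:4]), unname(stats::coef(g)[1:4]),
               tolerance = 1e-4)
  expect_equal(fit$edf, sum(g$edf), tolerance = 1e-3)
  expect_equal(fit$sigma2, g$sig2, tolerance = 1e-5)
  expect_equal(fit$subject_var, unname(g$sig2 / g$sp[2]), tolerance = 1e-3)
})

test_that("duplicating every observation leaves the fitted curve unchanged", {
  set.seed(5)
  d <- saturating_data(60, c(5, 35), 1.2, 0.6, 0.3, noise_sd = 0.05)
  f1 <- fit_gam(d)
  f2 <- fit_gam(rbind(d, d))
  grid <- seq(5, 35, length.out = 50)
  expect_equal(predict(f1, grid), predict(f2, grid), tolerance = 1e-3)
})

test_that("pure-noise fits shrink the smooth towards its null space", {
  set.seed(6)
  edfs <- replicate(60, {
    d <- data.frame(age = runif(60, 5, 35), value = rnorm(60))
    fit_gam(d)$edf
  })
  # intercept + linear age = 2 unpenalized df; median curvature edf near 0
  expect_lt(abs(median(edfs) - 2), 0.2)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fit_gam(data.frame(age = 1:5, value = 1:5)), "at least 10")
  set.seed(7)
  expect_error(fit_gam(data.frame(age = runif(20, 5, 35), value = rnorm(20),
                                  sex = rep("F", 20))),
               "rank-deficient")
  expect_error(fit_gam(data.frame(age = rep(1:2, 10), value = rnorm(20))),
               "distinct ages")
  expect_error(fit_gam(data.frame(age = runif(20, 5, 35), value = rnorm(20)),
                       random_intercepts = TRUE),
               "subject")
})
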