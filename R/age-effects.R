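#' Signed partial R-squared age effect from nested smooth fits
#'
#' Quantifies a unit's overall age effect by comparing the full trajectory
#' fit against the nested reduced fit with the whole age term removed:
#' the effect magnitude is the difference in variance explained
#' (`R^2_full - R^2_reduced`, both computed on fixed-effects fitted
#' values), the direction is the sign of the mean first derivative of the
#' fitted smooth over `age_grid`, and significance comes from the
#' chi-squared test on the drop in residual deviance with degrees of
#' freedom equal to the difference in effective degrees of freedom
#' (floored at 1).
#'
#' @param full A `smooth_fit` with the age smooth.
#' @param reduced The nested `smooth_fit` on the same data with
#'   `include_age = FALSE` and identical non-age structure.
#' @param age_grid Ages over which the mean derivative determines the sign.
#' @return List of class `age_effect`: `r2_partial` (unsigned magnitude),
#'   `r2_signed`, `sign` (+1/-1), `statistic`, `df`, `p_value`,
#'   `mean_derivative`.
#' @export
age_effect <- function(full, reduced, age_grid = NULL) {
  stopifnot(inherits(full, "smooth_fit"), inherits(reduced, "smooth_fit"))
  if (!full$include_age || reduced$include_age) {
    stop("`full` must include the age term and `reduced` must exclude it",
         call. = FALSE)
  }
  if (full$n != reduced$n || !isTRUE(all.equal(full$y, reduced$y))) {
    stop("models are not nested fits of the same data", call. = FALSE)
  }
  if (full$has_sex != reduced$has_sex ||
      full$random_intercepts != reduced$random_intercepts) {
    stop("non-age model structure differs between full and reduced fits",
         call. = FALSE)
  }
  if (is.null(age_grid)) {
    age_grid <- seq(full$age_range[1], full$age_range[2], length.out = 200)
  }
  r2p <- full$r_squared - reduced$r_squared
  md <- mean(fit_derivative(full, age_grid)$deriv)
  sgn <- if (md >= 0) 1 else -1
  stat <- (reduced$deviance - full$deviance) / full$sigma2
  stat <- max(stat, 0)
  # Reference df = parametric dimension of the dropped age term (2: linear
  # trend + curvature). Because REML smoothing selection explores the whole
  # span of the term, the deviance drop behaves like a 2-df quantity even
  # when the selected effective df is smaller; an effective-df difference
  # reference is anti-conservative. With a Gaussian response the scale is
  # estimated, so the scaled statistic is referred to F(df, n - edf) rather
  # than chi-squared -- the small-sample correction that keeps the far tail
  # (where FDR thresholds live) calibrated.
  df <- max(1, full$n_fixed - reduced$n_fixed)
  df2 <- max(1, full$n - full$edf)
  p <- stats::pf(stat / df, df, df2, lower.tail = FALSE)
  structure(list(r2_partial = abs(r2p), r2_signed = sgn * abs(r2p),
                 sign = sgn, statistic = stat, df = df, p_value = p,
                 mean_derivative = md),
            class = "age_effect")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values across a family of tests (one per parcel or
#' per parcel x depth bin).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values (monotone in p, `q >= p`).
#' @export
fdr_correct <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Mean developmental slope of a fitted trajectory
#'
#' Mean over an age grid of the analytic first derivative of the fitted
#' smooth (ratio units per age unit).
#'
#' @param fit A `smooth_fit` with an age term.
#' @param age_grid Grid of ages; must lie within the observed age range.
#' @return Scalar mean slope.
#' @export
mean_slope <- function(fit, age_grid = NULL) {
  stopifnot(inherits(fit, "smooth_fit"))
  if (is.null(age_grid)) {
    age_grid <- seq(fit$age_range[1], fit$age_range[2], length.out = 200)
  }
  tol <- 1e-8 * max(1, diff(fit$age_range))
  if (min(age_grid) < fit$age_range[1] - tol ||
      max(age_grid) > fit$age_range[2] + tol) {
    stop("`age_grid` extends outside the observed age range", call. = FALSE)
  }
  mean(fit_derivative(fit, age_grid)$deriv)
}

#' Regress per-parcel slopes on the hierarchy axis
#'
#' Fits per-parcel developmental slopes (or deep-minus-superficial slope
#' differences) against the sensorimotor-association axis rank with the
#' same rank-3 smooth machinery used for trajectories, and with an
#' ordinary linear regression alongside.
#'
#' @param slopes Data frame with columns `parcel` and `slope`.
#' @param axis An `axis_map` from [parcel_axis()].
#' @return List: `r2_smooth`, `p_smooth` (full-vs-reduced smooth
#'   comparison), `r2_linear`, `p_linear`, `slope_linear` (sign of the
#'   linear trend along the axis), `n`.
#' @export
slope_vs_axis <- function(slopes, axis) {
  stopifnot(is.data.frame(slopes), all(c("parcel", "slope") %in% names(slopes)))
  m <- merge(slopes, axis[, c("parcel", "rank")], by = "parcel")
  if (nrow(m) < 5) stop("need at least 5 parcels", call. = FALSE)
  if (length(unique(m$rank)) < 2) stop("degenerate axis: all ranks equal", call. = FALSE)
  if (stats::var(m$slope) == 0) {
    # constant slopes carry no axis information
    return(list(r2_smooth = 0, p_smooth = 1, r2_linear = 0, p_linear = 1,
                slope_linear = 0, n = nrow(m)))
  }
  dat <- data.frame(age = as.numeric(m$rank), value = m$slope)
  full <- fit_gam(dat, include_age = TRUE)
  reduced <- fit_gam(dat, include_age = FALSE)
  eff <- age_effect(full, reduced)
  lmfit <- stats::lm(value ~ age, data = dat)
  sm <- suppressWarnings(summary(lmfit))
  list(r2_smooth = full$r_squared, p_smooth = eff$p_value,
       r2_linear = sm$r.squared,
       p_linear = stats::coef(sm)["age", "Pr(>|t|)"],
       slope_linear = unname(stats::coef(lmfit)["age"]),
       n = nrow(m))
}
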