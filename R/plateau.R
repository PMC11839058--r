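#' Simultaneous confidence band for the first derivative
#'
#' Draws coefficient vectors from the Bayesian posterior
#' `N(beta_hat, V_beta)` of a fitted smooth, and calibrates a critical
#' multiplier `m*` as the `level` quantile of the maximum over the age
#' grid of the absolute standardized derivative deviation. The band
#' `derivative +/- m* * se` then covers the whole derivative curve jointly
#' at the nominal level, which is what "the derivative is
#' indistinguishable from zero beyond age a" needs; a pointwise band would
#' understate the multiplicity over the grid.
#'
#' @param fit A `smooth_fit` with an age term.
#' @param age_grid Evaluation grid (default 200 points over the observed
#'   range).
#' @param n_draws Posterior draws for the max-deviation quantile.
#' @param level Simultaneous coverage level.
#' @param seed Integer seed (mandatory for reproducible bands).
#' @return Object of class `derivative_band`: `age_grid`, `derivative`,
#'   `se`, `lower`, `upper`, `crit` (`m*`), `n_draws`, `level`.
#' @export
derivative_band <- function(fit, age_grid = NULL, n_draws = 10000,
                            level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "smooth_fit"))
  if (!fit$include_age) stop("fit has no age term", call. = FALSE)
  if (is.null(age_grid)) {
    age_grid <- seq(fit$age_range[1], fit$age_range[2], length.out = 200)
  }
  D <- smooth_basis_deriv(fit$basis, age_grid)
  idx <- match(c("age", "z"), names(fit$coefficients))
  V <- fit$Vb[idx, idx, drop = FALSE]
  V <- (V + t(V)) / 2
  d_hat <- drop(D %*% fit$coefficients[idx])
  se <- sqrt(pmax(rowSums((D %*% V) * D), 0))

  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1e-300)) {
    stop("coefficient covariance is not positive semi-definite", call. = FALSE)
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow = length(ev$values))

  crit <- with_local_seed(seed, {
    E <- matrix(stats::rnorm(n_draws * ncol(V)), n_draws)       # draws x p
    dev <- E %*% t(D %*% L)                                     # draws x grid
    sepos <- se > 0
    if (!any(sepos)) 0 else {
      zmax <- apply(abs(dev[, sepos, drop = FALSE]) /
                      rep(se[sepos], each = n_draws), 1, max)
      unname(stats::quantile(zmax, probs = level, type = 7))
    }
  })
  structure(list(age_grid = age_grid, derivative = d_hat, se = se,
                 lower = d_hat - crit * se, upper = d_hat + crit * se,
                 crit = crit, n_draws = n_draws, level = level),
            class = "derivative_band")
}

#' Plateau age from a derivative band
#'
#' The plateau age is the smallest grid age from which the simultaneous
#' confidence band on the first derivative contains zero all the way to
#' the end of the observed range (a terminal state, robust to mid-range
#' dips of the band onto zero). Three outcomes:
#' \describe{
#'   \item{`"plateau"`}{a terminal zero-containing run starts inside the
#'     range; `plateau_age` is its first grid age.}
#'   \item{`"no-plateau"`}{the band excludes zero at the maximum age;
#'     `plateau_age` is `NA` (growth continues past the range).}
#'   \item{`"no-growth"`}{the band never excludes zero below (no
#'     significant positive derivative anywhere); `plateau_age` is the
#'     start of the terminal run (typically the grid minimum) but the unit
#'     never showed detectable growth, which is distinct from maturing.}
#' }
#'
#' @param band A [derivative_band()].
#' @return List of class `plateau_result`: `plateau_age`, `flag`.
#' @export
plateau_age <- function(band) {
  stopifnot(inherits(band, "derivative_band"))
  contains0 <- band$lower <= 0 & band$upper >= 0
  n <- length(contains0)
  if (!contains0[n]) {
    return(structure(list(plateau_age = NA_real_, flag = "no-plateau"),
                     class = "plateau_result"))
  }
  run_start <- n
  while (run_start > 1 && contains0[run_start - 1]) run_start <- run_start - 1
  flag <- if (any(band$lower > 0)) "plateau" else "no-growth"
  structure(list(plateau_age = band$age_grid[run_start], flag = flag),
            class = "plateau_result")
}

#' Group-level plateau summary
#'
#' Per group (hierarchy tertile or depth bin): the proportion of units
#' reaching a plateau, the mean plateau timing among eligible units, and a
#' one-way ANOVA of plateau ages across groups. A unit counts as
#' plateaued when its band flag is `"plateau"` and its overall age effect
#' survives FDR (`q <= alpha`); non-significant units stay in the
#' proportion denominators (reported both ways) but are excluded from
#' timing means and the ANOVA.
#'
#' @param plateaus Data frame with columns `unit`, `plateau_age`, `flag`,
#'   and `q` (FDR-adjusted age-effect p-value; if absent all units are
#'   treated as significant).
#' @param groups Data frame mapping `unit` to `group`.
#' @param alpha Significance cutoff on `q`.
#' @return List of class `plateau_summary`: `by_group` data frame
#'   (`group, n_units, n_eligible, n_plateaued, proportion,
#'   proportion_of_eligible, mean_timing`), and `anova` (list `F`, `p`,
#'   `df1`, `df2`).
#' @export
plateau_summary <- function(plateaus, groups, alpha = 0.05) {
  stopifnot(all(c("unit", "plateau_age", "flag") %in% names(plateaus)))
  if (!"q" %in% names(plateaus)) plateaus$q <- 0
  m <- merge(plateaus, groups, by = "unit")
  if (nrow(m) < nrow(plateaus)) {
    stop("some units are missing a group assignment", call. = FALSE)
  }
  m$eligible <- m$q <= alpha
  m$plateaued <- m$eligible & m$flag == "plateau"
  glev <- if (is.factor(m$group)) levels(droplevels(m$group)) else sort(unique(m$group))
  by_group <- do.call(rbind, lapply(glev, function(g) {
    s <- m[m$group == g, , drop = FALSE]
    data.frame(group = g,
               n_units = nrow(s),
               n_eligible = sum(s$eligible),
               n_plateaued = sum(s$plateaued),
               proportion = if (nrow(s)) sum(s$plateaued) / nrow(s) else 0,
               proportion_of_eligible =
                 if (sum(s$eligible)) sum(s$plateaued) / sum(s$eligible) else 0,
               mean_timing = if (sum(s$plateaued)) {
                 mean(s$plateau_age[s$plateaued])
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  empty <- by_group$group[by_group$n_plateaued == 0]
  if (length(empty)) {
    warning(sprintf("group(s) without plateaued units excluded from ANOVA: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  keep <- m$plateaued & m$group %in% setdiff(glev, empty)
  aov_res <- oneway_f(m$plateau_age[keep], droplevels(factor(m$group[keep])))
  structure(list(by_group = by_group, anova = aov_res),
            class = "plateau_summary")
}

# One-way ANOVA via stats::aov with guards for the degenerate layouts that
# phantom-style fixtures can produce (zero between- or within-group SS).
oneway_f <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (length(values) < 3 || nlevels(groups) < 2) {
    return(list(F = NA_real_, p = NA_real_, df1 = NA_integer_, df2 = NA_integer_))
  }
  fit <- stats::aov(values ~ groups)
  tab <- suppressWarnings(stats::anova(fit))
  ssb <- tab$`Sum Sq`[1]
  ssw <- tab$`Sum Sq`[2]
  df1 <- tab$Df[1]
  df2 <- tab$Df[2]
  scale2 <- mean(values^2)
  if (ssb <= 1e-12 * max(scale2, 1e-300) * length(values)) {
    return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  }
  if (ssw <= 1e-12 * max(scale2, 1e-300) * length(values)) {
    warning("zero within-group variance: F reported as large finite", call. = FALSE)
    return(list(F = 1e12, p = 0, df1 = df1, df2 = df2))
  }
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1], df1 = df1, df2 = df2)
}
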