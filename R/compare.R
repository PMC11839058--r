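#' Cross-species developmental time scaling
#'
#' Holds the human:macaque developmental time ratio `s` (human age =
#' `s` x macaque age; the canonical value is 4) and the baseline ages at
#' which trajectories are anchored to zero before cross-species overlay
#' (defaults: 4 years human, 1 year macaque, which correspond under
#' `s = 4`).
#'
#' @param factor Time ratio `s > 0`.
#' @param human_baseline_age Human baseline, years.
#' @param macaque_baseline_age Macaque baseline, years.
#' @return An object of class `species_scaling`.
#' @export
species_scaling <- function(factor = 4, human_baseline_age = 4,
                            macaque_baseline_age = 1) {
  stop_if_not_scalar_pos(factor, "factor")
  stop_if_not_scalar_pos(human_baseline_age, "human_baseline_age")
  stop_if_not_scalar_pos(macaque_baseline_age, "macaque_baseline_age")
  structure(list(factor = factor,
                 human_baseline_age = human_baseline_age,
                 macaque_baseline_age = macaque_baseline_age),
            class = "species_scaling")
}

#' Rescale ages between species clocks
#'
#' Multiplies macaque ages by the scaling factor (macaque to human) or
#' divides human ages by it; the two directions are exact inverses. Works
#' in whatever unit the input carries (months in, months out).
#'
#' @param ages Positive ages.
#' @param scaling A [species_scaling()].
#' @param direction `"macaque_to_human"` or `"human_to_macaque"`.
#' @return Rescaled ages.
#' @export
rescale_age <- function(ages, scaling,
                        direction = c("macaque_to_human", "human_to_macaque")) {
  stopifnot(inherits(scaling, "species_scaling"), is.numeric(ages))
  if (any(ages <= 0)) stop("ages must be positive", call. = FALSE)
  direction <- match.arg(direction)
  if (direction == "macaque_to_human") ages * scaling$factor
  else ages / scaling$factor
}

#' Baseline-adjust a fitted trajectory
#'
#' Subtracts the fitted value at `baseline_age` from the fitted
#' trajectory, so the adjusted curve is exactly zero at the baseline.
#' Because T1w/T2w units are arbitrary, cross-species overlays always
#' compare baseline-adjusted curves, never absolute levels.
#'
#' @param fit A `smooth_fit`.
#' @param baseline_age Anchor age; must lie within the fitted age range.
#' @param ages Ages at which to evaluate the adjusted trajectory.
#' @return Numeric adjusted values (`0` at `baseline_age` exactly).
#' @export
baseline_adjust <- function(fit, baseline_age, ages) {
  stopifnot(inherits(fit, "smooth_fit"))
  if (baseline_age < fit$age_range[1] || baseline_age > fit$age_range[2]) {
    stop("`baseline_age` lies outside the fitted age range", call. = FALSE)
  }
  predict(fit, ages) - predict(fit, baseline_age)
}

#' Estimate the cross-species time-scaling factor
#'
#' Recovery harness for the 4:1 claim: finds the factor `s_hat` under
#' which the macaque trajectories, evaluated at `a / s`, best match the
#' paired human trajectories at human age `a` over the overlap of the
#' (rescaled) observed ranges. For each candidate `s`, both members of
#' every trajectory pair are refitted on the overlap window only (a fit
#' over a species' full range carries window-dependent smoothing bias
#' that does not cancel across species; refitting on the common window
#' makes the rank-3 smoothing bias align). Because absolute T1w/T2w
#' levels are arbitrary, each refitted curve is anchored by subtracting
#' its own window mean (L2-optimal offset alignment; display overlays use
#' [baseline_adjust()] at configured baseline ages instead). The
#' objective is the shape-normalized misfit
#' `sum_j mean((ch_j - cm_j)^2) / sum_j mean(ch_j^2 + cm_j^2)` across
#' pairs, minimized by coarse grid search plus local refinement;
#' deterministic. All ages must be on a common unit (years); macaque ages
#' recorded in months are divided by 12 upstream.
#'
#' @param human_data,macaque_data A data frame (columns `age`, `value`,
#'   optionally `sex`, `subject`) or a list of such data frames (paired
#'   by position: the j-th human trajectory corresponds to the j-th
#'   macaque one). Ages in years.
#' @param candidate_range Interval searched for `s`.
#' @param step Coarse grid step on `s`.
#' @param n_eval Evaluation points on each overlap window.
#' @param min_obs Minimum observations per species and trajectory inside
#'   the overlap window for a candidate to be evaluable (shape comparison
#'   on fewer points is unreliable).
#' @param min_overlap Minimum overlap width, years.
#' @return List: `s_hat`, `objective` at the optimum, and the coarse
#'   `profile` data frame.
#' @export
estimate_scaling <- function(human_data, macaque_data,
                             candidate_range = c(1, 8),
                             step = 0.2, n_eval = 50,
                             min_obs = 30, min_overlap = 1) {
  stopifnot(length(candidate_range) == 2, candidate_range[1] > 0,
            candidate_range[2] > candidate_range[1], candidate_range[2] <= 10)
  if (is.data.frame(human_data)) human_data <- list(human_data)
  if (is.data.frame(macaque_data)) macaque_data <- list(macaque_data)
  stopifnot(length(human_data) == length(macaque_data),
            length(human_data) >= 1)

  objective <- function(s) {
    num <- 0
    den <- 0
    for (j in seq_along(human_data)) {
      dh <- human_data[[j]]
      dm <- macaque_data[[j]]
      lo <- max(min(dh$age), s * min(dm$age))
      hi <- min(max(dh$age), s * max(dm$age))
      if (hi - lo < min_overlap) return(NA_real_)
      sh <- dh[dh$age >= lo & dh$age <= hi, , drop = FALSE]
      sm <- dm[dm$age >= lo / s & dm$age <= hi / s, , drop = FALSE]
      if (nrow(sh) < min_obs || nrow(sm) < min_obs) return(NA_real_)
      fh <- tryCatch(fit_gam(sh), error = function(e) NULL)
      fm <- tryCatch(fit_gam(sm), error = function(e) NULL)
      if (is.null(fh) || is.null(fm)) return(NA_real_)
      grid <- seq(lo, hi, length.out = n_eval)
      gh <- predict(fh, grid)
      gm <- predict(fm, grid / s)
      ch <- gh - mean(gh)
      cm <- gm - mean(gm)
      num <- num + mean((ch - cm)^2)
      den <- den + mean(ch^2 + cm^2)
    }
    if (den <= 0) 0 else num / den
  }
  svals <- seq(candidate_range[1], candidate_range[2], by = step)
  prof <- vapply(svals, objective, numeric(1))
  if (all(is.na(prof))) {
    stop("no candidate scaling yields overlapping age ranges with enough data",
         call. = FALSE)
  }
  best <- which.min(prof)
  lo <- svals[max(1, best - 1)]
  hi <- svals[min(length(svals), best + 1)]
  refined <- suppressWarnings(stats::optimize(function(s) {
    v <- objective(s); if (is.na(v)) Inf else v
  }, interval = c(lo, hi), tol = 1e-4))
  list(s_hat = refined$minimum, objective = refined$objective,
       profile = data.frame(s = svals, objective = prof))
}

#' One-way ANOVA of developmental slopes across depth bins
#'
#' Within each hierarchy group, tests whether per-parcel mean GAM slopes
#' differ across equivolumetric depth bins (the depth-wise "inside-out"
#' signature).
#'
#' @param slopes Data frame with columns `parcel`, `depth_bin`, `group`,
#'   `slope`.
#' @return Data frame per group: `group, F, p, df1, df2`.
#' @export
depth_slope_anova <- function(slopes) {
  stopifnot(is.data.frame(slopes),
            all(c("parcel", "depth_bin", "group", "slope") %in% names(slopes)))
  glev <- if (is.factor(slopes$group)) levels(droplevels(slopes$group))
          else sort(unique(slopes$group))
  out <- lapply(glev, function(g) {
    s <- slopes[slopes$group == g, , drop = FALSE]
    tab <- table(s$depth_bin)
    if (length(tab) < 2 || any(tab < 2)) {
      stop(sprintf("group '%s' needs >= 2 bins with >= 2 parcels each", g),
           call. = FALSE)
    }
    f <- oneway_f(s$slope, factor(s$depth_bin))
    data.frame(group = g, F = f$F, p = f$p, df1 = f$df1, df2 = f$df2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
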