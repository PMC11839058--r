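#' Saturating growth-curve parameters
#'
#' Bundles the parameters of the saturating-exponential mean trajectory used
#' by the synthetic cortex generator:
#' \deqn{\mu(a) = \mathrm{baseline} + \mathrm{amplitude}\,(1 - e^{-\mathrm{rate}\cdot a}).}
#' The curve rises monotonically from `baseline` at age 0 towards
#' `baseline + amplitude`, with the true first derivative
#' `amplitude * rate * exp(-rate * age)`.
#'
#' The ground-truth plateau onset is defined as the age at which the true
#' derivative first drops below `epsilon_frac` times its value at age 0,
#' i.e. `plateau_onset = -log(epsilon_frac) / rate`, so that
#' `amplitude * rate * exp(-rate * plateau_onset)` equals
#' `epsilon_frac * amplitude * rate` exactly.
#'
#' @param baseline Ratio value at age 0 (arbitrary T1w/T2w units).
#' @param amplitude Asymptotic increase over `baseline`; must be `>= 0`.
#' @param rate Exponential rate constant, 1/age-units; must be `> 0`.
#' @param noise_sd SD of additive Gaussian observation noise (ratio units).
#' @param sex_effect Additive offset applied to male observations (ratio units).
#' @param subject_sd SD of subject-level random intercepts (ratio units).
#' @param epsilon_frac Fraction of the initial derivative defining the
#'   plateau onset; default 0.01 (1 percent).
#' @return An object of class `growth_params`: a list with the fields above
#'   plus the derived `plateau_onset`.
#' @examples
#' gp <- growth_params(baseline = 1.2, amplitude = 0.6, rate = 0.5)
#' growth_curve(gp, age = 2)  # 1.2 + 0.6 * (1 - exp(-1))
#' @export
growth_params <- function(baseline, amplitude, rate, noise_sd = 0,
                          sex_effect = 0, subject_sd = 0, epsilon_frac = 0.01) {
  stopifnot(is_scalar_num(baseline), is_scalar_num(amplitude),
            is_scalar_num(rate), is_scalar_num(noise_sd),
            is_scalar_num(sex_effect), is_scalar_num(subject_sd),
            is_scalar_num(epsilon_frac))
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (subject_sd < 0) stop("`subject_sd` must be >= 0", call. = FALSE)
  if (epsilon_frac <= 0 || epsilon_frac >= 1) {
    stop("`epsilon_frac` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(baseline = baseline, amplitude = amplitude, rate = rate,
         noise_sd = noise_sd, sex_effect = sex_effect,
         subject_sd = subject_sd, epsilon_frac = epsilon_frac,
         plateau_onset = -log(epsilon_frac) / rate),
    class = "growth_params"
  )
}

#' Noise-free saturating growth curve
#'
#' Mean T1w/T2w trajectory `baseline + amplitude * (1 - exp(-rate * age))`.
#'
#' @param params A [growth_params()] object.
#' @param age Non-negative age(s), in the same units as `1/params$rate`.
#' @return Numeric vector of mean ratio values.
#' @export
growth_curve <- function(params, age) {
  stopifnot(inherits(params, "growth_params"), is.numeric(age))
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("`age` must be finite and >= 0", call. = FALSE)
  }
  params$baseline + params$amplitude * (1 - exp(-params$rate * age))
}

#' First derivative of the saturating growth curve
#'
#' @inheritParams growth_curve
#' @return Numeric vector `amplitude * rate * exp(-rate * age)`.
#' @export
growth_curve_deriv <- function(params, age) {
  stopifnot(inherits(params, "growth_params"), is.numeric(age))
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("`age` must be finite and >= 0", call. = FALSE)
  }
  params$amplitude * params$rate * exp(-params$rate * age)
}
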