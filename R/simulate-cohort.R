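#' Simulate a synthetic developmental cohort with known ground truth
#'
#' Generates parcel x depth-bin x subject T1w/T2w ratio observations from
#' saturating growth curves whose plateau timing increases along a synthetic
#' sensorimotor-association (S-A) axis and whose depth profile mimics an
#' "inside-out" maturation: deeper bins start higher, rise with larger
#' amplitude, and plateau earlier than superficial bins. Observations are
#'
#' \deqn{y = \mu_{pk}(a) + \mathrm{sex\_effect}\cdot 1[\mathrm{sex}=M] +
#'       b_{subject} + \varepsilon,}
#'
#' with \eqn{\mu_{pk}} a [growth_curve()] per parcel p and bin k,
#' \eqn{b \sim N(0, \mathrm{subject\_sd}^2)} and
#' \eqn{\varepsilon \sim N(0, \mathrm{noise\_sd}^2)}.
#'
#' The macaque arm is an exact time-compressed copy of the human curves:
#' the macaque mean at age m months equals the human mean at
#' `species_scale * m` months (i.e. `species_scale * m / 12` years), so
#' cross-species alignment at the true scale is exact by construction.
#' Macaque ages are recorded in months, human ages in years.
#'
#' @param n_subjects Subjects per arm (scalar, or length-2
#'   `c(human, macaque)` when `species = "both"`). Minimum 10.
#' @param n_parcels Number of cortical parcels (axis positions).
#' @param n_depth_bins Number of equivolumetric depth bins K (bin 1 = deepest).
#' @param axis_spec Parcel-rank-to-plateau-onset map: either a list
#'   `list(onset_min=, onset_max=)` giving a linear ramp of deepest-bin
#'   plateau onsets (human years; rank 1 = sensorimotor end, earliest), or a
#'   non-decreasing numeric vector of length `n_parcels`.
#' @param depth_spec Depth-bin profile: a list with `onset_step` (years added
#'   to the plateau onset per bin of superficiality), `amplitude_deep` /
#'   `amplitude_superficial` (growth amplitudes at bin 1 and bin K; deep
#'   must be `>=` superficial) and `baseline_step` (ratio units added to the
#'   baseline per bin of depth). Alternatively a list with explicit vectors
#'   `onset_offsets`, `amplitudes`, `baselines` of length `n_depth_bins`.
#' @param species `"human"`, `"macaque"`, or `"both"`.
#' @param species_scale Developmental time ratio human:macaque (default 4).
#' @param age_range Observed age range: years for humans (default
#'   `c(5.5, 36)`), months for macaques (default `c(1, 36)`). When
#'   `species = "both"` a list `list(human=, macaque=)` may be given.
#' @param n_sessions Scans per subject (default 1 for humans, 5 for
#'   macaques; within-subject ages are strictly increasing).
#' @param baseline Ratio at age 0 for the most superficial bin.
#' @param noise_sd,sex_effect,subject_sd Noise and covariate magnitudes
#'   (ratio units); see formula above.
#' @param epsilon_frac Plateau-onset definition passed to [growth_params()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list of class `synthetic_cohort` with elements
#'   `cohort` (subject table: `subject_id, age, sex, species, session`),
#'   `ratios` (long table: `subject_id, age, sex, species, session, parcel,
#'   depth_bin, ratio`), and `truth` (per species x parcel x bin:
#'   `species, parcel, depth_bin, baseline, amplitude, rate, plateau_onset`,
#'   rate and onset in the species' recorded age unit).
#' @export
simulate_cohort <- function(n_subjects = c(human = 400, macaque = 34),
                            n_parcels = 60,
                            n_depth_bins = 5,
                            axis_spec = list(onset_min = 12, onset_max = 26),
                            depth_spec = list(onset_step = 1.2,
                                              amplitude_deep = 0.95,
                                              amplitude_superficial = 0.30,
                                              baseline_step = 0.04),
                            species = c("human", "macaque", "both"),
                            species_scale = 4,
                            age_range = NULL,
                            n_sessions = NULL,
                            baseline = 1.2,
                            noise_sd = 0.15,
                            sex_effect = 0.02,
                            subject_sd = 0.03,
                            epsilon_frac = 0.01,
                            seed = 1L) {
  species <- match.arg(species)
  stopifnot(is_scalar_num(n_parcels), n_parcels >= 1,
            is_scalar_num(n_depth_bins), n_depth_bins >= 1)
  stop_if_not_scalar_pos(species_scale, "species_scale")
  if (any(n_subjects < 10)) stop("`n_subjects` must be >= 10", call. = FALSE)

  onsets <- resolve_axis_spec(axis_spec, n_parcels)
  depth <- resolve_depth_spec(depth_spec, n_depth_bins)

  arms <- if (species == "both") c("human", "macaque") else species
  n_sub <- rep_len(n_subjects, length(arms))
  if (!is.null(names(n_subjects)) && all(arms %in% names(n_subjects))) {
    n_sub <- unname(n_subjects[arms])
  }

  with_local_seed(seed, {
    out <- lapply(seq_along(arms), function(i) {
      simulate_arm(
        species = arms[i], n_subjects = n_sub[i],
        onsets = onsets, depth = depth,
        species_scale = species_scale,
        age_range = arm_age_range(age_range, arms[i]),
        n_sessions = arm_sessions(n_sessions, arms[i]),
        baseline = baseline, noise_sd = noise_sd,
        sex_effect = sex_effect, subject_sd = subject_sd,
        epsilon_frac = epsilon_frac
      )
    })
    res <- list(
      cohort = do.call(rbind, lapply(out, `[[`, "cohort")),
      ratios = do.call(rbind, lapply(out, `[[`, "ratios")),
      truth  = do.call(rbind, lapply(out, `[[`, "truth"))
    )
    rownames(res$cohort) <- rownames(res$ratios) <- rownames(res$truth) <- NULL
    res$params <- list(n_parcels = n_parcels, n_depth_bins = n_depth_bins,
                       onsets = onsets, depth = depth,
                       species_scale = species_scale, seed = seed,
                       noise_sd = noise_sd, sex_effect = sex_effect,
                       subject_sd = subject_sd, baseline = baseline,
                       epsilon_frac = epsilon_frac)
    class(res) <- "synthetic_cohort"
    res
  })
}

# Parcel-rank -> deepest-bin plateau onset (human years), monotone required.
resolve_axis_spec <- function(axis_spec, n_parcels) {
  if (is.numeric(axis_spec)) {
    if (length(axis_spec) != n_parcels) {
      stop("numeric `axis_spec` must have length `n_parcels`", call. = FALSE)
    }
    onsets <- as.numeric(axis_spec)
  } else if (is.list(axis_spec)) {
    stopifnot(is_scalar_num(axis_spec$onset_min), is_scalar_num(axis_spec$onset_max))
    onsets <- seq(axis_spec$onset_min, axis_spec$onset_max, length.out = n_parcels)
  } else {
    stop("`axis_spec` must be a numeric vector or list(onset_min=, onset_max=)",
         call. = FALSE)
  }
  if (any(onsets <= 0)) stop("plateau onsets must be positive", call. = FALSE)
  if (is.unsorted(onsets)) {
    stop("`axis_spec` must map parcel rank to plateau onset monotonically (non-decreasing)",
         call. = FALSE)
  }
  onsets
}

# Depth-bin profile: onset offsets (non-decreasing with superficiality),
# amplitudes (non-increasing) and baseline offsets (non-increasing).
resolve_depth_spec <- function(depth_spec, K) {
  if (!is.list(depth_spec)) stop("`depth_spec` must be a list", call. = FALSE)
  if (!is.null(depth_spec$onset_offsets)) {
    off <- as.numeric(depth_spec$onset_offsets)
    amp <- as.numeric(depth_spec$amplitudes)
    bas <- as.numeric(depth_spec$baselines)
    if (length(off) != K || length(amp) != K || length(bas) != K) {
      stop("explicit `depth_spec` vectors must have length `n_depth_bins`",
           call. = FALSE)
    }
  } else {
    stopifnot(is_scalar_num(depth_spec$onset_step),
              is_scalar_num(depth_spec$amplitude_deep),
              is_scalar_num(depth_spec$amplitude_superficial),
              is_scalar_num(depth_spec$baseline_step))
    off <- (seq_len(K) - 1) * depth_spec$onset_step
    amp <- seq(depth_spec$amplitude_deep, depth_spec$amplitude_superficial,
               length.out = K)
    bas <- (K - seq_len(K)) * depth_spec$baseline_step
  }
  if (is.unsorted(off)) {
    stop("`depth_spec` must give non-decreasing onset offsets from deep to superficial",
         call. = FALSE)
  }
  if (is.unsorted(rev(amp)) || any(amp < 0)) {
    stop("`depth_spec` amplitudes must be non-negative and non-increasing with superficiality",
         call. = FALSE)
  }
  list(onset_offsets = off, amplitudes = amp, baselines = bas)
}

arm_age_range <- function(age_range, species) {
  default <- if (species == "human") c(5.5, 36) else c(1, 36)
  r <- if (is.null(age_range)) {
    default
  } else if (is.list(age_range)) {
    if (is.null(age_range[[species]])) default else age_range[[species]]
  } else {
    age_range
  }
  stopifnot(length(r) == 2, r[1] > 0, r[2] > r[1])
  r
}

arm_sessions <- function(n_sessions, species) {
  if (is.null(n_sessions)) {
    return(if (species == "human") 1L else 5L)
  }
  s <- if (is.list(n_sessions) && !is.null(n_sessions[[species]])) {
    n_sessions[[species]]
  } else {
    n_sessions
  }
  as.integer(s[1])
}

# Ground-truth growth parameters for one arm. Human-years onsets are
# converted to the macaque clock (months) via the species time compression.
arm_growth_params <- function(species, onsets, depth, species_scale,
                              baseline, epsilon_frac) {
  K <- length(depth$onset_offsets)
  P <- length(onsets)
  grid <- expand.grid(depth_bin = seq_len(K), parcel = seq_len(P))
  onset_h <- onsets[grid$parcel] + depth$onset_offsets[grid$depth_bin]
  rate_h <- -log(epsilon_frac) / onset_h           # per human-year
  if (species == "human") {
    rate <- rate_h
    onset <- onset_h
  } else {
    # macaque age m months maps to human age species_scale * m / 12 years
    rate <- rate_h * species_scale / 12            # per macaque-month
    onset <- onset_h * 12 / species_scale          # months
  }
  data.frame(
    species = species,
    parcel = grid$parcel,
    depth_bin = grid$depth_bin,
    baseline = baseline + depth$baselines[grid$depth_bin],
    amplitude = depth$amplitudes[grid$depth_bin],
    rate = rate,
    plateau_onset = onset,
    stringsAsFactors = FALSE
  )
}

simulate_arm <- function(species, n_subjects, onsets, depth, species_scale,
                         age_range, n_sessions, baseline, noise_sd,
                         sex_effect, subject_sd, epsilon_frac) {
  truth <- arm_growth_params(species, onsets, depth, species_scale,
                             baseline, epsilon_frac)
  ids <- sprintf("%s%03d", if (species == "human") "H" else "M",
                 seq_len(n_subjects))
  sex <- sample(c("F", "M"), n_subjects, replace = TRUE)
  b_sub <- stats::rnorm(n_subjects, 0, subject_sd)

  # stratified increasing ages per subject: covers the range, strictly
  # increasing across sessions with probability one
  width <- diff(age_range)
  ages <- lapply(seq_len(n_subjects), function(i) {
    age_range[1] + width * ((seq_len(n_sessions) - 1) + stats::runif(n_sessions)) / n_sessions
  })
  cohort <- data.frame(
    subject_id = rep(ids, each = n_sessions),
    age = unlist(ages),
    sex = rep(sex, each = n_sessions),
    species = species,
    session = rep(seq_len(n_sessions), times = n_subjects),
    stringsAsFactors = FALSE
  )

  n_obs <- nrow(cohort)
  n_cell <- nrow(truth)
  # long table: observation rows crossed with parcel x bin cells
  idx_obs <- rep(seq_len(n_obs), each = n_cell)
  idx_cell <- rep(seq_len(n_cell), times = n_obs)
  mu <- truth$baseline[idx_cell] +
    truth$amplitude[idx_cell] * (1 - exp(-truth$rate[idx_cell] * cohort$age[idx_obs]))
  y <- mu +
    sex_effect * (cohort$sex[idx_obs] == "M") +
    rep(rep(b_sub, each = n_sessions), each = n_cell)[seq_along(idx_obs)] +
    if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
  ratios <- data.frame(
    subject_id = cohort$subject_id[idx_obs],
    age = cohort$age[idx_obs],
    sex = cohort$sex[idx_obs],
    species = species,
    session = cohort$session[idx_obs],
    parcel = truth$parcel[idx_cell],
    depth_bin = truth$depth_bin[idx_cell],
    ratio = y,
    stringsAsFactors = FALSE
  )
  truth$noise_sd <- noise_sd
  truth$sex_effect <- sex_effect
  truth$subject_sd <- subject_sd
  list(cohort = cohort, ratios = ratios, truth = truth)
}
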