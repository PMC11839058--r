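#' Default pipeline configuration
#'
#' Study-scale defaults for the synthetic end-to-end run: a 60-parcel
#' cortex with 7-bin equivolume segmentation trimmed to 5 analysis bins,
#' 150 cross-sectional human subjects (ages 5.5-36 years) and 34
#' longitudinal macaques (5 sessions, 1-36 months), 10% k-means seed
#' subsampling for the geodesic axis, rank-3 REML smooths, 200-point age
#' grids, 10000-draw simultaneous bands, and 4:1 species scaling.
#'
#' @return Named list understood by [run_pipeline()].
#' @export
default_config <- function() {
  list(
    mode = "synthetic",
    out_dir = "results/pipeline",
    n_subjects = c(human = 400, macaque = 34),
    n_parcels = 60,
    k_depth_bins = 7,
    trim_extremes = TRUE,
    mesh = list(n_rows = 30, n_cols = 50, parcel_blocks = c(6, 10)),
    cluster_fraction = 0.1,
    smooth_k = 3,
    grid_points = 200,
    n_draws = 10000,
    level = 0.95,
    fdr_alpha = 0.05,
    depth_plateaus = TRUE,
    species_scaling = list(factor = 4, human_baseline_age = 4,
                           macaque_baseline_age = 1),
    seeds = list(cohort = 11, kmeans = 13, band = 17)
  )
}

#' Run the full synthetic-cortex pipeline
#'
#' Executes every stage end-to-end on synthetic data with known ground
#' truth: cohort simulation, phantom equivolume QC, geodesic
#' sensorimotor-association axis with tertile groups, per-parcel and
#' per-depth-bin trajectory fits with signed partial R-squared and FDR,
#' derivative-band plateau detection with group summaries and ANOVAs,
#' depth-slope ANOVAs, and cross-species 4:1 scaling recovery. All
#' randomness flows from `config$seeds`, so identical configurations give
#' byte-identical output tables.
#'
#' Outputs written under `config$out_dir`: `axis.csv`, `profiles.csv`,
#' `phantom_qc.csv`, `effects.csv`, `plateaus.csv`, `plateau_groups.csv`,
#' `depth_anova.csv`, `summary.json`, `run_log.txt`.
#'
#' @param config List as produced by [default_config()]; partial lists are
#'   completed with the defaults.
#' @return Invisibly, a list with all result tables plus `summary`.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- utils::modifyList(default_config(), config, keep.null = TRUE)
  if (!identical(config$mode, "synthetic")) {
    stop("stage[config]: only `mode = \"synthetic\"` is implemented; real-data ",
         "runs require externally preprocessed volumes", call. = FALSE)
  }
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage[%s]: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  n_bins <- config$k_depth_bins - if (config$trim_extremes) 2L else 0L

  sim <- stage("synthetic_cortex", simulate_cohort(
    n_subjects = config$n_subjects, n_parcels = config$n_parcels,
    n_depth_bins = n_bins, species = "both",
    species_scale = config$species_scaling$factor,
    seed = config$seeds$cohort
  ))

  axis <- stage("surface_axis", pipeline_axis(config))
  qc <- stage("myelin_maps", pipeline_phantom_qc(config))

  grid_h <- NULL  # per-species grids are built from each arm's age range
  fits <- stage("trajectory_model", pipeline_fits(sim, config))
  plat <- stage("plateau_inference", pipeline_plateaus(fits, axis, config))
  cmp <- stage("compare_report", pipeline_compare(sim, fits, axis, plat, config))

  res <- c(list(axis = axis, phantom_qc = qc, truth = sim$truth,
                profiles = sim$ratios), fits["effects"], plat, cmp)
  stage("write_outputs", write_pipeline_outputs(res, sim, config))
  invisible(res)
}

validate_config <- function(config) {
  need <- c("out_dir", "n_parcels", "k_depth_bins", "cluster_fraction",
            "grid_points", "n_draws", "level", "fdr_alpha", "seeds",
            "species_scaling", "mesh")
  miss <- need[!need %in% names(config) |
                 vapply(config[need], is.null, logical(1))]
  if (length(miss)) {
    stop(sprintf("config is missing field(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (config$k_depth_bins < 3) stop("`k_depth_bins` must be >= 3", call. = FALSE)
  invisible(config)
}

# geodesic S-A axis on the toy lattice: seed parcels are the final column
# block (association end), so parcel index increases towards the seeds
pipeline_axis <- function(config) {
  m <- config$mesh
  mesh <- make_grid_mesh(m$n_rows, m$n_cols, spacing = 1,
                         parcel_blocks = m$parcel_blocks)
  pb <- m$parcel_blocks
  seed_parcels <- (pb[2] - 1) * pb[1] + seq_len(pb[1])
  seeds <- select_seed_nodes(mesh, seed_parcels,
                             cluster_fraction = config$cluster_fraction,
                             seed = config$seeds$kmeans)
  d <- geodesic_distance(mesh, seeds)
  axis <- parcel_axis(d, mesh$parcel)
  assign_groups(axis)
}

# annulus phantom: equivolume bin balance and boundary accuracy
pipeline_phantom_qc <- function(config) {
  K <- config$k_depth_bins
  rb <- make_phantom_ribbon("annulus", 10, 12, voxel_size = 0.1,
                            grid_shape = c(280, 280, 3))
  bins <- assign_depth_bins(rb, K)
  counts <- tabulate(bins[bins > 0L], nbins = K)
  data.frame(depth_bin = seq_len(K), n_voxels = counts,
             volume_fraction = counts / sum(counts),
             target_fraction = 1 / K)
}

# per-parcel and per-parcel x depth-bin trajectory fits for both arms
pipeline_fits <- function(sim, config) {
  ratios <- sim$ratios
  effects <- list()
  fits_parcel <- list()
  slopes_bin <- list()
  for (sp in unique(ratios$species)) {
    arm <- ratios[ratios$species == sp, , drop = FALSE]
    re <- sp == "macaque"          # longitudinal arm
    # parcel-level: average across depth bins within observation
    key <- paste(arm$subject_id, arm$session, arm$parcel)
    agg <- stats::aggregate(arm$ratio, by = list(key = key), FUN = mean)
    meta <- arm[!duplicated(key), c("subject_id", "age", "sex", "session", "parcel")]
    meta <- meta[match(agg$key, paste(meta$subject_id, meta$session, meta$parcel)), ]
    parcel_dat <- data.frame(meta, value = agg$x)
    for (p in sort(unique(parcel_dat$parcel))) {
      d <- parcel_dat[parcel_dat$parcel == p, ]
      d <- data.frame(age = d$age, value = d$value, sex = d$sex,
                      subject = d$subject_id)
      full <- fit_gam(d, random_intercepts = re)
      reduced <- fit_gam(d, random_intercepts = re, include_age = FALSE)
      grid <- seq(full$age_range[1], full$age_range[2],
                  length.out = config$grid_points)
      eff <- age_effect(full, reduced, grid)
      effects[[length(effects) + 1L]] <- data.frame(
        species = sp, parcel = p, depth_bin = NA_integer_,
        r2_partial = eff$r2_partial, sign = eff$sign, p_value = eff$p_value,
        mean_slope = mean_slope(full, grid), edf = full$edf,
        lambda = full$lambda, stringsAsFactors = FALSE)
      fits_parcel[[paste(sp, p)]] <- full
    }
    # depth-bin level: per parcel x bin mean slopes
    for (p in sort(unique(arm$parcel))) {
      for (k in sort(unique(arm$depth_bin))) {
        d <- arm[arm$parcel == p & arm$depth_bin == k, ]
        d <- data.frame(age = d$age, value = d$ratio, sex = d$sex,
                        subject = d$subject_id)
        full <- fit_gam(d, random_intercepts = re)
        grid <- seq(full$age_range[1], full$age_range[2],
                    length.out = config$grid_points)
        slopes_bin[[length(slopes_bin) + 1L]] <- data.frame(
          species = sp, parcel = p, depth_bin = k,
          mean_slope = mean_slope(full, grid), edf = full$edf,
          stringsAsFactors = FALSE)
      }
    }
  }
  effects <- do.call(rbind, effects)
  # FDR within each species' parcel family
  effects$q_value <- NA_real_
  for (sp in unique(effects$species)) {
    i <- effects$species == sp
    effects$q_value[i] <- fdr_correct(effects$p_value[i])
  }
  list(effects = effects, fits_parcel = fits_parcel,
       slopes_bin = do.call(rbind, slopes_bin))
}

pipeline_plateaus <- function(fits, axis, config) {
  effects <- fits$effects
  plateaus <- list()
  for (nm in names(fits$fits_parcel)) {
    parts <- strsplit(nm, " ")[[1]]
    fit <- fits$fits_parcel[[nm]]
    grid <- seq(fit$age_range[1], fit$age_range[2],
                length.out = config$grid_points)
    unit_seed <- config$seeds$band + 1000L * (parts[1] == "macaque") +
      as.integer(parts[2])
    band <- derivative_band(fit, grid, n_draws = config$n_draws,
                            level = config$level, seed = unit_seed)
    pa <- plateau_age(band)
    plateaus[[nm]] <- data.frame(
      species = parts[1], parcel = as.integer(parts[2]),
      plateau_age = pa$plateau_age, flag = pa$flag, stringsAsFactors = FALSE)
  }
  plateaus <- do.call(rbind, plateaus)
  rownames(plateaus) <- NULL
  ep <- effects[is.na(effects$depth_bin), , drop = FALSE]
  plateaus$q <- ep$q_value[match(paste(plateaus$species, plateaus$parcel),
                                 paste(ep$species, ep$parcel))]

  groups <- data.frame(unit = axis$parcel, group = axis$group)
  summaries <- lapply(split(plateaus, plateaus$species), function(s) {
    pl <- data.frame(unit = s$parcel, plateau_age = s$plateau_age,
                     flag = s$flag, q = s$q)
    plateau_summary(pl, groups, alpha = config$fdr_alpha)
  })
  list(plateaus = plateaus, group_summaries = summaries)
}

pipeline_compare <- function(sim, fits, axis, plat, config) {
  sc <- do.call(species_scaling, config$species_scaling)  # validates config
  slopes <- fits$slopes_bin
  # deep-vs-superficial contrast per parcel (human arm)
  hs <- slopes[slopes$species == "human", ]
  kmin <- min(hs$depth_bin); kmax <- max(hs$depth_bin)
  deep <- hs$mean_slope[hs$depth_bin == kmin][order(hs$parcel[hs$depth_bin == kmin])]
  sup <- hs$mean_slope[hs$depth_bin == kmax][order(hs$parcel[hs$depth_bin == kmax])]
  deep_fraction <- mean(deep > sup)

  # slope-vs-axis association (parcel-level human slopes along the axis)
  eh <- fits$effects
  eh <- eh[eh$species == "human" & is.na(eh$depth_bin), ]
  sva <- slope_vs_axis(data.frame(parcel = eh$parcel, slope = eh$mean_slope), axis)

  # depth-slope ANOVA per group and species
  m <- merge(slopes, axis[, c("parcel", "group")], by = "parcel")
  depth_anova <- do.call(rbind, lapply(split(m, m$species), function(s) {
    out <- depth_slope_anova(data.frame(parcel = s$parcel,
                                        depth_bin = s$depth_bin,
                                        group = s$group, slope = s$mean_slope))
    out$species <- s$species[1]
    out
  }))
  rownames(depth_anova) <- NULL

  # cross-species scaling on paired group- and depth-trajectory tables
  # (macaque months converted to years)
  scal <- estimate_scaling(
    species_trajectories(sim, axis, "human"),
    species_trajectories(sim, axis, "macaque")
  )

  # hierarchy recovery: true onset rank vs recovered plateau-age rank
  th <- sim$truth[sim$truth$species == "human" & sim$truth$depth_bin == 1, ]
  ph <- plat$plateaus[plat$plateaus$species == "human", ]
  mjoin <- merge(th[, c("parcel", "plateau_onset")], ph, by = "parcel")
  ok <- mjoin$flag == "plateau"
  spearman <- if (sum(ok) >= 3) {
    stats::cor(mjoin$plateau_onset[ok], mjoin$plateau_age[ok],
               method = "spearman")
  } else NA_real_

  list(summary = list(
    s_hat = scal$s_hat,
    scaling_objective = scal$objective,
    hierarchy_spearman = spearman,
    n_plateaued_human = sum(ok),
    deep_vs_superficial_fraction = deep_fraction,
    slope_vs_axis_r2_linear = sva$r2_linear,
    slope_vs_axis_sign = sign(sva$slope_linear)
  ), depth_anova = depth_anova)
}

#' Mean trajectory tables for cross-species alignment
#'
#' Builds, for one species arm of a synthetic cohort, the list of mean
#' trajectory tables used by [estimate_scaling()]: one per hierarchy
#' group (parcel set from the axis map) and one per depth bin, each a
#' per-scan mean of the ratio observations. Macaque ages (months) are
#' converted to years so both species share an age unit.
#'
#' @param sim A [simulate_cohort()] result with both arms.
#' @param axis An `axis_map` with groups, parcels matching the cohort's.
#' @param species `"human"` or `"macaque"`.
#' @return List of data frames (`age`, `value`, `sex`, `subject`).
#' @export
species_trajectories <- function(sim, axis, species) {
  r <- sim$ratios[sim$ratios$species == species, , drop = FALSE]
  grp <- axis$group[match(r$parcel, axis$parcel)]
  sel_list <- c(
    lapply(levels(axis$group), function(g) grp == g),
    lapply(sort(unique(r$depth_bin)), function(k) r$depth_bin == k)
  )
  lapply(sel_list, function(sel) {
    rr <- r[sel, , drop = FALSE]
    key <- paste(rr$subject_id, rr$session)
    agg <- stats::aggregate(rr$ratio, by = list(key = key), FUN = mean)
    meta <- rr[!duplicated(key), c("subject_id", "age", "sex", "session")]
    meta <- meta[match(agg$key, paste(meta$subject_id, meta$session)), ]
    age <- if (species == "macaque") meta$age / 12 else meta$age
    data.frame(age = age, value = agg$x, sex = meta$sex,
               subject = meta$subject_id)
  })
}

write_pipeline_outputs <- function(res, sim, config) {
  out <- config$out_dir
  wcsv <- function(x, f) utils::write.csv(x, file.path(out, f), row.names = FALSE)
  wcsv(data.frame(parcel = res$axis$parcel, distance_mm = res$axis$distance,
                  rank = res$axis$rank, group = as.character(res$axis$group)),
       "axis.csv")
  wcsv(res$phantom_qc, "phantom_qc.csv")
  wcsv(sim$ratios, "profiles.csv")
  wcsv(sim$truth, "truth.csv")
  wcsv(res$effects, "effects.csv")
  wcsv(res$plateaus, "plateaus.csv")
  groups <- do.call(rbind, lapply(names(res$group_summaries), function(sp) {
    g <- res$group_summaries[[sp]]$by_group
    g$species <- sp
    g$anova_F <- res$group_summaries[[sp]]$anova$F
    g$anova_p <- res$group_summaries[[sp]]$anova$p
    g
  }))
  wcsv(groups, "plateau_groups.csv")
  wcsv(res$depth_anova, "depth_anova.csv")
  summary <- c(res$summary, list(config_hash = config_hash(config)))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    "corticalmyelin pipeline run",
    sprintf("package version: %s",
            as.character(utils::packageVersion("corticalmyelin"))),
    sprintf("config hash: %s", config_hash(config)),
    sprintf("seeds: cohort=%d kmeans=%d band=%d", config$seeds$cohort,
            config$seeds$kmeans, config$seeds$band)
  ), file.path(out, "run_log.txt"))
  invisible(out)
}
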