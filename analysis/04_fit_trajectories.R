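#!/usr/bin/env Rscript
# Stage 4 -- per-parcel developmental trajectory fits.
#
# Rebuilds the stage-1 cohort, fits the rank-3 REML smooth per parcel
# (bin-averaged ratios; subject random intercepts for the longitudinal
# macaques), quantifies each parcel's age effect as a signed partial R2
# with BH-FDR, and regresses the mean developmental slopes on the axis
# rank, which should fall off towards the association end.

suppressPackageStartupMessages(library(corticalmyelin))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

sim <- simulate_cohort(species = "both", seed = 11)
axis <- read.csv("results/analysis/axis.csv")

fit_parcels <- function(sp) {
  r <- sim$ratios[sim$ratios$species == sp, ]
  key <- paste(r$subject_id, r$session, r$parcel)
  agg <- aggregate(r$ratio, by = list(key = key), FUN = mean)
  meta <- r[!duplicated(key), c("subject_id", "age", "sex", "session", "parcel")]
  meta <- meta[match(agg$key, paste(meta$subject_id, meta$session, meta$parcel)), ]
  pd <- data.frame(meta, value = agg$x)
  do.call(rbind, lapply(sort(unique(pd$parcel)), function(p) {
    d <- pd[pd$parcel == p, ]
    d <- data.frame(age = d$age, value = d$value, sex = d$sex,
                    subject = d$subject_id)
    full <- fit_gam(d, random_intercepts = sp == "macaque")
    red <- fit_gam(d, random_intercepts = sp == "macaque", include_age = FALSE)
    eff <- age_effect(full, red)
    data.frame(species = sp, parcel = p, r2_partial = eff$r2_partial,
               sign = eff$sign, p_value = eff$p_value,
               mean_slope = mean_slope(full), edf = full$edf,
               lambda = full$lambda)
  }))
}

effects <- rbind(fit_parcels("human"), fit_parcels("macaque"))
effects$q_value <- ave(effects$p_value, effects$species, FUN = fdr_correct)

for (sp in c("human", "macaque")) {
  e <- effects[effects$species == sp, ]
  cat(sprintf("%s: signed partial R2 range %.3f-%.3f, %d/%d parcels significant (q <= .05)\n",
              sp, min(e$r2_partial), max(e$r2_partial),
              sum(e$q_value <= 0.05), nrow(e)))
  sva <- slope_vs_axis(data.frame(parcel = e$parcel, slope = e$mean_slope),
                       structure(axis[, c("parcel", "rank")],
                                 class = c("axis_map", "data.frame")))
  cat(sprintf("  slope vs axis rank: linear R2 = %.3f (p = %.2g), trend %s along the axis\n",
              sva$r2_linear, sva$p_linear,
              ifelse(sva$slope_linear < 0, "decreasing", "increasing")))
}

write.csv(effects, "results/analysis/effects.csv", row.names = FALSE)
cat("wrote results/analysis/effects.csv\n")
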