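# corticalmyelin

Depth-resolved cortical myelination trajectories from T1w/T2w ratio maps.

Intracortical myelin matures along two organizing dimensions: across the
cortical hierarchy (sensorimotor regions myelinate earlier and more
heavily than association regions) and across cortical depth (deep,
white-adjacent laminae lead superficial ones — the "inside-out" pattern).
This package implements, as a tested and reusable pipeline, the analysis
chain needed to quantify both dimensions developmentally and to compare
them between humans and macaques under the canonical ~4:1 developmental
time scaling:

1. **Myelin maps** — voxel-wise T1w/T2w ratio volumes, calibrated per
   subject with a two-point affine anchor on reference structures
   (ventricles; corpus callosum or pons), and parcel × depth profiles
   from **equivolumetric depth bins** (bin boundaries placed so each
   compartment holds equal tissue volume, compensating curvature;
   closed form `rho(alpha) = (-A_w + sqrt((1-alpha)A_w^2 + alpha A_p^2)) / (A_p - A_w)`).
2. **Sensorimotor–association (S-A) axis** — per-parcel minimum geodesic
   distance along the midthickness mesh from default-mode seed vertices
   (k-means-subsampled), ranked and split into equal-count tertiles.
3. **Trajectory model** — for each parcel (and depth bin), a penalized
   rank-3 thin-plate smooth of age with REML-selected smoothing, a ±0.5
   sex contrast and optional subject random intercepts:
   `y ~ β0 + β_sex·sex + f(age)`, with the age effect quantified as the
   signed partial R² between the full and age-free nested fits
   (`ΔR² = R²_full − R²_reduced`, signed by the mean first derivative)
   and BH-FDR across parcels.
4. **Plateau inference** — a simultaneous 95% confidence band on the
   analytic first derivative `Δratio/Δage` (10000 coefficient-posterior
   draws; max-deviation critical multiplier), with the plateau age
   defined as the earliest age from which the band contains zero through
   the end of the observed range; plateau proportions, mean timing and
   one-way ANOVAs by hierarchy group and depth bin.
5. **Cross-species comparison** — age rescaling (`human = s × macaque`,
   s = 4), baseline-anchored trajectory overlays, and a recovery harness
   that estimates s by profiling a shape misfit over candidate factors.

The study-scale human and macaque imaging cohorts such analyses run on
are controlled-access, so the package ships a first-class
**synthetic-cortex generator**: phantom ribbons with analytically known
equivolume boundaries, toy labeled meshes, and two-species cohorts of
saturating growth curves whose plateau timing increases along a synthetic
S-A axis and whose depth profile follows the inside-out pattern, with an
exact 4:1 macaque:human time compression. Every stage is tested against
that known ground truth (plus closed-form, brute-force and `mgcv`
oracles).

## Worked example

Fit one sensorimotor-end parcel of the default synthetic human cohort
(400 subjects, ages 5.5–36 y) and ask when it plateaus:

```r
library(corticalmyelin)

sim <- simulate_cohort(species = "human", seed = 11)
h <- sim$ratios[sim$ratios$parcel == 5, ]            # sensorimotor end
agg <- aggregate(h$ratio, by = list(key = h$subject_id), FUN = mean)
meta <- h[!duplicated(h$subject_id), c("subject_id", "age", "sex")]
d <- data.frame(age = meta$age, sex = meta$sex,
                value = agg$x[match(meta$subject_id, agg$key)])

full <- fit_gam(d)                      # rank-3 REML smooth + sex
reduced <- fit_gam(d, include_age = FALSE)
print(full)
#> Penalized smooth age-trajectory fit (k = 3)
#>   n = 400, edf = 3.90, sigma^2 = 0.004942, R^2 = 0.097
#>   lambda (curvature) = 44.06

eff <- age_effect(full, reduced)
sprintf("signed partial R2 = %+.3f (p = %.3g)", eff$r2_signed, eff$p_value)
#> "signed partial R2 = +0.086 (p = 1.35e-08)"

band <- derivative_band(full, n_draws = 10000, seed = 22)
plateau_age(band)$plateau_age
#> 23.35275
```

The parcel shows a positive age effect (partial R² ≈ 0.09) and its
derivative band contains zero from about 23 years on: the trajectory has
plateaued inside the observed window. Association-end parcels of the
same cohort typically return `flag = "no-plateau"` — their growth
continues past 36 years — reproducing the hierarchy-graded maturation
the pipeline is designed to detect. (Exact numbers vary with the
cohort and band seeds; these were printed by the code above.)

The numbered drivers under `analysis/` run the whole study on the
default synthetic cortex and write small tables under
`results/analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R    # cohort + ground truth
Rscript analysis/02_equivolume_phantom.R # phantom bin-balance QC
Rscript analysis/03_surface_axis.R       # geodesic S-A axis + tertiles
Rscript analysis/04_fit_trajectories.R   # per-parcel fits, partial R2, FDR
Rscript analysis/05_plateau_detection.R  # derivative bands, plateau summaries
Rscript analysis/06_cross_species.R      # 4:1 scaling recovery, depth ANOVAs
```

`run_pipeline(default_config())` executes the same stages in one call
and writes a flat, diffable result bundle (`axis.csv`, `effects.csv`,
`plateaus.csv`, `depth_anova.csv`, `summary.json`, ...); identical
configurations produce byte-identical outputs.

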