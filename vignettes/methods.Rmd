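---
title: "Depth-resolved cortical myelination trajectories: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved cortical myelination trajectories: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models it
fits, the geometric transforms it applies, the synthetic study design it
uses to test itself, and the numerical and statistical choices that were
genuinely open. The worked numbers live in `README.md` and in the
`analysis/` drivers; nothing here asserts a result the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement: calibrated T1w/T2w ratio at cortical depths

The T1w/T2w ratio — a T1-weighted MR volume divided voxel-wise by a
co-registered T2-weighted volume — cancels the receive-coil sensitivity
profile and enhances intracortical myelin contrast. Its units are
arbitrary: they depend on scanner and sequence, so levels are never
compared across studies or species, only within a calibrated cohort.
`compute_ratio()` performs the division inside a mask and treats any
in-mask T2w voxel at or below a floor (default `1e-6` in native units) as
a hard error, because such voxels would blow up the quotient silently.

Per-subject maps are aligned to the group by `calibrate_ratio()`, a
two-point affine map anchored on a low-intensity reference (ventricles)
and a high-intensity reference (corpus callosum in humans, pons in
macaques): the subject's own ROI means are mapped exactly onto the
group-averaged means. Among maps that remove per-subject scale and
offset, the two-point anchor is the one that needs no distributional
assumptions; the ROI summary statistic is the mean by default (median
available). The map is monotone, so it preserves all rank-based
downstream structure.

## Equivolumetric depth bins

Cortical "layers" at MRI resolution are approximated by K equal-volume
compartments between the white and pial surfaces. For a column whose
cross-sectional area grows linearly from `A_w` (white) to `A_p` (pial),
the depth fraction enclosing volume fraction `alpha` has the closed form

$$\rho(\alpha) = \frac{-A_w + \sqrt{(1-\alpha)A_w^2 + \alpha A_p^2}}{A_p - A_w},$$

reducing to `rho = alpha` for a flat slab. This compensates curvature:
bins are thinner where the bounding surface is larger (gyral crowns).
`equivolume_rho()` switches to the slab limit when `|A_p - A_w|` falls
below `1e-12` times the larger area, avoiding the 0/0 form; the unit
tests check it against brute-force numerical inversion of the cumulative
volume integral to `1e-9`.

Voxels are binned by their cumulative volume fraction: bin `k` covers
`[(k-1)/K, k/K)`, with `alpha = 1` assigned to bin K; bin 1 is always the
deepest (white-adjacent) bin. Two segmentations are used, mirroring
common practice: K = 6 for descriptive depth profiles (one bin per
histological layer), and K = 7 with the two border bins discarded
(`trim_extreme_bins()`, leaving 5 relabeled analysis bins) for
developmental modeling, because the outermost bins are most contaminated
by white matter and CSF partial-volume effects. Phantom ribbons (slab,
annulus, spherical shell) with analytically known bin boundaries validate
the discretization; at voxel sizes of a twentieth of the ribbon
thickness, per-bin volumes balance to within 2%.

For real ribbons the normalized geometric depth coordinate is consumed as
input (`depth_bins_from_rho()`), not recomputed: reproducing a full
Laplacian or columnar coordinate field is out of scope; the equivolume
transform from geometric depth to volume-fraction bins is in scope.

## The sensorimotor–association axis

The cortical hierarchy is proxied by geodesic distance along the
midthickness surface from default-mode (association) seed regions:
association cortex is near the seeds, sensorimotor cortex far. Distances
are multi-source shortest paths on the mesh edge graph with Euclidean
edge weights (`geodesic_distance()`, via igraph). This approximates the
true polyhedral geodesic from above; on right-triangulated lattices paths
are restricted to axis and single-diagonal moves, a known bias of the
edge-graph approximation that is immaterial for rank-based use. An
exhaustive Dijkstra oracle verifies exact agreement on random meshes in
the tests.

Seed vertices are chosen by k-means subsampling: seed-parcel vertices are
clustered on their 3-D coordinates into C clusters (default
`max(10, n/100)`, keeping granularity resolution-independent) and 10% of
the clusters, drawn uniformly under a fixed seed, contribute all their
member vertices. "Seed nodes" are read as member vertices rather than
centroids — centroids need not lie on the mesh.

Parcels get the mean of their vertices' minimum distances, are ranked
ascending (ties broken lexicographically by parcel label, for
determinism), and split into contiguous equal-count thirds: association
(nearest seeds), middle, sensorimotor. A remainder goes to the middle
group, so 400 parcels split 133/134/133. Group assignment is invariant to
any monotone transform of the distances. When an external hierarchy axis
is available, `validate_axis()` reports its Spearman correlation with the
geodesic axis over shared parcels.

## Trajectory model: a rank-3 penalized smooth with REML

Each unit's (parcel, or parcel × depth bin) trajectory is

`value ~ intercept + sex + s(age, k = 3) [+ subject random intercepts]`

with sex coded as a symmetric ±0.5 contrast (M = +0.5) and the smooth a
rank-3 thin-plate regression spline: radial basis `r^3/12` on knots at
the unique ages, eigen-truncated to the three dominant directions, side
conditions absorbed so that exactly one ridge-penalized curvature
function remains beside the unpenalized null space {1, age}. At `k = 3`
the smooth can bend once — what a monotone saturating trajectory needs —
and cannot chase noise; constants and straight lines are reproduced
exactly at every smoothing level (the suite asserts this at
`lambda` 0, 1 and `1e6`). The curvature column is centered against
{1, age} on the training ages and scaled to unit RMS; this
reparameterization changes nothing about the fitted family but keeps the
REML search well-scaled.

Smoothing is selected by exact Gaussian restricted maximum likelihood
with the scale profiled out:

$$-\,l_r = \tfrac{n-M}{2}\{\log(2\pi\hat\sigma^2)+1\} + \tfrac12\{\log|C^\top C+S| - \log|S|_+\},$$

minimized over `log(lambda)` by golden-section search on `[-18, 28]`
(tolerance `1e-8`). Subject random intercepts for the longitudinal
macaque arm are a ridge-penalized indicator block whose precision is a
second REML variance component — the penalized-regression view of a
Gaussian random effect — optimized jointly by Nelder–Mead from a coarse
grid start, with one restart on non-convergence and an error (with the
objective value) if it still fails. The fits agree with `mgcv`
(`s(age, k = 3)`, `paraPen`, `bs = "re"`) to numerical precision in the
test suite; `mgcv` is used only as that independent cross-check, never as
the implementation.

A unit's age effect compares the full fit with the nested reduced fit
(the whole age term removed, all other structure identical): the
magnitude is `R²_full − R²_reduced` with R² computed on fixed-effects
fitted values (random intercepts excluded, so the difference reflects
age, not subjects), and the direction is the sign of the mean analytic
first derivative over the age grid. Significance uses the scaled
deviance drop `(RSS_red − RSS_full)/σ̂²` referred to `F(2, n − edf)`.
Two reference-distribution choices here were genuinely open and were
settled by simulation rather than convention: taking the degrees of
freedom as the *effective*-df difference rejects true nulls at roughly
twice the nominal rate (smoothing selection explores the full span of
the age term, so the drop behaves like a 2-df quantity even when the
selected edf is smaller), and a chi-squared reference with estimated
Gaussian scale is materially liberal in the far tail where FDR
thresholds operate. The parametric-dimension df with an F reference
holds both the test's size (0.05 ± 0.03 band) and the BH false-discovery
proportion in the suite's null simulations. Multiplicity is handled by
Benjamini–Hochberg within each analysis family (per species, across
parcels).

Mean developmental slopes are the mean of the analytic derivative
(basis derivative times coefficients — not finite differences; a
finite-difference cross-check sits in the tests) over a 200-point age
grid spanning the observed range.

## Plateau detection

The first derivative of each fitted smooth gets a simultaneous 95%
confidence band: coefficients are drawn from the Bayesian posterior
`N(β̂, V_β)` (10000 draws, seeded), and the critical multiplier `m*` is
the 0.95 quantile of the maximum standardized deviation over the grid.
A pointwise band would understate the multiplicity over 200 grid points;
`m*` is necessarily at least the pointwise 1.96 and the Monte-Carlo error
at 10000 draws is below 1%.

The plateau age is the *earliest age from which the band contains zero
through the end of the range* — a terminal state, robust to mid-range
dips of a noisy band onto zero, matching the idea that a plateau is
reached and kept. Three outcomes are distinguished: `plateau` (terminal
run starts inside the range, with significant positive growth somewhere
before), `no-plateau` (band excludes zero at the maximum age — growth
continues past the window), and `no-growth` (the band never excludes
zero from below; such units never showed detectable growth, which is not
the same as maturing early, and they are flagged rather than merged).

Units whose overall age effect does not survive FDR stay in plateau
*proportion* denominators (both denominators are reported) but are
excluded from timing means and the one-way timing ANOVA across hierarchy
groups. The ANOVA is `stats::aov` with two degenerate-layout guards:
zero between-group variance reports F = 0, zero within-group variance
reports a large finite F with a warning.

One behavior discovered while designing the synthetic study is worth
recording: for a truth that keeps rising gently to the end of the
window, the rank-3 projection has a small *negative* derivative bias at
the range end (order 0.003 ratio-units/year for saturating-exponential
truths on a 30-year window). With very low noise and large cohorts the
simultaneous band becomes tight enough to declare that bias significant,
and no unit ever plateaus. This is an interaction of the deliberately
stiff `k = 3` basis with the two-sided band rule, not a property of the
data; at realistic noise levels it is immaterial. It is the reason the
generator's noise default is calibrated to realistic between-subject
variability (below) rather than to an optimistic small value.

## Cross-species comparison

Macaque development runs roughly four times faster than human, so
macaque ages (recorded in months) are aligned to human years by
`human_age = s × macaque_age` with s = 4 by default. Because ratio units
are arbitrary, overlays always compare *baseline-adjusted* trajectories:
`baseline_adjust()` subtracts the fitted value at the anchor age
(defaults: 1 year macaque, 4 years human — corresponding ages under
s = 4), making the adjusted curve exactly zero there, and it refuses
anchors outside the fitted range.

`estimate_scaling()` is a recovery harness for the 4:1 figure: it
profiles a shape-misfit objective over candidate factors. Three design
points matter. First, trajectories fitted on each species' full range
carry window-dependent rank-3 smoothing bias that does not cancel across
species, so for every candidate `s` both members of each trajectory pair
are *refitted on the overlap window only*, aligning the bias. Second,
each refitted curve is anchored by subtracting its own window mean (the
L2-optimal offset alignment; fixed-age anchors are a display convention
and need not lie inside every candidate's window). Third, the objective
pools eight paired mean trajectories — the three hierarchy groups and
the five depth bins — as `Σ mean((ch−cm)²) / Σ mean(ch²+cm²)`; a single
grand-mean pair leaves the profile too flat for stable recovery.
Candidates need at least 30 observations per species and series inside
the window and at least one year of overlap; shape comparison on fewer
points is unreliable and produced spurious optima at sliver windows.
Coarse grid (step 0.2 on [1, 8]) plus golden-section refinement keeps
the estimate deterministic.

## The synthetic cortex: what it emulates, and what it does not

All tests run on synthetic data with known ground truth, because the
study-scale human and macaque cohorts sit behind controlled-access
agreements. The generator (`simulate_cohort()`) emulates the features the
pipeline's claims rest on:

* **Trajectory shape.** Saturating exponentials
  `baseline + amplitude(1 − e^{−rate·age})` — the simplest monotone
  family with a well-defined plateau. The ground-truth plateau onset is
  the age where the true derivative falls to 1% of its initial value
  (`onset = ln(100)/rate`), matching the detection target.
* **Hierarchy.** Deepest-bin plateau onsets ramp linearly from 12 y
  (sensorimotor end) to 26 y (association end) across 60 parcels, inside
  the observed human window of 5.5–36 years.
* **Depth.** Per bin of superficiality, onsets shift 1.2 y later,
  amplitudes fall from 0.95 (deepest) to 0.30 (most superficial), and
  baselines drop 0.04 per bin towards the surface. The roughly 3:1
  amplitude gradient encodes the higher myelin content of deep cortex
  and is what makes deep bins steeper *within the observed window*: with
  equal amplitudes, a curve that matured earlier necessarily has the
  *shallower* in-window slope, which would invert the depth signature
  the pipeline is supposed to recover.
* **Noise.** Observation noise 0.15 ratio-units, subject random
  intercepts 0.03, male offset 0.02. The noise level is set to realistic
  between-subject variability for calibrated parcel ratios: it puts
  parcel-level partial R² in the few-tenths range typical of
  developmental effects of this kind, rather than making every effect
  near-deterministic.
* **Cohorts.** 400 cross-sectional humans (ages stratified-uniform over
  5.5–36 y) and 34 macaques with 5 strictly increasing sessions over
  1–36 months. The human arm is a scaled-down stand-in for a
  thousands-strong cohort; 400 preserves enough data in the
  cross-species overlap window (human 5.5–12 y under 4:1) for scaling
  recovery while keeping the full pipeline to minutes.
* **Species link.** The macaque mean at m months equals the human mean
  at `4m` months exactly, so the 4:1 recovery has an exact truth.

All randomness flows through one seeded generator per call; the RNG
state of the session is saved and restored, so repeated calls with one
seed are byte-identical and leave no global trace.

Deliberately *not* emulated: realistic MRI intensities, bias fields,
motion, scanner noise spectra, folded (gyrified) surfaces, spatial
autocorrelation between neighboring parcels, and site effects. Passing
tests therefore demonstrate that the pipeline recovers known structure
from data with the right statistical skeleton — not that it is robust to
every artifact of real acquisitions.

## Problem sizes and runtime choices

The suite's simulation studies use sizes chosen to give stable Monte
Carlo estimates in minutes on one core: test size and FDR control use
200 units × 100 replicates at n = 50; plateau recovery and its
monotone-growth controls use 100 replicates at n = 150 with 4000 band
draws; hierarchy and depth recovery run the full default cortex
(60 parcels × 5 bins, 400 + 170 scans); scaling recovery uses 20
replicate cohorts; the byte-stability check runs a reduced configuration
(12 parcels, 150 + 60 scans) twice. Production bands default to 10000
draws.

## Known limitations

* The rank-3 smooth is intentionally rigid: plateau ages inherit a
  systematic late shift for truths whose fast growth happens near the
  window start, and the absolute timing is best read comparatively
  (orderings, group contrasts), which is how the pipeline uses it.
* The edge-graph geodesic overestimates true surface distance with a
  lattice-dependent anisotropy; ranks and tertile groups are unaffected
  on meshes of reasonable regularity.
* `estimate_scaling()` assumes a single global time factor; regionally
  varying allochrony would be absorbed into the pooled objective.
* Real-data mode expects externally preprocessed, co-registered volumes
  and a precomputed depth coordinate; no registration, surface
  reconstruction, or B1 correction is attempted.
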