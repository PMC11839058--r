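Package: corticalmyelin
Title: Depth-Resolved Cortical Myelination Trajectories from T1w/T2w Ratio Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for depth-resolved cortical myelin
    development. Computes calibrated T1w/T2w ratio volumes, segments the
    cortical ribbon into equivolumetric depth bins, builds a
    sensorimotor-association axis from surface-mesh geodesic distances,
    fits penalized low-rank smooth age trajectories with REML-selected
    smoothing and optional subject random intercepts, detects
    developmental plateaus from simultaneous confidence bands on the
    first derivative, and aligns human and macaque trajectories under a
    4:1 developmental time scaling. Ships a synthetic-cortex generator
    (phantom ribbons, toy meshes, growth-curve cohorts with known ground
    truth) so the whole pipeline is testable without restricted
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
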