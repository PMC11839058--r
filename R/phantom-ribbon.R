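#' Phantom cortical ribbon with analytically known geometry
#'
#' Builds a voxelized ribbon (gray-matter stand-in) whose equivolume bin
#' boundaries are known in closed form, for validating the depth-binning
#' stage. Three geometries are supported:
#' \describe{
#'   \item{slab}{depth measured along z; ribbon where
#'     `inner_radius <= z < outer_radius` (use `inner_radius = 0` for a slab
#'     starting at the grid origin); cross-sectional area is constant so
#'     equivolume bins are equidistant.}
#'   \item{annulus}{cylindrical shell in the x-y plane extruded along z;
#'     area grows linearly with radius, the canonical curved-column case.}
#'   \item{spherical_shell}{radial shell in 3-D.}
#' }
#' Voxel centers are at `(i - 0.5) * voxel_size`; radii are measured from
#' the grid center (slab depth from z = 0).
#'
#' @param geometry One of `"slab"`, `"annulus"`, `"spherical_shell"`.
#' @param inner_radius,outer_radius Ribbon bounds in mm
#'   (`0 <= inner < outer`; strictly positive for curved geometries).
#' @param voxel_size Isotropic voxel edge, mm.
#' @param grid_shape Integer length-3 voxel grid dimensions; must contain
#'   the outer radius.
#' @return An object of class `phantom_ribbon`: list with `labels`
#'   (integer array, 1 = ribbon, 0 = background), `geometry`,
#'   `inner_radius`, `outer_radius`, `voxel_size`, `center` (mm) and `dim`.
#' @examples
#' rb <- make_phantom_ribbon("slab", 0, 2, voxel_size = 0.2,
#'                           grid_shape = c(50, 50, 15))
#' sum(rb$labels)  # 50 * 50 * 10 voxel slab
#' @export
make_phantom_ribbon <- function(geometry = c("slab", "annulus", "spherical_shell"),
                                inner_radius, outer_radius, voxel_size,
                                grid_shape) {
  geometry <- match.arg(geometry)
  stopifnot(is_scalar_num(inner_radius), inner_radius >= 0,
            is_scalar_num(outer_radius))
  stop_if_not_scalar_pos(voxel_size, "voxel_size")
  if (inner_radius >= outer_radius) {
    stop("`inner_radius` must be strictly less than `outer_radius`", call. = FALSE)
  }
  if (geometry != "slab" && inner_radius <= 0) {
    stop("curved geometries need `inner_radius` > 0", call. = FALSE)
  }
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))

  extent <- grid_shape * voxel_size
  center <- extent / 2
  needed <- switch(geometry,
    slab = outer_radius <= extent[3],
    annulus = outer_radius <= min(center[1], center[2]),
    spherical_shell = outer_radius <= min(center)
  )
  if (!needed) stop("grid too small to contain `outer_radius`", call. = FALSE)

  cx <- (seq_len(grid_shape[1]) - 0.5) * voxel_size
  cy <- (seq_len(grid_shape[2]) - 0.5) * voxel_size
  cz <- (seq_len(grid_shape[3]) - 0.5) * voxel_size
  r <- phantom_radius(geometry, cx, cy, cz, center, grid_shape)
  labels <- array(0L, grid_shape)
  labels[r >= inner_radius & r < outer_radius] <- 1L

  structure(
    list(labels = labels, geometry = geometry,
         inner_radius = inner_radius, outer_radius = outer_radius,
         voxel_size = voxel_size, center = center, dim = grid_shape),
    class = "phantom_ribbon"
  )
}

# per-voxel radial (or slab-depth) coordinate as an array
phantom_radius <- function(geometry, cx, cy, cz, center, grid_shape) {
  switch(geometry,
    slab = array(rep(cz, each = grid_shape[1] * grid_shape[2]), grid_shape),
    annulus = {
      r2 <- outer((cx - center[1])^2, (cy - center[2])^2, `+`)
      array(rep(sqrt(r2), times = grid_shape[3]), grid_shape)
    },
    spherical_shell = {
      r2 <- outer(outer((cx - center[1])^2, (cy - center[2])^2, `+`),
                  (cz - center[3])^2, `+`)
      sqrt(r2)
    }
  )
}

#' Analytic cumulative volume fraction for phantom ribbon voxels
#'
#' For each ribbon voxel, the exact fraction alpha of the column volume lying
#' deeper than that voxel's radial coordinate: linear in depth for the slab,
#' quadratic in radius for the annulus, cubic for the spherical shell.
#' Background voxels get `NA`.
#'
#' @param ribbon A [make_phantom_ribbon()] object.
#' @return Numeric array of alpha in `[0, 1)` over ribbon voxels.
#' @export
ribbon_alpha <- function(ribbon) {
  stopifnot(inherits(ribbon, "phantom_ribbon"))
  gs <- ribbon$dim
  cx <- (seq_len(gs[1]) - 0.5) * ribbon$voxel_size
  cy <- (seq_len(gs[2]) - 0.5) * ribbon$voxel_size
  cz <- (seq_len(gs[3]) - 0.5) * ribbon$voxel_size
  r <- phantom_radius(ribbon$geometry, cx, cy, cz, ribbon$center, gs)
  ri <- ribbon$inner_radius
  ro <- ribbon$outer_radius
  alpha <- switch(ribbon$geometry,
    slab = (r - ri) / (ro - ri),
    annulus = (r^2 - ri^2) / (ro^2 - ri^2),
    spherical_shell = (r^3 - ri^3) / (ro^3 - ri^3)
  )
  alpha[ribbon$labels == 0L] <- NA_real_
  alpha
}

#' Analytic ribbon volume of a phantom
#'
#' @param ribbon A [make_phantom_ribbon()] object.
#' @return Volume in mm^3 (annulus: over the full z extent of the grid).
#' @export
ribbon_analytic_volume <- function(ribbon) {
  stopifnot(inherits(ribbon, "phantom_ribbon"))
  ri <- ribbon$inner_radius
  ro <- ribbon$outer_radius
  switch(ribbon$geometry,
    slab = (ro - ri) * prod(ribbon$dim[1:2]) * ribbon$voxel_size^2,
    annulus = pi * (ro^2 - ri^2) * ribbon$dim[3] * ribbon$voxel_size,
    spherical_shell = 4 / 3 * pi * (ro^3 - ri^3)
  )
}

#' Write a phantom ribbon label volume as NIfTI
#'
#' @param ribbon A [make_phantom_ribbon()] object.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_ribbon_nifti <- function(ribbon, path) {
  stopifnot(inherits(ribbon, "phantom_ribbon"))
  img <- RNifti::asNifti(ribbon$labels, internal = FALSE)
  RNifti::pixdim(img) <- rep(ribbon$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
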