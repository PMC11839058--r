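#' Select geodesic seed vertices by k-means subsampling
#'
#' Vertices belonging to the seed parcels (default-mode / association
#' regions) are k-means-clustered on their 3-D coordinates and a random
#' fraction of the clusters is retained; all member vertices of the chosen
#' clusters become seed nodes. Subsampling clusters rather than vertices
#' keeps seeds spatially spread while cutting the multi-source distance
#' cost. With `cluster_fraction = 1` every seed-parcel vertex is returned
#' unchanged.
#'
#' @param mesh A [surface_mesh()] with parcel labels.
#' @param seed_parcels Parcel labels whose vertices act as sources.
#' @param cluster_fraction Fraction of clusters retained (default 0.1).
#' @param n_clusters Number of k-means clusters C; default
#'   `max(10, floor(n_seed_vertices / 100))`, capped at the vertex count.
#' @param seed Integer RNG seed (k-means initialization + cluster draw).
#' @return Sorted integer vector of seed vertex indices.
#' @export
select_seed_nodes <- function(mesh, seed_parcels, cluster_fraction = 0.1,
                              n_clusters = NULL, seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(mesh$parcel)) stop("mesh has no parcel labels", call. = FALSE)
  if (!is_scalar_num(cluster_fraction) || cluster_fraction <= 0 ||
      cluster_fraction > 1) {
    stop("`cluster_fraction` must lie in (0, 1]", call. = FALSE)
  }
  idx <- which(mesh$parcel %in% seed_parcels)
  if (!length(idx)) stop("no vertices carry a seed parcel label", call. = FALSE)
  if (cluster_fraction == 1) return(sort(idx))

  C <- if (is.null(n_clusters)) max(10, floor(length(idx) / 100)) else n_clusters
  C <- as.integer(min(C, length(idx)))
  with_local_seed(seed, {
    km <- suppressWarnings(
      stats::kmeans(mesh$vertices[idx, , drop = FALSE], centers = C,
                    nstart = 5, iter.max = 300)
    )
    chosen <- sample(C, ceiling(cluster_fraction * C))
    sort(idx[km$cluster %in% chosen])
  })
}

#' Minimum geodesic distance from seed vertices
#'
#' Multi-source shortest-path distance over the mesh edge graph with
#' Euclidean edge weights: each vertex gets the length of the shortest
#' edge path to its nearest seed. This approximates the true surface
#' geodesic from above; on right-triangulated lattices paths are
#' restricted to axis and one diagonal direction (documented bias of the
#' edge-graph approximation).
#'
#' @param mesh A [surface_mesh()].
#' @param seeds Non-empty integer vector of seed vertex indices.
#' @return Numeric per-vertex distance (mm); exactly 0 on seeds, `Inf`
#'   (with a warning) on vertices unreachable from every seed.
#' @export
geodesic_distance <- function(mesh, seeds) {
  stopifnot(inherits(mesh, "surface_mesh"))
  seeds <- unique(as.integer(seeds))
  if (!length(seeds)) stop("`seeds` must be non-empty", call. = FALSE)
  if (any(seeds < 1L | seeds > nrow(mesh$vertices))) {
    stop("seed indices outside the mesh", call. = FALSE)
  }
  ed <- mesh_edges(mesh)
  g <- igraph::make_graph(t(ed$edges), n = nrow(mesh$vertices), directed = FALSE)
  d <- igraph::distances(g, v = seeds, weights = ed$lengths)
  dist <- apply(d, 2, min)
  if (any(is.infinite(dist))) {
    warning(sprintf("%d vertex/vertices unreachable from all seeds (distance Inf)",
                    sum(is.infinite(dist))), call. = FALSE)
  }
  unname(dist)
}

#' Parcel-level sensorimotor-association axis from vertex distances
#'
#' Averages per-vertex minimum geodesic distances within each parcel and
#' ranks parcels by ascending distance (rank 1 = nearest the seeds, i.e.
#' the association end). Ties are broken lexicographically by parcel label.
#'
#' @param distance Per-vertex distances from [geodesic_distance()].
#' @param vertex_parcel Per-vertex parcel labels.
#' @return An `axis_map` data frame: `parcel, distance, rank`.
#' @export
parcel_axis <- function(distance, vertex_parcel) {
  if (length(distance) != length(vertex_parcel)) {
    stop("`distance` and `vertex_parcel` lengths differ", call. = FALSE)
  }
  keep <- !is.na(vertex_parcel)
  if (!all(keep)) warning("vertices without parcel labels ignored", call. = FALSE)
  parcels <- sort(unique(vertex_parcel[keep]))
  mean_d <- vapply(parcels, function(p) {
    mean(distance[keep][vertex_parcel[keep] == p])
  }, numeric(1))
  ord <- order(mean_d, parcels)
  axis <- data.frame(parcel = parcels, distance = mean_d,
                     stringsAsFactors = FALSE)
  axis$rank <- integer(nrow(axis))
  axis$rank[ord] <- seq_len(nrow(axis))
  class(axis) <- c("axis_map", "data.frame")
  axis
}

#' Assign equal-count hierarchy groups along the axis
#'
#' Splits the ranked parcels into contiguous near-equal thirds:
#' the smallest distances (nearest the seeds) form the association group,
#' the largest the sensorimotor group. When the parcel count is not
#' divisible by `n_groups` the remainder goes to the middle group
#' (399 parcels give 133/133/133; 400 give 133/134/133).
#'
#' @param axis An `axis_map` from [parcel_axis()].
#' @param n_groups Number of groups; the three-group labeling is standard.
#' @return The `axis_map` with a `group` factor column
#'   (`association < middle < sensorimotor` for `n_groups = 3`).
#' @export
assign_groups <- function(axis, n_groups = 3) {
  stopifnot(inherits(axis, "axis_map") || is.data.frame(axis))
  P <- nrow(axis)
  if (P < n_groups) stop("fewer parcels than groups", call. = FALSE)
  base <- P %/% n_groups
  sizes <- rep(base, n_groups)
  mid <- ceiling(n_groups / 2)
  sizes[mid] <- sizes[mid] + (P - base * n_groups)
  labels <- if (n_groups == 3) {
    c("association", "middle", "sensorimotor")
  } else {
    sprintf("group%d", seq_len(n_groups))
  }
  grp_by_rank <- rep(labels, times = sizes)
  axis$group <- factor(grp_by_rank[axis$rank], levels = labels)
  axis
}

#' Validate the geodesic axis against an external axis
#'
#' Spearman rank correlation between the geodesic-distance axis and an
#' externally supplied per-parcel axis (e.g. a multimodal or tracer-derived
#' sensorimotor-association axis) over the shared parcels.
#'
#' @param axis An `axis_map` from [parcel_axis()].
#' @param external_axis Named numeric vector (names = parcel labels) or
#'   data frame with columns `parcel, value`.
#' @return List with `rho`, `p_value` (two-sided) and `n_shared`.
#' @export
validate_axis <- function(axis, external_axis) {
  if (is.data.frame(external_axis)) {
    ext <- stats::setNames(external_axis$value, external_axis$parcel)
  } else {
    ext <- external_axis
  }
  shared <- intersect(as.character(axis$parcel), names(ext))
  if (length(shared) < 5) {
    stop("need at least 5 shared parcels to validate the axis", call. = FALSE)
  }
  x <- axis$distance[match(shared, as.character(axis$parcel))]
  y <- as.numeric(ext[shared])
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_shared = length(shared))
}

#' Write an axis map as CSV
#'
#' @param axis An `axis_map`, optionally with groups.
#' @param path Output CSV path (`parcel, distance_mm, rank, group`).
#' @return `path`, invisibly.
#' @export
write_axis_csv <- function(axis, path) {
  out <- data.frame(parcel = axis$parcel, distance_mm = axis$distance,
                    rank = axis$rank,
                    group = if ("group" %in% names(axis)) as.character(axis$group) else NA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
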