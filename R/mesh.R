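#' Triangle surface mesh container
#'
#' Minimal midthickness-surface representation used by the geodesic axis
#' stage: vertex coordinates, triangle connectivity and optional per-vertex
#' parcel labels.
#'
#' @param vertices Numeric n x 3 matrix of coordinates (mm).
#' @param triangles Integer m x 3 matrix of 1-based vertex indices.
#' @param parcel Optional length-n vector of parcel labels.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, parcel = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3, nrow(triangles) >= 1)
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop("`triangles` reference vertices outside the mesh", call. = FALSE)
  }
  if (!is.null(parcel) && length(parcel) != nrow(vertices)) {
    stop("`parcel` must have one label per vertex", call. = FALSE)
  }
  structure(list(vertices = vertices, triangles = triangles, parcel = parcel),
            class = "surface_mesh")
}

#' Planar right-triangulated grid mesh
#'
#' Builds an `n_rows x n_cols` lattice with vertex `(r, c)` at coordinates
#' `((r-1) * spacing, (c-1) * spacing, 0)` and each unit cell split along
#' the `(r, c) -- (r+1, c+1)` diagonal, giving `n_rows * n_cols` vertices and
#' `2 (n_rows-1)(n_cols-1)` triangles. Optionally assigns block parcel
#' labels by tiling the lattice into `parcel_blocks = c(block_rows,
#' block_cols)` tiles, numbered column-block-major so parcel index increases
#' along the column direction.
#'
#' @param n_rows,n_cols Lattice size (each `>= 2`).
#' @param spacing Lattice spacing, mm.
#' @param parcel_blocks Optional length-2 integer: number of parcel tiles
#'   along rows and columns.
#' @return A [surface_mesh()].
#' @examples
#' m <- make_grid_mesh(10, 10)
#' nrow(m$vertices)   # 100
#' nrow(m$triangles)  # 162
#' @export
make_grid_mesh <- function(n_rows, n_cols, spacing = 1, parcel_blocks = NULL) {
  stopifnot(is_scalar_num(n_rows), n_rows >= 2,
            is_scalar_num(n_cols), n_cols >= 2)
  stop_if_not_scalar_pos(spacing, "spacing")
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)

  # vertex index: v(r, c) = (r-1) * n_cols + c
  rr <- rep(seq_len(n_rows), each = n_cols)
  cc <- rep(seq_len(n_cols), times = n_rows)
  vertices <- cbind((rr - 1) * spacing, (cc - 1) * spacing, 0)

  r0 <- rep(seq_len(n_rows - 1), each = n_cols - 1)
  c0 <- rep(seq_len(n_cols - 1), times = n_rows - 1)
  v00 <- (r0 - 1) * n_cols + c0
  v01 <- v00 + 1L
  v10 <- v00 + n_cols
  v11 <- v10 + 1L
  triangles <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  parcel <- NULL
  if (!is.null(parcel_blocks)) {
    pb <- as.integer(parcel_blocks)
    stopifnot(length(pb) == 2, all(pb >= 1), pb[1] <= n_rows, pb[2] <= n_cols)
    br <- ceiling(rr * pb[1] / n_rows)
    bc <- ceiling(cc * pb[2] / n_cols)
    parcel <- (bc - 1L) * pb[1] + br
  }
  surface_mesh(vertices, triangles, parcel)
}

# undirected edge list of a mesh with Euclidean lengths
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  if (any(d <= 0)) stop("mesh contains zero-length edges", call. = FALSE)
  list(edges = e, lengths = d)
}

#' Write a surface mesh as ASCII PLY (plus optional CSV label table)
#'
#' @param mesh A [surface_mesh()].
#' @param path Output `.ply` path.
#' @param label_path Optional CSV path for the `(vertex, parcel)` table.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, label_path = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices", "end_header")
  vtx <- apply(mesh$vertices, 1, function(v) paste(format(v, trim = TRUE), collapse = " "))
  fac <- apply(mesh$triangles - 1L, 1, function(f) paste(c(3L, f), collapse = " "))
  writeLines(c(header, vtx, fac), path)
  if (!is.null(label_path)) {
    if (is.null(mesh$parcel)) stop("mesh has no parcel labels to write", call. = FALSE)
    utils::write.csv(data.frame(vertex = seq_len(nv), parcel = mesh$parcel),
                     label_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#'
#' @param path `.ply` file path.
#' @param label_path Optional CSV with columns `vertex, parcel`.
#' @return A [surface_mesh()].
#' @export
read_mesh_ply <- function(path, label_path = NULL) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file", call. = FALSE)
  end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  vtx <- do.call(rbind, lapply(strsplit(lines[end + seq_len(nv)], " +"),
                               function(x) as.numeric(x[1:3])))
  fac <- do.call(rbind, lapply(strsplit(lines[end + nv + seq_len(nf)], " +"),
                               function(x) as.integer(x[2:4]) + 1L))
  parcel <- NULL
  if (!is.null(label_path)) {
    tab <- utils::read.csv(label_path)
    parcel <- tab$parcel[order(tab$vertex)]
  }
  surface_mesh(vtx, fac, parcel)
}
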