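#' Triangulated cortical surface mesh
#'
#' Container for a triangulated surface: vertex coordinates in millimetres,
#' triangle vertex-index triples (consistent winding assumed, outward normals
#' by the right-hand rule), and a left/right hemisphere label per vertex.
#'
#' @param vertices numeric matrix, n_vertices x 3, coordinates in mm.
#' @param triangles integer matrix, n_triangles x 3, 1-based vertex indices.
#' @param hemisphere character vector of `"left"`/`"right"`, one per vertex.
#'   Defaults to labelling by the sign of the x coordinate (x > 0 is right),
#'   the usual RAS convention.
#' @param validate logical; run [validate_mesh()] on construction.
#'
#' @return An object of class `cortical_mesh`: a list with elements
#'   `vertices`, `triangles`, `hemisphere`.
#' @seealso [validate_mesh()], [make_sphere_mesh()], [read_mesh()]
#' @export
cortical_mesh <- function(vertices, triangles, hemisphere = NULL,
                          validate = TRUE) {
  vertices <- unname(as.matrix(vertices))
  storage.mode(vertices) <- "double"
  triangles <- unname(as.matrix(triangles))
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns (x, y, z)")
  if (ncol(triangles) != 3L) stop("`triangles` must have 3 columns")
  if (is.null(hemisphere)) {
    hemisphere <- ifelse(vertices[, 1L] > 0, "right", "left")
  }
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != nrow(vertices)) {
    stop("`hemisphere` must have one label per vertex")
  }
  if (!all(hemisphere %in% c("left", "right"))) {
    stop("hemisphere labels must be 'left' or 'right'")
  }
  mesh <- structure(
    list(vertices = vertices, triangles = triangles, hemisphere = hemisphere),
    class = "cortical_mesh"
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate a cortical mesh
#'
#' Checks the structural invariants a tessellation relies on: all triangle
#' indices in range, strictly positive triangle areas, and edge-manifoldness
#' (no edge shared by more than two triangles).
#'
#' @param mesh a [cortical_mesh()].
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$triangles)
  if (nt == 0L || nv == 0L) stop("empty mesh: no vertices or no triangles")
  tri <- mesh$triangles
  if (any(tri < 1L) || any(tri > nv)) {
    stop("triangle vertex index out of range")
  }
  if (any(tri[, 1L] == tri[, 2L] | tri[, 2L] == tri[, 3L] |
            tri[, 1L] == tri[, 3L])) {
    stop("degenerate triangle: repeated vertex index")
  }
  areas <- triangle_areas(mesh)
  if (any(areas <= 0 | !is.finite(areas))) {
    stop("all triangle areas must be finite and > 0")
  }
  ecodes <- edge_codes(mesh)
  cnt <- table(ecodes)
  if (any(cnt > 2L)) {
    stop("mesh is not edge-manifold: an edge is shared by > 2 triangles")
  }
  invisible(TRUE)
}

# Canonical integer codes for the 3 undirected edges of every triangle,
# in triangle order: (v1,v2), (v2,v3), (v3,v1). Length 3 * n_triangles.
edge_codes <- function(mesh) {
  tri <- mesh$triangles
  nv <- nrow(mesh$vertices)
  a <- c(tri[, 1L], tri[, 2L], tri[, 3L])
  b <- c(tri[, 2L], tri[, 3L], tri[, 1L])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  as.numeric(lo) * (nv + 1) + hi
}

#' Triangle geometry helpers
#'
#' `triangle_normals()` returns the un-normalised cross-product normal of each
#' triangle (its magnitude is twice the triangle area, so it is inherently
#' area-weighted); `triangle_areas()` the areas in mm^2; `triangle_centroids()`
#' the centroids in mm; `mesh_area()` the total surface area in cm^2.
#'
#' @param mesh a [cortical_mesh()].
#' @return A matrix (n_triangles x 3) for normals/centroids, a numeric vector
#'   for areas, a scalar for `mesh_area()`.
#' @export
triangle_normals <- function(mesh) {
  v <- mesh$vertices
  tri <- mesh$triangles
  e1 <- v[tri[, 2L], , drop = FALSE] - v[tri[, 1L], , drop = FALSE]
  e2 <- v[tri[, 3L], , drop = FALSE] - v[tri[, 1L], , drop = FALSE]
  cbind(
    e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
    e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
    e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  )
}

#' @rdname triangle_normals
#' @export
triangle_areas <- function(mesh) {
  n <- triangle_normals(mesh)
  0.5 * sqrt(rowSums(n^2))
}

#' @rdname triangle_normals
#' @export
triangle_centroids <- function(mesh) {
  v <- mesh$vertices
  tri <- mesh$triangles
  (v[tri[, 1L], , drop = FALSE] + v[tri[, 2L], , drop = FALSE] +
     v[tri[, 3L], , drop = FALSE]) / 3
}

#' @rdname triangle_normals
#' @export
mesh_area <- function(mesh) {
  sum(triangle_areas(mesh)) / 100  # mm^2 -> cm^2
}

# Hemisphere of each triangle by majority vote of its vertex labels
# (ties, only possible with 3 distinct labels, cannot occur with 2 levels;
# a 2-1 split goes to the majority).
triangle_hemisphere <- function(mesh) {
  h <- mesh$hemisphere
  tri <- mesh$triangles
  nright <- (h[tri[, 1L]] == "right") + (h[tri[, 2L]] == "right") +
    (h[tri[, 3L]] == "right")
  ifelse(nright >= 2L, "right", "left")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat("Cortical surface mesh\n")
  cat(sprintf("  %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  cat(sprintf("  total area: %.2f cm^2 (left %d / right %d vertices)\n",
              mesh_area(x),
              sum(x$hemisphere == "left"), sum(x$hemisphere == "right")))
  invisible(x)
}
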