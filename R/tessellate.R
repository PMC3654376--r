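# Triangle adjacency list: triangles sharing an undirected mesh edge.
# When `hemisphere` is supplied, adjacency never crosses the hemisphere
# boundary, so region growing cannot create a patch spanning both.
triangle_adjacency <- function(mesh, respect_hemisphere = TRUE) {
  nt <- nrow(mesh$triangles)
  codes <- edge_codes(mesh)
  tid <- rep(seq_len(nt), 3L)
  ord <- order(codes)
  codes <- codes[ord]
  tid <- tid[ord]
  same <- which(codes[-1L] == codes[-length(codes)])
  a <- tid[same]
  b <- tid[same + 1L]
  if (respect_hemisphere) {
    th <- triangle_hemisphere(mesh)
    keep <- th[a] == th[b]
    a <- a[keep]
    b <- b[keep]
  }
  adj <- vector("list", nt)
  if (length(a)) {
    pairs <- split(c(b, a), c(a, b))
    adj[as.integer(names(pairs))] <- lapply(pairs, function(x) sort(unique(x)))
  }
  adj[vapply(adj, is.null, TRUE)] <- list(integer(0))
  adj
}

# Connected components of an adjacency list; returns an integer label vector.
graph_components <- function(adj) {
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# BFS hop distances from a set of source nodes (Inf if unreachable).
bfs_distance <- function(adj, sources) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[sources] <- 0
  queue <- integer(n)
  queue[seq_along(sources)] <- sources
  head_i <- 1L
  tail_i <- length(sources)
  while (head_i <= tail_i) {
    v <- queue[[head_i]]
    head_i <- head_i + 1L
    nb <- adj[[v]]
    new <- nb[d[nb] == Inf]
    if (length(new)) {
      d[new] <- d[v] + 1
      queue[(tail_i + 1L):(tail_i + length(new))] <- new
      tail_i <- tail_i + length(new)
    }
  }
  d
}

#' Tessellate a cortical mesh into equal-area equivalent-dipole patches
#'
#' Partitions the triangles of a cortical mesh into edge-connected patches of
#' approximately `target_area` each, and equips every patch with an oriented
#' unit equivalent dipole (the normalised area-weighted sum of its triangle
#' normals), an area, a centroid, a hemisphere label, a neighbour set and,
#' through [build_laplacian()], a discrete surface Laplacian operator.
#'
#' The partition is grown greedily on the triangle adjacency graph: patch
#' seeds are placed by farthest-point sampling (the first seed drawn with the
#' given RNG seed, each further seed maximising the graph distance to all
#' previous seeds), then patches absorb frontier triangles one at a time,
#' always extending the currently smallest patch. This keeps areas balanced
#' while guaranteeing that every patch stays edge-connected. Patches never
#' cross the hemisphere boundary.
#'
#' @param mesh a [cortical_mesh()].
#' @param target_area target patch area in cm^2 (the classical choice for
#'   cortical source modelling is 1 cm^2).
#' @param seed integer RNG seed for the farthest-point seeding (default 0);
#'   the result is fully deterministic given the seed.
#' @param across_hemispheres logical; may patch *neighbour* relations cross
#'   the hemisphere boundary (default `FALSE`)? Patch membership never does.
#'
#' @return An object of class `patch_tessellation`: list with
#'   `patch_of_triangle` (integer per triangle), `n_patches`, `area`
#'   (cm^2 per patch), `orientation` (n_patches x 3 unit rows), `centroid`
#'   (n_patches x 3, mm), `hemisphere` (per patch), `neighbors` (list of
#'   integer vectors), `degenerate` (logical per patch: orientation sum
#'   cancelled), `target_area`, `seed`.
#' @export
tessellate_patches <- function(mesh, target_area, seed = 0L,
                               across_hemispheres = FALSE) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  if (nrow(mesh$triangles) == 0L) stop("empty mesh")
  if (!is.numeric(target_area) || target_area <= 0) {
    stop("`target_area` must be > 0")
  }
  total <- mesh_area(mesh)
  if (target_area > total) {
    warning("target_area (", target_area, " cm^2) exceeds total mesh area (",
            round(total, 3), " cm^2); producing one patch per component")
  }
  areas_cm2 <- triangle_areas(mesh) / 100
  adj <- triangle_adjacency(mesh, respect_hemisphere = TRUE)
  comp <- graph_components(adj)
  nt <- length(adj)

  assign <- integer(nt)
  next_patch <- 0L
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  for (ci in sort(unique(comp))) {
    tris <- which(comp == ci)
    comp_area <- sum(areas_cm2[tris])
    n_patches <- max(1L, as.integer(round(comp_area / target_area)))
    n_patches <- min(n_patches, length(tris))
    # farthest-point seeds on the component subgraph
    seeds <- tris[sample.int(length(tris), 1L)]
    while (length(seeds) < n_patches) {
      d <- bfs_distance(adj, seeds)
      cand <- tris[which.max(d[tris])]
      if (!is.finite(max(d[tris])) || cand %in% seeds) break
      seeds <- c(seeds, cand)
    }
    ids <- next_patch + seq_along(seeds)
    next_patch <- next_patch + length(seeds)
    assign[seeds] <- ids
    patch_area <- areas_cm2[seeds]
    frontier <- lapply(seeds, function(s) adj[[s]])
    active <- rep(TRUE, length(seeds))
    n_left <- length(tris) - length(seeds)
    while (n_left > 0L) {
      open <- which(active)
      if (!length(open)) break
      k <- open[which.min(patch_area[open])]
      f <- frontier[[k]]
      f <- f[assign[f] == 0L]
      if (!length(f)) {
        active[k] <- FALSE
        next
      }
      t0 <- f[[1L]]
      assign[t0] <- ids[[k]]
      patch_area[k] <- patch_area[k] + areas_cm2[t0]
      frontier[[k]] <- c(f[-1L], adj[[t0]])
      n_left <- n_left - 1L
    }
    # unreachable leftovers (cannot occur on a connected component, but be safe)
    left <- tris[assign[tris] == 0L]
    if (length(left)) assign[left] <- ids[[1L]]
  }

  finish_tessellation(mesh, assign, target_area, seed, across_hemispheres)
}

# Assemble a patch_tessellation from a triangle -> patch assignment.
finish_tessellation <- function(mesh, assign, target_area, seed,
                                across_hemispheres = FALSE) {
  assign <- match(assign, sort(unique(assign)))  # compact 1..P
  np <- max(assign)
  areas_cm2 <- triangle_areas(mesh) / 100
  normals <- triangle_normals(mesh)
  cents <- triangle_centroids(mesh)
  th <- triangle_hemisphere(mesh)

  area <- as.numeric(rowsum(areas_cm2, assign))
  wc <- rowsum(cents * areas_cm2, assign) / area
  hemi <- vapply(split(th, assign), function(h) names(which.max(table(h))), "")

  orientation <- matrix(0, np, 3L)
  degenerate <- logical(np)
  for (p in seq_len(np)) {
    o <- patch_orientation(mesh, which(assign == p), normals = normals,
                           on_degenerate = "silent")
    orientation[p, ] <- o
    degenerate[p] <- isTRUE(attr(o, "degenerate"))
  }
  if (any(degenerate)) {
    warning(sum(degenerate), " patch(es) have degenerate orientation ",
            "(opposing normals cancel); an arbitrary axis was kept")
  }

  tess <- structure(
    list(patch_of_triangle = assign, n_patches = np, area = area,
         orientation = orientation, centroid = unname(as.matrix(wc)),
         hemisphere = unname(hemi), neighbors = NULL,
         degenerate = degenerate, target_area = target_area, seed = seed),
    class = "patch_tessellation"
  )
  tess$neighbors <- build_neighbors(tess, mesh,
                                    across_hemispheres = across_hemispheres)
  tess
}

#' Equivalent-dipole orientation of a cortical patch
#'
#' The orientation of a patch is the vector sum of its triangle surface
#' normals, normalised to unit length. The un-normalised cross-product normal
#' of a triangle has magnitude twice the triangle area, so the sum is
#' inherently area-weighted: larger triangles contribute proportionally more.
#'
#' On strongly folded patches the normals may cancel; when the magnitude of
#' the sum falls below `tol` times the summed normal magnitudes the patch is
#' flagged degenerate (attribute `degenerate`) and an arbitrary axis
#' (+z) is returned so the caller can decide to drop or keep the patch.
#'
#' @param mesh a [cortical_mesh()].
#' @param triangles integer indices of the triangles forming the patch.
#' @param tol relative cancellation tolerance (default `1e-6`).
#' @param normals optional precomputed [triangle_normals()] matrix.
#' @param on_degenerate one of `"warn"`, `"error"`, `"silent"`.
#' @return Unit numeric 3-vector with logical attribute `degenerate`.
#' @export
patch_orientation <- function(mesh, triangles, tol = 1e-6, normals = NULL,
                              on_degenerate = c("warn", "error", "silent")) {
  on_degenerate <- match.arg(on_degenerate)
  if (length(triangles) == 0L) stop("patch must contain at least one triangle")
  if (is.null(normals)) normals <- triangle_normals(mesh)
  n <- normals[triangles, , drop = FALSE]
  vsum <- colSums(n)
  scale <- sum(sqrt(rowSums(n^2)))
  nrm <- sqrt(sum(vsum^2))
  if (nrm < tol * scale) {
    msg <- "degenerate patch orientation: triangle normals cancel"
    if (on_degenerate == "error") stop(msg)
    if (on_degenerate == "warn") warning(msg)
    out <- c(0, 0, 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- vsum / nrm
  attr(out, "degenerate") <- FALSE
  out
}

#' Patch neighbour map
#'
#' Two patches are neighbours iff they contain triangles sharing a mesh edge.
#' The relation is symmetric and irreflexive. With
#' `across_hemispheres = FALSE` (default) edges on the hemisphere boundary do
#' not create neighbour relations, so the smoothing operator never couples
#' the hemispheres.
#'
#' @param tess a [tessellate_patches()] result (or any list with
#'   `patch_of_triangle` and `n_patches`).
#' @param mesh the [cortical_mesh()] the tessellation was built from.
#' @param across_hemispheres logical, see above.
#' @return List of length `n_patches`; element i is the sorted integer vector
#'   of neighbours of patch i (possibly empty).
#' @export
build_neighbors <- function(tess, mesh, across_hemispheres = FALSE) {
  assign <- tess$patch_of_triangle
  adj <- triangle_adjacency(mesh,
                            respect_hemisphere = !across_hemispheres)
  np <- tess$n_patches
  nb <- vector("list", np)
  pairs_a <- integer(0)
  pairs_b <- integer(0)
  for (t0 in seq_along(adj)) {
    for (t1 in adj[[t0]]) {
      if (t1 <= t0) next
      pa <- assign[[t0]]
      pb <- assign[[t1]]
      if (pa != pb) {
        pairs_a <- c(pairs_a, pa)
        pairs_b <- c(pairs_b, pb)
      }
    }
  }
  for (p in seq_len(np)) nb[[p]] <- integer(0)
  if (length(pairs_a)) {
    key <- paste(pmin(pairs_a, pairs_b), pmax(pairs_a, pairs_b))
    keep <- !duplicated(key)
    pa <- pairs_a[keep]
    pb <- pairs_b[keep]
    all_a <- c(pa, pb)
    all_b <- c(pb, pa)
    sp <- split(all_b, all_a)
    nb[as.integer(names(sp))] <- lapply(sp, function(x) sort(unique(x)))
  }
  nb
}

#' Discrete cortical surface Laplacian operator
#'
#' Builds the smoothing operator W on the patch adjacency graph:
#' `w[i,i] = -1`, `w[i,j] = 1/N_i` when j is one of the `N_i` neighbours of
#' patch i, and 0 otherwise. Rows of non-isolated patches sum to zero, so W
#' annihilates spatially constant source patterns on a connected graph; note
#' W is generally *not* symmetric when neighbour counts differ.
#'
#' An isolated patch (no neighbours) gets the row `(-1 at the diagonal, 0
#' elsewhere)` with a warning: the penalty then shrinks that patch's
#' amplitude instead of its roughness.
#'
#' @param neighbors a neighbour list as from [build_neighbors()], or a
#'   `patch_tessellation` (its `$neighbors` is used).
#' @return A sparse `dgCMatrix` (package \pkg{Matrix}) of dimension
#'   n_patches x n_patches.
#' @export
build_laplacian <- function(neighbors) {
  if (inherits(neighbors, "patch_tessellation")) {
    neighbors <- neighbors$neighbors
  }
  np <- length(neighbors)
  if (np == 0L) stop("empty neighbour map")
  for (i in seq_len(np)) {
    for (j in neighbors[[i]]) {
      if (!(i %in% neighbors[[j]])) {
        stop("neighbour map is not symmetric: ", i, " -> ", j)
      }
    }
  }
  ni <- lengths(neighbors)
  if (any(ni == 0L)) {
    warning(sum(ni == 0L), " isolated patch(es): their Laplacian row only ",
            "penalises amplitude (row sum -1)")
  }
  ii <- rep(seq_len(np), ni)
  jj <- unlist(neighbors, use.names = FALSE)
  xx <- rep(1 / pmax(ni, 1L), ni)
  Matrix::sparseMatrix(
    i = c(seq_len(np), ii), j = c(seq_len(np), jj),
    x = c(rep(-1, np), xx), dims = c(np, np)
  )
}

#' @export
print.patch_tessellation <- function(x, ...) {
  cat("Patch tessellation\n")
  cat(sprintf("  %d patches (target %.3g cm^2), areas %.3g-%.3g cm^2\n",
              x$n_patches, x$target_area, min(x$area), max(x$area)))
  cat(sprintf("  hemisphere: %d right / %d left; mean neighbours %.2f\n",
              sum(x$hemisphere == "right"), sum(x$hemisphere == "left"),
              mean(lengths(x$neighbors))))
  if (any(x$degenerate)) {
    cat(sprintf("  %d degenerate orientation(s)\n", sum(x$degenerate)))
  }
  invisible(x)
}

# Run code under a private RNG stream, restoring the caller's state.
# Returns the restore function (call it, or let on.exit do so).
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Write a tessellation to TSV files
#'
#' Writes `<stem>_triangles.tsv` (triangle_id, patch_id) and
#' `<stem>_patches.tsv` (patch_id, x, y, z, nx, ny, nz, hemisphere,
#' area_cm2), plus the Laplacian as sparse triples
#' `<stem>_laplacian.tsv` (i, j, value).
#'
#' @param tess a `patch_tessellation`.
#' @param stem output file stem (path without suffix).
#' @param laplacian optional matrix from [build_laplacian()].
#' @return Invisibly, the vector of files written.
#' @export
write_tessellation <- function(tess, stem, laplacian = NULL) {
  f1 <- paste0(stem, "_triangles.tsv")
  write.table(
    data.frame(triangle_id = seq_along(tess$patch_of_triangle),
               patch_id = tess$patch_of_triangle),
    f1, sep = "\t", quote = FALSE, row.names = FALSE
  )
  f2 <- paste0(stem, "_patches.tsv")
  write.table(
    data.frame(patch_id = seq_len(tess$n_patches),
               x = tess$centroid[, 1L], y = tess$centroid[, 2L],
               z = tess$centroid[, 3L],
               nx = tess$orientation[, 1L], ny = tess$orientation[, 2L],
               nz = tess$orientation[, 3L],
               hemisphere = tess$hemisphere, area_cm2 = tess$area),
    f2, sep = "\t", quote = FALSE, row.names = FALSE
  )
  files <- c(f1, f2)
  if (!is.null(laplacian)) {
    f3 <- paste0(stem, "_laplacian.tsv")
    trip <- Matrix::summary(methods::as(laplacian, "TsparseMatrix"))
    write.table(data.frame(i = trip$i, j = trip$j, value = trip$x),
                f3, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f3)
  }
  invisible(files)
}
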