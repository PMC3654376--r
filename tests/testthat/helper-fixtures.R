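# Shared fixtures, all built in code.

# Two coplanar triangles in the z = 0 plane (consistent counter-clockwise
# winding seen from +z), forming a unit square. All vertices x <= 0 so the
# default hemisphere labelling puts them in one hemisphere.
square_mesh <- function() {
  v <- rbind(c(-1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4))
  cortical_mesh(v, f)
}

# A 1 x n strip of unit squares (2n triangles) in the z = 0 plane.
strip_mesh <- function(n = 6) {
  v <- NULL
  for (i in 0:n) v <- rbind(v, c(i, 0, 0), c(i, 1, 0))
  f <- NULL
  for (i in seq_len(n)) {
    a <- 2 * i - 1  # (i-1, 0)
    b <- 2 * i      # (i-1, 1)
    c0 <- 2 * i + 1 # (i, 0)
    d <- 2 * i + 2  # (i, 1)
    f <- rbind(f, c(a, c0, d), c(a, d, b))
  }
  cortical_mesh(v, f, hemisphere = rep("left", nrow(v)))
}

# Triangulated planar n x n sheet (2 n^2 triangles), single hemisphere.
sheet_mesh <- function(n = 24) {
  idx <- function(i, j) i * (n + 1) + j + 1
  v <- as.matrix(expand.grid(j = 0:n, i = 0:n))[, c(2, 1)]
  v <- cbind(v[, 2], v[, 1], 0)
  f <- NULL
  for (i in 0:(n - 1)) {
    for (j in 0:(n - 1)) {
      f <- rbind(f,
                 c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                 c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  cortical_mesh(v, f, hemisphere = rep("left", nrow(v)))
}

# Path-graph neighbour map 1-2-3-...-n.
path_neighbors <- function(n = 3) {
  lapply(seq_len(n), function(i) {
    setdiff(intersect(c(i - 1L, i + 1L), seq_len(n)), i)
  })
}

# Small deterministic simulation for pipeline-level tests.
small_sim_config <- function(seed = 7, ...) {
  sim_config(n_sensors = 32L, subdivisions = 2L, n_patches = 50L,
             parcels_per_hemisphere = 6L, n_spikes = 8L, seed = seed, ...)
}
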