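test_that("tessellation partitions the mesh into connected equal-area patches", {
  m <- make_sphere_mesh(3, radius_cm = 5)
  target <- 4
  tess <- tessellate_patches(m, target_area = target)
  # partition: every triangle in exactly one patch, areas add up exactly
  expect_length(tess$patch_of_triangle, nrow(m$triangles))
  expect_true(all(tess$patch_of_triangle >= 1 &
                    tess$patch_of_triangle <= tess$n_patches))
  expect_equal(sum(tess$area), mesh_area(m), tolerance = 1e-9)
  # patch count ~ total area / target
  expect_lte(abs(tess$n_patches - round(mesh_area(m) / target)), 2)
  # balanced areas: within [0.5, 2] x target up to one leftover per component
  out_of_band <- sum(tess$area < 0.5 * target | tess$area > 2 * target)
  expect_lte(out_of_band, 2)
  # edge-connectivity of every patch
  adj <- epicoh:::triangle_adjacency(m)
  for (p in seq_len(tess$n_patches)) {
    tris <- which(tess$patch_of_triangle == p)
    sub <- lapply(adj[tris], function(nb) match(intersect(nb, tris), tris))
    sub <- lapply(sub, function(x) x[!is.na(x)])
    expect_true(all(is.finite(epicoh:::bfs_distance(sub, 1L))))
  }
  # no patch crosses the hemisphere boundary
  th <- epicoh:::triangle_hemisphere(m)
  expect_true(all(vapply(split(th, tess$patch_of_triangle),
                         function(h) length(unique(h)) == 1L, TRUE)))
})

test_that("tessellation is deterministic given the seed", {
  m <- make_sphere_mesh(2, radius_cm = 3)
  t1 <- tessellate_patches(m, 2, seed = 4L)
  t2 <- tessellate_patches(m, 2, seed = 4L)
  expect_identical(t1$patch_of_triangle, t2$patch_of_triangle)
})

test_that("unit-sphere tessellation at 1 cm^2 yields 12-13 patches", {
  # total area 4*pi ~ 12.57 cm^2; expected count round(total/target) +- 1
  m <- make_sphere_mesh(3, radius_cm = 1)
  tess <- tessellate_patches(m, 1)
  expect_gte(tess$n_patches, 12L)
  expect_lte(tess$n_patches, 13L)
})

test_that("degenerate targets are handled", {
  m <- square_mesh()
  expect_warning(tess <- tessellate_patches(m, mesh_area(m) * 10),
                 "exceeds")
  expect_equal(tess$n_patches, 1L)
  expect_identical(tess$patch_of_triangle, c(1L, 1L))
  expect_identical(tess$neighbors, list(integer(0)))
  expect_error(tessellate_patches(m, -1), "target_area")
})

test_that("patch orientation is the normalised area-weighted normal sum", {
  m <- square_mesh()
  o <- patch_orientation(m, 1:2)
  expect_equal(as.numeric(o), c(0, 0, 1), tolerance = 1e-12)
  expect_false(attr(o, "degenerate"))
  # brute-force oracle on a curved patch: explicit cross-product summation
  sph <- make_sphere_mesh(2, radius_cm = 3)
  cap <- which(triangle_centroids(sph)[, 3] > 25)
  v <- sph$vertices
  acc <- c(0, 0, 0)
  for (t0 in cap) {
    tri <- sph$triangles[t0, ]
    acc <- acc + c(
      crossprod_vec <- local({
        e1 <- v[tri[2], ] - v[tri[1], ]
        e2 <- v[tri[3], ] - v[tri[1], ]
        c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
      })
    )
  }
  expect_equal(as.numeric(patch_orientation(sph, cap)),
               acc / sqrt(sum(acc^2)), tolerance = 1e-12)
})

test_that("opposing normals flag a degenerate orientation", {
  # same square twice with opposite winding: normal sums cancel exactly
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 2))
  m <- structure(list(vertices = v, triangles = f,
                      hemisphere = rep("left", 3)), class = "cortical_mesh")
  expect_warning(o <- patch_orientation(m, 1:2), "degenerate")
  expect_true(attr(o, "degenerate"))
  expect_error(patch_orientation(m, 1:2, on_degenerate = "error"))
  expect_error(patch_orientation(m, integer(0)), "at least one")
})

test_that("flipping all windings flips every orientation sign", {
  m <- make_sphere_mesh(2, radius_cm = 3)
  tess <- tessellate_patches(m, 6)
  flipped <- cortical_mesh(m$vertices, m$triangles[, c(1, 3, 2)],
                           hemisphere = m$hemisphere)
  for (p in seq_len(tess$n_patches)) {
    tris <- which(tess$patch_of_triangle == p)
    expect_equal(as.numeric(patch_orientation(flipped, tris)),
                 -as.numeric(patch_orientation(m, tris)), tolerance = 1e-12)
  }
})

test_that("neighbours are exactly the edge-sharing patches", {
  # strip of 3 patches in a row: ends have 1 neighbour, middle has 2
  m <- strip_mesh(6)
  tess <- tessellate_patches(m, mesh_area(m) / 3)
  expect_equal(tess$n_patches, 3L)
  expect_equal(sort(lengths(tess$neighbors)), c(1L, 1L, 2L))
  # brute-force oracle: pairwise edge-sharing check on the sphere
  sph <- make_sphere_mesh(2, radius_cm = 3)
  ts <- tessellate_patches(sph, 6)
  codes <- epicoh:::edge_codes(sph)
  patch_of_edge <- rep(ts$patch_of_triangle, 3)
  th <- epicoh:::triangle_hemisphere(sph)
  hemi_of_edge <- rep(th, 3)
  for (i in seq_len(ts$n_patches)) {
    for (j in seq_len(ts$n_patches)) {
      if (i >= j) next
      shared <- intersect(codes[patch_of_edge == i], codes[patch_of_edge == j])
      same_hemi <- ts$hemisphere[i] == ts$hemisphere[j]
      expect_identical(j %in% ts$neighbors[[i]],
                       length(shared) > 0 && same_hemi,
                       info = paste(i, j))
      # symmetry
      expect_identical(j %in% ts$neighbors[[i]], i %in% ts$neighbors[[j]])
    }
  }
})

test_that("interior patches of a regular planar sheet have about 6 neighbours", {
  m <- sheet_mesh(24)
  tess <- tessellate_patches(m, mesh_area(m) / 36)
  # interior = patches not touching the sheet boundary
  boundary <- tess$centroid[, 1] < 3 | tess$centroid[, 1] > 21 |
    tess$centroid[, 2] < 3 | tess$centroid[, 2] > 21
  inner <- lengths(tess$neighbors)[!boundary]
  expect_gt(length(inner), 3)
  expect_gt(mean(inner), 4.5)
  expect_lt(mean(inner), 7.5)
})

test_that("the Laplacian operator follows the neighbour-count formula", {
  W <- as.matrix(build_laplacian(path_neighbors(3)))
  expect_equal(W[1, ], c(-1, 1, 0))
  expect_equal(W[2, ], c(1 / 2, -1, 1 / 2))
  expect_equal(W[3, ], c(0, 1, -1))
  # general contract on a random symmetric neighbour map
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    A <- matrix(runif(n * n) < 0.4, n, n)
    A <- A | t(A)
    diag(A) <- FALSE
    nb <- lapply(seq_len(n), function(i) which(A[i, ]))
    W <- suppressWarnings(as.matrix(build_laplacian(nb)))
    ni <- lengths(nb)
    for (i in seq_len(n)) {
      expect_equal(W[i, i], -1)
      if (ni[i] > 0) {
        expect_equal(W[i, nb[[i]]], rep(1 / ni[i], ni[i]))
        expect_equal(sum(W[i, ]), 0)
      }
      expect_true(all(W[i, setdiff(seq_len(n), c(i, nb[[i]]))] == 0))
    }
  }
})

test_that("the Laplacian annihilates constants on connected graphs", {
  m <- make_sphere_mesh(2, radius_cm = 3)
  tess <- tessellate_patches(m, 6, across_hemispheres = TRUE)
  W <- build_laplacian(tess$neighbors)
  J <- matrix(3.7, tess$n_patches, 4)
  expect_lt(max(abs(W %*% J)), 1e-12)
})

test_that("isolated patches and asymmetric maps are reported", {
  expect_warning(W <- build_laplacian(list(2L, 1L, integer(0))), "solated")
  expect_equal(as.matrix(W)[3, ], c(0, 0, -1))
  expect_error(build_laplacian(list(2L, integer(0))), "not symmetric")
})

test_that("tessellation TSV bundle round-trips patches and Laplacian triples", {
  m <- make_sphere_mesh(2, radius_cm = 3)
  tess <- tessellate_patches(m, 6)
  W <- build_laplacian(tess$neighbors)
  stem <- file.path(withr::local_tempdir(), "tess")
  files <- write_tessellation(tess, stem, laplacian = W)
  expect_true(all(file.exists(files)))
  tri <- read.delim(files[1])
  expect_equal(tri$patch_id, tess$patch_of_triangle)
  pat <- read.delim(files[2])
  expect_equal(pat$hemisphere, tess$hemisphere)
  expect_equal(pat$area_cm2, tess$area, tolerance = 1e-9)
  expect_equal(as.matrix(pat[, c("nx", "ny", "nz")]), tess$orientation,
               tolerance = 1e-9, ignore_attr = TRUE)
  trip <- read.delim(files[3])
  W2 <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$value,
                             dims = dim(W))
  expect_equal(as.matrix(W2), as.matrix(W), tolerance = 1e-12)
})
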