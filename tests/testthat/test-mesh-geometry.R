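test_that("box erosion shrinks a cube by one voxel per face and is anti-extensive", {
  occ <- array(FALSE, c(11, 11, 11))
  occ[3:9, 3:9, 3:9] <- TRUE  # 7x7x7 cube
  m <- voxel_mask(occ, diag(4))
  er <- erode_mask(m)
  expect_equal(sum(er$data), 125)   # 5x5x5
  expect_true(all(er$data[4:8, 4:8, 4:8]))

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_error(erode_mask(voxel_mask(single, diag(4))), "erosion-emptied-mask")

  set.seed(1)
  blob <- array(stats::runif(15^3) > 0.4, c(15, 15, 15))
  blob[c(1, 15), , ] <- blob[, c(1, 15), ] <- blob[, , c(1, 15)] <- FALSE
  bm <- voxel_mask(blob, diag(4))
  eb <- try(erode_mask(bm), silent = TRUE)
  if (!inherits(eb, "try-error"))
    expect_true(all(bm$data[eb$data]))  # eroded subset of original
})

test_that("mask_to_mesh produces a closed genus-0 surface with the right volume", {
  ball <- make_ball_mask(6, voxel_mm = 1)
  mesh <- mask_to_mesh(ball, target_voxel_mm = 1, erode = FALSE)
  expect_equal(euler_characteristic(mesh), 2)
  expect_lt(abs(mesh_volume(mesh) - 4 / 3 * pi * 6^3) / (4 / 3 * pi * 6^3), 0.1)

  # with erosion the mesh tracks the eroded mask instead
  meshe <- mask_to_mesh(ball, target_voxel_mm = 1)
  er <- erode_mask(ball)
  expect_lt(abs(mesh_volume(meshe) - mask_volume(er)) / mask_volume(er), 0.15)

  two <- array(FALSE, c(16, 16, 16))
  two[3:6, 3:6, 3:6] <- TRUE
  two[10:13, 10:13, 10:13] <- TRUE
  expect_error(mask_to_mesh(voxel_mask(two, diag(4)), 1, erode = FALSE),
               "topology.*2")
})

test_that("vertex normals are outward and radial on a sphere, axis-aligned on a box", {
  s <- icosphere(10, subdivisions = 3)
  cosang <- rowSums(s$normals * s$vertices / 10)
  expect_true(all(acos(pmin(1, cosang)) < 5 * pi / 180))

  # inward-oriented input is flipped so enclosed volume is positive
  flipped <- triangle_mesh(s$vertices, s$triangles[, c(1, 3, 2)])
  expect_gt(mesh_volume(flipped, signed = TRUE), 0)
  expect_equal(flipped$normals, s$normals, tolerance = 1e-12)

  box <- make_box_mesh(0.5, 5.5)
  # face-interior vertices (smoothing disabled here) have axis normals
  top <- which(abs(box$vertices[, 3] - max(box$vertices[, 3])) < 1e-9 &
               box$vertices[, 1] > 1.5 & box$vertices[, 1] < 4.5 &
               box$vertices[, 2] > 1.5 & box$vertices[, 2] < 4.5)
  expect_true(length(top) > 0)
  for (v in top)
    expect_equal(box$normals[v, ], c(0, 0, 1), tolerance = 1e-9)
})

test_that("apply_displacements moves vertices along normals", {
  s <- icosphere(10, subdivisions = 2)
  expect_identical(apply_displacements(s, rep(0, nrow(s$vertices)))$vertices,
                   s$vertices)
  out <- apply_displacements(s, rep(1, nrow(s$vertices)))
  radii <- sqrt(rowSums(out$vertices^2))
  expect_lt(abs(mean(radii) - 11) / 11, 0.02)
  expect_error(apply_displacements(s, c(1, 2, 3)), "length")
})

test_that("mesh_to_mask follows the voxel-center-inside rule", {
  grid8 <- voxel_mask(array(TRUE, c(8, 8, 8)), diag(4))
  cube <- make_box_mesh(0.5, 3.5)
  expect_equal(sum(mesh_to_mask(cube, grid8)$data), 27)

  tiny <- laplacian_smooth(icosphere(0.25, center = c(1.5, 1.5, 1.5),
                                     subdivisions = 1), iterations = 0)
  expect_equal(sum(mesh_to_mask(tiny, grid8)$data), 0)

  # convexity oracle: occupancy of a convex surface equals the analytic
  # inside test of the sphere it approximates (away from the boundary shell)
  s <- icosphere(5.3, center = c(4, 4, 4), subdivisions = 3)
  occ <- mesh_to_mask(s, grid8)
  ctr <- voxel_centers(grid8)
  d <- sqrt(rowSums(sweep(ctr, 2, c(4, 4, 4))^2))
  clear <- abs(d - 5.3) > 0.2  # outside the facet-error shell
  expect_equal(as.vector(occ$data)[clear], (d < 5.3)[clear])
})

test_that("signed distance is zero on the surface, signed off it, and 1-Lipschitz", {
  s <- icosphere(10, subdivisions = 3)
  on_surf <- signed_distance(s, s$vertices[seq(1, 600, by = 37), ])
  expect_true(all(abs(on_surf) < 1e-9))
  expect_equal(signed_distance(s, matrix(c(13, 0, 0), 1)), 3, tolerance = 0.02)
  expect_equal(signed_distance(s, matrix(c(0, 7, 0), 1)), -3, tolerance = 0.02)

  set.seed(2)
  P <- matrix(stats::rnorm(60 * 3, sd = 8), 60, 3)
  Q <- P + matrix(stats::rnorm(60 * 3, sd = 2), 60, 3)
  dP <- signed_distance(s, P); dQ <- signed_distance(s, Q)
  step <- sqrt(rowSums((P - Q)^2))
  expect_true(all(abs(dP - dQ) <= step + 1e-9))
})

test_that("rasterized reconstruction of a digitized ball matches the eroded mask", {
  for (r in c(4, 6)) {
    ball <- make_ball_mask(r, voxel_mm = 1)
    mesh <- mask_to_mesh(ball, target_voxel_mm = 1)
    rec <- mesh_to_mask(mesh, ball)
    expect_gte(dice_score(rec, erode_mask(ball)), 0.9)
  }
})

test_that("mesh files round-trip preserving vertex order", {
  s <- icosphere(7, center = c(1, 2, 3), subdivisions = 1)
  gp <- tempfile(fileext = ".surf.gii")
  write_gifti_mesh(s, gp)
  s2 <- read_gifti_mesh(gp)
  expect_equal(s2$vertices, s$vertices, tolerance = 1e-5)
  expect_identical(s2$triangles, s$triangles)

  vp <- tempfile(fileext = ".vtk")
  write_vtk_mesh(s, vp)
  s3 <- read_vtk_mesh(vp)
  expect_equal(s3$vertices, s$vertices, tolerance = 1e-5)
  expect_identical(s3$triangles, s$triangles)
})
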