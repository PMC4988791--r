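test_that("phantom truth geometry matches the analytic shape", {
  spec <- phantom_spec(seed = 31)
  tr <- make_structure_truth(spec)
  expect_lt(abs(mask_volume(tr$mask) - tr$analytic_volume) /
              tr$analytic_volume, 0.05)
  # truth mask is exactly the rasterization of the truth mesh
  expect_identical(tr$mask$data, mesh_to_mask(tr$mesh, tr$mask)$data)
  # mesh vertices lie on the implicit surface (within half a voxel)
  phi <- meshseg:::phantom_phi(tr$mesh$vertices, spec$structures[[1]])
  expect_lt(max(abs(phi)), 0.5 * spec$voxel_mm)

  big <- phantom_spec(structures = list(huge = list(center = c(11, 11, 11),
                                                    semi_axes = c(15, 15, 15))))
  expect_error(make_structure_truth(big), "clipped")
})

test_that("truth-mask volume converges to the analytic volume with finer voxels", {
  vols <- vapply(c(1, 0.5, 0.25), function(vx) {
    n <- as.integer(round(22 / vx))
    spec <- phantom_spec(grid_shape = rep(n, 3), voxel_mm = vx,
                         structures = list(s = list(center = c(11, 11, 11),
                                                    semi_axes = c(5, 5, 5))),
                         seed = 1)
    mask_volume(make_structure_truth(spec)$mask)
  }, numeric(1))
  truth <- 4 / 3 * pi * 5^3
  err <- abs(vols - truth) / truth
  expect_true(all(diff(err) <= 1e-12) || err[3] < err[1])
  expect_lt(err[3], 0.02)
})

test_that("rendered edges follow the template families and seeds are reproducible", {
  spec <- phantom_spec(
    modalities = list(t2s = list(inside = 0.75, outside = 1, edge = "step",
                                 noise_sd = 0),
                      qsm = list(inside = 0.1, outside = 0,
                                 edge = "exponential", lambda = 1,
                                 noise_sd = 0)),
    seed = 32)
  ph <- render_phantom(spec)
  g <- meshseg:::phantom_grid(spec)
  ctr <- voxel_centers(g)
  phi <- meshseg:::phantom_phi(ctr, spec$structures[[1]])
  t2s <- as.vector(ph$volumes$t2s$data)
  expect_true(all(t2s[phi < 0] == 0.75))
  expect_true(all(t2s[phi >= 0] == 1))
  # probe the exponential tail 1 mm outside the surface along +x
  st <- spec$structures[[1]]
  probe <- matrix(st$center + c(st$semi_axes[1] + 1, 0, 0), 1)
  val <- meshseg:::trilinear_sample(ph$volumes$qsm$data, spec$affine, probe)
  expect_equal(val, 0.1 * exp(-1), tolerance = 0.01)

  noisy <- phantom_spec(seed = 33)
  a <- render_phantom(noisy); b <- render_phantom(noisy)
  expect_identical(a$volumes$t2s$data, b$volumes$t2s$data)
  expect_identical(a$volumes$qsm$data, b$volumes$qsm$data)
  c3 <- render_phantom(phantom_spec(seed = 34))
  expect_false(identical(a$volumes$t2s$data, c3$volumes$t2s$data))
})

test_that("phantom truth displacements solve the implicit surface crossing", {
  spec <- phantom_spec(seed = 35)
  ref <- icosphere(4, center = c(11, 11, 11), subdivisions = 2)
  d <- phantom_truth_displacements(spec, ref)
  # sphere radius 5 vs reference radius 4: outward crossing at +1 mm
  expect_equal(d, rep(1, nrow(ref$vertices)), tolerance = 0.02)
})

test_that("cohort generation plants effects, records a manifest, and round-trips", {
  spec <- phantom_spec(seed = 36)
  co0 <- generate_cohort(spec, n_per_group = c(a = 6, b = 6), seed = 37,
                         render = FALSE)
  m <- co0$manifest
  expect_equal(nrow(m), 12)
  # no planted effect: group mean true volumes agree within sampling error
  sp <- split(m$true_volume, m$group)
  expect_gt(stats::t.test(sp$a, sp$b)$p.value, 0.01)

  co1 <- generate_cohort(spec, n_per_group = c(a = 6, b = 6),
                         volume_effect = c(a = 1, b = 0.7), seed = 37)
  m1 <- co1$manifest
  expect_lt(mean(m1$true_volume[m1$group == "b"]),
            mean(m1$true_volume[m1$group == "a"]))
  expect_equal(mean(m1$true_volume[m1$group == "b"]) /
                 mean(m1$true_volume[m1$group == "a"]), 0.7,
               tolerance = 0.1)

  # manifest round-trip: re-rendering from recorded parameters is identical
  row <- m1[3, ]
  sspec <- spec
  sspec$structures[[1]]$semi_axes <- c(row$semi_a, row$semi_b, row$semi_c)
  sspec$seed <- row$seed
  re <- render_phantom(sspec)
  expect_identical(re$volumes$t2s$data,
                   co1$subjects[[3]]$volumes$t2s$data)
  expect_identical(re$volumes$qsm$data,
                   co1$subjects[[3]]$volumes$qsm$data)
})

test_that("planted volume effects are detectable on true volumes with high power", {
  spec <- phantom_spec(seed = 38)
  # power over replicates of a -10% volume effect, n = 15 + 15,
  # using the manifest's true volumes (a property of the generator itself)
  hits <- vapply(1:20, function(r) {
    co <- generate_cohort(spec, n_per_group = c(a = 15, b = 15),
                          volume_effect = c(a = 1, b = 0.9),
                          seed = 1000 + r, render = FALSE)
    m <- co$manifest
    stats::t.test(m$true_volume[m$group == "a"],
                  m$true_volume[m$group == "b"])$p.value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
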