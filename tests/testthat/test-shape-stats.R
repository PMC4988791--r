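test_that("translation registration is the centroid difference", {
  ref <- icosphere(8, subdivisions = 1)
  shifted <- ref
  shifted$vertices <- sweep(ref$vertices, 2, c(1, -2, 3), "+")
  expect_equal(register_translation(shifted, ref), c(-1, 2, -3),
               tolerance = 1e-12)
  expect_equal(register_translation(ref, ref), c(0, 0, 0))

  set.seed(11)
  noisy <- ref
  noise <- matrix(stats::rnorm(nrow(ref$vertices) * 3, 0, 0.3), ncol = 3)
  noisy$vertices <- ref$vertices + noise
  expect_equal(register_translation(noisy, ref), -colMeans(noise),
               tolerance = 1e-12)
  small <- icosphere(8, subdivisions = 0)
  expect_error(register_translation(small, ref), "correspondence")
})

test_that("vertex displacements are signed offsets from the reference surface", {
  ref <- icosphere(10, subdivisions = 2)
  expect_true(all(abs(vertex_displacements(ref, ref)) < 1e-9))
  bigger <- icosphere(11, subdivisions = 2)
  expect_equal(vertex_displacements(bigger, ref),
               rep(1, nrow(ref$vertices)), tolerance = 0.02)
  smaller <- icosphere(9, subdivisions = 2)
  expect_equal(vertex_displacements(smaller, ref),
               rep(-1, nrow(ref$vertices)), tolerance = 0.02)
})

test_that("GLM t-statistics match the pooled two-sample t and calibrate under the null", {
  set.seed(12)
  n <- 40; V <- 300
  data <- matrix(stats::rnorm(n * V), n, V)
  design <- cbind(1, rep(0:1, each = n / 2))
  t_glm <- glm_contrast_tstats(data, design, c(0, 1))
  t_ref <- vapply(seq_len(V), function(v)
    stats::t.test(data[21:40, v], data[1:20, v],
                  var.equal = TRUE)$statistic, numeric(1))
  expect_equal(t_glm, unname(t_ref), tolerance = 1e-10)

  crit <- stats::qt(0.975, n - 2)
  expect_lt(abs(mean(abs(t_glm) > crit) - 0.05), 0.03)

  data2 <- data
  patch <- 1:30
  data2[21:40, patch] <- data2[21:40, patch] + 1
  t2 <- glm_contrast_tstats(data2, design, c(0, 1))
  expect_gt(min(t2[patch]), max(0, stats::quantile(t2[-patch], 0.75)))

  expect_error(glm_contrast_tstats(data, design, c(0, 0)), "zero")
  expect_error(glm_contrast_tstats(data, cbind(design, design[, 2]),
                                   c(0, 1, 0)), "rank")
})

test_that("TFCE matches its closed form on a constant patch and is monotone", {
  mesh <- icosphere(10, subdivisions = 2)
  nv <- nrow(mesh$vertices)
  expect_equal(tfce_enhance(rep(0, nv), mesh), rep(0, nv))

  patch <- which(mesh$vertices[, 3] > 7)
  h0 <- 2.5
  stat <- numeric(nv); stat[patch] <- h0
  A <- sum(vertex_areas(mesh)[patch])
  enh <- tfce_enhance(stat, mesh, H = 2, E = 1, dh = h0 / 500)
  expect_lt(max(abs(enh[patch] - A * h0^3 / 3)) / (A * h0^3 / 3), 0.02)
  expect_true(all(enh[-patch] == 0))
  expect_error(tfce_enhance(stat, mesh, dh = -1), "dh")

  # raising any single vertex's statistic never decreases any enhancement
  set.seed(13)
  base <- abs(stats::rnorm(nv))
  e0 <- tfce_enhance(base, mesh, dh = max(base) / 100)
  for (r in 1:5) {
    v <- sample(nv, 1)
    up <- base; up[v] <- up[v] + stats::runif(1, 0.1, 1)
    e1 <- tfce_enhance(up, mesh, dh = max(base) / 100)
    expect_true(all(e1 - e0 >= -1e-9))
  }
})

test_that("permutation p-values behave as permutation p-values must", {
  mesh <- icosphere(10, subdivisions = 1)  # 42 vertices
  nv <- nrow(mesh$vertices)
  set.seed(14)
  n <- 12
  design <- cbind(1, rep(0:1, each = n / 2))
  data <- matrix(stats::rnorm(n * nv, 0, 0.5), n, nv)
  data[7:12, mesh$vertices[, 3] > 7] <-
    data[7:12, mesh$vertices[, 3] > 7] + 3

  res <- permutation_fwer(data, design, c(0, 1), mesh, n_perm = 300,
                          seed = 21)
  expect_true(all(res$p_pos > 0 & res$p_pos <= 1))
  # monotone: larger observed TFCE implies smaller or equal p
  ord <- order(res$tfce_pos)
  expect_true(all(diff(res$p_pos[ord]) <= 1e-12))
  # choose(12,6) = 924 seedless enumeration when n_perm covers it
  res_a <- permutation_fwer(data, design, c(0, 1), mesh, n_perm = 924,
                            seed = 1)
  res_b <- permutation_fwer(data, design, c(0, 1), mesh, n_perm = 924,
                            seed = 999)
  expect_true(res_a$exhaustive)
  expect_identical(res_a$p_pos, res_b$p_pos)
  expect_identical(res_a$p_neg, res_b$p_neg)
  # minimum attainable p under enumeration
  expect_equal(min(res_a$p_pos), 1 / res_a$n_perm_used)
})
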