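test_that("profile sampling interpolates trilinearly along the normal", {
  cfg <- profile_config(voxel_mm = 0.5)
  expect_equal(cfg$k, 17L)
  expect_equal(range(cfg$positions), c(-2, 2))

  vol <- array(3.7, c(20, 20, 20))
  aff <- diag(4) * 0.5; aff[4, 4] <- 1
  p <- sample_profile(vol, aff, c(4, 4, 4), c(0, 0, 1), cfg)
  expect_equal(p, rep(3.7, cfg$k))

  # volume equal to world z: linear field is reproduced exactly
  g <- voxel_mask(array(TRUE, c(20, 20, 20)), aff)
  zvol <- array(voxel_centers(g)[, 3], c(20, 20, 20))
  p2 <- sample_profile(zvol, aff, c(4, 4, 3), c(0, 0, 1), cfg)
  expect_equal(p2, 3 + cfg$positions, tolerance = 1e-12)

  expect_error(sample_profile(vol, aff, c(100, 100, 100), c(0, 0, 1), cfg),
               "profile-out-of-bounds")
})

test_that("modal intensity finds the dominant histogram mode", {
  aff <- diag(4)
  vol <- array(2.5, c(10, 10, 10))
  m <- voxel_mask(array(TRUE, c(10, 10, 10)), aff)
  expect_equal(modal_intensity(vol, m), 2.5)

  set.seed(3)
  vals <- c(rep(2, 800), rep(5, 200))[sample(1000)]
  vol2 <- array(vals, c(10, 10, 10))
  got <- modal_intensity(vol2, m)
  # oracle: recompute histogram argmax independently
  qs <- stats::quantile(vals, c(0.01, 0.99), names = FALSE)
  br <- seq(qs[1], qs[2], length.out = 101)
  h <- hist(vals[vals >= qs[1] & vals <= qs[2]], breaks = br, plot = FALSE)
  expect_equal(got, h$mids[which.max(h$counts)])
  expect_lt(abs(got - 2), diff(br)[1])

  empty <- voxel_mask(array(FALSE, c(10, 10, 10)), aff)
  expect_error(modal_intensity(vol, empty), "empty")
})

test_that("edge templates follow the rule formulas", {
  cfg <- profile_config(voxel_mm = 0.5)

  st <- build_edge_templates(list(prior_rule("m", "step", inside = 1,
                                             outside = 0)),
                             cfg, sigma_i = 0)[[1]]
  expect_equal(as.numeric(st), as.numeric(cfg$positions < 0))

  ex <- build_edge_templates(list(prior_rule("m", "exponential", lambda = 1,
                                             inside = 0.1, outside = 0)),
                             cfg, sigma_i = 0)[[1]]
  expect_equal(ex[which(abs(cfg$positions - 1) < 1e-9)], 0.1 * exp(-1),
               tolerance = 1e-12)

  sf <- build_edge_templates(list(prior_rule("m", "step", inside = "self",
                                             outside = "self*1.33")),
                             cfg, self_value = 0.6, sigma_i = 0)[[1]]
  expect_equal(max(sf), 0.798, tolerance = 1e-12)  # Self x 1.33 plateau
  sfe <- build_edge_templates(list(prior_rule("m", "exponential", lambda = 1,
                                              inside = "self",
                                              outside = "self*1.33")),
                              cfg, self_value = 0.6, sigma_i = 0)[[1]]
  expect_equal(max(sfe), 0.6 + (0.798 - 0.6) * (1 - exp(-2)),
               tolerance = 1e-12)  # asymptote 0.798 approached with lambda=1

  expect_error(build_edge_templates(
    list(prior_rule("m", "step", inside = "self", outside = 1)), cfg,
    sigma_i = 0), "self_value")

  # rules with outside > inside give non-decreasing templates after smoothing
  up <- build_edge_templates(list(prior_rule("m", "exponential", lambda = 2,
                                             inside = 1, outside = 1.33)),
                             cfg, sigma_i = 0.5)[[1]]
  expect_true(all(diff(up) >= -1e-9))
  dn <- build_edge_templates(list(prior_rule("m", "step", inside = 0.15,
                                             outside = 0.05)),
                             cfg, sigma_i = 0.5)[[1]]
  expect_true(all(diff(dn) <= 1e-9))

  # one or two components per rule row, per decay scale
  two <- build_edge_templates(list(prior_rule("m", "exponential",
                                              lambda = c(1, 3), inside = 0.1,
                                              outside = 0)), cfg, sigma_i = 0)
  expect_length(two, 2)
})

test_that("EM training recovers the generating component and respects the prior", {
  cfg <- profile_config(voxel_mm = 0.5)
  hy <- meshseg_hyperparams(cfg$k)
  rules <- list(prior_rule("qsm", "exponential", lambda = c(1, 3),
                           inside = 0.1, outside = 0))
  tex <- build_edge_templates(rules, cfg, sigma_i = hy$sigma_i,
                              extended = TRUE)
  S <- 20; V <- 4; k <- cfg$k
  set.seed(4)
  X <- array(0, c(S, V, k))
  shifts <- c(0, 1, -1, 2)
  sd_noise <- 0.01
  for (v in seq_len(V)) {
    d <- shifts[v] + cfg$n_steps / 2 + 1
    i <- seq_len(k) - d + cfg$n_steps + 1
    for (s in seq_len(S))
      X[s, v, ] <- tex[[1]][i] + stats::rnorm(k, 0, sd_noise)
  }
  fit <- train_modality_mixture(X, tex, cfg, beta_f = 3e-4, hy)
  # component 1 generated the data; its weight dominates everywhere
  expect_true(all(fit$weights[, 1] > 0.9))
  # log-posterior is non-decreasing (EM monotonicity)
  for (tr in fit$traces)
    expect_true(all(diff(tr) >= -1e-8 * pmax(abs(tr[-length(tr)]), 1)))

  # prior-dominated limit: huge n0 pins the means to the templates
  hy_big <- hy; hy_big$n0 <- 1e6
  fit_big <- train_modality_mixture(X, tex, cfg, beta_f = 3e-4, hy_big,
                                    max_iter = 10L)
  expect_lt(max(abs(fit_big$means[1, 1, ] - tex[[1]])), 1e-3)

  # learned mean near truth where the data actually constrain it
  mid <- cfg$n_steps + 1 + (-4:4)
  resid_sd <- sqrt(1 / min(fit$precisions[1, 1, mid]))
  expect_lt(max(abs(fit$means[1, 1, mid] - tex[[1]][mid])), 2 * resid_sd)

  expect_error(train_modality_mixture(X[1, , , drop = FALSE], tex, cfg,
                                      3e-4, hy), "at least 2")
})

test_that("displacement posteriors normalize, shift equivariantly, and weight precision", {
  cfg <- profile_config(voxel_mm = 0.5)
  rules <- list(prior_rule("qsm", "exponential", lambda = 1,
                           inside = 0.1, outside = 0))
  V <- 30
  model <- intensity_model_from_templates(rules, cfg, c(qsm = "absolute"), V)
  hy <- model$hyper
  tex <- build_edge_templates(rules, cfg, sigma_i = hy$sigma_i,
                              extended = TRUE)[[1]]
  k <- cfg$k
  window <- function(shift) {
    d <- shift + cfg$n_steps / 2 + 1
    tex[seq_len(k) - d + cfg$n_steps + 1]
  }
  set.seed(5)
  base_shift <- sample(-2:2, V, replace = TRUE)
  obs0 <- t(vapply(base_shift, window, numeric(k))) +
    matrix(stats::rnorm(V * k, 0, 1e-4), V, k)
  dp0 <- displacement_posterior(model, list(qsm = obs0))
  expect_true(all(abs(rowSums(exp(dp0$logp)) - 1) < 1e-9))
  am0 <- apply(dp0$logp, 1, which.max)
  expect_equal(dp0$grid[am0], base_shift * cfg$step_mm)

  # shifting the observation by +2 grid steps shifts the argmax by +2
  obs2 <- t(vapply(base_shift + 2L, window, numeric(k)))
  dp2 <- displacement_posterior(model, list(qsm = obs2))
  am2 <- apply(dp2$logp, 1, which.max)
  expect_gte(mean(am2 - am0 == 2), 0.95)

  # a flat inside-level profile carries no edge: the prior centers delta at 0
  flat <- matrix(tex[1], V, k)
  dpf <- displacement_posterior(model, list(qsm = flat))
  expect_true(all(apply(dpf$logp, 1, which.max) ==
                    which(dp0$grid == 0)))

  # two modalities: the one with 100x smaller residual sd decides the argmax
  rules2 <- list(prior_rule("a", "step", inside = 1, outside = 0),
                 prior_rule("b", "step", inside = 1, outside = 0))
  m2 <- intensity_model_from_templates(rules2, cfg,
                                       c(a = "absolute", b = "absolute"), 1)
  m2$modalities$a$precisions[] <- 1 / 0.001^2  # sharp modality
  m2$modalities$b$precisions[] <- 1 / 0.1^2    # sloppy modality
  ta <- m2$modalities$a$templates[1, ]
  shift_win <- function(tmpl, shift) {
    d <- shift + cfg$n_steps / 2 + 1
    tmpl[seq_len(k) - d + cfg$n_steps + 1]
  }
  obs_a <- matrix(shift_win(ta, 2), 1)   # modality a says +2 steps
  obs_b <- matrix(shift_win(m2$modalities$b$templates[1, ], -2), 1)
  joint <- displacement_posterior(m2, list(a = obs_a, b = obs_b))
  m_a_only <- intensity_model_from_templates(rules2[1], cfg,
                                             c(a = "absolute"), 1)
  m_a_only$modalities$a$precisions[] <- 1 / 0.001^2
  alone <- displacement_posterior(m_a_only, list(a = obs_a))
  expect_equal(which.max(joint$logp[1, ]), which.max(alone$logp[1, ]))
})
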