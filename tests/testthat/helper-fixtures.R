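# shared fixtures, all generated in code

# digitized ball of given radius (mm) on an isotropic grid centered at 0
make_ball_mask <- function(radius, voxel_mm = 1, margin = 4) {
  half <- radius + margin
  n <- as.integer(2 * ceiling(half / voxel_mm) + 1)
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_mm
  aff[1:3, 4] <- -(n - 1) / 2 * voxel_mm
  g <- voxel_mask(array(TRUE, c(n, n, n)), aff)
  ctr <- voxel_centers(g)
  voxel_mask(array(sqrt(rowSums(ctr^2)) <= radius, c(n, n, n)), aff)
}

# axis-aligned closed box mesh from an iso-surfaced cubic mask
make_box_mesh <- function(lo = 0.5, hi = 3.5) {
  n <- as.integer(hi + 5)
  occ <- array(FALSE, c(n, n, n))
  rng <- (ceiling(lo) + 1):(floor(hi) + 1)
  occ[rng, rng, rng] <- TRUE
  field_to_mesh(array(as.numeric(occ), dim(occ)), diag(4), 0.5)
}

# smooth unimodal displacement log-likelihood tables: Gaussian bumps with
# random centers plus mild perturbation (the regime ICM is designed for)
random_smooth_liktab <- function(nv, grid, strength = 3, noise = 0.3) {
  mu <- stats::runif(nv, min(grid), max(grid))
  lp <- -strength * outer(mu, grid, function(m, g) (g - m)^2) +
    matrix(stats::rnorm(nv * length(grid), 0, noise), nv, length(grid))
  lp - log(rowSums(exp(lp)))
}

# small two-modality phantom rules matching the default phantom contrasts
phantom_rules <- function() {
  list(prior_rule("t2s", "exponential", lambda = c(1, 3),
                  inside = "self", outside = "self*1.33"),
       prior_rule("qsm", "exponential", lambda = c(1, 3),
                  inside = 0.12, outside = 0.02))
}

# exhaustive MAP energy over all |grid|^nv configurations (oracle)
exhaustive_map_energy <- function(logp, grid, mesh, w) {
  nv <- nrow(logp)
  combos <- as.matrix(expand.grid(rep(list(seq_along(grid)), nv)))
  en <- numeric(nrow(combos))
  for (v in seq_len(nv)) en <- en - logp[v, ][combos[, v]]
  dmat <- matrix(grid[combos], nrow(combos), nv)
  tr <- mesh$triangles
  for (t in seq_len(nrow(tr)))
    en <- en + triangle_energy(dmat[, tr[t, 1]], dmat[, tr[t, 2]],
                               dmat[, tr[t, 3]], w)
  min(en)
}
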