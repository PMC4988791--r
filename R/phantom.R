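#' Specify a synthetic multimodal phantom
#'
#' Describes a small midbrain-like structure (a smoothly deformed
#' ellipsoid) on an isotropic grid, rendered in one or more modalities
#' with boundary profiles from the model's template families.  Default
#' contrasts mimic the target application: a quantitative susceptibility-
#' like modality with absolute levels (inside about 0.1-0.15, outside
#' 0.0-0.05) and a T2*-like relative modality whose outside/inside ratio
#' is about 1.33.
#'
#' @param grid_shape length-3 integer grid dimensions.
#' @param voxel_mm isotropic voxel size (mm).
#' @param structures named list; each element a list with \code{center}
#'   (mm), \code{semi_axes} (mm, length 3) and optional
#'   \code{deform_amplitude} (relative radial deformation, default 0).
#' @param modalities named list; each element a list with \code{inside},
#'   \code{outside} levels, \code{edge} ("step" or "exponential"),
#'   \code{lambda} (mm, for exponential) and \code{noise_sd}.
#' @param seed RNG seed; all phantom randomness flows from it.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(44L, 44L, 44L), voxel_mm = 0.5,
                         structures = list(
                           nucleus = list(center = c(11, 11, 11),
                                          semi_axes = c(5, 5, 5),
                                          deform_amplitude = 0)),
                         modalities = list(
                           t2s = list(inside = 0.75, outside = 1.0,
                                      edge = "exponential", lambda = 1,
                                      noise_sd = 0.02),
                           qsm = list(inside = 0.12, outside = 0.02,
                                      edge = "exponential", lambda = 1,
                                      noise_sd = 0.01)),
                         seed = 1L) {
  stopifnot(voxel_mm > 0, length(grid_shape) == 3L)
  for (s in structures) {
    stopifnot(all(s$semi_axes > 0))
    if (is.null(s$deform_amplitude)) s$deform_amplitude <- 0
  }
  for (m in modalities) stopifnot(m$noise_sd >= 0)
  affine <- diag(4); diag(affine)[1:3] <- voxel_mm
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 affine = affine, structures = structures,
                 modalities = modalities, seed = as.integer(seed)),
            class = "phantom_spec")
}

# radial signed distance of points to a deformed ellipsoid:
# phi(p) = |p - c| - R(u), with R the directional ellipsoid radius times a
# smooth low-order angular deformation (exact Euclidean distance for
# spheres, near-exact for mild deformation)
phantom_phi <- function(points, st) {
  d <- sweep(points, 2, st$center)
  r <- sqrt(rowSums(d^2))
  u <- d / pmax(r, 1e-12)
  er <- 1 / sqrt((u[, 1] / st$semi_axes[1])^2 +
                 (u[, 2] / st$semi_axes[2])^2 +
                 (u[, 3] / st$semi_axes[3])^2)
  er[r < 1e-9] <- min(st$semi_axes)  # at the center, direction is undefined
  amp <- if (is.null(st$deform_amplitude)) 0 else st$deform_amplitude
  if (amp != 0) {
    theta <- acos(pmin(pmax(u[, 3], -1), 1))
    phi_a <- atan2(u[, 2], u[, 1])
    er <- er * (1 + amp * sin(2 * theta) * cos(2 * phi_a))
  }
  r - er
}

phantom_grid <- function(spec) {
  voxel_mask(array(TRUE, spec$grid_shape), spec$affine)
}

#' Ground-truth geometry for one phantom structure
#'
#' Evaluates the implicit surface on the phantom grid, extracts the truth
#' mesh by iso-surfacing the (smooth) field, and defines the truth mask as
#' the rasterization of that mesh, so mask and mesh are exactly
#' consistent.  The undeformed analytic ellipsoid volume is recorded.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param structure structure name (default first).
#' @return List with \code{mesh} (\code{triangle_mesh}), \code{mask}
#'   (\code{voxel_mask}), \code{analytic_volume} (mm^3) and the structure
#'   parameters.
#' @export
make_structure_truth <- function(spec, structure = names(spec$structures)[1]) {
  st <- spec$structures[[structure]]
  amp <- if (is.null(st$deform_amplitude)) 0 else st$deform_amplitude
  extent <- max(st$semi_axes) * (1 + abs(amp)) + 2 * spec$voxel_mm
  world_hi <- (spec$grid_shape - 1) * spec$voxel_mm
  if (any(st$center - extent < 0) || any(st$center + extent > world_hi))
    stop("structure clipped: surface extends beyond the field of view")
  grid <- phantom_grid(spec)
  centers <- voxel_centers(grid)
  phi <- phantom_phi(centers, st)
  field <- array(-phi, spec$grid_shape)   # inside where phi < 0
  mesh <- field_to_mesh(field, spec$affine, level = 0, smooth_iter = 0L)
  mask <- mesh_to_mask(mesh, grid)
  list(mesh = mesh, mask = mask,
       analytic_volume = 4 / 3 * pi * prod(st$semi_axes),
       structure = structure, params = st)
}

#' Render a multimodal phantom
#'
#' Intensity at a voxel center is
#' \code{outside + (inside - outside) * g(phi)} with \code{phi} the signed
#' distance to the truth surface and \code{g} the chosen edge family (step,
#' or exponential decay outside the surface), plus independent Gaussian
#' voxel noise.  Identical seeds give bit-identical volumes.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return List with \code{volumes} (named list of \code{list(data,
#'   affine)}) and \code{truth} (named list from
#'   \code{\link{make_structure_truth}}).
#' @export
render_phantom <- function(spec) {
  grid <- phantom_grid(spec)
  centers <- voxel_centers(grid)
  truth <- lapply(names(spec$structures), function(s)
    make_structure_truth(spec, s))
  names(truth) <- names(spec$structures)
  # combined edge response: take the per-structure minimum phi (union)
  phi <- Reduce(pmin, lapply(spec$structures, function(st)
    phantom_phi(centers, st)))
  volumes <- list()
  rng <- set_local_seed(spec$seed)
  on.exit(restore_seed(rng), add = TRUE)
  for (m in names(spec$modalities)) {
    mo <- spec$modalities[[m]]
    g <- if (mo$edge == "step") {
      as.numeric(phi < 0)
    } else {
      ifelse(phi <= 0, 1, exp(-phi / mo$lambda))
    }
    vals <- mo$outside + (mo$inside - mo$outside) * g
    if (mo$noise_sd > 0)
      vals <- vals + stats::rnorm(length(vals), 0, mo$noise_sd)
    volumes[[m]] <- list(data = array(vals, spec$grid_shape),
                         affine = spec$affine)
  }
  list(volumes = volumes, truth = truth)
}

#' True displacements of a reference mesh to the phantom surface
#'
#' For each reference vertex, the signed offset along its outward normal at
#' which the structure's implicit surface is crossed (grid search plus
#' linear interpolation); the ground truth against which recovered
#' displacement fields are scored.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param mesh reference \code{triangle_mesh} (roughly aligned to the
#'   structure).
#' @param structure structure name.
#' @param t_range search range in mm (default +/- 4).
#' @return Numeric vector of per-vertex true displacements (mm); NA where
#'   no crossing lies in range.
#' @export
phantom_truth_displacements <- function(spec, mesh,
                                        structure = names(spec$structures)[1],
                                        t_range = 4) {
  st <- spec$structures[[structure]]
  ts <- seq(-t_range, t_range, by = 0.02)
  out <- rep(NA_real_, nrow(mesh$vertices))
  for (v in seq_len(nrow(mesh$vertices))) {
    pts <- outer(ts, mesh$normals[v, ]) +
      matrix(mesh$vertices[v, ], length(ts), 3, byrow = TRUE)
    ph <- phantom_phi(pts, st)
    sc <- which(diff(sign(ph)) != 0)
    if (length(sc) == 0) next
    # crossing closest to zero displacement
    best <- sc[which.min(abs(ts[sc]))]
    t0 <- ts[best]; t1 <- ts[best + 1]
    p0 <- ph[best]; p1 <- ph[best + 1]
    out[v] <- t0 - p0 * (t1 - t0) / (p1 - p0)
  }
  out
}

#' Generate a synthetic cohort with planted group effects
#'
#' Per subject, structure size and contrast are jittered around group
#' means; group-level volume and intensity effects are planted
#' multiplicatively/additively.  A manifest records every true parameter
#' and the per-subject render seed, so re-rendering from the manifest
#' reproduces identical volumes.
#'
#' @param spec base \code{\link{phantom_spec}} (its first structure is the
#'   cohort template).
#' @param n_per_group named integer vector of group sizes.
#' @param volume_effect named multiplicative volume effect per group
#'   (1 = no effect).
#' @param intensity_effect named additive effect per group on each
#'   modality's inside level, as a list of named vectors per modality
#'   (or NULL).
#' @param size_jitter_sd lognormal sd of the per-subject volume jitter.
#' @param seed cohort seed.
#' @param render render the volumes and truth geometry (default TRUE); with
#'   \code{render = FALSE} only the per-subject specs and the manifest are
#'   produced (enough for generator-level power analyses).
#' @return List with \code{subjects} (list of \code{list(volumes, truth,
#'   group, spec)}) and \code{manifest} (data.frame).
#' @export
generate_cohort <- function(spec, n_per_group = c(young = 15, old = 15),
                            volume_effect = NULL, intensity_effect = NULL,
                            size_jitter_sd = 0.05, seed = 1L,
                            render = TRUE) {
  stopifnot(all(n_per_group >= 2))
  groups <- names(n_per_group)
  if (is.null(volume_effect))
    volume_effect <- stats::setNames(rep(1, length(groups)), groups)
  stname <- names(spec$structures)[1]
  base_st <- spec$structures[[stname]]
  rng <- set_local_seed(seed)
  on.exit(restore_seed(rng), add = TRUE)
  ntot <- sum(n_per_group)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, ntot)
  size_jit <- exp(stats::rnorm(ntot, 0, size_jitter_sd))
  subjects <- list()
  manifest <- NULL
  i <- 0L
  for (g in groups) {
    for (j in seq_len(n_per_group[[g]])) {
      i <- i + 1L
      scale <- (volume_effect[[g]] * size_jit[i])^(1 / 3)
      st <- base_st
      st$semi_axes <- base_st$semi_axes * scale
      mods <- spec$modalities
      if (!is.null(intensity_effect)) {
        for (m in names(intensity_effect)) {
          eff <- intensity_effect[[m]]
          if (!is.null(eff[[g]]))
            mods[[m]]$inside <- mods[[m]]$inside + eff[[g]]
        }
      }
      sspec <- spec
      sspec$structures <- stats::setNames(list(st), stname)
      sspec$modalities <- mods
      sspec$seed <- sub_seeds[i]
      if (render) {
        ph <- render_phantom(sspec)
        subjects[[i]] <- list(volumes = ph$volumes,
                              truth = ph$truth[[stname]],
                              group = g, spec = sspec)
      } else {
        subjects[[i]] <- list(volumes = NULL, truth = NULL,
                              group = g, spec = sspec)
      }
      manifest <- rbind(manifest, data.frame(
        subject = i, group = g, seed = sub_seeds[i],
        semi_a = st$semi_axes[1], semi_b = st$semi_axes[2],
        semi_c = st$semi_axes[3],
        true_volume = 4 / 3 * pi * prod(st$semi_axes),
        t2s_inside = mods$t2s$inside %||% NA,
        qsm_inside = mods$qsm$inside %||% NA,
        stringsAsFactors = FALSE))
    }
  }
  list(subjects = subjects, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
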