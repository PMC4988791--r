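#' MRF configuration
#'
#' @param w non-negative MRF weight; larger values give smoother
#'   displacement fields (10 for the substantia nigra and red nucleus,
#'   100 for the finer subthalamic nucleus mesh).
#' @param max_sweeps ICM sweep cap.
#' @return An object of class \code{mrf_config}.
#' @export
mrf_config <- function(w = 10, max_sweeps = 100L) {
  stopifnot(w >= 0, max_sweeps >= 1L)
  structure(list(w = w, max_sweeps = as.integer(max_sweeps)),
            class = "mrf_config")
}

#' Single-triangle MRF energy
#'
#' \eqn{U(\delta_i, \delta_j, \delta_k) = w[(\delta_i - \bar\delta)^2 +
#' (\delta_j - \bar\delta)^2 + (\delta_k - \bar\delta)^2]} with
#' \eqn{\bar\delta} the triangle mean: the (scaled) variance of the three
#' displacements, zero iff they are equal.
#'
#' @param di,dj,dk displacements (mm); vectorized.
#' @param w MRF weight.
#' @return Energy value(s).
#' @export
triangle_energy <- function(di, dj, dk, w) {
  m <- (di + dj + dk) / 3
  w * ((di - m)^2 + (dj - m)^2 + (dk - m)^2)
}

#' MRF log-prior of a displacement field
#'
#' The unnormalized log-probability \eqn{-\sum_{(ijk) \in T} U(\delta_i,
#' \delta_j, \delta_k)} over all mesh triangles.  Always non-positive, zero
#' iff the field is constant, and invariant under adding a constant to all
#' displacements.
#'
#' @param delta per-vertex displacement vector (mm).
#' @param mesh a \code{triangle_mesh}.
#' @param config an \code{\link{mrf_config}}.
#' @return Scalar log-prior (<= 0).
#' @export
mrf_log_prior <- function(delta, mesh, config) {
  if (length(delta) != nrow(mesh$vertices))
    stop("displacement length does not match vertex count")
  tr <- mesh$triangles
  -sum(triangle_energy(delta[tr[, 1]], delta[tr[, 2]], delta[tr[, 3]],
                       config$w))
}

#' MAP displacements by iterated conditional modes
#'
#' Starting from the per-vertex likelihood argmax (the intensity-only
#' solution), each sweep visits vertices in ascending index order and sets
#' the vertex's displacement to the grid value maximizing its log-
#' likelihood plus the MRF terms of its incident triangles.  Stops when a
#' full sweep changes nothing or after \code{max_sweeps}.  Ties break
#' toward the smaller |delta|, then toward negative delta.  The posterior
#' energy is non-increasing across updates.
#'
#' @param lik a \code{displacement_table} (or a list with \code{logp}
#'   vertices x grid and \code{grid}).
#' @param mesh the \code{triangle_mesh} defining the cliques.
#' @param config an \code{\link{mrf_config}}.
#' @return List with \code{delta} (the MAP \code{displacement field}),
#'   \code{converged}, \code{sweeps}, \code{energy} (final posterior
#'   energy) and \code{energy_trace} (per accepted update).
#' @export
icm_optimize <- function(lik, mesh, config) {
  logp <- lik$logp
  grid <- lik$grid
  nv <- nrow(mesh$vertices)
  if (nrow(logp) != nv) stop("likelihood table does not match vertex count")
  bad <- which(!apply(is.finite(logp), 1, all))
  if (length(bad) > 0)
    stop(sprintf("non-finite likelihood row at vertex %d", bad[1]))
  D <- length(grid)
  # tie-break order: smaller |delta| first, then negative delta
  pref <- order(abs(grid), grid)
  rank_pref <- integer(D); rank_pref[pref] <- seq_len(D)
  argmax_pref <- function(vals) {
    mx <- max(vals)
    cand <- which(vals >= mx - 1e-12 * max(1, abs(mx)))
    cand[which.min(rank_pref[cand])]
  }

  # incident triangles per vertex and the two opposite vertices per incidence
  tr <- mesh$triangles
  inc <- vector("list", nv)
  for (t in seq_len(nrow(tr))) {
    v <- tr[t, ]
    inc[[v[1]]] <- rbind(inc[[v[1]]], v[2:3])
    inc[[v[2]]] <- rbind(inc[[v[2]]], v[c(1, 3)])
    inc[[v[3]]] <- rbind(inc[[v[3]]], v[1:2])
  }

  # initialization: intensity-only maxima
  idx <- apply(logp, 1, argmax_pref)
  delta <- grid[idx]

  post_energy <- function(idx) {
    d <- grid[idx]
    -sum(logp[cbind(seq_len(nv), idx)]) +
      sum(triangle_energy(d[tr[, 1]], d[tr[, 2]], d[tr[, 3]], config$w))
  }
  trace <- post_energy(idx)
  sweeps <- 0L; converged <- FALSE
  for (sweep in seq_len(config$max_sweeps)) {
    sweeps <- sweep
    changed <- FALSE
    for (v in seq_len(nv)) {
      opp <- inc[[v]]
      if (config$w > 0 && !is.null(opp)) {
        dj <- delta[opp[, 1]]; dk <- delta[opp[, 2]]
        mrf <- -vapply(grid, function(g)
          sum(triangle_energy(g, dj, dk, config$w)), numeric(1))
        vals <- logp[v, ] + mrf
      } else {
        vals <- logp[v, ]
      }
      new_idx <- argmax_pref(vals)
      if (new_idx != idx[v]) {
        idx[v] <- new_idx
        delta[v] <- grid[new_idx]
        changed <- TRUE
        trace <- c(trace, post_energy(idx))
      }
    }
    if (!changed) { converged <- TRUE; break }
  }
  list(delta = delta, converged = converged, sweeps = sweeps,
       energy = post_energy(idx), energy_trace = trace, grid = grid)
}

#' Segment one structure in a subject
#'
#' Full pipeline for a new subject: map the reference mesh into subject
#' space, sample perpendicular profiles in every modality (normalizing
#' Self-scaled modalities by the subject's modal inside intensity),
#' compute the displacement posterior, run ICM with the MRF prior, apply
#' the MAP displacements and rasterize the final mesh.
#'
#' @param volumes named list (per modality) of \code{list(data, affine)}.
#' @param transform \code{\link{spatial_transform}} from reference to
#'   subject space.
#' @param model trained \code{intensity_model}.
#' @param reference_mesh the structure's reference \code{triangle_mesh}.
#' @param config an \code{\link{mrf_config}}.
#' @param grid optional \code{voxel_mask} geometry for the output mask;
#'   defaults to the first modality's grid.
#' @return List with \code{mesh} (final \code{triangle_mesh}), \code{mask}
#'   (\code{voxel_mask}), \code{delta} (displacement field), and
#'   \code{report} (convergence and normalization details).
#' @export
segment_structure <- function(volumes, transform, model, reference_mesh,
                              config, grid = NULL) {
  pconf <- model$config
  mesh_s <- transform_mesh(reference_mesh, transform)
  observed <- list()
  selfs <- list()
  for (m in names(model$modalities)) {
    vol <- volumes[[m]]
    if (is.null(vol)) stop(sprintf("missing modality '%s'", m))
    Pm <- sample_profiles_mesh(vol$data, vol$affine, mesh_s, pconf)
    if (model$modalities[[m]]$normalization == "relative") {
      g <- voxel_mask(array(TRUE, dim(vol$data)), vol$affine)
      self <- modal_intensity(vol$data, mesh_to_mask(mesh_s, g))
      Pm <- Pm / self
      selfs[[m]] <- self
    }
    observed[[m]] <- Pm
  }
  lik <- displacement_posterior(model, observed)
  fit <- icm_optimize(lik, mesh_s, config)
  final_mesh <- apply_displacements(mesh_s, fit$delta)
  if (is.null(grid)) {
    v1 <- volumes[[1]]
    grid <- voxel_mask(array(TRUE, dim(v1$data)), v1$affine)
  }
  mask <- mesh_to_mask(final_mesh, grid)
  report <- list(converged = fit$converged, sweeps = fit$sweeps,
                 energy = fit$energy, self_intensities = selfs,
                 mrf_weight = config$w,
                 mean_abs_delta = mean(abs(fit$delta)))
  if (!fit$converged)
    warning(sprintf("ICM did not converge within %d sweeps", config$max_sweeps))
  list(mesh = final_mesh, mask = mask, delta = fit$delta, report = report)
}
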