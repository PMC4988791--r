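#' Spatial transform from reference to subject space
#'
#' An affine (4x4, world mm) optionally composed with a dense displacement
#' warp: points map as \code{A p + warp(A p)}.  The warp is a 4D array
#' (x, y, z, 3) of mm offsets with its own affine.
#'
#' @param affine 4x4 matrix (default identity).
#' @param warp optional list with elements \code{field} (4D array, last
#'   dim 3) and \code{affine}.
#' @return An object of class \code{spatial_transform}.
#' @export
spatial_transform <- function(affine = diag(4), warp = NULL) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (!is.null(warp)) {
    stopifnot(length(dim(warp$field)) == 4L, dim(warp$field)[4] == 3L)
  }
  structure(list(affine = affine, warp = warp), class = "spatial_transform")
}

#' Apply a spatial transform to points
#' @param transform a \code{\link{spatial_transform}}.
#' @param points n x 3 matrix of world-mm points.
#' @return n x 3 matrix of mapped points.
#' @export
transform_points <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  out <- (cbind(points, 1) %*% t(transform$affine))[, 1:3, drop = FALSE]
  if (!is.null(transform$warp)) {
    for (c in 1:3) {
      out[, c] <- out[, c] + trilinear_sample(
        transform$warp$field[, , , c], transform$warp$affine, out)
    }
  }
  out
}

#' Map a mesh into subject space
#'
#' Vertices are transformed; the mesh is rebuilt so that orientation and
#' normals are recomputed in the target space.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param transform a \code{\link{spatial_transform}}.
#' @return The mapped \code{triangle_mesh}.
#' @export
transform_mesh <- function(mesh, transform) {
  triangle_mesh(transform_points(transform, mesh$vertices), mesh$triangles)
}

# --------------------------------------------------------------------------
# Conjugate mixture EM over (component, displacement).
#
# Observation model for subject profile x (length k) at a vertex, given
# component c and grid displacement delta_d:
#   x_j ~ N(mu_c[p(j,d)], 1 / tau_c[p(j,d)])
# where mu_c, tau_c live on the extended grid of P = 2*Delta + 1 positions
# and p(j,d) = j - d + Delta + 1 selects the window shifted by delta_d.
# Priors: mu_p ~ N(template_p, (n0 tau_p)^-1), tau_p ~ Gamma(alpha0, b0)
# with b0 = alpha0 * (beta/f)^2, mixture weights ~ Dirichlet(alpha).
# The displacement prior N(0, sigma_delta^2) (normalized on the grid) is
# part of the latent-variable prior.  ECM with exact conditional M-steps
# gives a monotone penalized log-posterior.
# --------------------------------------------------------------------------

log_gauss_delta_prior <- function(config, sigma_delta) {
  lp <- -config$positions^2 / (2 * sigma_delta^2)
  lp - log(sum(exp(lp)))
}

# window index matrix: I[d, j] = extended position of window sample j at
# displacement index d (both 1-based); D = k
window_index <- function(config) {
  D <- config$k; k <- config$k; Delta <- config$n_steps
  outer(seq_len(D), seq_len(k), function(d, j) j - d + Delta + 1L)
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# per-component log density table: S x D for data X (S x k)
component_loglik <- function(X, mu_ext, tau_ext, Iw) {
  Tm <- matrix(tau_ext[Iw], nrow(Iw), ncol(Iw))
  Mm <- matrix(mu_ext[Iw], nrow(Iw), ncol(Iw))
  k <- ncol(Iw)
  t1 <- (X^2) %*% t(Tm)
  t2 <- X %*% t(Tm * Mm)
  t3 <- rowSums(Tm * Mm^2)
  ld <- rowSums(log(Tm))
  -0.5 * sweep(t1 - 2 * t2, 2, t3, "+") +
    matrix(0.5 * ld - 0.5 * k * log(2 * pi), nrow(X), length(ld), byrow = TRUE)
}

#' Train the per-vertex edge-appearance mixture for one modality
#'
#' EM over latent (component, displacement) pairs on profiles from
#' unlabelled training subjects.  Mean profiles get the rule template as a
#' conjugate prior mean with weight \code{n0} pseudo-observations;
#' precisions are diagonal (per extended sample position) with a Gamma
#' (1-D Wishart) prior of shape \code{alpha0} and mean \code{1/(beta/f)^2};
#' mixture weights have a symmetric Dirichlet prior.
#'
#' @param X subjects x vertices x k array of (normalized) profiles.
#' @param templates_ext list of extended-grid template vectors (from
#'   \code{\link{build_edge_templates}} with \code{extended = TRUE}); a
#'   flat no-edge component is appended automatically.
#' @param config a \code{\link{profile_config}}.
#' @param beta_f prior residual standard deviation for this modality.
#' @param hyper hyperparameter list from \code{\link{meshseg_hyperparams}}.
#' @param flat_level level of the appended flat component (defaults to the
#'   first template's inside plateau).
#' @param max_iter,tol EM iteration cap and relative log-posterior
#'   tolerance.
#' @return List with per-vertex arrays \code{means}, \code{precisions}
#'   (vertices x components x P), \code{weights} (vertices x components),
#'   and the per-vertex log-posterior traces.
#' @export
train_modality_mixture <- function(X, templates_ext, config, beta_f, hyper,
                                   flat_level = NULL, max_iter = 100L,
                                   tol = 1e-6) {
  stopifnot(length(dim(X)) == 3L, dim(X)[3] == config$k)
  S <- dim(X)[1]; V <- dim(X)[2]; k <- config$k
  if (S < 2L) stop("training requires at least 2 subjects")
  P <- 2L * config$n_steps + 1L
  if (is.null(flat_level)) flat_level <- templates_ext[[1]][1]
  tmpl <- c(templates_ext, list(rep(flat_level, P)))
  C <- length(tmpl)
  Tm <- do.call(rbind, lapply(tmpl, as.numeric))  # C x P
  Iw <- window_index(config)
  ldp <- log_gauss_delta_prior(config, hyper$sigma_delta)
  a0 <- hyper$alpha0
  b0 <- a0 * beta_f^2
  n0 <- hyper$n0
  adir <- hyper$alpha_dir
  tau0 <- 1 / beta_f^2
  iw_vec <- as.integer(Iw)  # length D*k, scatter index into 1..P

  means <- array(0, c(V, C, P))
  precs <- array(0, c(V, C, P))
  weights <- matrix(0, V, C)
  traces <- vector("list", V)

  for (v in seq_len(V)) {
    Xv <- matrix(X[, v, ], S, k)
    if (any(!is.finite(Xv)))
      stop(sprintf("non-finite training profile at vertex %d", v))
    mu <- Tm
    tau <- matrix(tau0, C, P)
    pis <- rep(1 / C, C)
    prev <- -Inf; trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      # E-step: joint log responsibilities over (c, d)
      ll <- array(0, c(S, C, length(ldp)))
      for (c in seq_len(C))
        ll[, c, ] <- component_loglik(Xv, mu[c, ], tau[c, ], Iw) +
          matrix(ldp + log(pis[c]), S, length(ldp), byrow = TRUE)
      flat <- matrix(ll, S, C * length(ldp))
      lse <- logsumexp_rows(flat)
      if (any(!is.finite(lse)))
        stop(sprintf("non-finite log-posterior at vertex %d", v))
      R <- exp(flat - lse)  # S x (C*D)

      # penalized objective at current parameters
      lp_prior <- sum((a0 - 0.5) * log(tau) - b0 * tau -
                        0.5 * n0 * tau * (mu - Tm)^2) +
        (adir - 1) * sum(log(pis))
      obj <- sum(lse) + lp_prior
      trace <- c(trace, obj)
      if (is.finite(prev) && abs(obj - prev) <= tol * (abs(prev) + 1e-12))
        break
      prev <- obj

      # M-step
      Rarr <- array(R, c(S, C, length(ldp)))
      for (c in seq_len(C)) {
        Rc <- matrix(Rarr[, c, ], S, length(ldp))   # S x D
        wd <- colSums(Rc)                            # D
        A <- t(Rc) %*% Xv                            # D x k, sum r*x
        B <- t(Rc) %*% (Xv^2)                        # D x k, sum r*x^2
        Nmat <- matrix(wd, length(wd), k)            # D x k, sum r
        n_p <- as.numeric(rowsum(as.numeric(Nmat), iw_vec))
        Sx <- as.numeric(rowsum(as.numeric(A), iw_vec))
        Sxx <- as.numeric(rowsum(as.numeric(B), iw_vec))
        # rowsum drops absent groups; scatter back defensively
        grp <- sort(unique(iw_vec))
        np_full <- Sx_full <- Sxx_full <- numeric(P)
        np_full[grp] <- n_p; Sx_full[grp] <- Sx; Sxx_full[grp] <- Sxx
        muc <- (n0 * Tm[c, ] + Sx_full) / (n0 + np_full)
        ss <- Sxx_full - 2 * muc * Sx_full + np_full * muc^2
        tauc <- (a0 + np_full / 2 - 0.5) /
          (b0 + 0.5 * n0 * (muc - Tm[c, ])^2 + 0.5 * ss)
        mu[c, ] <- muc
        tau[c, ] <- pmax(tauc, 1e-12)
      }
      rc_tot <- apply(Rarr, 2, sum)
      pis <- (adir - 1 + rc_tot) / (S + C * (adir - 1))
      pis <- pmax(pis, 1e-12); pis <- pis / sum(pis)
    }
    means[v, , ] <- mu
    precs[v, , ] <- tau
    weights[v, ] <- pis
    traces[[v]] <- trace
  }
  list(means = means, precisions = precs, weights = weights,
       templates = Tm, traces = traces, n_components = C)
}

#' Train the full multimodal intensity model
#'
#' Maps the reference mesh into each training subject's space, samples
#' perpendicular profiles in every modality, normalizes Self-scaled
#' modalities by the subject's modal inside intensity, and runs the
#' conjugate mixture EM per modality.
#'
#' @param subjects list of subjects; each a list with \code{volumes} (named
#'   list of \code{list(data, affine)} per modality) and \code{transform}
#'   (a \code{\link{spatial_transform}} from reference to subject space).
#' @param reference_mesh the structure's reference \code{triangle_mesh}.
#' @param rules list of \code{\link{prior_rule}}s for this structure (all
#'   modalities).
#' @param config a \code{\link{profile_config}}.
#' @param modality_norm named character vector mapping modality label to
#'   \code{"relative"} or \code{"absolute"}.
#' @param hyper optional hyperparameter list (default
#'   \code{\link{meshseg_hyperparams}}).
#' @param max_iter,tol EM controls passed through.
#' @return An object of class \code{intensity_model}.
#' @export
train_intensity_model <- function(subjects, reference_mesh, rules, config,
                                  modality_norm, hyper = NULL,
                                  max_iter = 100L, tol = 1e-6) {
  if (length(subjects) < 2L) stop("training requires at least 2 subjects")
  if (is.null(hyper)) hyper <- meshseg_hyperparams(config$k)
  modalities <- unique(vapply(rules, function(r) r$modality, character(1)))
  nv <- nrow(reference_mesh$vertices)

  profs <- lapply(modalities, function(m)
    array(NA_real_, c(length(subjects), nv, config$k)))
  names(profs) <- modalities

  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]
    mesh_s <- transform_mesh(reference_mesh, sub$transform)
    for (m in modalities) {
      vol <- sub$volumes[[m]]
      if (is.null(vol)) stop(sprintf("subject %d lacks modality '%s'", s, m))
      Pm <- sample_profiles_mesh(vol$data, vol$affine, mesh_s, config)
      if (modality_norm[[m]] == "relative") {
        grid <- voxel_mask(array(TRUE, dim(vol$data)), vol$affine)
        self <- modal_intensity(vol$data, mesh_to_mask(mesh_s, grid))
        Pm <- Pm / self
      }
      profs[[m]][s, , ] <- Pm
    }
  }

  fits <- list()
  for (m in modalities) {
    mr <- Filter(function(r) r$modality == m, rules)
    self_value <- if (modality_norm[[m]] == "relative") 1 else NULL
    te <- build_edge_templates(mr, config, self_value = self_value,
                               sigma_i = hyper$sigma_i, extended = TRUE)
    beta_f <- if (modality_norm[[m]] == "relative")
      hyper$beta_f_relative else hyper$beta_f_absolute
    fits[[m]] <- train_modality_mixture(profs[[m]], te, config, beta_f,
                                        hyper, max_iter = max_iter,
                                        tol = tol)
    fits[[m]]$normalization <- modality_norm[[m]]
    fits[[m]]$beta_f <- beta_f
  }
  structure(list(config = config, hyper = hyper, modalities = fits,
                 n_vertices = nv, rules = rules),
            class = "intensity_model")
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf("<intensity_model> %d vertices, modalities: %s\n",
              x$n_vertices, paste(names(x$modalities), collapse = ", ")))
  invisible(x)
}

#' Build an intensity model directly from prior templates
#'
#' The prior-dominated limit of training: per-vertex means equal the rule
#' templates, precisions equal the prior precision \eqn{1/(\beta/f)^2} and
#' mixture weights are uniform.  Useful for controlled shift-recovery
#' experiments and for segmenting data whose edges match the priors.
#'
#' @param rules list of \code{\link{prior_rule}}s (all modalities).
#' @param config a \code{\link{profile_config}}.
#' @param modality_norm named character vector (\code{"relative"} /
#'   \code{"absolute"} per modality).
#' @param n_vertices number of mesh vertices the model addresses.
#' @param hyper optional hyperparameters.
#' @return An \code{intensity_model}.
#' @export
intensity_model_from_templates <- function(rules, config, modality_norm,
                                           n_vertices, hyper = NULL) {
  if (is.null(hyper)) hyper <- meshseg_hyperparams(config$k)
  modalities <- unique(vapply(rules, function(r) r$modality, character(1)))
  P <- 2L * config$n_steps + 1L
  fits <- list()
  for (m in modalities) {
    mr <- Filter(function(r) r$modality == m, rules)
    self_value <- if (modality_norm[[m]] == "relative") 1 else NULL
    te <- build_edge_templates(mr, config, self_value = self_value,
                               sigma_i = hyper$sigma_i, extended = TRUE)
    te <- c(te, list(rep(te[[1]][1], P)))  # flat no-edge component
    beta_f <- if (modality_norm[[m]] == "relative")
      hyper$beta_f_relative else hyper$beta_f_absolute
    C <- length(te)
    Tm <- do.call(rbind, lapply(te, as.numeric))
    means <- array(0, c(n_vertices, C, P))
    precs <- array(0, c(n_vertices, C, P))
    for (c in seq_len(C)) {
      means[, c, ] <- matrix(Tm[c, ], n_vertices, P, byrow = TRUE)
      precs[, c, ] <- 1 / beta_f^2
    }
    fits[[m]] <- list(means = means, precisions = precs,
                      weights = matrix(1 / C, n_vertices, C),
                      templates = Tm, n_components = C,
                      normalization = modality_norm[[m]], beta_f = beta_f)
  }
  structure(list(config = config, hyper = hyper, modalities = fits,
                 n_vertices = n_vertices, rules = rules),
            class = "intensity_model")
}

#' Per-vertex displacement log-posterior table
#'
#' For each vertex, combines the mixture likelihoods of the observed
#' profiles across modalities (log-addition, conditional independence)
#' with the Gaussian displacement prior, normalized over the displacement
#' grid so each row exponentiates and sums to one.
#'
#' @param model a trained \code{intensity_model}.
#' @param observed named list (per modality) of vertices x k matrices of
#'   observed (already normalized, for relative modalities) profiles.
#' @return An object of class \code{displacement_table}: list with
#'   \code{logp} (vertices x grid matrix) and \code{grid} (displacement
#'   values in mm).
#' @export
displacement_posterior <- function(model, observed) {
  config <- model$config
  Iw <- window_index(config)
  ldp <- log_gauss_delta_prior(config, model$hyper$sigma_delta)
  D <- length(ldp)
  V <- model$n_vertices
  total <- matrix(rep(ldp, each = V), V, D)
  for (m in names(model$modalities)) {
    fit <- model$modalities[[m]]
    if (is.null(fit$means)) stop("model has no trained parameters")
    X <- observed[[m]]
    if (is.null(X)) stop(sprintf("observed profiles missing modality '%s'", m))
    if (ncol(X) != config$k) stop("profile length does not match model k")
    C <- fit$n_components
    for (v in seq_len(V)) {
      ll <- matrix(0, C, D)
      for (c in seq_len(C))
        ll[c, ] <- component_loglik(matrix(X[v, ], 1, config$k),
                                    fit$means[v, c, ], fit$precisions[v, c, ],
                                    Iw) + log(fit$weights[v, c])
      mx <- apply(ll, 2, max)
      total[v, ] <- total[v, ] + mx + log(colSums(exp(sweep(ll, 2, mx))))
    }
  }
  logp <- total - logsumexp_rows(total)
  structure(list(logp = logp, grid = config$positions),
            class = "displacement_table")
}
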