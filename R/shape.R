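#' Translation-only mesh registration
#'
#' The translation minimizing the mean squared distance between
#' corresponding vertices is the difference of centroids.  Rotation and
#' scaling are deliberately excluded: the near-spherical and cylindrical
#' shapes of the target nuclei make rotations poorly determined.
#'
#' @param mesh subject \code{triangle_mesh}.
#' @param reference reference \code{triangle_mesh} with identical vertex
#'   correspondence.
#' @return Length-3 translation (mm) to add to \code{mesh}'s vertices.
#' @export
register_translation <- function(mesh, reference) {
  if (nrow(mesh$vertices) != nrow(reference$vertices))
    stop("vertex counts differ; meshes are not in correspondence")
  colMeans(reference$vertices) - colMeans(mesh$vertices)
}

#' Signed vertex displacements relative to a reference mesh
#'
#' After translation registration, each subject vertex's signed distance
#' to the reference surface: positive where the subject surface lies
#' outside the reference, negative inside.
#'
#' @param subject_mesh subject \code{triangle_mesh}.
#' @param reference_mesh reference \code{triangle_mesh}.
#' @param register apply translation registration first (default TRUE).
#' @return Numeric vector of per-vertex signed distances (mm).
#' @export
vertex_displacements <- function(subject_mesh, reference_mesh,
                                 register = TRUE) {
  V <- subject_mesh$vertices
  if (register) {
    tr <- register_translation(subject_mesh, reference_mesh)
    V <- sweep(V, 2, tr, "+")
  }
  signed_distance(reference_mesh, V)
}

#' Per-vertex GLM contrast t-statistics
#'
#' Ordinary least squares fitted independently at every vertex with a
#' shared design matrix; \eqn{t = c^T\hat\beta / \mathrm{se}}.  With a
#' two-group indicator design this reproduces the classical pooled-
#' variance two-sample t.
#'
#' @param data subjects x vertices matrix of signed displacements (mm).
#' @param design subjects x regressors design matrix (full column rank).
#' @param contrast length-regressors contrast vector (not all zero).
#' @return Numeric vector of per-vertex t statistics.
#' @export
glm_contrast_tstats <- function(data, design, contrast) {
  design <- as.matrix(design)
  data <- as.matrix(data)
  n <- nrow(design); p <- ncol(design)
  if (nrow(data) != n) stop("data rows must match design rows")
  if (length(contrast) != p) stop("contrast length must equal regressor count")
  if (all(contrast == 0)) stop("contrast must not be the zero vector")
  if (qr(design)$rank < p) stop("design matrix is rank deficient")
  if (n < p + 1L) stop("need more subjects than regressors")
  XtXi <- solve(crossprod(design))
  beta <- XtXi %*% crossprod(design, data)    # p x V
  resid <- data - design %*% beta
  sigma2 <- colSums(resid^2) / (n - p)
  cb <- as.numeric(crossprod(contrast, beta))
  se <- sqrt(sigma2 * as.numeric(t(contrast) %*% XtXi %*% contrast))
  cb / se
}

#' One-ring vertex areas
#'
#' Barycentric one-ring areas: each triangle contributes a third of its
#' area to each of its corners.  Used as the per-vertex surface measure in
#' mesh TFCE.
#'
#' @param mesh a \code{triangle_mesh}.
#' @return Numeric vector of per-vertex areas (mm^2); sums to the total
#'   surface area.
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh) / 3
  n <- nrow(mesh$vertices)
  acc <- numeric(n)
  for (c in 1:3) {
    s <- rowsum(ta, mesh$triangles[, c])
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s
  }
  acc
}

#' Mesh-based threshold-free cluster enhancement
#'
#' \eqn{\mathrm{TFCE}(v) = \sum_h e_v(h)^E\, h^H\, \mathrm{d}h} over
#' thresholds from \code{dh} to the map maximum, where \eqn{e_v(h)} is the
#' surface area (mm^2) of the suprathreshold connected component
#' containing \eqn{v}.  Only positive values are enhanced; the negative
#' tail is handled by enhancing \code{-stat} separately (see
#' \code{two_sided}).
#'
#' @param stat per-vertex statistic map.
#' @param mesh a \code{triangle_mesh} (adjacency and areas).
#' @param H height exponent (default 2).
#' @param E extent exponent (default 1).
#' @param dh threshold step; default \code{max(stat)/100}.
#' @param two_sided if TRUE, returns the signed combination: positive
#'   enhancement minus the enhancement of the negated map.
#' @return Numeric vector of enhanced values.
#' @export
tfce_enhance <- function(stat, mesh, H = 2, E = 1, dh = NULL,
                         two_sided = FALSE) {
  if (length(stat) != nrow(mesh$vertices))
    stop("stat map length must equal vertex count")
  edges <- mesh_edges(mesh)
  areas <- vertex_areas(mesh)
  run <- function(s) {
    mx <- max(s)
    if (mx <= 0) return(numeric(length(s)))
    step <- if (is.null(dh)) mx / 100 else dh
    if (step <= 0) stop("dh must be positive")
    cpp_tfce(s, edges - 1L, areas, H, E, step)
  }
  pos <- run(pmax(stat, 0))
  if (!two_sided) return(pos)
  pos - run(pmax(-stat, 0))
}

# distinct two-group assignments (subject indices of group A) if the
# design's permutation space is small enough to enumerate
enumerate_two_group <- function(group, limit) {
  n <- length(group)
  nA <- sum(group == group[1])
  n_distinct <- choose(n, nA)
  if (n_distinct > limit) return(NULL)
  utils::combn(n, nA, simplify = FALSE)
}

#' Permutation inference with TFCE and FWER control
#'
#' Freely exchangeable group-label permutations; for every permutation the
#' GLM contrast t-map is TFCE-enhanced and its maximum over vertices forms
#' the null distribution.  Corrected p-values are
#' \eqn{p_v = (1 + \#\{\max^{perm} \ge \mathrm{obs}_v\}) / (n_{perm}+1)};
#' both contrast signs are tested and reported separately so each tail can
#' be thresholded at 0.025.  If \code{n_perm} is at least the number of
#' distinct two-group assignments, the permutation space is enumerated
#' exhaustively and the result is seed-free.
#'
#' @param data subjects x vertices displacement matrix.
#' @param design subjects x regressors design matrix.
#' @param contrast contrast vector.
#' @param mesh reference \code{triangle_mesh}.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for Monte-Carlo permutation sampling.
#' @param H,E,dh TFCE parameters.
#' @param group optional group labels (length subjects) identifying the
#'   exchangeable two-group structure; defaults to the levels of the
#'   contrast regressor.
#' @return List with \code{t} (observed t-map), \code{tfce_pos},
#'   \code{tfce_neg}, \code{p_pos}, \code{p_neg} (corrected p per tail),
#'   \code{exhaustive}, \code{n_perm_used}, and \code{report}.
#' @export
permutation_fwer <- function(data, design, contrast, mesh, n_perm = 500L,
                             seed = 1L, H = 2, E = 1, dh = NULL,
                             group = NULL) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  data <- as.matrix(data)
  n <- nrow(data)
  if (is.null(group)) {
    gv <- as.numeric(as.matrix(design) %*% contrast)
    group <- factor(gv)
    if (nlevels(group) != 2L) group <- NULL
  }
  edges <- mesh_edges(mesh)
  areas <- vertex_areas(mesh)
  tfce_of <- function(tmap, sign) {
    s <- pmax(sign * tmap, 0)
    mx <- max(s)
    if (mx <= 0) return(numeric(length(s)))
    step <- if (is.null(dh)) mx / 100 else dh
    cpp_tfce(s, edges - 1L, areas, H, E, step)
  }

  t_obs <- glm_contrast_tstats(data, design, contrast)
  obs_pos <- tfce_of(t_obs, 1)
  obs_neg <- tfce_of(t_obs, -1)

  perms <- NULL
  exhaustive <- FALSE
  if (!is.null(group)) {
    gi <- as.integer(factor(group))
    combos <- enumerate_two_group(gi, n_perm)
    if (!is.null(combos)) {
      exhaustive <- TRUE
      slotA <- which(gi == gi[1]); slotB <- which(gi != gi[1])
      perms <- lapply(combos, function(idxA) {
        out <- integer(n)
        out[slotA] <- idxA
        out[slotB] <- setdiff(seq_len(n), idxA)
        out
      })
    }
  }
  if (!exhaustive) {
    rng_state <- set_local_seed(seed)
    on.exit(restore_seed(rng_state), add = TRUE)
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  }

  max_pos <- max_neg <- numeric(length(perms))
  for (i in seq_along(perms)) {
    tp <- glm_contrast_tstats(data[perms[[i]], , drop = FALSE], design,
                              contrast)
    max_pos[i] <- max(c(0, tfce_of(tp, 1)))
    max_neg[i] <- max(c(0, tfce_of(tp, -1)))
  }

  if (exhaustive) {
    p_pos <- vapply(obs_pos, function(o) mean(max_pos >= o), numeric(1))
    p_neg <- vapply(obs_neg, function(o) mean(max_neg >= o), numeric(1))
    np <- length(perms)
  } else {
    np <- length(perms)
    p_pos <- vapply(obs_pos, function(o) (1 + sum(max_pos >= o)) / (np + 1),
                    numeric(1))
    p_neg <- vapply(obs_neg, function(o) (1 + sum(max_neg >= o)) / (np + 1),
                    numeric(1))
  }
  list(t = t_obs, tfce_pos = obs_pos, tfce_neg = obs_neg,
       p_pos = p_pos, p_neg = p_neg, exhaustive = exhaustive,
       n_perm_used = np,
       report = list(seed = seed, n_perm = np, H = H, E = E,
                     dh = if (is.null(dh)) "max/100" else dh,
                     exhaustive = exhaustive))
}

# run code under a local RNG seed without clobbering the caller's stream
set_local_seed <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  state
}

restore_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
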