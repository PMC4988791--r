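#' Construct a triangle mesh
#'
#' The deformable segmentation surface: world-mm vertex coordinates,
#' triangle index triples and per-vertex unit outward normals.  On
#' construction the mesh is checked to be a closed orientable surface
#' (every edge shared by exactly two triangles) with no degenerate
#' triangles, and normals are (re)computed with outward orientation.
#'
#' @param vertices n x 3 numeric matrix (mm, world space).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param validate check the closed-surface invariants (default TRUE).
#' @return An object of class \code{triangle_mesh} with elements
#'   \code{vertices}, \code{triangles}, \code{normals}.
#' @export
triangle_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle index out of range")
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         normals = NULL), class = "triangle_mesh")
  if (validate) {
    if (any(triangle_areas(mesh) < 1e-12))
      stop("mesh contains degenerate (zero-area) triangles")
    check_closed(mesh)
  }
  mesh <- orient_outward(mesh)
  mesh$normals <- compute_vertex_normals(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles, volume %.2f mm^3\n",
              nrow(x$vertices), nrow(x$triangles), mesh_volume(x)))
  invisible(x)
}

tri_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$triangles[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$triangles[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$triangles[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-triangle areas in mm^2
#' @param mesh a \code{triangle_mesh}.
#' @return Vector of triangle areas.
#' @export
triangle_areas <- function(mesh) {
  co <- tri_corners(mesh)
  cr <- cross3(co$b - co$a, co$c - co$a)
  0.5 * sqrt(rowSums(cr^2))
}

# unnormalized outward-weighted triangle normals (area-weighted)
triangle_normals_raw <- function(mesh) {
  co <- tri_corners(mesh)
  0.5 * cross3(co$b - co$a, co$c - co$a)
}

#' Enclosed volume via the divergence theorem
#'
#' Signed volume \eqn{\sum_t \det[a b c]/6}; positive for consistently
#' outward-oriented closed meshes.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param signed return the signed value (default FALSE returns |V|).
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  co <- tri_corners(mesh)
  v <- sum(rowSums(co$a * cross3(co$b, co$c))) / 6
  if (signed) v else abs(v)
}

# undirected edge list (each edge once), as a 2-column matrix of vertex ids
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

check_closed <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L))
    stop(sprintf("mesh is not a closed surface: %d edge(s) not shared by exactly 2 triangles",
                 sum(cnt != 2L)))
  ncomp <- mesh_component_count(mesh)
  if (ncomp != 1L)
    stop(sprintf("topology: surface has %d connected components (expected 1)", ncomp))
  invisible(TRUE)
}

# connected components over the vertex adjacency graph (union-find)
mesh_component_count <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  e <- mesh_edges(mesh)
  for (k in seq_len(nrow(e))) {
    ra <- find(e[k, 1]); rb <- find(e[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# flip all triangles if the signed enclosed volume is negative
orient_outward <- function(mesh) {
  if (mesh_volume(mesh, signed = TRUE) < 0)
    mesh$triangles <- mesh$triangles[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Per-vertex outward unit normals
#'
#' Area-weighted average of incident triangle normals, normalized to unit
#' length.  The mesh must be consistently outward oriented (enforced by
#' \code{\link{triangle_mesh}}).
#'
#' @param mesh a \code{triangle_mesh}.
#' @return n x 3 matrix of unit normals.
#' @export
compute_vertex_normals <- function(mesh) {
  tn <- triangle_normals_raw(mesh)   # area-weighted
  n <- nrow(mesh$vertices)
  acc <- matrix(0, n, 3)
  for (c in 1:3) {
    idx <- mesh$triangles[, c]
    s <- rowsum(tn, idx)
    rows <- as.integer(rownames(s))
    acc[rows, ] <- acc[rows, ] + s
  }
  len <- sqrt(rowSums(acc^2))
  bad <- which(len < 1e-12)
  if (length(bad) > 0)
    stop(sprintf("zero-length accumulated normal at vertex %d", bad[1]))
  acc / len
}

#' Displace mesh vertices along their normals
#'
#' Vertex \eqn{v} moves to \eqn{x_v + \delta_v n_v}; positive displacements
#' are outward.  Topology is unchanged and normals are recomputed.
#' Self-intersection of the displaced surface is not checked.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param delta numeric vector of per-vertex displacements (mm), length equal
#'   to the vertex count.
#' @return The displaced \code{triangle_mesh}.
#' @export
apply_displacements <- function(mesh, delta) {
  if (length(delta) != nrow(mesh$vertices))
    stop(sprintf("displacement length %d does not match vertex count %d",
                 length(delta), nrow(mesh$vertices)))
  out <- mesh
  out$vertices <- mesh$vertices + delta * mesh$normals
  out$normals <- compute_vertex_normals(out)
  out
}

#' Extract an iso-surface mesh from a scalar field
#'
#' Marching-tetrahedra iso-surfacing (Kuhn 6-tet cube subdivision) at the
#' given level, producing a closed orientable triangle mesh in world mm.
#'
#' @param field 3D numeric array of field values at voxel grid points.
#' @param affine 4x4 voxel-to-world affine.
#' @param level iso level.
#' @param smooth_iter,smooth_factor Laplacian smoothing iterations/factor
#'   applied after extraction (set \code{smooth_iter = 0} to disable).
#' @return A \code{triangle_mesh}.
#' @export
field_to_mesh <- function(field, affine = diag(4), level = 0.5,
                          smooth_iter = 0L, smooth_factor = 0.2) {
  f <- as.numeric(field)
  # nudge grid values lying (almost) on the level to the inside so that
  # edge intersections stay away from grid points (no degenerate triangles)
  dev <- abs(f - level)
  scale <- max(dev[is.finite(dev)], 1e-12)
  eps <- 1e-4 * scale
  f[abs(f - level) < eps] <- level + eps
  res <- cpp_marching_tets(f, dim(field), level)
  if (nrow(res$vertices) == 0L)
    stop("iso-surface is empty at the requested level")
  world <- cbind(res$vertices, 1) %*% t(affine)
  mesh <- triangle_mesh(world[, 1:3, drop = FALSE], res$triangles + 1L)
  if (smooth_iter > 0L)
    mesh <- laplacian_smooth(mesh, iterations = smooth_iter,
                             factor = smooth_factor)
  mesh
}

#' Mild Laplacian smoothing
#'
#' Each iteration moves every vertex a fraction \code{factor} of the way
#' toward the mean of its one-ring neighbours; removes the voxelization
#' staircase of iso-surfaced binary masks.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param iterations number of smoothing passes.
#' @param factor relaxation factor in (0, 1].
#' @return The smoothed \code{triangle_mesh}.
#' @export
laplacian_smooth <- function(mesh, iterations = 10L, factor = 0.2) {
  e <- mesh_edges(mesh)
  both <- rbind(e, e[, 2:1, drop = FALSE])
  n <- nrow(mesh$vertices)
  deg <- tabulate(both[, 1], nbins = n)
  V <- mesh$vertices
  for (it in seq_len(iterations)) {
    s <- rowsum(V[both[, 2], , drop = FALSE], both[, 1])
    rows <- as.integer(rownames(s))
    nb <- matrix(0, n, 3)
    nb[rows, ] <- s
    V <- V + factor * (nb / pmax(deg, 1L) - V)
  }
  out <- mesh
  out$vertices <- V
  out <- orient_outward(out)
  out$normals <- compute_vertex_normals(out)
  out
}

#' Build a triangle mesh from a voxel mask
#'
#' The mask is eroded with the 3x3x3 box kernel, resampled to an isotropic
#' grid at \code{target_voxel_mm} (nearest neighbour), iso-surfaced at the
#' 0.5 level and lightly Laplacian-smoothed.  Errors if the surface is not
#' a single closed component.
#'
#' @param mask a \code{\link{voxel_mask}}.
#' @param target_voxel_mm isotropic working resolution for surface
#'   extraction (mm); smaller values give denser meshes.
#' @param erode apply the 3x3x3 erosion first (default TRUE).
#' @param smooth_iter,smooth_factor Laplacian smoothing parameters.
#' @return A \code{triangle_mesh} in world mm.
#' @export
mask_to_mesh <- function(mask, target_voxel_mm = 1,
                         erode = TRUE, smooth_iter = 10L,
                         smooth_factor = 0.2) {
  stopifnot(inherits(mask, "voxel_mask"), target_voxel_mm > 0)
  if (erode) mask <- erode_mask(mask)
  iso <- resample_mask_iso(mask, target_voxel_mm)
  field <- array(as.numeric(iso$data), dim(iso$data))
  field_to_mesh(field, iso$affine, level = 0.5,
                smooth_iter = smooth_iter, smooth_factor = smooth_factor)
}

#' Rasterize a closed mesh onto a voxel grid
#'
#' Occupancy is true exactly for voxels whose center is inside the surface,
#' decided by even-odd ray casting along +x with deterministic perturbation
#' of degenerate hits.
#'
#' @param mesh a closed \code{triangle_mesh}.
#' @param grid a \code{voxel_mask} (or anything with \code{data} dims and
#'   \code{affine}) defining the output grid geometry; its occupancy is
#'   ignored.
#' @return A \code{voxel_mask} on the same grid.
#' @export
mesh_to_mask <- function(mesh, grid) {
  check_closed(mesh)
  d <- dim(grid$data)
  # map vertices to continuous voxel-index coordinates; even-odd parity is
  # affine invariant, so one +x ray per (y, z) row of centers suffices
  inv <- solve(grid$affine)
  Vidx <- (cbind(mesh$vertices, 1) %*% t(inv))[, 1:3, drop = FALSE]
  occ <- cpp_rasterize_grid(Vidx, mesh$triangles - 1L, as.integer(d))
  voxel_mask(array(occ, d), grid$affine)
}

#' Signed distance from points to a closed mesh
#'
#' Magnitude is the Euclidean distance to the nearest point on any triangle;
#' the sign is negative inside the surface and positive outside.
#'
#' @param mesh a closed \code{triangle_mesh}.
#' @param points n x 3 matrix of world-mm query points.
#' @return Numeric vector of signed distances (mm).
#' @export
signed_distance <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- cpp_point_mesh_dist(mesh$vertices, mesh$triangles - 1L, points)
  inside <- cpp_points_in_mesh(mesh$vertices, mesh$triangles - 1L, points)
  ifelse(inside, -d, d)
}

#' Euler characteristic V - E + F
#' @param mesh a \code{triangle_mesh}.
#' @return Integer Euler characteristic (2 for a genus-0 closed surface).
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$triangles)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; a standard synthetic
#' closed genus-0 test surface.
#'
#' @param radius sphere radius (mm).
#' @param center length-3 center (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 gives the
#'   bare icosahedron with 12 vertices).
#' @return A \code{triangle_mesh}.
#' @export
icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 2L) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  Fm <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    newF <- matrix(0L, 0, 3)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      V <<- rbind(V, (V[i, ] + V[j, ]) / 2)
      mid_cache[[key]] <- nrow(V)
      nrow(V)
    }
    for (t in seq_len(nrow(Fm))) {
      a <- Fm[t, 1]; b <- Fm[t, 2]; c <- Fm[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                    c(ab, bc, ca))
    }
    Fm <- newF
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  V <- sweep(V, 2, center, "+")
  triangle_mesh(V, Fm)
}
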