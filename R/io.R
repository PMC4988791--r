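#' Load a 3D NIfTI volume
#'
#' @param path NIfTI-1/2 file, optionally gzipped.
#' @return List with \code{data} (3D numeric array) and \code{affine}
#'   (4x4 voxel-to-world matrix).
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected a 3D volume, got %dD: %s", length(dim(img)), path))
  aff <- structure(RNifti::xform(img), class = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  if (abs(det(aff)) < .Machine$double.eps)
    stop(sprintf("singular affine in %s", path))
  list(data = array(as.numeric(img), dim(img)), affine = aff)
}

#' Save a 3D volume as NIfTI
#'
#' @param volume list with \code{data} and \code{affine} (as returned by
#'   \code{\link{load_volume}}), or a \code{voxel_mask}.
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI datatype; masks default to \code{"uint8"}, other
#'   volumes to \code{"double"}.
#' @return The path, invisibly.
#' @export
save_volume <- function(volume, path, datatype = NULL) {
  if (inherits(volume, "voxel_mask")) {
    data <- array(as.integer(volume$data), dim(volume$data))
    affine <- volume$affine
    if (is.null(datatype)) datatype <- "uint8"
  } else {
    data <- volume$data
    affine <- volume$affine
    if (is.null(datatype)) datatype <- "double"
  }
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Load a mask from NIfTI
#' @param path NIfTI file of a binary mask.
#' @return A \code{\link{voxel_mask}}.
#' @export
load_mask <- function(path) {
  v <- load_volume(path)
  voxel_mask(v$data != 0, v$affine)
}

# ---------------------------------------------------------------------------
# GIFTI surface I/O (ASCII-encoded DataArrays).  Vertex order is preserved
# across save/load, which vertex correspondence depends on.
# ---------------------------------------------------------------------------

#' Write a mesh as a GIFTI surface file
#' @param mesh a \code{triangle_mesh}.
#' @param path output path (.surf.gii).
#' @return The path, invisibly.
#' @export
write_gifti_mesh <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  fmt_rows <- function(m) paste(apply(m, 1, paste, collapse = " "),
                                collapse = "\n")
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  da1 <- xml2::xml_add_child(doc, "DataArray",
                             Intent = "NIFTI_INTENT_POINTSET",
                             DataType = "NIFTI_TYPE_FLOAT32",
                             ArrayIndexingOrder = "RowMajorOrder",
                             Dimensionality = "2",
                             Dim0 = as.character(nv), Dim1 = "3",
                             Encoding = "ASCII", Endian = "LittleEndian")
  xml2::xml_add_child(da1, "Data", fmt_rows(mesh$vertices))
  da2 <- xml2::xml_add_child(doc, "DataArray",
                             Intent = "NIFTI_INTENT_TRIANGLE",
                             DataType = "NIFTI_TYPE_INT32",
                             ArrayIndexingOrder = "RowMajorOrder",
                             Dimensionality = "2",
                             Dim0 = as.character(nt), Dim1 = "3",
                             Encoding = "ASCII", Endian = "LittleEndian")
  xml2::xml_add_child(da2, "Data", fmt_rows(mesh$triangles - 1L))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GIFTI surface file
#' @param path .surf.gii path (ASCII encoding).
#' @return A \code{triangle_mesh}.
#' @export
read_gifti_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  verts <- tris <- NULL
  for (da in das) {
    enc <- xml2::xml_attr(da, "Encoding")
    if (!identical(enc, "ASCII"))
      stop("only ASCII-encoded GIFTI data arrays are supported")
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
                 quiet = TRUE)
    n0 <- as.integer(xml2::xml_attr(da, "Dim0"))
    m <- matrix(vals, n0, 3, byrow = TRUE)
    intent <- xml2::xml_attr(da, "Intent")
    if (intent == "NIFTI_INTENT_POINTSET") verts <- m
    if (intent == "NIFTI_INTENT_TRIANGLE") tris <- m + 1L
  }
  if (is.null(verts) || is.null(tris))
    stop("GIFTI file lacks a pointset or triangle array")
  triangle_mesh(verts, tris)
}

#' Write per-vertex data as a GIFTI functional file
#' @param values numeric vector or matrix (vertices x maps).
#' @param path output path (.func.gii).
#' @return The path, invisibly.
#' @export
write_gifti_data <- function(values, path) {
  values <- as.matrix(values)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(ncol(values)))
  for (j in seq_len(ncol(values))) {
    da <- xml2::xml_add_child(doc, "DataArray",
                              Intent = "NIFTI_INTENT_NONE",
                              DataType = "NIFTI_TYPE_FLOAT32",
                              ArrayIndexingOrder = "RowMajorOrder",
                              Dimensionality = "1",
                              Dim0 = as.character(nrow(values)),
                              Encoding = "ASCII", Endian = "LittleEndian")
    xml2::xml_add_child(da, "Data",
                        paste(format(values[, j], digits = 9),
                              collapse = "\n"))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Legacy ASCII VTK PolyData I/O
# ---------------------------------------------------------------------------

#' Write a mesh as legacy ASCII VTK PolyData
#' @param mesh a \code{triangle_mesh}.
#' @param path output .vtk path.
#' @return The path, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "meshseg surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nv)), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nt, 4L * nt), con)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a legacy ASCII VTK PolyData mesh
#' @param path .vtk path.
#' @return A \code{triangle_mesh}.
#' @export
read_vtk_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("not a VTK PolyData file: no POINTS section")
  nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pvals <- scan(text = paste(lines[(ip + 1):length(lines)], collapse = "\n"),
                n = nv * 3, quiet = TRUE)
  verts <- matrix(pvals, nv, 3, byrow = TRUE)
  ig <- grep("^POLYGONS", lines)[1]
  nt <- as.integer(strsplit(lines[ig], "\\s+")[[1]][2])
  gvals <- scan(text = paste(lines[(ig + 1):length(lines)], collapse = "\n"),
                n = nt * 4, quiet = TRUE)
  gm <- matrix(gvals, nt, 4, byrow = TRUE)
  if (any(gm[, 1] != 3)) stop("VTK PolyData contains non-triangle cells")
  triangle_mesh(verts, gm[, 2:4] + 1L)
}

# ---------------------------------------------------------------------------
# Configuration and model serialization
# ---------------------------------------------------------------------------

#' Read a run configuration (YAML)
#'
#' Mirrors the rule and parameter tables field-for-field: per structure a
#' list of rules (modality, type, lambda, inside, outside), per modality a
#' normalization mode, plus sampling and MRF parameters.
#'
#' @param path YAML file.
#' @return List with \code{rules} (per structure, lists of
#'   \code{prior_rule}), \code{modality_norm}, \code{mrf_weights},
#'   \code{voxel_mm} and any further scalar fields.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- raw
  if (!is.null(raw$rules)) {
    out$rules <- lapply(raw$rules, function(rr)
      lapply(rr, function(r)
        prior_rule(r$modality, r$type,
                   lambda = if (!is.null(r$lambda)) as.numeric(r$lambda),
                   inside = r$inside, outside = r$outside)))
  }
  if (!is.null(raw$modality_norm))
    out$modality_norm <- unlist(raw$modality_norm)
  if (!is.null(raw$mrf_weights))
    out$mrf_weights <- unlist(raw$mrf_weights)
  out
}

#' Save a trained intensity model
#'
#' Single-file JSON archive: a versioned header (sampling configuration,
#' hyperparameters, component metadata) plus all per-vertex arrays.
#'
#' @param model an \code{intensity_model}.
#' @param path output .json path.
#' @return The path, invisibly.
#' @export
save_intensity_model <- function(model, path) {
  ser <- list(schema = "meshseg-intensity-model-1",
              config = unclass(model$config),
              hyper = model$hyper,
              n_vertices = model$n_vertices,
              modalities = lapply(model$modalities, function(f) list(
                normalization = f$normalization,
                beta_f = f$beta_f,
                n_components = f$n_components,
                dims = dim(f$means),
                means = as.numeric(f$means),
                precisions = as.numeric(f$precisions),
                weights = as.numeric(f$weights),
                templates = as.numeric(f$templates),
                templates_dim = dim(f$templates))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trained intensity model
#' @param path .json path written by \code{\link{save_intensity_model}}.
#' @return An \code{intensity_model}.
#' @export
load_intensity_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$schema, "meshseg-intensity-model-1"))
    stop("unrecognized model schema")
  config <- structure(list(step_mm = ser$config$step_mm,
                           n_steps = as.integer(ser$config$n_steps),
                           k = as.integer(ser$config$k),
                           positions = as.numeric(ser$config$positions)),
                      class = "profile_config")
  mods <- lapply(ser$modalities, function(f) {
    d <- as.integer(f$dims)
    list(normalization = f$normalization, beta_f = f$beta_f,
         n_components = as.integer(f$n_components),
         means = array(f$means, d),
         precisions = array(f$precisions, d),
         weights = matrix(f$weights, d[1], d[2]),
         templates = matrix(f$templates, as.integer(f$templates_dim)[1],
                            as.integer(f$templates_dim)[2]))
  })
  structure(list(config = config, hyper = ser$hyper, modalities = mods,
                 n_vertices = as.integer(ser$n_vertices)),
            class = "intensity_model")
}

#' Read a 4x4 affine transform from a text file
#' @param path whitespace-delimited 4x4 matrix file.
#' @return A \code{\link{spatial_transform}}.
#' @export
read_affine_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  spatial_transform(affine = m)
}
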