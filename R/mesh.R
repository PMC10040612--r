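#' Triangulated luminal surface mesh
#'
#' The central geometry container of the pipeline: a triangle mesh of the
#' vessel lumen wall with optional named per-vertex scalar or 3-vector
#' attributes (wall shear indices, enhancement ratio, arc-length coordinate,
#' ...). All coordinates are millimetres in the world frame of the imaging
#' volume.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param point_data named list of per-vertex attributes: numeric vectors of
#'   length n (scalars) or n x 3 matrices (vectors).
#' @return An object of class `surface_mesh`.
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   matrix(c(1L, 2L, 3L), 1))
#' vertex_areas(m)
#' @export
surface_mesh <- function(vertices, faces, point_data = list()) {
  vertices <- as_points3(vertices)
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must be an m x 3 index matrix", call. = FALSE)
  storage.mode(faces) <- "integer"
  m <- structure(list(vertices = vertices, faces = faces,
                      point_data = point_data),
                 class = "surface_mesh")
  validate_surface_mesh(m)
}

validate_surface_mesh <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (nv < 3L || nrow(mesh$faces) < 1L)
    stop("mesh must have at least 3 vertices and 1 face", call. = FALSE)
  if (anyNA(mesh$vertices)) stop("mesh vertices contain NA", call. = FALSE)
  f <- mesh$faces
  if (min(f) < 1L || max(f) > nv)
    stop("faces index vertices outside 1..n_vertices", call. = FALSE)
  for (nm in names(mesh$point_data)) {
    a <- mesh$point_data[[nm]]
    len <- if (is.matrix(a)) nrow(a) else length(a)
    if (len != nv)
      stop(sprintf("point_data array '%s' has length %d, expected %d",
                   nm, len, nv), call. = FALSE)
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (length(x$point_data))
    cat("  point_data:", paste(names(x$point_data), collapse = ", "), "\n")
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a [surface_mesh()].
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

face_corner_coords <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

#' Per-face areas and (optionally unit) normals
#' @noRd
face_areas <- function(mesh) {
  fc <- face_corner_coords(mesh)
  0.5 * row_norms(cross3(fc$b - fc$a, fc$c - fc$a))
}

face_normals <- function(mesh, unit = TRUE) {
  fc <- face_corner_coords(mesh)
  n <- cross3(fc$b - fc$a, fc$c - fc$a)
  if (unit) normalize_rows(n) else n
}

#' Per-vertex surface areas
#'
#' Each vertex receives one third of the summed areas of its incident faces
#' (barycentric lumping), so that the vertex areas always sum exactly to the
#' total face area. These weights drive every area-weighted surface mean and
#' the enhancement-area bookkeeping.
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  validate_surface_mesh(mesh)
  fa <- face_areas(mesh)
  if (any(fa == 0))
    warning("mesh contains zero-area faces; they contribute no area")
  acc <- numeric(nrow(mesh$vertices))
  third <- fa / 3
  for (k in 1:3) {
    s <- rowsum(third, mesh$faces[, k])
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
  }
  acc
}

#' Area-weighted per-vertex outward normals
#' @param mesh a [surface_mesh()].
#' @return n x 3 matrix of unit normals (zero rows where undefined).
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh, unit = FALSE)  # length = 2 * face area
  acc <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      s <- rowsum(fn[, d], mesh$faces[, k])
      acc[as.integer(rownames(s)), d] <- acc[as.integer(rownames(s)), d] + s[, 1]
    }
  }
  normalize_rows(acc)
}

#' Arc-length coordinate of each vertex along a centerline
#'
#' Maps every mesh vertex to the arc length of its nearest centerline point.
#' Swept synthetic meshes carry the exact coordinate in `point_data$s`, which
#' is used when present.
#'
#' @param mesh a [surface_mesh()].
#' @param cl a [centerline()].
#' @return numeric vector of arc lengths (mm), one per vertex.
#' @export
vertex_arclength <- function(mesh, cl) {
  if (!is.null(mesh$point_data$s)) return(as.numeric(mesh$point_data$s))
  nn <- nearest_points(mesh$vertices, cl$points)
  cl$arclength[nn$index]
}
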