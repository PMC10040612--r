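#' Read a triangulated surface from STL, PLY or legacy VTK polydata
#'
#' STL (binary or ASCII, auto-detected) and PLY (ASCII) carry geometry only;
#' legacy VTK polydata additionally carries named per-vertex SCALARS/VECTORS
#' arrays, which are preserved in `point_data`. STL facet soups are welded:
#' vertices with identical coordinates are merged so faces share vertices.
#'
#' @param path file to read.
#' @param format one of `"stl"`, `"ply"`, `"vtk"`; inferred from the file
#'   extension when omitted.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         vtk = read_vtk_polydata(path),
         stop("unsupported surface format: ", format, call. = FALSE))
}

#' Write a triangulated surface to STL, PLY or legacy VTK polydata
#'
#' @param mesh a [surface_mesh()].
#' @param path destination file.
#' @param format `"stl"`, `"ply"` or `"vtk"`; inferred from the
#'   extension when omitted. Only VTK keeps `point_data`.
#' @param ascii write ASCII STL (default; round-trips coordinates to better
#'   than 1e-6 mm) instead of binary STL (float32 per the format standard).
#' @export
write_surface <- function(mesh, path, format = NULL, ascii = TRUE) {
  validate_surface_mesh(mesh)
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         stl = write_stl(mesh, path, ascii = ascii),
         ply = write_ply(mesh, path),
         vtk = write_vtk_polydata(mesh, path),
         stop("unsupported surface format: ", format, call. = FALSE))
  invisible(NULL)
}

weld_vertices <- function(tri_coords) {
  # tri_coords: (3*m) x 3, consecutive triples form faces
  key <- paste(sprintf("%.9g", tri_coords[, 1]),
               sprintf("%.9g", tri_coords[, 2]),
               sprintf("%.9g", tri_coords[, 3]))
  uid <- match(key, unique(key))
  vertices <- tri_coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(vertices, faces)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  if (length(head) < 80L) stop("STL format error: file shorter than 80-byte header",
                               call. = FALSE)
  # ASCII files begin with "solid", but so may binary headers; disambiguate
  # by checking the byte budget implied by the facet count.
  nfac <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  size <- file.size(path)
  is_binary <- length(nfac) == 1L && !is.na(nfac) &&
    size == 84 + 50 * as.numeric(nfac)
  if (is_binary) {
    coords <- matrix(NA_real_, nfac * 3L, 3L)
    for (i in seq_len(nfac)) {
      rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      if (length(rec) < 12L)
        stop(sprintf("STL format error: truncated facet record %d", i),
             call. = FALSE)
      readBin(con, "raw", 2L)
      coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
    return(weld_vertices(coords))
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1], ignore.case = TRUE))
    stop("STL format error: neither valid binary nor ASCII ('solid' missing)",
         call. = FALSE)
  vtx <- grep("^\\s*vertex\\s", lines, ignore.case = TRUE, value = TRUE)
  if (!length(vtx) || length(vtx) %% 3 != 0)
    stop(sprintf("STL format error: %d vertex records (not a multiple of 3)",
                 length(vtx)), call. = FALSE)
  nums <- lapply(strsplit(trimws(vtx), "\\s+"), function(x) as.numeric(x[2:4]))
  coords <- do.call(rbind, nums)
  if (anyNA(coords))
    stop("STL format error: non-numeric vertex coordinate", call. = FALSE)
  weld_vertices(coords)
}

write_stl <- function(mesh, path, ascii = FALSE) {
  fc <- face_corner_coords(mesh)
  fn <- face_normals(mesh)
  m <- nrow(mesh$faces)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid fusiwall", con)
    for (i in seq_len(m)) {
      writeLines(c(
        sprintf(" facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
        "  outer loop",
        sprintf("   vertex %.9g %.9g %.9g", fc$a[i, 1], fc$a[i, 2], fc$a[i, 3]),
        sprintf("   vertex %.9g %.9g %.9g", fc$b[i, 1], fc$b[i, 2], fc$b[i, 3]),
        sprintf("   vertex %.9g %.9g %.9g", fc$c[i, 1], fc$c[i, 2], fc$c[i, 3]),
        "  endloop",
        " endfacet"), con)
    }
    writeLines("endsolid fusiwall", con)
    return(invisible(NULL))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("fusiwall binary STL"), raw(80 - 19)), con)
  writeBin(as.integer(m), con, size = 4L, endian = "little")
  for (i in seq_len(m)) {
    writeBin(as.numeric(c(fn[i, ], fc$a[i, ], fc$b[i, ], fc$c[i, ])), con,
             size = 4L, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(NULL)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("PLY format error: missing 'ply' magic", call. = FALSE)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY format error: no end_header", call. = FALSE)
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr))))
    stop("PLY format error: only ASCII PLY is supported", call. = FALSE)
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf))
    stop("PLY format error: vertex/face element counts missing", call. = FALSE)
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf)
    stop("PLY format error: truncated body", call. = FALSE)
  vt <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                              function(x) as.numeric(x[1:3])))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fl, function(x) {
    k <- as.integer(x[1])
    if (k != 3L) stop("PLY format error: non-triangular face", call. = FALSE)
    as.integer(x[2:4]) + 1L
  }))
  surface_mesh(vt, faces)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(NULL)
}

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    stop("VTK format error: missing DataFile header", call. = FALSE)
  if (toupper(trimws(lines[3])) != "ASCII")
    stop("VTK format error: only ASCII legacy files are supported", call. = FALSE)
  if (!grepl("POLYDATA", lines[4]))
    stop("VTK format error: DATASET POLYDATA expected", call. = FALSE)
  toks <- scan(text = paste(lines[-(1:4)], collapse = "\n"), what = "character",
               quiet = TRUE)
  i <- 1L
  take <- function(k) {
    out <- toks[i:(i + k - 1L)]
    i <<- i + k
    out
  }
  nv <- NULL; vertices <- NULL; faces <- NULL
  point_data <- list()
  n_pd <- 0L
  while (i <= length(toks)) {
    kw <- toupper(toks[i]); i <- i + 1L
    if (kw == "POINTS") {
      nv <- as.integer(toks[i]); i <- i + 2L  # count + dtype
      vals <- as.numeric(take(3L * nv))
      vertices <- matrix(vals, ncol = 3, byrow = TRUE)
    } else if (kw == "POLYGONS") {
      np <- as.integer(toks[i]); sz <- as.integer(toks[i + 1L]); i <- i + 2L
      vals <- as.integer(take(sz))
      faces <- matrix(NA_integer_, np, 3)
      p <- 1L
      for (r in seq_len(np)) {
        k <- vals[p]
        if (k != 3L) stop("VTK format error: non-triangular polygon", call. = FALSE)
        faces[r, ] <- vals[(p + 1L):(p + 3L)] + 1L
        p <- p + k + 1L
      }
    } else if (kw == "POINT_DATA") {
      n_pd <- as.integer(toks[i]); i <- i + 1L
    } else if (kw == "SCALARS") {
      nm <- toks[i]; i <- i + 2L  # name + dtype
      ncomp <- 1L
      if (grepl("^[0-9]+$", toks[i])) { ncomp <- as.integer(toks[i]); i <- i + 1L }
      if (ncomp != 1L)
        stop("VTK format error: only 1-component SCALARS supported", call. = FALSE)
      if (toupper(toks[i]) == "LOOKUP_TABLE") i <- i + 2L
      point_data[[nm]] <- as.numeric(take(n_pd))
    } else if (kw == "VECTORS") {
      nm <- toks[i]; i <- i + 2L
      point_data[[nm]] <- matrix(as.numeric(take(3L * n_pd)), ncol = 3,
                                 byrow = TRUE)
    } else if (kw %in% c("LINES", "VERTICES", "CELL_DATA")) {
      stop("VTK format error: unsupported section ", kw, call. = FALSE)
    } else {
      stop("VTK format error: unexpected token '", kw, "'", call. = FALSE)
    }
  }
  if (is.null(vertices) || is.null(faces))
    stop("VTK format error: POINTS or POLYGONS section missing", call. = FALSE)
  surface_mesh(vertices, faces, point_data)
}

write_vtk_polydata <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c("# vtk DataFile Version 3.0", "fusiwall surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  if (length(mesh$point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(mesh$point_data)) {
      a <- mesh$point_data[[nm]]
      if (is.matrix(a)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.12g %.12g %.12g", a[, 1], a[, 2], a[, 3]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.12g", as.numeric(a)), con)
      }
    }
  }
  invisible(NULL)
}
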