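# Shared fixtures, all generated in code.

# ASCII STL of the unit cube: 12 facets, welds to 8 vertices.
write_unit_cube_stl <- function(path) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))  # 8 corners
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  # faces by corner index (1-based into v), outward orientation not needed
  f <- rbind(quad(1, 2, 4, 3), quad(5, 7, 8, 6), quad(1, 5, 6, 2),
             quad(3, 4, 8, 7), quad(1, 3, 7, 5), quad(2, 6, 8, 4))
  con <- file(path, "w")
  writeLines("solid cube", con)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    writeLines(c(" facet normal 0 0 0", "  outer loop",
                 sprintf("   vertex %g %g %g", tri[, 1], tri[, 2], tri[, 3]),
                 "  endloop", " endfacet"), con)
  }
  writeLines("endsolid cube", con)
  close(con)
  path
}

# Regular triangulated grid on the z = 0 plane over [0, 1] x [0, 1].
planar_patch <- function(nx = 10, ny = 10) {
  xs <- seq(0, 1, length.out = nx)
  ys <- seq(0, 1, length.out = ny)
  verts <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  id <- function(i, j) (j - 1L) * nx + i
  faces <- do.call(rbind, lapply(seq_len(ny - 1), function(j) {
    do.call(rbind, lapply(seq_len(nx - 1), function(i) {
      rbind(c(id(i, j), id(i + 1, j), id(i, j + 1)),
            c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
    }))
  }))
  surface_mesh(verts, faces)
}

# Straight swept cylinder with generator ground truth attached.
cylinder_case <- function(r0 = 2, L = 40, spacing = 0.5, angular_res = 48) {
  cl <- make_centerline(list(type = "straight", length = L), spacing = spacing)
  mesh <- make_fusiform_surface(cl, shape_params("fusiform", r0 = r0),
                                angular_res = angular_res)
  list(cl = cl, mesh = mesh)
}

# Focal-bulge tube (fusiform) with known radius function.
bulge_case <- function(r0 = 2, A = 1, L = 40, s0 = 20, sigma = 4,
                       spacing = 0.5, angular_res = 48) {
  cl <- make_centerline(list(type = "straight", length = L), spacing = spacing)
  shape <- shape_params("fusiform", r0 = r0, A = A, s0 = s0, sigma = sigma)
  mesh <- make_fusiform_surface(cl, shape, angular_res = angular_res)
  list(cl = cl, mesh = mesh, shape = shape)
}

# Small constant-in-space WSS series on a tiny mesh: one vector per time.
tiny_series <- function(times, vectors_by_time) {
  mesh <- planar_patch(3, 3)
  nt <- length(times)
  vec <- array(0, c(nt, n_vertices(mesh), 3))
  for (t in seq_len(nt))
    vec[t, , ] <- matrix(vectors_by_time[t, ], n_vertices(mesh), 3,
                         byrow = TRUE)
  wss_series(times, vec, mesh)
}

# Random (seeded) WSS series with n_t samples on a small tube.
random_series <- function(n_t = 4, seed = 7, n_vert = NULL) {
  cs <- cylinder_case(r0 = 1.5, L = 10, spacing = 1, angular_res = 16)
  nv <- n_vertices(cs$mesh)
  set.seed(seed)
  vec <- array(rnorm(n_t * nv * 3), c(n_t, nv, 3))
  wss_series(seq(0, 0.8, length.out = n_t), vec, cs$mesh)
}

# Independent trapezoid oracle used against cycle-integral-based indices.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Independent total-area oracle (Heron's formula per face).
face_areas_for_test <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  vapply(seq_len(nrow(f)), function(i) {
    a <- sqrt(sum((v[f[i, 1], ] - v[f[i, 2], ])^2))
    b <- sqrt(sum((v[f[i, 2], ] - v[f[i, 3], ])^2))
    cc <- sqrt(sum((v[f[i, 3], ] - v[f[i, 1], ])^2))
    s <- (a + b + cc) / 2
    sqrt(max(0, s * (s - a) * (s - b) * (s - cc)))
  }, numeric(1))
}

# 1-ring least-squares gradient oracle (independent of the P1 route):
# fits f(x) ~ f(x0) + g . (x - x0) over the vertex's neighbors (planar
# patches only: gradient in the x-y plane).
one_ring_ls_gradient <- function(mesh, f) {
  nv <- n_vertices(mesh)
  fidx <- mesh$faces
  nbr <- vector("list", nv)
  for (k in 1:3) {
    for (m in setdiff(1:3, k)) {
      for (r in seq_len(nrow(fidx)))
        nbr[[fidx[r, k]]] <- c(nbr[[fidx[r, k]]], fidx[r, m])
    }
  }
  out <- matrix(NA_real_, nv, 2)
  for (i in seq_len(nv)) {
    js <- unique(nbr[[i]])
    if (length(js) < 2) next
    dx <- mesh$vertices[js, 1:2, drop = FALSE] -
      matrix(mesh$vertices[i, 1:2], length(js), 2, byrow = TRUE)
    df <- f[js] - f[i]
    out[i, ] <- qr.coef(qr(dx), df)
  }
  out
}
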