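test_that("cycle integrals reproduce hand-computed trapezoids", {
  # constant vector v over T
  v <- c(1.2, -0.4, 2)
  ser <- tiny_series(seq(0, 0.8, length.out = 9),
                     matrix(v, 9, 3, byrow = TRUE))
  vi <- cycle_integral(ser, "vector")
  expect_equal(vi[1, ], 0.8 * v, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cycle_integral(ser, "magnitude"),
               rep(0.8 * sqrt(sum(v^2)), n_vertices(ser$mesh)),
               tolerance = 1e-12)

  # half-cycle reversal of equal magnitude w
  w <- 1.5
  mesh1 <- planar_patch(2, 2)
  arr <- array(0, c(8, n_vertices(mesh1), 3))
  for (t in 1:8) arr[t, , 1] <- if (t <= 4) w else -w
  ser2 <- wss_series(seq(0, 0.8, length.out = 8), arr, mesh1)
  vi2 <- cycle_integral(ser2, "vector")
  # trapezoid leaves one straddling interval; oracle by direct sum
  tt <- ser2$times
  expect_equal(vi2[1, 1], trapz(tt, arr[, 1, 1]), tolerance = 1e-12)
  expect_equal(cycle_integral(ser2, "magnitude")[1], 0.8 * w,
               tolerance = 1e-12)

  # 3-sample hand computation
  ser3 <- tiny_series(c(0, 0.25, 0.8),
                      rbind(c(1, 0, 0), c(3, 0, 0), c(2, 0, 0)))
  hand <- 0.25 * (1 + 3) / 2 + 0.55 * (3 + 2) / 2
  expect_equal(cycle_integral(ser3, "vector")[1, 1], hand,
               tolerance = 1e-12)

  bad <- ser3
  bad$vectors[2, 1, 1] <- NA
  expect_error(cycle_integral(bad, "vector"), "vertex")
})

test_that("TAWSS averages the magnitude, not the vector", {
  ser <- tiny_series(seq(0, 0.8, length.out = 5),
                     matrix(c(0, 1.5, 0), 5, 3, byrow = TRUE))
  expect_equal(tawss(ser), rep(1.5, n_vertices(ser$mesh)),
               tolerance = 1e-12)
  # reversal: vector integral cancels, magnitude does not
  mesh1 <- planar_patch(2, 2)
  arr <- array(0, c(100, n_vertices(mesh1), 3))
  arr[, , 1] <- sign(sin(2 * pi * seq(0, 1, length.out = 100))) * 2
  arr[1, , 1] <- 2
  ser2 <- wss_series(seq(0, 0.8, length.out = 100), arr, mesh1)
  expect_equal(tawss(ser2)[1], 2, tolerance = 0.03)
  expect_gt(osi(ser2)[1], 0.45)
})

test_that("OSI hits its closed-form limits and matches brute force", {
  ser <- tiny_series(seq(0, 0.8, length.out = 7),
                     matrix(c(2, 1, 0), 7, 3, byrow = TRUE))
  expect_equal(osi(ser), rep(0, n_vertices(ser$mesh)))

  rs <- random_series(n_t = 4, seed = 42)
  o <- osi(rs)
  # brute-force evaluation of the defining formula per vertex
  tt <- rs$times
  for (vtx in c(1, 5, 17)) {
    vecint <- vapply(1:3, function(d) trapz(tt, rs$vectors[, vtx, d]),
                     numeric(1))
    magint <- trapz(tt, sqrt(rowSums(rs$vectors[, vtx, ]^2)))
    expect_equal(o[vtx], 0.5 * (1 - sqrt(sum(vecint^2)) / magint),
                 tolerance = 1e-12)
  }
  expect_true(all(o >= 0 & o <= 0.5))
})

test_that("P1 surface gradient is exact for linear fields", {
  mesh <- planar_patch(9, 9)
  nrm <- vertex_normals(mesh)
  # frame with p = +x, q = +y on the z = 0 plane (mean WSS along x)
  frame <- wss_tangent_frame(mesh, matrix(rep(c(1, 0, 0), each =
                                                n_vertices(mesh)),
                                          ncol = 3))
  expect_false(any(frame$degenerate))
  wp <- 2 * mesh$vertices[, 1] + 1
  wq <- -3 * mesh$vertices[, 2]
  field <- wp * frame$p + wq * frame$q
  G <- wss_surface_gradient(mesh, field, frame)
  expect_lt(max(abs(G[, 1] - 2)), 1e-10)
  expect_lt(max(abs(G[, 2] + 3)), 1e-10)

  # independent 1-ring least-squares oracle agrees on the linear field
  Gls <- one_ring_ls_gradient(mesh, rowSums(field * frame$p))
  expect_lt(max(abs(Gls[, 1] - 2)), 1e-10)   # d(W_p)/dx
  expect_lt(max(abs(Gls[, 2] - 0)), 1e-10)   # d(W_p)/dy

  # constant field has zero gradient
  G0 <- wss_surface_gradient(mesh, matrix(5, n_vertices(mesh), 3), frame)
  expect_lt(max(abs(G0)), 1e-12)
})

test_that("P1 gradient error shrinks under refinement for quadratic fields", {
  errs <- vapply(c(6, 12, 24), function(nx) {
    mesh <- planar_patch(nx, nx)
    frame <- wss_tangent_frame(mesh, matrix(rep(c(1, 0, 0),
                                                each = n_vertices(mesh)),
                                            ncol = 3))
    x <- mesh$vertices[, 1]
    field <- (x^2) * frame$p
    G <- wss_surface_gradient(mesh, field, frame)
    interior <- x > 0.2 & x < 0.8
    max(abs(G[interior, 1] - 2 * x[interior]))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("GON hits its closed-form limits", {
  # steady spatially varying field: G constant != 0 -> GON = 0
  mesh <- planar_patch(8, 8)
  frame_field <- matrix(rep(c(1, 0, 0), each = n_vertices(mesh)), ncol = 3)
  arr <- array(0, c(6, n_vertices(mesh), 3))
  for (t in 1:6) arr[t, , 1] <- 4 * mesh$vertices[, 1]
  ser <- wss_series(seq(0, 0.8, length.out = 6), arr, mesh)
  expect_lt(max(gon(ser)), 1e-10)

  # alternating field: gradient reverses every half cycle -> GON = 1
  arr2 <- arr
  for (t in 1:6) arr2[t, , 1] <- arr[t, , 1] * c(1, -1)[(t > 3) + 1]
  # use antisymmetric weights: equal time at +g and -g
  ser2 <- wss_series(c(0, 0.1, 0.2, 0.6, 0.7, 0.8), arr2, mesh)
  g2 <- gon(ser2)
  interior <- mesh$vertices[, 1] > 0.2 & mesh$vertices[, 1] < 0.8
  expect_gt(min(g2[interior]), 0.99)
  expect_true(all(g2 >= 0 & g2 <= 1))
})

test_that("RRT satisfies the algebraic identity with OSI and TAWSS", {
  # steady field of magnitude 2 -> RRT = 1/2
  ser <- tiny_series(seq(0, 0.8, length.out = 5),
                     matrix(c(0, 2, 0), 5, 3, byrow = TRUE))
  expect_equal(rrt(ser), rep(0.5, n_vertices(ser$mesh)), tolerance = 1e-12)

  # constructed case with OSI = 0.25, TAWSS = 1 -> RRT = 2
  mesh1 <- planar_patch(2, 2)
  arr <- array(0, c(3, n_vertices(mesh1), 3))
  arr[1, , 1] <- 1.5; arr[2, , 1] <- -0.5; arr[3, , 1] <- 1.5
  ser2 <- wss_series(c(0, 0.5, 1), arr, mesh1)
  expect_equal(tawss(ser2)[1], 1, tolerance = 1e-12)
  expect_equal(osi(ser2)[1], 0.25, tolerance = 1e-12)
  expect_equal(rrt(ser2)[1], 2, tolerance = 1e-12)

  rs <- random_series(n_t = 4, seed = 13)
  r <- rrt(rs); o <- osi(rs); tw <- tawss(rs)
  ok <- is.finite(r)
  expect_lt(max(abs(r[ok] - 1 / ((1 - 2 * o[ok]) * tw[ok])) / r[ok]), 1e-10)
})

test_that("parent-vessel normalization and regional summaries", {
  bc <- bulge_case(r0 = 2, A = 1, s0 = 20, sigma = 3, spacing = 1,
                   angular_res = 16)
  nv <- n_vertices(bc$mesh)
  uniform <- rep(3.3, nv)
  norm <- normalize_tawss(uniform, bc$mesh, c(12, 28), cl = bc$cl)
  expect_equal(norm, rep(1, nv), tolerance = 1e-12)
  expect_error(normalize_tawss(uniform, bc$mesh, c(12, 28),
                               parent_region = rep(FALSE, nv)), "empty")

  # area-weighted mean by hand on the two-triangle square
  sq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  maps <- list(TAWSS = c(4, 0, 0, 0))
  rs <- regional_summary(maps, sq, rep(TRUE, 4))
  expect_equal(rs$mean, 4 * (1 / 3), tolerance = 1e-12)  # weights 1/3,1/6,...
  expect_equal(rs$max, 4)
  const <- regional_summary(list(OSI = rep(0.2, 4)), sq, rep(TRUE, 4))
  expect_equal(const$mean, 0.2)
  expect_equal(const$max, 0.2)
  expect_error(regional_summary(maps, sq, rep(FALSE, 4)), "empty")
})

test_that("doubling the time sampling barely changes TAWSS and OSI", {
  bc <- bulge_case(r0 = 2, A = 1, s0 = 20, sigma = 4, spacing = 1,
                   angular_res = 16)
  w1 <- make_wss_series(bc$mesh, bc$cl, flow_params(n_t = 100, noise_sd = 0))
  w2 <- make_wss_series(bc$mesh, bc$cl, flow_params(n_t = 200, noise_sd = 0))
  expect_lt(max(abs(tawss(w2) - tawss(w1)) / tawss(w1)), 0.005)
  expect_lt(max(abs(osi(w2) - osi(w1))), 0.005)
})
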