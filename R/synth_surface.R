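#' Shape parameters of a synthetic fusiform-aneurysm vessel
#'
#' The luminal radius along the centerline is
#' \deqn{r(s) = r_0 [\, 1 + (g-1)\,w(s) + A \exp(-(s-s_0)^2 / 2\sigma^2) \,]}
#' where `w(s)` is a raised-cosine plateau equal to 1 over the dilated
#' extent `[ext_lo, ext_hi]` and tapering to 0 over `ramp` mm at either
#' side, so every vessel retains a parent tube of radius `r0` near the
#' inlet and outlet. At the bulge centre (inside the plateau)
#' `r(s0) = r0 (g + A)`. The Flemming type mapping is: fusiform `g = 1,
#' A > 0`; dolichoectatic `g > 1, A = 0`, longer; transitional `g > 1` and
#' `A > 0`, longest.
#'
#' @param ifa_type `"fusiform"`, `"dolichoectatic"` or `"transitional"`.
#' @param r0 parent-vessel radius (mm), > 0.
#' @param g uniform dilation factor over the dilated extent, >= 1.
#' @param A focal bulge amplitude (in units of `r0`), >= 0.
#' @param s0 bulge centre (mm arc length).
#' @param sigma bulge Gaussian width (mm), > 0.
#' @param ext_lo,ext_hi arc-length bounds of the uniformly dilated extent
#'   (mm); ignored when `g = 1`.
#' @param ramp taper length of the dilation plateau (mm).
#' @return an object of class `shape_params`.
#' @export
shape_params <- function(ifa_type = c("fusiform", "dolichoectatic",
                                      "transitional"),
                         r0, g = 1, A = 0, s0 = NA, sigma = 3,
                         ext_lo = NA, ext_hi = NA, ramp = 5) {
  ifa_type <- match.arg(ifa_type)
  stopifnot_scalar(r0, "r0", positive = TRUE)
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  if (g < 1) stop("uniform dilation factor g must be >= 1", call. = FALSE)
  if (A < 0) stop("bulge amplitude A must be >= 0", call. = FALSE)
  structure(list(ifa_type = ifa_type, r0 = r0, g = g, A = A, s0 = s0,
                 sigma = sigma, ext_lo = ext_lo, ext_hi = ext_hi, ramp = ramp),
            class = "shape_params")
}

#' Ground-truth radius function of a shape
#' @param shape a [shape_params()].
#' @param s arc-length positions (mm).
#' @param total_length vessel length (mm), used for unset defaults.
#' @return luminal radius (mm) at each `s`.
#' @export
radius_function <- function(shape, s, total_length = max(s)) {
  s0 <- if (is.na(shape$s0)) total_length / 2 else shape$s0
  lo <- if (is.na(shape$ext_lo)) 0.3 * total_length else shape$ext_lo
  hi <- if (is.na(shape$ext_hi)) 0.7 * total_length else shape$ext_hi
  w <- numeric(length(s))
  w[s >= lo & s <= hi] <- 1
  rl <- s < lo & s > lo - shape$ramp
  w[rl] <- 0.5 * (1 + cos(pi * (lo - s[rl]) / shape$ramp))
  rh <- s > hi & s < hi + shape$ramp
  w[rh] <- 0.5 * (1 + cos(pi * (s[rh] - hi) / shape$ramp))
  bulge <- shape$A * exp(-(s - s0)^2 / (2 * shape$sigma^2))
  shape$r0 * (1 + (shape$g - 1) * w + bulge)
}

# Rotation-minimizing frames along a polyline (double-reflection method).
# Returns list of n x 3 matrices e1, e2 orthonormal to the local tangent.
rmf_frames <- function(points) {
  n <- nrow(points)
  tang <- matrix(0, n, 3)
  tang[1, ] <- points[2, ] - points[1, ]
  tang[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- points[3:n, ] - points[1:(n - 2), ]
  tang <- normalize_rows(tang)
  e1 <- matrix(0, n, 3)
  # seed: any unit vector orthogonal to the first tangent
  t1 <- tang[1, ]
  seed <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- seed - sum(seed * t1) * t1
  e1[1, ] <- v / sqrt(sum(v^2))
  for (i in seq_len(n - 1)) {
    # reflection 1: across the chord bisecting plane
    v1 <- points[i + 1, ] - points[i, ]
    c1 <- sum(v1 * v1)
    rL <- e1[i, ] - (2 / c1) * sum(v1 * e1[i, ]) * v1
    tL <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
    # reflection 2: align reflected tangent with the next tangent
    v2 <- tang[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    e1[i + 1, ] <- if (c2 < 1e-16) rL else rL - (2 / c2) * sum(v2 * rL) * v2
  }
  e2 <- cross3(tang, e1)
  list(tangent = tang, e1 = e1, e2 = normalize_rows(e2))
}

#' Sweep a fusiform-aneurysm surface along a centerline
#'
#' Generates an open tube of radius [radius_function()] swept along the
#' centerline with a rotation-minimizing frame (double-reflection), which is
#' stable through inflection points where a Frenet frame would flip. The
#' exact generating quantities are attached as per-vertex ground truth:
#' `s` (arc length), `radius_true`, `axis` (local tangent) and `circ`
#' (local circumferential direction), which the flow surrogate reuses.
#'
#' @param cl a [centerline()].
#' @param shape a [shape_params()].
#' @param angular_res vertices per cross-sectional ring (default 48).
#' @return a [surface_mesh()] with ground-truth `point_data` and the shape
#'   stored in `attr(, "shape")`.
#' @export
make_fusiform_surface <- function(cl, shape, angular_res = 48L) {
  angular_res <- as.integer(angular_res)
  if (angular_res < 8L) stop("angular_res must be >= 8", call. = FALSE)
  s <- cl$arclength
  L <- centerline_length(cl)
  r <- radius_function(shape, s, total_length = L)
  # reject sweeps whose bulge would fold over in a curved region
  if (!is.null(cl$per_point$kappa_true)) {
    if (max(r * cl$per_point$kappa_true) >= 0.9)
      stop("self-intersecting sweep: bulge radius exceeds the local radius of curvature",
           call. = FALSE)
  }
  fr <- rmf_frames(cl$points)
  n <- nrow(cl$points)
  theta <- 2 * pi * (seq_len(angular_res) - 1L) / angular_res
  ct <- cos(theta); st <- sin(theta)
  nv <- n * angular_res
  verts <- matrix(NA_real_, nv, 3)
  circ <- matrix(NA_real_, nv, 3)
  axis <- matrix(NA_real_, nv, 3)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * angular_res + seq_len(angular_res)
    radial <- outer(ct, fr$e1[i, ]) + outer(st, fr$e2[i, ])
    verts[rows, ] <- matrix(cl$points[i, ], angular_res, 3, byrow = TRUE) +
      r[i] * radial
    circ[rows, ] <- outer(-st, fr$e1[i, ]) + outer(ct, fr$e2[i, ])
    axis[rows, ] <- matrix(fr$tangent[i, ], angular_res, 3, byrow = TRUE)
  }
  # quad strip between consecutive rings, split into triangles with
  # outward-facing orientation
  i0 <- rep(seq_len(n - 1L), each = angular_res)
  j0 <- rep(seq_len(angular_res), n - 1L)
  j1 <- j0 %% angular_res + 1L
  a <- (i0 - 1L) * angular_res + j0
  b <- (i0 - 1L) * angular_res + j1
  cc <- i0 * angular_res + j0
  d <- i0 * angular_res + j1
  faces <- rbind(cbind(a, b, cc), cbind(b, d, cc))
  mesh <- surface_mesh(verts, faces,
                       point_data = list(
                         s = rep(s, each = angular_res),
                         theta = rep(theta, n),
                         radius_true = rep(r, each = angular_res),
                         axis = axis, circ = circ))
  attr(mesh, "shape") <- shape
  mesh
}
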