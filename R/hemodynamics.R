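#' Trapezoid cycle integral of a WSS series
#'
#' Composite trapezoid over the provided samples; the cycle duration is
#' `T = t_N - t_0`. With `integrand = "vector"` the vector integral
#' \eqn{\int_0^T WSS_i\, dt} is returned (n x 3); with `"magnitude"` the
#' scalar integral \eqn{\int_0^T |WSS_i|\, dt} (length n).
#'
#' @param series a [wss_series()].
#' @param integrand `"vector"` or `"magnitude"`.
#' @return per-vertex integral (Pa s).
#' @export
cycle_integral <- function(series, integrand = c("vector", "magnitude")) {
  integrand <- match.arg(integrand)
  vec <- series$vectors
  if (anyNA(vec)) {
    bad <- which(is.na(vec), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN/NA WSS sample at time index %d, vertex %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  w <- trapezoid_weights(series$times)
  if (integrand == "vector") {
    out <- vapply(1:3, function(d) colSums(vec[, , d] * w),
                  numeric(dim(vec)[2]))
    return(out)
  }
  mag <- sqrt(vec[, , 1]^2 + vec[, , 2]^2 + vec[, , 3]^2)
  colSums(mag * w)
}

trapezoid_weights <- function(times) {
  dt <- diff(times)
  c(dt[1] / 2, (dt[-length(dt)] + dt[-1]) / 2, dt[length(dt)] / 2)
}

#' Time-averaged wall shear stress magnitude
#'
#' \eqn{TAWSS = (1/T) \int_0^T |WSS_i|\, dt} (Pa), the magnitude taken
#' inside the integral ("average magnitude of tangential frictional
#' stress"), which is the convention under which the relative-residence-time
#' identity holds.
#'
#' @param series a [wss_series()].
#' @return per-vertex TAWSS (Pa).
#' @export
tawss <- function(series) {
  cycle_integral(series, "magnitude") / cycle_duration(series)
}

#' Oscillatory shear index
#'
#' \eqn{OSI = \frac12 (1 - |\int WSS_i dt| / \int |WSS_i| dt)}, the degree
#' of directional variation of the WSS vector over the cycle; 0 for steady
#' unidirectional shear, 0.5 for perfect reversal. Defined as 0 where the
#' magnitude integral vanishes.
#'
#' @param series a [wss_series()].
#' @return per-vertex OSI in `[0, 0.5]`.
#' @export
osi <- function(series) {
  vi <- row_norms(cycle_integral(series, "vector"))
  mi <- cycle_integral(series, "magnitude")
  out <- ifelse(mi == 0, 0, 0.5 * (1 - vi / mi))
  pmin(pmax(out, 0), 0.5)
}

#' Relative residence time
#'
#' Computed as \eqn{RRT = T / |\int_0^T WSS_i dt|}, which is algebraically
#' identical to \eqn{1/((1 - 2\,OSI)\, TAWSS)}. Vertices where the vector
#' integral vanishes (pure oscillation) get `Inf`.
#'
#' @param series a [wss_series()].
#' @return per-vertex RRT (1/Pa).
#' @export
rrt <- function(series) {
  vi <- row_norms(cycle_integral(series, "vector"))
  ifelse(vi == 0, Inf, cycle_duration(series) / vi)
}

#' Per-vertex tangent frame aligned with the time-averaged WSS
#'
#' `p` is the unit projection of the mean WSS vector onto the tangent plane
#' (defined by the area-weighted vertex normal); `q = n x p`. Where the mean
#' WSS is (numerically) parallel to the normal or zero, an arbitrary tangent
#' basis is substituted and the vertex flagged.
#'
#' @param mesh a [surface_mesh()].
#' @param mean_wss n x 3 matrix of time-averaged WSS vectors.
#' @return list with n x 3 matrices `p`, `q` and logical `degenerate`.
#' @export
wss_tangent_frame <- function(mesh, mean_wss) {
  nrm <- vertex_normals(mesh)
  tangential <- mean_wss - rowSums(mean_wss * nrm) * nrm
  tn <- row_norms(tangential)
  scale <- pmax(row_norms(mean_wss), .Machine$double.eps)
  degen <- tn < 1e-8 * scale | tn == 0
  # fallback basis: normal crossed with the least-aligned axis
  axis_pick <- cbind(as.numeric(abs(nrm[, 1]) < 0.9), 0, 0)
  axis_pick[axis_pick[, 1] == 0, 2] <- 1
  fb <- normalize_rows(cross3(nrm, axis_pick))
  p <- normalize_rows(tangential)
  p[degen, ] <- fb[degen, , drop = FALSE]
  q <- normalize_rows(cross3(nrm, p))
  list(p = p, q = q, degenerate = degen)
}

#' Surface gradient components of a WSS snapshot
#'
#' The scalar fields `W_p = WSS . p` and `W_q = WSS . q` are differentiated
#' on the surface with per-face linear (P1) gradients averaged to vertices
#' with face-area weights; the returned per-vertex 2-vector is
#' `G = (dW_p/dp, dW_q/dq)` — the diagonal gradient components in the frame
#' aligned with the time-averaged WSS, as in the gradient-oscillatory-number
#' construction.
#'
#' @param mesh a [surface_mesh()].
#' @param wss_field n x 3 matrix, WSS vectors at one instant.
#' @param frame a frame from [wss_tangent_frame()].
#' @return n x 2 matrix of gradient components (Pa/mm).
#' @export
wss_surface_gradient <- function(mesh, wss_field, frame) {
  wp <- rowSums(wss_field * frame$p)
  wq <- rowSums(wss_field * frame$q)
  gp <- p1_vertex_gradient(mesh, wp)
  gq <- p1_vertex_gradient(mesh, wq)
  cbind(rowSums(gp * frame$p), rowSums(gq * frame$q))
}

# P1 (piecewise-linear) surface gradient of a per-vertex scalar field,
# averaged from faces to vertices with face-area weights.
p1_vertex_gradient <- function(mesh, f) {
  fc <- face_corner_coords(mesh)
  fidx <- mesh$faces
  n2 <- cross3(fc$b - fc$a, fc$c - fc$a)    # normal, |n2| = 2 * area
  a2 <- row_norms(n2)
  nh <- n2 / pmax(a2, .Machine$double.xmin)
  s <- f[fidx[, 1]] * (fc$c - fc$b) + f[fidx[, 2]] * (fc$a - fc$c) +
    f[fidx[, 3]] * (fc$b - fc$a)
  gf <- cross3(nh, s) / pmax(a2, .Machine$double.xmin)  # per-face gradient
  w <- a2 / 2                                           # face areas
  acc <- matrix(0, nrow(mesh$vertices), 3)
  wacc <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    for (d in 1:3) {
      sres <- rowsum(gf[, d] * w, fidx[, k])
      acc[as.integer(rownames(sres)), d] <-
        acc[as.integer(rownames(sres)), d] + sres[, 1]
    }
    sw <- rowsum(w, fidx[, k])
    wacc[as.integer(rownames(sw))] <- wacc[as.integer(rownames(sw))] + sw[, 1]
  }
  acc / pmax(wacc, .Machine$double.xmin)
}

#' Gradient oscillatory number
#'
#' \eqn{GON = 1 - |\int_0^T G\, dt| / \int_0^T |G|\, dt} with Euclidean
#' norms on the gradient 2-vector `G`; quantifies temporal oscillation of
#' the spatial WSS gradient. 0 where the magnitude integral vanishes.
#'
#' @param series a [wss_series()].
#' @param mesh the surface (defaults to the series' mesh).
#' @return per-vertex GON in `[0, 1]`.
#' @export
gon <- function(series, mesh = series$mesh) {
  w <- trapezoid_weights(series$times)
  mean_wss <- cycle_integral(series, "vector") / cycle_duration(series)
  frame <- wss_tangent_frame(mesh, mean_wss)
  nv <- n_vertices(mesh)
  acc_vec <- matrix(0, nv, 2)
  acc_mag <- numeric(nv)
  for (t in seq_along(series$times)) {
    G <- wss_surface_gradient(mesh, series$vectors[t, , ], frame)
    acc_vec <- acc_vec + w[t] * G
    acc_mag <- acc_mag + w[t] * sqrt(rowSums(G^2))
  }
  out <- ifelse(acc_mag == 0, 0, 1 - sqrt(rowSums(acc_vec^2)) / acc_mag)
  pmin(pmax(out, 0), 1)
}

#' All four hemodynamic maps of a series
#'
#' @param series a [wss_series()].
#' @param mesh the surface (defaults to the series' mesh).
#' @return list with per-vertex `TAWSS`, `OSI`, `GON`, `RRT` and a logical
#'   `degenerate` flag marking vertices where OSI/GON/RRT hit a
#'   division-by-zero sentinel.
#' @export
hemodynamic_maps <- function(series, mesh = series$mesh) {
  vi <- row_norms(cycle_integral(series, "vector"))
  mi <- cycle_integral(series, "magnitude")
  list(TAWSS = tawss(series), OSI = osi(series), GON = gon(series, mesh),
       RRT = rrt(series), degenerate = vi == 0 | mi == 0)
}

#' Normalize a TAWSS map by the parent-vessel level
#'
#' Divides every vertex's TAWSS by the area-weighted mean TAWSS of the
#' parent region, making magnitudes comparable across patients.
#'
#' @param tawss_map per-vertex TAWSS (Pa).
#' @param mesh the [surface_mesh()].
#' @param segment arc-length bounds `c(s_start, s_end)` (mm) of the aneurysm.
#' @param cl the [centerline()] used to assign vertices an arc length.
#' @param parent_region optional logical vertex mask overriding the default
#'   parent definition (the tube proximal to the segment; if that is empty,
#'   everything outside the segment).
#' @return per-vertex dimensionless TAWSS.
#' @export
normalize_tawss <- function(tawss_map, mesh, segment, cl = NULL,
                            parent_region = NULL) {
  if (is.null(parent_region)) {
    s <- vertex_arclength(mesh, cl)
    parent_region <- s < segment[1]
    if (!any(parent_region)) parent_region <- s < segment[1] | s > segment[2]
  }
  if (!any(parent_region)) stop("parent region is empty", call. = FALSE)
  va <- vertex_areas(mesh)
  ref <- sum(tawss_map[parent_region] * va[parent_region]) /
    sum(va[parent_region])
  if (ref == 0) stop("parent-region mean TAWSS is zero", call. = FALSE)
  tawss_map / ref
}

#' Regional max/mean summaries of hemodynamic maps
#'
#' @param maps named list of per-vertex maps (e.g. from
#'   [hemodynamic_maps()]; the `degenerate` entry is ignored).
#' @param mesh the [surface_mesh()].
#' @param mask logical vertex mask of the region.
#' @param area_weighted use vertex-area weights for the mean (default TRUE).
#' @return data.frame with one row per map: `index`, `max`, `mean`.
#' @export
regional_summary <- function(maps, mesh, mask, area_weighted = TRUE) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty region mask", call. = FALSE)
  va <- vertex_areas(mesh)[mask]
  nms <- setdiff(names(maps), "degenerate")
  do.call(rbind, lapply(nms, function(nm) {
    x <- maps[[nm]][mask]
    fin <- is.finite(x)
    mean_val <- if (area_weighted)
      sum(x[fin] * va[fin]) / sum(va[fin]) else mean(x[fin])
    data.frame(index = nm, max = max(x[fin]), mean = mean_val,
               stringsAsFactors = FALSE)
  }))
}
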