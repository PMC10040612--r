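#' Vessel centerline
#'
#' Ordered 3D polyline with a cumulative arc-length parameterization, an
#' optional index pair delimiting the aneurysmal portion, and named
#' per-point attributes (local radius, curvature, torsion, ...).
#'
#' @param points n x 3 matrix of ordered points (mm).
#' @param segment optional integer pair `(start, end)` of point indices
#'   bounding the aneurysm segment, with `start < end`.
#' @param per_point named list of length-n per-point attribute vectors.
#' @return an object of class `centerline`.
#' @export
centerline <- function(points, segment = NULL, per_point = list()) {
  points <- as_points3(points)
  n <- nrow(points)
  if (n < 2L) stop("centerline needs at least 2 points", call. = FALSE)
  seglen <- row_norms(diff(points))
  if (any(seglen == 0))
    stop("centerline has coincident consecutive points", call. = FALSE)
  arclength <- c(0, cumsum(seglen))
  if (!is.null(segment)) {
    segment <- as.integer(segment)
    if (length(segment) != 2L || segment[1] < 1L || segment[2] > n ||
        segment[1] >= segment[2])
      stop("segment must be an index pair (start, end) with start < end",
           call. = FALSE)
  }
  for (nm in names(per_point)) {
    if (length(per_point[[nm]]) != n)
      stop(sprintf("per_point array '%s' has wrong length", nm), call. = FALSE)
  }
  structure(list(points = points, arclength = arclength, segment = segment,
                 per_point = per_point),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, length %.2f mm", nrow(x$points),
              max(x$arclength)))
  if (!is.null(x$segment))
    cat(sprintf(", segment [%.2f, %.2f] mm", x$arclength[x$segment[1]],
                x$arclength[x$segment[2]]))
  cat("\n")
  invisible(x)
}

#' Total arc length of a centerline (mm)
#' @param cl a [centerline()].
#' @export
centerline_length <- function(cl) max(cl$arclength)

#' Generate a closed-form centerline
#'
#' Produces a straight line, a planar circular arc or a circular helix,
#' sampled uniformly in arc length, with the analytic curvature and torsion
#' attached as per-point ground truth (`kappa_true`, `tau_true`). For the
#' helix `(R cos t, R sin t, c t)` these are `kappa = R/(R^2+c^2)` and
#' `tau = c/(R^2+c^2)`.
#'
#' @param recipe a list with `type` one of `"straight"`, `"arc"`, `"helix"`;
#'   `length` total arc length (mm); for `"arc"` a radius `R` (or curvature
#'   `kappa0`); for `"helix"` radius `R` and pitch parameter `c`.
#' @param spacing arc-length sample spacing (mm).
#' @return a [centerline()] with ground-truth `kappa_true`/`tau_true`.
#' @export
make_centerline <- function(recipe, spacing = 0.25) {
  stopifnot_scalar(spacing, "spacing", positive = TRUE)
  L <- recipe$length
  if (is.null(L) || L <= 0) stop("recipe$length must be > 0", call. = FALSE)
  s <- seq(0, L, length.out = max(2L, round(L / spacing) + 1L))
  type <- match.arg(recipe$type, c("straight", "arc", "helix"))
  if (type == "straight") {
    pts <- cbind(s, 0, 0)
    kap <- rep(0, length(s)); tau <- rep(0, length(s))
  } else if (type == "arc") {
    R <- recipe$R %||% (1 / recipe$kappa0)
    stopifnot_scalar(R, "R", positive = TRUE)
    th <- s / R
    pts <- cbind(R * sin(th), R * (1 - cos(th)), 0)
    kap <- rep(1 / R, length(s)); tau <- rep(0, length(s))
  } else {
    R <- recipe$R; cc <- recipe$c
    stopifnot_scalar(R, "R", positive = TRUE)
    stopifnot_scalar(cc, "c")
    t <- s / sqrt(R^2 + cc^2)
    pts <- cbind(R * cos(t), R * sin(t), cc * t)
    kap <- rep(R / (R^2 + cc^2), length(s))
    tau <- rep(abs(cc) / (R^2 + cc^2), length(s))
  }
  centerline(pts, per_point = list(kappa_true = kap, tau_true = tau))
}

#' Resample a centerline to uniform arc-length spacing
#'
#' Linear interpolation of the coordinates against the original arc-length
#' parameter; both endpoints are preserved and the realized spacing is the
#' closest uniform divisor of the total length.
#'
#' @param cl a [centerline()].
#' @param spacing target spacing (mm); must be positive and shorter than the
#'   total length.
#' @return a resampled [centerline()] (per-point attributes are dropped; the
#'   segment bounds are remapped by arc length).
#' @export
resample_centerline <- function(cl, spacing) {
  stopifnot_scalar(spacing, "spacing", positive = TRUE)
  if (nrow(cl$points) < 4L)
    stop("resampling needs at least 4 input points", call. = FALSE)
  L <- centerline_length(cl)
  if (spacing >= L) stop("spacing must be shorter than the centerline",
                         call. = FALSE)
  n_seg <- max(1L, round(L / spacing))
  s_new <- seq(0, L, length.out = n_seg + 1L)
  pts <- vapply(1:3, function(d) stats::approx(cl$arclength, cl$points[, d],
                                               xout = s_new)$y,
                numeric(length(s_new)))
  out <- centerline(pts)
  if (!is.null(cl$segment)) {
    s_seg <- cl$arclength[cl$segment]
    out$segment <- c(which.min(abs(out$arclength - s_seg[1])),
                     which.min(abs(out$arclength - s_seg[2])))
  }
  out
}

#' Centerline curvature and torsion by smoothed finite differences
#'
#' At every point a local polynomial (Savitzky-Golay style least-squares fit
#' of degree 4 over a sliding window) is fitted to each coordinate as a
#' function of arc length; the fitted derivatives give
#' \deqn{\kappa = |r' \times r''| / |r'|^3, \qquad
#'       \tau = (r' \times r'') \cdot r''' / |r' \times r''|^2,}
#' with torsion reported as an absolute value. Both are set to 0 where
#' \eqn{|r' \times r''|} falls below `tol` (straight portions, where torsion
#' is undefined).
#'
#' @param cl a [centerline()], uniformly resampled, with >= 7 points.
#' @param smooth_window odd window width in points (default 7).
#' @param tol straightness cutoff on \eqn{|r' \times r''|} (default 1e-7).
#' @return list with numeric vectors `kappa` and `tau` (mm^-1).
#' @export
curvature_torsion <- function(cl, smooth_window = 7L, tol = 1e-7) {
  n <- nrow(cl$points)
  if (n < 7L) stop("curvature/torsion needs at least 7 points", call. = FALSE)
  if (any(diff(cl$arclength) <= 0))
    stop("arc length must be strictly increasing", call. = FALSE)
  w <- as.integer(smooth_window)
  if (w %% 2L == 0L) w <- w + 1L
  w <- max(7L, min(w, n))
  hw <- (w - 1L) %/% 2L
  deg <- 4L
  d1 <- matrix(NA_real_, n, 3)
  d2 <- matrix(NA_real_, n, 3)
  d3 <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - hw, n - w + 1L))
    idx <- lo:(lo + w - 1L)
    ds <- cl$arclength[idx] - cl$arclength[i]
    X <- outer(ds, 0:deg, `^`)
    coef <- qr.coef(qr(X), cl$points[idx, , drop = FALSE])
    d1[i, ] <- coef[2, ]
    d2[i, ] <- 2 * coef[3, ]
    d3[i, ] <- 6 * coef[4, ]
  }
  cr <- cross3(d1, d2)
  ncr <- row_norms(cr)
  nd1 <- row_norms(d1)
  kappa <- ifelse(ncr < tol, 0, ncr / nd1^3)
  tau <- ifelse(ncr < tol, 0, abs(rowSums(cr * d3)) / ncr^2)
  list(kappa = kappa, tau = tau)
}
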