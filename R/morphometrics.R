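#' Local luminal radius along the centerline
#'
#' At each centerline point the mesh is sliced by the plane normal to the
#' local tangent; intersection segments of the plane with mesh faces are
#' chained into connected cross-section curves and the curve nearest the
#' centerline point is kept. The local radius is the mean distance of that
#' curve's points to the centerline point. Empty slices (e.g. beyond an
#' open end) are interpolated from neighbours and flagged.
#'
#' @param mesh a [surface_mesh()].
#' @param cl a [centerline()] lying inside the mesh.
#' @return numeric vector of radii (mm) with attribute `interpolated`
#'   (logical) marking filled-in values, and attribute `sections` (list of
#'   k x 3 cross-section point matrices, for caliper measurements).
#' @export
local_radius <- function(mesh, cl) {
  n <- nrow(cl$points)
  tang <- rmf_frames(cl$points)$tangent
  out <- rep(NA_real_, n)
  sections <- vector("list", n)
  for (i in seq_len(n)) {
    sec <- cross_section(mesh, cl$points[i, ], tang[i, ])
    if (!is.null(sec)) {
      sections[[i]] <- sec
      out[i] <- mean(sqrt(colSums((t(sec) - cl$points[i, ])^2)))
    }
  }
  interp <- is.na(out)
  if (all(interp)) stop("no centerline point produced a cross-section",
                        call. = FALSE)
  if (any(interp)) {
    ok <- which(!interp)
    out[interp] <- stats::approx(cl$arclength[ok], out[ok],
                                 xout = cl$arclength[interp], rule = 2)$y
  }
  structure(out, interpolated = interp, sections = sections)
}

# Intersect the mesh with the plane through `origin` with normal `normal`;
# return the points of the connected section curve nearest `origin`.
cross_section <- function(mesh, origin, normal) {
  sd <- as.numeric(mesh$vertices %*% normal) - sum(origin * normal)
  # nudge exactly coplanar vertices so slices through mesh rings still cut
  scale <- max(abs(sd), 1)
  sd[abs(sd) < 1e-12 * scale] <- 1e-9 * scale
  f <- mesh$faces
  sd_f <- cbind(sd[f[, 1]], sd[f[, 2]], sd[f[, 3]])
  crossing <- which(apply(sd_f, 1, min) < 0 & apply(sd_f, 1, max) > 0)
  if (!length(crossing)) return(NULL)
  pts <- list(); edge_key <- list()
  for (fi in crossing) {
    vid <- f[fi, ]
    d <- sd[vid]
    seg_pts <- matrix(NA_real_, 0, 3); seg_keys <- character(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- d[e[1]]; d2 <- d[e[2]]
      if ((d1 < 0) == (d2 < 0)) next
      tfrac <- d1 / (d1 - d2)
      p <- mesh$vertices[vid[e[1]], ] +
        tfrac * (mesh$vertices[vid[e[2]], ] - mesh$vertices[vid[e[1]], ])
      seg_pts <- rbind(seg_pts, p)
      seg_keys <- c(seg_keys, paste(sort(vid[e]), collapse = "-"))
    }
    if (nrow(seg_pts) == 2) {
      pts[[length(pts) + 1L]] <- seg_pts
      edge_key[[length(edge_key) + 1L]] <- seg_keys
    }
  }
  if (!length(pts)) return(NULL)
  # union-find over shared cut edges chains segments into section curves
  keys <- unique(unlist(edge_key))
  parent <- seq_along(pts)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  key_owner <- list()
  for (si in seq_along(pts)) {
    for (k in edge_key[[si]]) {
      if (is.null(key_owner[[k]])) key_owner[[k]] <- si
      else {
        ra <- find(key_owner[[k]]); rb <- find(si)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  comp <- vapply(seq_along(pts), find, integer(1))
  best <- NULL; best_d <- Inf
  for (cid in unique(comp)) {
    cp <- do.call(rbind, pts[comp == cid])
    dmin <- min(sqrt(colSums((t(cp) - origin)^2)))
    if (dmin < best_d) { best_d <- dmin; best <- cp }
  }
  unique(best)
}

#' Delimit the aneurysmal segment from the radius profile
#'
#' Finds the maximal contiguous arc-length interval where the local radius
#' is at least `ratio_threshold` times the reference parent radius (the
#' median radius over the non-dilated portion of the profile, taken as its
#' lowest quartile). User-supplied bounds short-circuit the detection.
#'
#' @param mesh a [surface_mesh()].
#' @param cl a [centerline()].
#' @param ratio_threshold dilation threshold relative to the parent radius
#'   (default 1.5, the usual clinical definition of fusiform dilation).
#' @param bounds optional `c(s_start, s_end)` returned verbatim.
#' @param radius_profile optional precomputed [local_radius()] result.
#' @return numeric `c(s_start, s_end)` (mm arc length), with the parent
#'   reference radius as attribute `r_parent`.
#' @export
segment_aneurysm <- function(mesh, cl, ratio_threshold = 1.5, bounds = NULL,
                             radius_profile = NULL) {
  if (!is.null(bounds)) return(as.numeric(bounds))
  r <- radius_profile %||% local_radius(mesh, cl)
  r_parent <- stats::median(r[r <= stats::quantile(r, 0.25)])
  dilated <- r >= ratio_threshold * r_parent
  if (!any(dilated)) stop("no aneurysmal dilation detected", call. = FALSE)
  runs <- rle(dilated)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  true_runs <- which(runs$values)
  longest <- true_runs[which.max(runs$lengths[true_runs])]
  structure(c(cl$arclength[starts[longest]], cl$arclength[ends[longest]]),
            r_parent = r_parent)
}

#' Maximal cross-sectional diameter of the aneurysm segment
#'
#' D_max is the maximum over the segment's cross-sections of the section's
#' caliper diameter (maximum pairwise distance among section points); for a
#' circular section this equals twice the maximal centerline-to-surface
#' distance. `as_radius = TRUE` instead returns the maximal
#' centerline-to-surface distance itself.
#'
#' @param mesh a [surface_mesh()].
#' @param cl a [centerline()].
#' @param segment `c(s_start, s_end)` arc-length bounds (mm).
#' @param as_radius return the radius-like maximal distance instead of the
#'   caliper diameter.
#' @param radius_profile optional precomputed [local_radius()] result
#'   (avoids re-slicing the mesh).
#' @return D_max (mm).
#' @export
d_max <- function(mesh, cl, segment, as_radius = FALSE,
                  radius_profile = NULL) {
  idx <- which(cl$arclength >= segment[1] & cl$arclength <= segment[2])
  if (!length(idx)) stop("empty aneurysm segment", call. = FALSE)
  rp <- radius_profile %||% local_radius(mesh, cl)
  sections <- attr(rp, "sections")
  best <- 0
  for (i in idx) {
    sec <- sections[[i]]
    if (is.null(sec)) next
    if (as_radius) {
      best <- max(best, max(sqrt(colSums((t(sec) - cl$points[i, ])^2))))
    } else {
      d2 <- outer(rowSums(sec^2), rowSums(sec^2), `+`) - 2 * sec %*% t(sec)
      best <- max(best, sqrt(max(d2)))
    }
  }
  if (best == 0) stop("no cross-sections inside the segment", call. = FALSE)
  best
}

#' Centerline length of the aneurysm segment
#' @param cl a [centerline()] (unused beyond validation; kept for a uniform
#'   signature).
#' @param segment `c(s_start, s_end)` arc-length bounds (mm).
#' @return L_max (mm), `s_end - s_start`.
#' @export
l_max <- function(cl, segment) {
  as.numeric(segment[2] - segment[1])
}

#' Full morphometric record of one case
#'
#' Resamples the centerline, computes curvature/torsion, delimits the
#' aneurysm segment from the radius profile (unless bounds are supplied)
#' and summarizes: D_max, L_max, max/mean curvature and max/mean torsion
#' over the segment.
#'
#' @param mesh a [surface_mesh()].
#' @param cl a [centerline()].
#' @param spacing resampling spacing (mm), default 0.5.
#' @param ratio_threshold see [segment_aneurysm()].
#' @param bounds optional fixed segment bounds `c(s_start, s_end)`.
#' @return one-row data.frame: `d_max`, `l_max`, `kappa_max`, `kappa_mean`,
#'   `tau_max`, `tau_mean`, `s_start`, `s_end`.
#' @export
morphometrics <- function(mesh, cl, spacing = 0.5, ratio_threshold = 1.5,
                          bounds = NULL) {
  clr <- resample_centerline(cl, spacing)
  ct <- curvature_torsion(clr)
  rp <- local_radius(mesh, clr)
  seg <- segment_aneurysm(mesh, clr, ratio_threshold, bounds,
                          radius_profile = rp)
  in_seg <- clr$arclength >= seg[1] & clr$arclength <= seg[2]
  data.frame(d_max = d_max(mesh, clr, seg, radius_profile = rp),
             l_max = l_max(clr, seg),
             kappa_max = max(ct$kappa[in_seg]),
             kappa_mean = mean(ct$kappa[in_seg]),
             tau_max = max(ct$tau[in_seg]),
             tau_mean = mean(ct$tau[in_seg]),
             s_start = seg[1], s_end = seg[2])
}
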