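#' Maximum pituitary-stalk signal intensity
#'
#' Reference intensity used for the enhancement threshold and for the
#' enhancement-ratio normalization.
#'
#' @param vol an [intensity_volume()] with a nonempty `stalk_mask`.
#' @return the maximum voxel intensity within the stalk ROI.
#' @export
stalk_reference <- function(vol) {
  if (!any(vol$stalk_mask)) stop("stalk mask is empty", call. = FALSE)
  max(vol$voxels[vol$stalk_mask])
}

#' Threshold-based segmentation of wall enhancement
#'
#' Selects voxels whose intensity reaches `threshold_factor` times the
#' maximum stalk signal, restricted to the vessel wall: outside the lumen
#' mask, within `wall_band_mm` of the luminal surface (distance to the
#' nearest mesh vertex), and not part of the stalk ROI.
#'
#' @param vol an [intensity_volume()] with a lumen mask.
#' @param mesh the luminal [surface_mesh()] in the volume's world frame.
#' @param stalk_max reference intensity, default [stalk_reference()].
#' @param threshold_factor enhancement threshold relative to the stalk
#'   maximum (default 0.6).
#' @param wall_band_mm admissible distance from the luminal surface
#'   (default 1.5 mm, about two voxel diagonals at 0.7 mm).
#' @return logical voxel array (the AWE mask).
#' @export
segment_awe <- function(vol, mesh, stalk_max = stalk_reference(vol),
                        threshold_factor = 0.6, wall_band_mm = 1.5) {
  if (threshold_factor < 0) stop("threshold_factor must be >= 0", call. = FALSE)
  bright <- vol$voxels >= threshold_factor * stalk_max &
    !vol$lumen_mask & !vol$stalk_mask
  out <- array(FALSE, dim(vol$voxels))
  cand <- which(bright)
  if (!length(cand)) return(out)
  ctr <- voxel_centers(vol, bright)
  nn <- nearest_points(ctr, mesh$vertices, radius = wall_band_mm)
  out[cand[!is.na(nn$index)]] <- TRUE
  out
}

#' Project the enhancement segmentation onto the surface
#'
#' A vertex is enhanced when at least one AWE-mask voxel centre lies within
#' `search_radius_mm` of it; it is assigned the intensity of the nearest
#' such voxel. Non-enhanced vertices get intensity 0, so downstream
#' node-wise correlations operate on every vertex.
#'
#' @param vol an [intensity_volume()].
#' @param awe_mask logical voxel array from [segment_awe()].
#' @param mesh the luminal [surface_mesh()].
#' @param search_radius_mm projection radius (default 1.5 mm).
#' @return list with per-vertex numeric `intensity` and logical `enhanced`.
#' @export
project_to_surface <- function(vol, awe_mask, mesh, search_radius_mm = 1.5) {
  nv <- n_vertices(mesh)
  if (!any(awe_mask) || search_radius_mm <= 0)
    return(list(intensity = numeric(nv), enhanced = rep(FALSE, nv)))
  ctr <- voxel_centers(vol, awe_mask)
  # mesh entirely outside the voxel lattice is a frame mismatch
  lo <- apply(voxel_centers(vol, NULL), 2, range)
  if (all(mesh$vertices[, 1] < lo[1, 1] | mesh$vertices[, 1] > lo[2, 1]))
    stop("mesh lies entirely outside the volume; check registration",
         call. = FALSE)
  nn <- nearest_points(mesh$vertices, ctr, radius = search_radius_mm)
  enhanced <- !is.na(nn$index)
  vals <- vol$voxels[awe_mask]
  intensity <- numeric(nv)
  intensity[enhanced] <- vals[nn$index[enhanced]]
  list(intensity = intensity, enhanced = enhanced)
}

#' Enhancement-ratio map
#'
#' Per-vertex wall signal normalized by the maximum pituitary-stalk signal.
#'
#' @param intensity per-vertex intensity (0 where not enhanced).
#' @param stalk_max positive reference intensity.
#' @return per-vertex ER.
#' @export
er_map <- function(intensity, stalk_max) {
  if (!is.numeric(stalk_max) || stalk_max <= 0)
    stop("stalk_max must be > 0", call. = FALSE)
  intensity / stalk_max
}

#' Enhancement area, proportion and maximal contrast ratio
#'
#' Area bookkeeping uses the shared barycentric vertex areas, so enhanced
#' and non-enhanced areas always partition the segment area exactly.
#'
#' @param mesh the [surface_mesh()].
#' @param enhanced logical per-vertex flags.
#' @param er per-vertex enhancement ratio.
#' @param segment_mask logical per-vertex mask of the aneurysm segment.
#' @return list with `enhancement_area` (mm^2), `nonenhanced_area` (mm^2),
#'   `segment_area` (mm^2), `proportion_enhanced` and `cr_max`.
#' @export
enhancement_metrics <- function(mesh, enhanced, er, segment_mask) {
  segment_mask <- as.logical(segment_mask)
  if (!any(segment_mask)) stop("empty aneurysm segment", call. = FALSE)
  va <- vertex_areas(mesh)
  area_seg <- sum(va[segment_mask])
  area_enh <- sum(va[segment_mask & enhanced])
  list(enhancement_area = area_enh,
       nonenhanced_area = area_seg - area_enh,
       segment_area = area_seg,
       proportion_enhanced = area_enh / area_seg,
       cr_max = if (any(segment_mask)) max(er[segment_mask]) else 0)
}

#' Full enhancement analysis of one case
#'
#' Chains [stalk_reference()], [segment_awe()], [project_to_surface()],
#' [er_map()] and [enhancement_metrics()] over the aneurysm segment.
#'
#' @param vol an [intensity_volume()].
#' @param mesh the luminal [surface_mesh()].
#' @param cl the [centerline()].
#' @param segment arc-length bounds `c(s_start, s_end)` (mm).
#' @param threshold_factor,wall_band_mm,search_radius_mm see the stage
#'   functions.
#' @return list with `er`, `enhanced`, `intensity`, `stalk_max`,
#'   `threshold`, `awe_mask` and the metrics of [enhancement_metrics()].
#' @export
enhancement_map <- function(vol, mesh, cl, segment, threshold_factor = 0.6,
                            wall_band_mm = 1.5, search_radius_mm = 1.5) {
  stalk_max <- stalk_reference(vol)
  awe <- segment_awe(vol, mesh, stalk_max, threshold_factor, wall_band_mm)
  proj <- project_to_surface(vol, awe, mesh, search_radius_mm)
  er <- er_map(proj$intensity, stalk_max)
  s <- vertex_arclength(mesh, cl)
  seg_mask <- s >= segment[1] & s <= segment[2]
  metrics <- enhancement_metrics(mesh, proj$enhanced, er, seg_mask)
  c(list(er = er, enhanced = proj$enhanced, intensity = proj$intensity,
         stalk_max = stalk_max, threshold = threshold_factor * stalk_max,
         awe_mask = awe, segment_mask = seg_mask), metrics)
}
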