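#' Draw per-type shape parameters for a synthetic case
#'
#' Type recipes follow the Flemming classification: fusiform cases are a
#' focal Gaussian bulge on a parent tube; dolichoectatic cases a longer,
#' uniformly dilated extent; transitional cases the longest, a uniform
#' dilation with a superimposed focal bulge. Defaults are scaled so the
#' cohort reproduces the clinical size ordering (transitional largest
#' D_max and L_max, fusiform smallest); multiplicative lognormal jitter
#' (sd 0.08) individualizes cases.
#'
#' @param ifa_type `"fusiform"`, `"dolichoectatic"` or `"transitional"`.
#' @param seed integer seed for the parameter jitter.
#' @return list with `shape` (a [shape_params()]), `total_length` (mm) and
#'   the centerline `recipe`.
#' @export
draw_case_params <- function(ifa_type, seed) {
  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  jit <- function(x) x * exp(stats::rnorm(1, sd = 0.08))
  base <- switch(ifa_type,
    fusiform = list(L = 38, r0 = 1.7, g = 1, A = 1.55, sigma = 4.5,
                    half_ext = NA),
    dolichoectatic = list(L = 45, r0 = 1.9, g = 2.6, A = 0, sigma = 4.5,
                          half_ext = 9),
    transitional = list(L = 52, r0 = 1.9, g = 2.2, A = 1.35, sigma = 4.5,
                        half_ext = 12),
    stop("unknown ifa_type: ", ifa_type, call. = FALSE))
  L <- jit(base$L)
  r0 <- jit(base$r0)
  A <- if (base$A > 0) jit(base$A) else 0
  g <- if (base$g > 1) 1 + jit(base$g - 1) else 1
  sigma <- jit(base$sigma)
  half_ext <- if (is.na(base$half_ext)) NA else jit(base$half_ext)
  R_helix <- stats::runif(1, 9, 14)
  c_helix <- stats::runif(1, 2.5, 4.5)
  .Random.seed_restore(old)
  shape <- shape_params(ifa_type, r0 = r0, g = g, A = A, s0 = L / 2,
                        sigma = sigma,
                        ext_lo = if (is.na(half_ext)) NA else L / 2 - half_ext,
                        ext_hi = if (is.na(half_ext)) NA else L / 2 + half_ext,
                        ramp = 5)
  list(shape = shape, total_length = L,
       recipe = list(type = "helix", R = R_helix, c = c_helix, length = L))
}

#' Generate a seeded synthetic cohort of fusiform aneurysms
#'
#' For each case: a helical centerline, a swept luminal surface with
#' ground-truth radius, a pulsatile WSS series, the relative residence time
#' derived from it, and (optionally) a surrogate post-contrast volume whose
#' wall intensity is rank-coupled to RRT. The default design is seven cases
#' of each of the three types. The cohort is bit-reproducible for a given
#' seed.
#'
#' @param n_per_type cases per type (>= 1), default 7.
#' @param seed integer master seed; case seeds are derived from it.
#' @param flow a [flow_params()].
#' @param coupling a [coupling_params()].
#' @param ring_spacing centerline/ring spacing of the swept mesh (mm).
#' @param angular_res vertices per ring.
#' @param voxel_spacing voxel size of the surrogate volume (mm).
#' @param with_volume generate the surrogate volume (default TRUE).
#' @return list of cases; each case is a list with `case_id`, `ifa_type`,
#'   `seed`, `shape`, `centerline`, `mesh`, `wss`, `rrt_truth` and `volume`.
#' @export
make_cohort <- function(n_per_type = 7L, seed = 1L,
                        flow = flow_params(), coupling = coupling_params(),
                        ring_spacing = 0.7, angular_res = 48L,
                        voxel_spacing = 0.7, with_volume = TRUE) {
  n_per_type <- as.integer(n_per_type)
  if (n_per_type < 1L) stop("n_per_type must be >= 1", call. = FALSE)
  types <- c("fusiform", "dolichoectatic", "transitional")
  cases <- list()
  k <- 0L
  for (ty in types) {
    for (i in seq_len(n_per_type)) {
      k <- k + 1L
      case_seed <- as.integer(seed) * 1000L + k
      par <- draw_case_params(ty, case_seed)
      cl <- make_centerline(par$recipe, spacing = ring_spacing)
      mesh <- make_fusiform_surface(cl, par$shape, angular_res = angular_res)
      wss <- make_wss_series(mesh, cl, flow, seed = case_seed + 500000L)
      rrt_truth <- rrt(wss)
      vol <- if (with_volume)
        make_enhancement_volume(mesh, rrt_truth, coupling,
                                voxel_spacing = voxel_spacing,
                                seed = case_seed + 900000L) else NULL
      cases[[k]] <- list(case_id = sprintf("case%02d", k), ifa_type = ty,
                         seed = case_seed, shape = par$shape,
                         centerline = cl, mesh = mesh, wss = wss,
                         rrt_truth = rrt_truth, volume = vol)
    }
  }
  cases
}

#' Cohort manifest table
#' @param cohort a list from [make_cohort()].
#' @return data.frame with case id, type, seed and ground-truth size.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(cs) {
    r <- cs$mesh$point_data$radius_true
    data.frame(case_id = cs$case_id, ifa_type = cs$ifa_type, seed = cs$seed,
               n_vertices = n_vertices(cs$mesh),
               d_max_true = 2 * max(r),
               stringsAsFactors = FALSE)
  }))
}
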