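#' Pulsatile flow parameters for the wall-shear surrogate
#'
#' The surrogate drives a Poiseuille-type axial wall shear
#' \eqn{\tau(s,t) = 4 \mu Q(t) / (\pi r(s)^3)} with a carotid-like
#' two-peak flow waveform, plus a sign-alternating transverse component
#' confined to the dilation, mimicking the disturbed, oscillatory near-wall
#' flow CFD predicts inside fusiform dilations. Density and viscosity are
#' the usual blood values and are used only to report a nominal peak
#' Reynolds number `Re = 2 rho Q_peak / (pi mu r0)`.
#'
#' @param T_cycle cardiac-cycle duration (s), default 0.8.
#' @param n_t samples per cycle (>= 8), default 100 (step 0.008 s).
#' @param q_peak peak volumetric flow (m^3/s); the default 4.95e-6 puts the
#'   nominal peak Reynolds number near 600 for a 1.6 mm parent radius.
#' @param rho blood density (kg/m^3), default 1066.
#' @param mu dynamic viscosity (Pa s), default 0.0035.
#' @param beta_osc oscillatory transverse fraction in `[0, 1]`, default 0.5.
#' @param noise_sd additive WSS noise (Pa), default 0.02.
#' @param waveform function of phase `u` in `[0, 1]` returning the flow
#'   fraction of `q_peak` (max 1); default [carotid_waveform()].
#' @return an object of class `flow_params`.
#' @export
flow_params <- function(T_cycle = 0.8, n_t = 100L, q_peak = 4.95e-6,
                        rho = 1066, mu = 0.0035, beta_osc = 0.5,
                        noise_sd = 0.02, waveform = carotid_waveform) {
  stopifnot_scalar(T_cycle, "T_cycle", positive = TRUE)
  n_t <- as.integer(n_t)
  if (n_t < 8L) stop("n_t must be >= 8 samples per cycle", call. = FALSE)
  if (beta_osc < 0 || beta_osc > 1)
    stop("beta_osc must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(T_cycle = T_cycle, n_t = n_t, q_peak = q_peak, rho = rho,
                 mu = mu, beta_osc = beta_osc, noise_sd = noise_sd,
                 waveform = waveform),
            class = "flow_params")
}

#' Two-peak carotid-like flow waveform
#'
#' Systolic peak near 15% of the cycle and a broad diastolic secondary peak,
#' normalized to a maximum of 1 and everywhere positive.
#'
#' @param u cycle phase in `[0, 1]`.
#' @return flow fraction of the peak value.
#' @export
carotid_waveform <- function(u) {
  raw <- 0.25 + 0.75 * exp(-((u - 0.15) / 0.08)^2) +
    0.20 * exp(-((u - 0.50) / 0.18)^2)
  raw / 1.004581  # template maximum, so max(q) = 1
}

#' Synthesize a pulsatile WSS series on a swept surface
#'
#' Axial wall shear follows the Poiseuille law \eqn{4\mu Q(t)/(\pi r(s)^3)}
#' along the local tangent; inside the dilation a transverse component
#' `beta_osc * 0.12 * tau_parent_peak * bulge_weight(s) *
#' (0.6 + 0.4 cos(2 theta)) * sin(2 pi t / T)` oscillates along the
#' circumferential direction. The sign-alternating time course makes OSI
#' high inside the bulge while the axial r^-3 law keeps its TAWSS below the
#' parent level, and the circumferential modulation gives the transverse
#' field a spatial gradient whose direction oscillates, so GON is also
#' elevated in the dilation — the disturbed-flow signature CFD predicts
#' there. Optional isotropic Gaussian vector noise is added per vertex and
#' sample.
#'
#' @param mesh a surface from [make_fusiform_surface()] (carries the
#'   ground-truth radius and local frame).
#' @param cl the [centerline()] the surface was swept along.
#' @param flow a [flow_params()].
#' @param seed integer seed for the noise (ignored when `noise_sd = 0`).
#' @return a [wss_series()]; `meta$re_peak` holds the nominal peak Reynolds
#'   number of the parent vessel.
#' @export
make_wss_series <- function(mesh, cl, flow = flow_params(), seed = 1L) {
  pd <- mesh$point_data
  if (is.null(pd$radius_true) || is.null(pd$axis) || is.null(pd$circ))
    stop("mesh must carry generator ground truth (radius_true/axis/circ)",
         call. = FALSE)
  shape <- attr(mesh, "shape")
  r0 <- shape$r0
  nv <- n_vertices(mesh)
  times <- seq(0, flow$T_cycle, length.out = flow$n_t)
  q <- flow$waveform(times / flow$T_cycle)
  r_m <- pd$radius_true * 1e-3
  tau_ax <- outer(q * flow$q_peak, 4 * flow$mu / (pi * r_m^3))  # n_t x nv, Pa
  tau_parent_peak <- 4 * flow$mu * flow$q_peak / (pi * (r0 * 1e-3)^3)
  rr <- pd$radius_true / r0
  bw <- if (max(rr) > 1 + 1e-9) pmax(0, (rr - 1) / (max(rr) - 1)) else
    numeric(nv)
  circ_mod <- 0.6 + 0.4 * cos(2 * pd$theta)
  tau_tr <- outer(sin(2 * pi * times / flow$T_cycle),
                  flow$beta_osc * 0.12 * tau_parent_peak * bw * circ_mod)
  vec <- array(0, c(flow$n_t, nv, 3))
  for (d in 1:3) {
    vec[, , d] <- tau_ax * matrix(pd$axis[, d], flow$n_t, nv, byrow = TRUE) +
      tau_tr * matrix(pd$circ[, d], flow$n_t, nv, byrow = TRUE)
  }
  if (flow$noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(as.integer(seed))
    vec <- vec + array(stats::rnorm(length(vec), sd = flow$noise_sd), dim(vec))
    .Random.seed_restore(old)
  }
  re_peak <- 2 * flow$rho * flow$q_peak / (pi * flow$mu * (r0 * 1e-3))
  wss_series(times, vec, mesh,
             meta = list(re_peak = re_peak, q_peak = flow$q_peak,
                         beta_osc = flow$beta_osc))
}

# save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
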