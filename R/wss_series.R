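#' Per-vertex wall-shear-stress vector time series
#'
#' Instantaneous WSS vectors (Pa) sampled at instants spanning one cardiac
#' cycle, on the vertices of a [surface_mesh()]. The cycle duration `T` is
#' the span `max(times) - min(times)`.
#'
#' @param times strictly increasing sample instants (s).
#' @param vectors numeric array of shape `(n_times, n_vertices, 3)` (Pa).
#' @param mesh the [surface_mesh()] the samples live on.
#' @param meta optional named list of provenance (waveform, Reynolds number...).
#' @return an object of class `wss_series`.
#' @export
wss_series <- function(times, vectors, mesh, meta = list()) {
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be >= 2 strictly increasing instants", call. = FALSE)
  vectors <- as.array(vectors)
  dm <- dim(vectors)
  if (length(dm) != 3L || dm[1] != length(times) || dm[3] != 3L)
    stop("vectors must have shape (n_times, n_vertices, 3)", call. = FALSE)
  if (dm[2] != nrow(mesh$vertices))
    stop("vectors second dimension must equal the mesh vertex count",
         call. = FALSE)
  structure(list(times = times, vectors = vectors, mesh = mesh, meta = meta),
            class = "wss_series")
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf("wss_series: %d samples over T = %.3f s on %d vertices\n",
              length(x$times), cycle_duration(x), dim(x$vectors)[2]))
  invisible(x)
}

#' Cardiac-cycle duration of a series (s)
#' @param series a [wss_series()].
#' @export
cycle_duration <- function(series) {
  max(series$times) - min(series$times)
}
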