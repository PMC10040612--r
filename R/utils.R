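`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row-wise cross product of two n x 3 matrices
#' @noRd
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Row-wise Euclidean norms of an n x 3 (or n x k) matrix
#' @noRd
row_norms <- function(m) sqrt(rowSums(m * m))

#' Normalize rows to unit length; zero rows stay zero
#' @noRd
normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Nearest-neighbor search from query points to reference points
#'
#' Grid-binned nearest neighbor: reference points are hashed into cubic cells
#' of side `cell`, each query scans its own and adjacent cells, widening the
#' shell until a neighbor is found (or `radius` is exhausted when given).
#'
#' @param query n x 3 matrix of query points.
#' @param ref m x 3 matrix of reference points.
#' @param radius optional search cap (same units as coordinates). Queries with
#'   no reference point within `radius` get index `NA` and distance `Inf`.
#' @param cell bin size; defaults to `radius` or a size scaled to the
#'   reference cloud.
#' @return list with integer `index` (into rows of `ref`) and `dist`.
#' @keywords internal
nearest_points <- function(query, ref, radius = NULL, cell = NULL) {
  query <- as_points3(query)
  ref <- as_points3(ref)
  m <- nrow(ref)
  if (m == 0L) stop("no reference points", call. = FALSE)
  if (is.null(cell)) {
    if (!is.null(radius) && radius > 0) {
      cell <- radius
    } else {
      span <- max(apply(ref, 2, function(v) diff(range(v))), 1e-9)
      cell <- span / max(1, ceiling(m^(1 / 3)))
    }
  }
  org <- apply(rbind(query, ref), 2, min) - cell
  key <- function(p) {
    ij <- floor(sweep(p, 2, org) / cell)
    ij[, 1] * 73856093 + ij[, 2] * 19349663 + ij[, 3] * 83492791
  }
  ij_ref <- floor(sweep(ref, 2, org) / cell)
  hash_ref <- ij_ref[, 1] * 73856093 + ij_ref[, 2] * 19349663 + ij_ref[, 3] * 83492791
  buckets <- split(seq_len(m), hash_ref)
  ij_q <- floor(sweep(query, 2, org) / cell)
  n <- nrow(query)
  idx <- rep(NA_integer_, n)
  dst <- rep(Inf, n)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  max_shell <- if (is.null(radius)) {
    span <- max(apply(rbind(query, ref), 2, function(v) diff(range(v))), cell)
    as.integer(ceiling(span / cell)) + 1L
  } else 1L
  for (q in seq_len(n)) {
    shell <- 1L
    repeat {
      if (shell == 1L) {
        cand_ij <- sweep(offsets, 2, as.numeric(ij_q[q, ]), `+`)
      } else {
        # hollow shell at Chebyshev distance `shell`
        rng <- -shell:shell
        grid <- as.matrix(expand.grid(rng, rng, rng))
        grid <- grid[apply(abs(grid), 1, max) == shell, , drop = FALSE]
        cand_ij <- sweep(grid, 2, as.numeric(ij_q[q, ]), `+`)
      }
      keys <- as.character(cand_ij[, 1] * 73856093 + cand_ij[, 2] * 19349663 +
                             cand_ij[, 3] * 83492791)
      cand <- unlist(buckets[keys], use.names = FALSE)
      if (length(cand)) {
        d2 <- (ref[cand, 1] - query[q, 1])^2 + (ref[cand, 2] - query[q, 2])^2 +
          (ref[cand, 3] - query[q, 3])^2
        j <- which.min(d2)
        if (sqrt(d2[j]) < dst[q]) {
          dst[q] <- sqrt(d2[j])
          idx[q] <- cand[j]
        }
      }
      # a hit in shell k guarantees the true NN lies within shell k+1
      if (!is.na(idx[q]) && dst[q] <= (shell - 1) * cell) break
      if (!is.null(radius) && (shell * cell) > radius) break
      if (shell > max_shell && !is.na(idx[q])) break
      if (shell > max_shell + 2L) break
      shell <- shell + 1L
    }
  }
  if (!is.null(radius)) {
    miss <- dst > radius
    idx[miss] <- NA_integer_
    dst[miss] <- Inf
  } else if (anyNA(idx)) {
    # sparse stragglers: exact scan
    for (q in which(is.na(idx))) {
      d2 <- (ref[, 1] - query[q, 1])^2 + (ref[, 2] - query[q, 2])^2 +
        (ref[, 3] - query[q, 3])^2
      idx[q] <- which.min(d2)
      dst[q] <- sqrt(d2[idx[q]])
    }
  }
  list(index = idx, dist = dst)
}

as_points3 <- function(p) {
  p <- as.matrix(p)
  if (is.null(dim(p)) || ncol(p) != 3L) {
    if (length(p) == 3L) p <- matrix(as.numeric(p), 1L, 3L)
    else stop("expected an n x 3 coordinate matrix", call. = FALSE)
  }
  storage.mode(p) <- "double"
  dimnames(p) <- NULL
  p
}
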