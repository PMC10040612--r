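# 16^3 fixture: cylinder of radius 3 along x (axis y = z = 8), 1 mm voxels,
# world coordinates equal to 0-based voxel indices.
awe_fixture <- function() {
  dm <- c(16L, 16L, 16L)
  vox <- array(0, dm)
  aff <- diag(4)
  lin <- function(i, j, k) cbind(i, j, k) + 1L
  lumen <- array(FALSE, dm)
  idx <- as.matrix(expand.grid(0:15, 0:15, 0:15))
  dist_axis <- sqrt((idx[, 2] - 8)^2 + (idx[, 3] - 8)^2)
  in_x <- idx[, 1] >= 2 & idx[, 1] <= 14
  lumen[idx[dist_axis < 3 & in_x, , drop = FALSE] + 1L] <- TRUE
  stalk <- array(FALSE, dm)
  stalk[16, 16, 16] <- TRUE
  vox[16, 16, 16] <- 1000
  # 6 bright voxels on the wall (distance 3 from the axis)
  wall6 <- rbind(c(5, 11, 8), c(6, 11, 8), c(7, 11, 8),
                 c(8, 5, 8), c(9, 8, 11), c(10, 8, 5))
  vox[wall6 + 1L] <- 700
  # 3 bright voxels inside the lumen
  lum3 <- rbind(c(6, 8, 8), c(7, 9, 8), c(8, 8, 9))
  vox[lum3 + 1L] <- 700
  # 1 bright voxel beyond the wall band
  far1 <- rbind(c(12, 13, 12))
  vox[far1 + 1L] <- 700
  cl <- make_centerline(list(type = "straight", length = 12), spacing = 0.25)
  cl$points[, 1] <- cl$points[, 1] + 2
  cl$points[, 2] <- 8; cl$points[, 3] <- 8
  cl <- centerline(cl$points)
  mesh <- make_fusiform_surface(cl, shape_params("fusiform", r0 = 3),
                                angular_res = 64)
  list(vol = intensity_volume(vox, aff, stalk_mask = stalk,
                              lumen_mask = lumen),
       mesh = mesh, wall6 = wall6, cl = cl)
}

# brute-force re-implementation of the AWE selection rule
awe_oracle <- function(vol, mesh, thr, band) {
  dm <- dim(vol$voxels)
  out <- array(FALSE, dm)
  idx <- as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]),
                               seq_len(dm[3])))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    if (vol$voxels[i, j, k] < thr) next
    if (vol$lumen_mask[i, j, k] || vol$stalk_mask[i, j, k]) next
    w <- vol$affine %*% c(i - 1, j - 1, k - 1, 1)
    d <- sqrt((mesh$vertices[, 1] - w[1])^2 + (mesh$vertices[, 2] - w[2])^2 +
                (mesh$vertices[, 3] - w[3])^2)
    if (min(d) <= band) out[i, j, k] <- TRUE
  }
  out
}
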