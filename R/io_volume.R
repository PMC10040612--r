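#' Post-contrast intensity volume with ROI masks
#'
#' Voxel grid of post-contrast signal intensity (arbitrary units) with a
#' 4x4 voxel-to-world affine (mm), plus the two boolean ROI grids the
#' enhancement analysis needs: the pituitary-stalk reference region and the
#' vessel lumen. Voxel indexing is 0-based and a voxel's world position is
#' the affine applied to its integer index (voxel centre).
#'
#' @param voxels 3D numeric array of signal intensities.
#' @param affine invertible 4x4 voxel-to-world transform (mm).
#' @param stalk_mask,lumen_mask logical arrays with the grid shape of
#'   `voxels` (default all-FALSE).
#' @return an object of class `intensity_volume`.
#' @export
intensity_volume <- function(voxels, affine,
                             stalk_mask = NULL, lumen_mask = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  dm <- dim(voxels)
  blank <- array(FALSE, dm)
  for (nm in c("stalk_mask", "lumen_mask")) {
    m <- get(nm)
    if (is.null(m)) next
    if (!identical(dim(m), dm))
      stop(nm, " shape does not match the voxel grid", call. = FALSE)
  }
  structure(list(voxels = voxels, affine = affine,
                 stalk_mask = if (is.null(stalk_mask)) blank else (stalk_mask > 0),
                 lumen_mask = if (is.null(lumen_mask)) blank else (lumen_mask > 0)),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("intensity_volume: %s voxels, %d stalk / %d lumen\n",
              paste(dim(x$voxels), collapse = " x "),
              sum(x$stalk_mask), sum(x$lumen_mask)))
  invisible(x)
}

#' Voxel edge lengths implied by the affine (mm)
#' @param vol an [intensity_volume()].
#' @export
voxel_spacing <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' World coordinates of voxel centres
#'
#' @param vol an [intensity_volume()].
#' @param which logical array selecting voxels (default: all).
#' @return k x 3 matrix of world coordinates (mm), in the array-linear order
#'   of the selected voxels.
#' @export
voxel_centers <- function(vol, which = NULL) {
  dm <- dim(vol$voxels)
  lin <- if (is.null(which)) seq_len(prod(dm)) else base::which(which)
  ijk <- arrayInd(lin, dm) - 1L   # 0-based indices
  h <- cbind(ijk, 1)
  w <- h %*% t(vol$affine)
  w[, 1:3, drop = FALSE]
}

#' Read / write an intensity volume as NIfTI-1
#'
#' The signal volume is stored at `path`; the stalk and lumen masks are
#' stored as companion files `<stem>_stalk.nii.gz` and `<stem>_lumen.nii.gz`
#' sharing the affine. Missing companions yield all-FALSE masks.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return [read_volume()] returns an [intensity_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), code = NULL)
  if (all(abs(affine[1:3, 1:3]) < 1e-12))
    stop("NIfTI volume carries no usable affine", call. = FALSE)
  vox <- array(as.numeric(img), dim = dim(img))
  read_mask <- function(p) {
    if (!file.exists(p)) return(NULL)
    m <- RNifti::readNifti(p)
    if (!identical(dim(m)[1:3], dim(vox))) stop("mask shape mismatch: ", p,
                                                call. = FALSE)
    array(as.numeric(m) > 0.5, dim = dim(vox))
  }
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  intensity_volume(vox, unclass(affine)[1:4, 1:4],
                   stalk_mask = read_mask(paste0(stem, "_stalk.nii.gz")),
                   lumen_mask = read_mask(paste0(stem, "_lumen.nii.gz")))
}

#' @rdname read_volume
#' @param vol an [intensity_volume()].
#' @export
write_volume <- function(vol, path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  wr <- function(arr, p) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
    img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
    img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
    RNifti::writeNifti(img, p)
  }
  wr(vol$voxels, path)
  if (any(vol$stalk_mask)) wr(vol$stalk_mask * 1L, paste0(stem, "_stalk.nii.gz"))
  if (any(vol$lumen_mask)) wr(vol$lumen_mask * 1L, paste0(stem, "_lumen.nii.gz"))
  invisible(NULL)
}
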