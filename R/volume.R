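#' 3D scalar volume with physical geometry
#'
#' A minimal raster container: a 3D array of values (Hounsfield units for CT
#' phantoms), a physical voxel spacing and a world origin. World coordinates
#' are in millimetres; the centre of voxel `(i, j, k)` (0-based) sits at
#' `origin + c(i, j, k) * spacing`.
#'
#' @param voxels 3D numeric or logical array.
#' @param spacing_mm positive length-3 numeric, voxel spacing in mm.
#' @param origin_mm length-3 numeric, world position of voxel (0,0,0) in mm.
#' @return An object of class `aq_volume` (or `aq_mask` for logical voxels).
#' @export
aq_volume <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3L, length(spacing_mm) == 3L,
            length(origin_mm) == 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing must be strictly positive and finite")
  v <- structure(
    list(voxels = voxels, spacing = as.numeric(spacing_mm),
         origin = as.numeric(origin_mm)),
    class = if (is.logical(voxels)) c("aq_mask", "aq_volume") else "aq_volume")
  v
}

#' Binary mask on a raster grid
#'
#' @param voxels logical 3D array.
#' @inheritParams aq_volume
#' @return An `aq_mask` object.
#' @export
aq_mask <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  storage.mode(voxels) <- "logical"
  aq_volume(voxels, spacing_mm, origin_mm)
}

#' @export
print.aq_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              class(x)[1L], d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (is.logical(x$voxels)) {
    cat(sprintf("  foreground voxels: %d (%.2f%%)\n", sum(x$voxels),
                100 * mean(x$voxels)))
  } else {
    cat(sprintf("  value range: [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  }
  invisible(x)
}

vol_dims <- function(v) dim(v$voxels)

#' Convert world (mm) coordinates to continuous 0-based voxel indices
#' @param v an `aq_volume`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_index <- function(v, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, v$origin, "-"), 2, v$spacing, "/")
}

#' Convert 0-based voxel indices to world (mm) coordinates
#' @inheritParams world_to_index
#' @param idx n x 3 matrix of (continuous) 0-based voxel indices.
#' @export
index_to_world <- function(v, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, v$spacing, "*"), 2, v$origin, "+")
}

#' Sample a volume at arbitrary world points
#'
#' @param v an `aq_volume` or `aq_mask`.
#' @param pts_mm n x 3 matrix of world coordinates in mm.
#' @param method "linear" (trilinear) or "nearest".
#' @param fill value returned outside the grid.
#' @return numeric vector of sampled values.
#' @export
sample_volume <- function(v, pts_mm, method = c("linear", "nearest"),
                          fill = NA_real_) {
  method <- match.arg(method)
  idx <- world_to_index(v, pts_mm)
  vox <- as.numeric(v$voxels)
  if (method == "linear")
    .cpp_trilinear(vox, dim(v$voxels), idx, fill)
  else
    .cpp_nearest(vox, dim(v$voxels), idx, fill)
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear resampling onto an isotropic grid that preserves the physical
#' extent of the input to within one voxel. Masks are resampled on their
#' 0/1 indicator and re-thresholded at 0.5.
#'
#' @param v an `aq_volume` or `aq_mask`.
#' @param target_mm positive isotropic target spacing in mm.
#' @return A resampled volume of the same class.
#' @export
resample_isotropic <- function(v, target_mm) {
  stopifnot(is.numeric(target_mm), length(target_mm) == 1L, target_mm > 0)
  if (any(!is.finite(v$voxels))) stop("volume contains non-finite voxels")
  d <- vol_dims(v)
  # grid-count convention: 128 voxels at 1 mm -> 64 voxels at 2 mm; the
  # physical extent is preserved to within one target voxel
  nd <- pmax(2L, as.integer(round(d * v$spacing / target_mm)))
  grid <- expand.grid(x = seq_len(nd[1]) - 1, y = seq_len(nd[2]) - 1,
                      z = seq_len(nd[3]) - 1)
  pts <- index_to_world(
    aq_volume(array(0, c(2, 2, 2)), rep(target_mm, 3), v$origin),
    as.matrix(grid))
  is_mask <- is.logical(v$voxels)
  vals <- sample_volume(v, pts, method = "linear",
                        fill = if (is_mask) 0 else min(v$voxels))
  arr <- array(vals, nd)
  if (is_mask)
    aq_mask(arr >= 0.5, rep(target_mm, 3), v$origin)
  else
    aq_volume(arr, rep(target_mm, 3), v$origin)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] mapping
#' between `aq_volume` and the NIfTI-1 sform geometry.
#'
#' @param path file path, conventionally `.nii` or `.nii.gz`.
#' @return `read_volume` returns an `aq_volume` (or `aq_mask` when the file
#'   stores only 0/1 values and `as_mask = TRUE`).
#' @param as_mask logical; threshold the data at 0.5 into a mask.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff)[1:3])
  if (any(spacing == 0)) spacing <- RNifti::pixdim(img)[1:3]
  origin <- aff[1:3, 4]
  if (as_mask) aq_mask(arr > 0.5, spacing, origin)
  else aq_volume(arr, spacing, origin)
}

#' @rdname read_volume
#' @param v an `aq_volume` or `aq_mask` to write.
#' @export
write_volume <- function(v, path) {
  arr <- v$voxels
  if (is.logical(arr)) {
    arr2 <- array(0L, dim(arr)); arr2[arr] <- 1L; arr <- arr2
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- v$spacing
  sform <- rbind(cbind(diag(v$spacing), v$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(sform, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
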