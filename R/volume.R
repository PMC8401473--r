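#' 3D scalar volume with world-coordinate geometry
#'
#' A `Volume` carries a 3D numeric array together with its voxel spacing (mm),
#' world origin (mm) and an anatomical axis label. World coordinates follow the
#' convention `world = origin + index0 * spacing` with 0-based voxel indices,
#' so `origin` is the world position of the centre of voxel `[1,1,1]`.
#'
#' @param data 3D numeric array of voxel values.
#' @param spacing length-3 positive numeric, mm per voxel along each axis.
#' @param origin length-3 numeric, world mm of the first voxel centre.
#' @param axes character axis label (e.g. `"RAS"`); stored, not interpreted.
#' @return An object of class `breastfem_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0), axes = "RAS") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive and finite on all axes")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin), axes = axes),
    class = "breastfem_volume"
  )
}

#' @export
print.breastfem_volume <- function(x, ...) {
  cat("<Volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm [",
      x$axes, "]\n", sep = "")
  invisible(x)
}

#' Label map aligned to a volume
#'
#' Integer tissue classes on the same grid as a [volume()]. The legend is
#' fixed: 0 background, 1 adipose, 2 fibro-glandular, 3 lesion, 4 chest wall.
#'
#' @param data 3D integer array of labels.
#' @inheritParams volume
#' @return An object of class `breastfem_labelmap` (also a `breastfem_volume`).
#' @export
label_map <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0), axes = "RAS") {
  v <- volume(data, spacing, origin, axes)
  bad <- setdiff(unique(as.integer(data)), 0:4)
  if (length(bad)) stop("labels outside legend 0..4: ", paste(bad, collapse = ", "))
  v$legend <- c(`0` = "background", `1` = "adipose", `2` = "fibro-glandular",
                `3` = "lesion", `4` = "chest wall")
  class(v) <- c("breastfem_labelmap", class(v))
  v
}

#' Label legend constants
#' @export
LABELS <- c(background = 0L, adipose = 1L, gland = 2L, lesion = 3L, chest_wall = 4L)

#' Convert 0-based voxel indices to world mm
#' @param v a [volume()]
#' @param idx N x 3 matrix of 0-based (possibly fractional) voxel indices
#' @return N x 3 matrix of world coordinates in mm
#' @export
voxel_to_world <- function(v, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, v$spacing, `*`), 2, v$origin, `+`)
}

#' Convert world mm to 0-based fractional voxel indices
#' @inheritParams voxel_to_world
#' @param pts N x 3 matrix of world coordinates in mm
#' @export
world_to_voxel <- function(v, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, v$origin, `-`), 2, v$spacing, `/`)
}

# Trilinear sampling of a 3D array at fractional 0-based voxel coordinates.
# Points outside the grid return `fill` (or are clamped when clamp = TRUE).
sample_trilinear_idx <- function(arr, t, fill = 0, clamp = FALSE) {
  d <- dim(arr)
  t <- rbind(t)
  if (clamp) for (k in 1:3) t[, k] <- pmin(pmax(t[, k], 0), d[k] - 1)
  inside <- t[, 1] >= 0 & t[, 1] <= d[1] - 1 &
            t[, 2] >= 0 & t[, 2] <= d[2] - 1 &
            t[, 3] >= 0 & t[, 3] <= d[3] - 1
  out <- rep(as.numeric(fill), nrow(t))
  if (!any(inside)) return(out)
  ti <- t[inside, , drop = FALSE]
  i0 <- pmin(floor(ti[, 1]), d[1] - 2); fx <- ti[, 1] - i0
  j0 <- pmin(floor(ti[, 2]), d[2] - 2); fy <- ti[, 2] - j0
  k0 <- pmin(floor(ti[, 3]), d[3] - 2); fz <- ti[, 3] - k0
  # degenerate single-slab axes
  if (d[1] == 1) { i0 <- rep(0, length(fx)); fx <- fx * 0 }
  if (d[2] == 1) { j0 <- rep(0, length(fy)); fy <- fy * 0 }
  if (d[3] == 1) { k0 <- rep(0, length(fz)); fz <- fz * 0 }
  lin <- function(di, dj, dk) {
    arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  dx1 <- if (d[1] > 1) 1 else 0; dy1 <- if (d[2] > 1) 1 else 0; dz1 <- if (d[3] > 1) 1 else 0
  val <-
    lin(0, 0, 0)       * (1 - fx) * (1 - fy) * (1 - fz) +
    lin(dx1, 0, 0)     * fx       * (1 - fy) * (1 - fz) +
    lin(0, dy1, 0)     * (1 - fx) * fy       * (1 - fz) +
    lin(dx1, dy1, 0)   * fx       * fy       * (1 - fz) +
    lin(0, 0, dz1)     * (1 - fx) * (1 - fy) * fz +
    lin(dx1, 0, dz1)   * fx       * (1 - fy) * fz +
    lin(0, dy1, dz1)   * (1 - fx) * fy       * fz +
    lin(dx1, dy1, dz1) * fx       * fy       * fz
  out[inside] <- val
  out
}

#' Sample a volume at world-mm points by trilinear interpolation
#' @param v a [volume()]
#' @param pts N x 3 matrix of world mm
#' @param fill value returned outside the grid
#' @param clamp clamp out-of-grid points to the boundary instead
#' @return numeric vector of length N
#' @export
sample_volume <- function(v, pts, fill = 0, clamp = FALSE) {
  sample_trilinear_idx(v$data, world_to_voxel(v, pts), fill = fill, clamp = clamp)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around RNifti preserving spacing and origin. The origin is
#' carried in the NIfTI sform/qform translation.
#'
#' @param v a [volume()] or [label_map()]
#' @param path file path (`.nii` or `.nii.gz`)
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  # affine: diagonal spacing, translation = origin
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param path file path to read
#' @param labels logical, return a [label_map()] instead of a [volume()]
#' @export
read_volume <- function(path, labels = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  arr <- array(as.numeric(img), dim = dim(img))
  if (labels) label_map(array(as.integer(round(arr)), dim(arr)), sp, org)
  else volume(arr, sp, org)
}
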